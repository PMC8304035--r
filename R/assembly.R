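#' Construct an assembly of contigs
#'
#' An `assembly` is an ordered set of named contig sequences together with
#' their length statistics. It is the unit every other stage of the package
#' operates on: candidate assembler outputs, merged consensus assemblies and
#' simulated truth transcriptomes are all `assembly` objects.
#'
#' @param ids Character vector of contig identifiers. Must be nonempty,
#'   unique, and contain no empty strings.
#' @param sequences Character vector of nucleotide sequences (same length as
#'   `ids`). Stored uppercase; `N` is the only ambiguity code retained —
#'   other IUPAC ambiguity codes are mapped to `N` with a warning.
#' @param label Single string naming the assembly (assembler or combination
#'   name).
#'
#' @return An object of class `assembly`: a list with elements `label`,
#'   `ids`, `sequences`, `lengths` and `total_bases`.
#' @examples
#' a <- assembly(c("c1", "c2"), c("ACGT", "GGGTTT"), label = "demo")
#' a$total_bases
#' @export
assembly <- function(ids, sequences, label = "assembly") {
  stopifnot(is.character(ids), is.character(sequences),
            length(ids) == length(sequences), is.character(label),
            length(label) == 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("contig ids must be nonempty strings")
  if (anyDuplicated(ids))
    stop("duplicate contig id: ", ids[duplicated(ids)][1L])
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTNRYSWKMBDHV]", sequences)
  if (any(bad))
    stop("non-nucleotide characters in contig ", ids[bad][1L])
  amb <- grepl("[RYSWKMBDHV]", sequences)
  if (any(amb)) {
    warning("ambiguity codes other than N mapped to N in ",
            sum(amb), " contig(s)")
    sequences[amb] <- gsub("[RYSWKMBDHV]", "N", sequences[amb])
  }
  lens <- nchar(sequences)
  if (any(lens < 1L)) stop("zero-length contig: ", ids[lens < 1L][1L])
  structure(list(label = label, ids = ids, sequences = sequences,
                 lengths = lens, total_bases = sum(as.numeric(lens))),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly '%s': %d contigs, %s bp, n50 %s>\n",
              x$label, length(x$ids), format(x$total_bases, big.mark = ","),
              if (length(x$ids)) nx_length(x, 0.5) else NA))
  invisible(x)
}

#' @export
length.assembly <- function(x) length(x$ids)

#' Read a FASTA file into an assembly
#'
#' Tolerates line-wrapped records, lower case and blank lines. Sequences are
#' uppercased; IUPAC ambiguity codes other than `N` are mapped to `N` with a
#' warning. Duplicate header ids and non-nucleotide characters are errors
#' (the latter reported with the offending line number).
#'
#' @param path Path to a FASTA file.
#' @param label Assembly label; defaults to the file stem.
#' @return An [assembly].
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("no records in FASTA file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  seqs <- unname(toupper(as.character(set)))
  bad <- regexpr("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("non-nucleotide character in record '", ids[i], "' near line ",
         fasta_offending_line(path, ids[i], bad[i]))
  }
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  assembly(ids, seqs, label = label)
}

# locate the file line holding the bad character (pos = offset into the
# concatenated record sequence)
fasta_offending_line <- function(path, id, pos) {
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, ">"))
  start <- hdr[match(id, sub("\\s.*$", "", sub("^>", "", lines[hdr])))]
  if (is.na(start)) return(NA_integer_)
  i <- start + 1L
  seen <- 0L
  while (i <= length(lines) && !startsWith(lines[i], ">")) {
    seen <- seen + nchar(gsub("\\s", "", lines[i]))
    if (seen >= pos) return(i)
    i <- i + 1L
  }
  NA_integer_
}

#' Write an assembly to FASTA
#'
#' Records are written in contig order, uppercase, wrapped at 80 columns,
#' with bare `>id` headers. `read_fasta(write_fasta(a, p))` reproduces the
#' ids, order and sequences of `a`.
#'
#' @param x An [assembly]; must be nonempty.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "assembly"))
  if (length(x$ids) == 0L) stop("cannot write an empty assembly")
  set <- Biostrings::DNAStringSet(x$sequences)
  names(set) <- x$ids
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta",
                              width = 80L)
  invisible(path)
}

#' Nx contig length statistic
#'
#' The length of the first contig, traversing contigs longest-first, at
#' which the cumulative base count reaches at least `fraction` of the total:
#' `fraction = 0.5` gives the N50, `0.9` the N90. Equal-length contigs are
#' consumed in input order and the returned value is always a contig length
#' actually present in the assembly.
#'
#' @param x An [assembly]; must be nonempty.
#' @param fraction Proportion in (0, 1].
#' @return Integer base-pair length.
#' @examples
#' a <- assembly(c("a", "b", "c"),
#'               c(strrep("A", 100), strrep("C", 50), strrep("G", 50)))
#' nx_length(a, 0.5)  # 100
#' nx_length(a, 0.9)  # 50
#' @export
nx_length <- function(x, fraction) {
  stopifnot(inherits(x, "assembly"), is.numeric(fraction),
            length(fraction) == 1L, fraction > 0, fraction <= 1)
  if (length(x$ids) == 0L) stop("nx_length of an empty assembly")
  lens <- sort(x$lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(lens))
  lens[which(cum >= fraction * x$total_bases)[1L]]
}

#' Drop contigs shorter than a length threshold
#'
#' Keeps exactly the contigs with length `>= min_len`, preserving the
#' original order. An empty result is legal.
#'
#' @param x An [assembly].
#' @param min_len Minimum contig length in bp (kept at the boundary).
#' @return A filtered [assembly] (possibly with zero contigs).
#' @export
filter_by_length <- function(x, min_len) {
  stopifnot(inherits(x, "assembly"), is.numeric(min_len),
            length(min_len) == 1L, min_len >= 0)
  keep <- x$lengths >= min_len
  structure(list(label = x$label, ids = x$ids[keep],
                 sequences = x$sequences[keep], lengths = x$lengths[keep],
                 total_bases = sum(as.numeric(x$lengths[keep]))),
            class = "assembly")
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
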