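#' Marker set for completeness assessment
#'
#' A set of conserved reference sequences (in spirit, single-copy ortholog
#' markers) against which assembly completeness is scored. Each marker must
#' be at least 100 bp and ids must be unique.
#'
#' @param ids Character vector of marker ids (unique).
#' @param sequences Character vector of nucleotide sequences, all >= 100 bp.
#' @return A list of class `marker_set` with `ids`, `sequences`, `count`.
#' @export
marker_set <- function(ids, sequences) {
  stopifnot(is.character(ids), is.character(sequences),
            length(ids) == length(sequences))
  if (length(ids) == 0L) stop("marker set must be nonempty")
  if (anyDuplicated(ids)) stop("duplicate marker id: ",
                               ids[duplicated(ids)][1L])
  sequences <- toupper(sequences)
  if (any(nchar(sequences) < 100L))
    stop("every marker must be at least 100 bp")
  structure(list(ids = ids, sequences = sequences, count = length(ids)),
            class = "marker_set")
}

#' Longest common substring lengths
#'
#' Exact longest common substring length between `pattern` and each element
#' of `subjects`, computed with a suffix automaton over the pattern.
#'
#' @param pattern Single nucleotide string.
#' @param subjects Character vector of nucleotide strings.
#' @return Integer vector of LCS lengths, one per subject.
#' @export
lcs_lengths <- function(pattern, subjects) {
  stopifnot(is.character(pattern), length(pattern) == 1L,
            is.character(subjects))
  lcs_lengths_cpp(pattern, subjects)
}

#' Marker recovery (completeness proxy)
#'
#' For each marker the best single-contig coverage fraction is the longest
#' exact common substring with any contig — on either strand — divided by
#' the marker length. A marker is *complete* if that fraction reaches
#' `complete_frac`, *fragmented* if it falls in
#' `[fragment_frac, complete_frac)` and *missing* otherwise. A marker
#' complete in two or more distinct contigs is additionally counted as
#' *duplicated* (duplicated is a subset of complete).
#'
#' @param x A nonempty [assembly].
#' @param markers A [marker_set].
#' @param complete_frac Coverage needed to call a marker complete
#'   (default 0.95).
#' @param fragment_frac Coverage needed to call a marker fragmented
#'   (default 0.30; must be < `complete_frac`).
#' @return Named integer vector: `complete`, `duplicated`, `fragmented`,
#'   `missing`. `complete + fragmented + missing == markers$count`.
#' @export
marker_recovery <- function(x, markers, complete_frac = 0.95,
                            fragment_frac = 0.30) {
  stopifnot(inherits(x, "assembly"), inherits(markers, "marker_set"),
            fragment_frac < complete_frac)
  if (length(x$ids) == 0L)  # nothing recovered from an empty assembly
    return(c(complete = 0L, duplicated = 0L, fragmented = 0L,
             missing = markers$count))
  complete <- duplicated_n <- fragmented <- 0L
  for (i in seq_len(markers$count)) {
    m <- markers$sequences[i]
    cov_fwd <- lcs_lengths(m, x$sequences)
    cov_rev <- lcs_lengths(revcomp(m), x$sequences)
    cov <- pmax(cov_fwd, cov_rev) / nchar(m)
    best <- max(cov)
    if (best >= complete_frac) {
      complete <- complete + 1L
      if (sum(cov >= complete_frac) >= 2L)
        duplicated_n <- duplicated_n + 1L
    } else if (best >= fragment_frac) {
      fragmented <- fragmented + 1L
    }
  }
  c(complete = complete, duplicated = duplicated_n, fragmented = fragmented,
    missing = markers$count - complete - fragmented)
}

# all canonical k-mers of a set of sequences (canonical = lexicographic min
# of a k-mer and its reverse complement)
canonical_kmers <- function(seqs, k) {
  kmers <- unlist(lapply(seqs, seq_words, w = k), use.names = FALSE)
  if (length(kmers) == 0L) return(character(0))
  pmin(kmers, revcomp(kmers))
}

#' Read-representation rate (alignment-rate proxy)
#'
#' Measures how much of the raw read data an assembly explains: a read is
#' *represented* if at least `hit_frac` of its canonical k-mers occur in the
#' assembly's canonical k-mer set. Returns the percentage of represented
#' reads among those examined. Reads shorter than `k` are skipped and
#' tallied in the `skipped` attribute; if every read is skipped an error is
#' raised.
#'
#' @param x A nonempty [assembly].
#' @param reads Path to a FASTQ file.
#' @param k Odd k-mer size (default 31).
#' @param hit_frac Fraction of a read's k-mers that must be present
#'   (default 0.8).
#' @param sample_limit Maximum reads examined (default 1e5).
#' @return Percentage in \[0, 100\] with attribute `skipped`.
#' @export
read_representation <- function(x, reads, k = 31L, hit_frac = 0.80,
                                sample_limit = 100000L) {
  stopifnot(inherits(x, "assembly"), k %% 2 == 1, hit_frac > 0,
            hit_frac <= 1)
  recs <- read_fastq_records(reads, sample_limit)
  lens <- nchar(recs$seq)
  usable <- lens >= k
  skipped <- sum(!usable)
  if (!any(usable))
    stop("all ", length(lens), " reads are shorter than k = ", k)
  kset <- unique(canonical_kmers(x$sequences, k))
  seqs <- recs$seq[usable]
  n_kmers <- lens[usable] - k + 1L
  read_idx <- rep.int(seq_along(seqs), n_kmers)
  kmers <- unlist(lapply(seqs, seq_words, w = k), use.names = FALSE)
  hit <- pmin(kmers, revcomp(kmers)) %in% kset
  frac <- vapply(split(hit, read_idx), mean, numeric(1))
  structure(100 * mean(frac >= hit_frac), skipped = skipped)
}

#' Assess one assembly
#'
#' Produces the raw assessment metrics for a candidate: read-representation
#' rate (alignment proxy), marker recovery counts (completeness proxy) and
#' the N50/N90 contig statistics. The result has the same shape whether the
#' metrics come from these proxies or from real-tool summaries parsed with
#' [parse_busco_summary()] / [parse_alignment_summary()].
#'
#' @param x A nonempty [assembly].
#' @param markers A [marker_set].
#' @param reads Path to a FASTQ file.
#' @param dataset Dataset identifier recorded in the output.
#' @param candidate Candidate label (defaults to the assembly label).
#' @param ... Passed on to [marker_recovery()] and [read_representation()].
#' @return A one-row `data.frame` (a *metric record*) with columns
#'   `candidate`, `dataset`, `alignment_rate`, `complete`, `duplicated`,
#'   `fragmented`, `missing`, `n50`, `n90`.
#' @export
assess <- function(x, markers, reads, dataset, candidate = x$label, ...) {
  mr <- marker_recovery(x, markers, ...)
  ar <- read_representation(x, reads)
  metric_record(candidate = candidate, dataset = dataset,
                alignment_rate = as.numeric(ar),
                complete = mr[["complete"]], duplicated = mr[["duplicated"]],
                fragmented = mr[["fragmented"]], missing = mr[["missing"]],
                n50 = nx_length(x, 0.5), n90 = nx_length(x, 0.9))
}

#' Construct a metric record
#'
#' @param candidate,dataset Identifiers.
#' @param alignment_rate Percentage in \[0, 100\].
#' @param complete,duplicated,fragmented,missing Marker counts
#'   (duplicated <= complete).
#' @param n50,n90 Contig length statistics (n90 <= n50).
#' @return A one-row `data.frame`.
#' @export
metric_record <- function(candidate, dataset, alignment_rate, complete,
                          duplicated, fragmented, missing, n50, n90) {
  stopifnot(alignment_rate >= 0, alignment_rate <= 100,
            duplicated <= complete, n90 <= n50)
  data.frame(candidate = candidate, dataset = dataset,
             alignment_rate = alignment_rate, complete = as.integer(complete),
             duplicated = as.integer(duplicated),
             fragmented = as.integer(fragmented),
             missing = as.integer(missing),
             n50 = as.integer(n50), n90 = as.integer(n90),
             stringsAsFactors = FALSE)
}

#' Write metric records as TSV
#'
#' Fixed column order (candidate, dataset, alignment_rate, complete,
#' duplicated, fragmented, missing, n50, n90); floats to 2 decimals.
#'
#' @param records Metric-record `data.frame` (rows from [assess()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path) {
  out <- records[, c("candidate", "dataset", "alignment_rate", "complete",
                     "duplicated", "fragmented", "missing", "n50", "n90")]
  out$alignment_rate <- sprintf("%.2f", out$alignment_rate)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse a BUSCO short-summary text
#'
#' Extracts the `C:…%[S:…%,D:…%],F:…%,M:…%` results line and the absolute
#' count lines from a BUSCO short summary.
#'
#' @param text The summary as a single string or character vector of lines.
#' @return A list with `complete_pct`, `complete`, `duplicated`,
#'   `fragmented`, `missing`, `total`.
#' @export
parse_busco_summary <- function(text) {
  text <- paste(text, collapse = "\n")
  line <- regmatches(text, regexpr(
    "C:[0-9.]+%\\[S:[0-9.]+%,D:[0-9.]+%\\],F:[0-9.]+%,M:[0-9.]+%[^\n]*",
    text))
  if (length(line) == 0L)
    stop("no BUSCO results block found in: ",
         substr(gsub("\n", " ", text), 1L, 80L))
  pct <- as.numeric(regmatches(line, gregexpr("[0-9.]+(?=%)", line,
                                              perl = TRUE))[[1L]])
  grab <- function(pat) {
    m <- regmatches(text, regexpr(paste0("[0-9]+(?=\\s+", pat, ")"), text,
                                  perl = TRUE))
    if (length(m) == 0L) NA_integer_ else as.integer(m)
  }
  counts <- list(complete = grab("Complete BUSCOs"),
                 duplicated = grab("Complete and duplicated BUSCOs"),
                 fragmented = grab("Fragmented BUSCOs"),
                 missing = grab("Missing BUSCOs"),
                 total = grab("Total BUSCO groups searched"))
  c(list(complete_pct = pct[1L]), counts)
}

#' Parse an aligner summary for the overall alignment rate
#'
#' Looks for the line ending `"% overall alignment rate"` and returns the
#' percentage exactly as printed.
#'
#' @param text Summary text (string or lines).
#' @return Numeric percentage.
#' @export
parse_alignment_summary <- function(text) {
  text <- paste(text, collapse = "\n")
  m <- regmatches(text,
                  regexpr("[0-9.]+(?=% overall alignment rate)", text,
                          perl = TRUE))
  if (length(m) == 0L)
    stop("no 'overall alignment rate' line found")
  as.numeric(m)
}
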