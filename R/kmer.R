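#' Profile a FASTQ file
#'
#' Scans up to `sample_limit` records of a FASTQ file (4-line records) and
#' reports the read count examined and the minimum and maximum read length.
#' These statistics drive the adaptive k-mer plan.
#'
#' @param path Path to a FASTQ file (uncompressed or gzip).
#' @param sample_limit Maximum number of records to examine (default 1e5).
#' @return A list of class `read_stats` with `read_count`,
#'   `min_read_length`, `max_read_length`.
#' @export
profile_reads <- function(path, sample_limit = 100000L) {
  stopifnot(is.numeric(sample_limit), sample_limit >= 1)
  recs <- read_fastq_records(path, sample_limit)
  lens <- nchar(recs$seq)
  read_stats(read_count = length(lens), min_read_length = min(lens),
             max_read_length = max(lens))
}

#' Read statistics
#'
#' @param read_count Number of reads examined (>= 1).
#' @param min_read_length,max_read_length Read length bounds in bp.
#' @return A list of class `read_stats`.
#' @export
read_stats <- function(read_count, min_read_length, max_read_length) {
  stopifnot(read_count >= 1, min_read_length >= 1,
            min_read_length <= max_read_length)
  structure(list(read_count = as.integer(read_count),
                 min_read_length = as.integer(min_read_length),
                 max_read_length = as.integer(max_read_length)),
            class = "read_stats")
}

# 4-line-record FASTQ reader with record-level validation; Phred qualities
# are ignored beyond the length check.
read_fastq_records <- function(path, sample_limit = Inf) {
  if (!file.exists(path)) stop("file not found: ", path)
  n_lines <- if (is.finite(sample_limit)) 4L * as.integer(sample_limit) else -1L
  lines <- readLines(path, n = n_lines, warn = FALSE)
  while (length(lines) > 0L && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) stop("empty FASTQ file: ", path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ record ", length(lines) %/% 4L + 1L,
         ": truncated record")
  m <- matrix(lines, nrow = 4L)
  bad_hdr <- !startsWith(m[1L, ], "@")
  if (any(bad_hdr))
    stop("malformed FASTQ record ", which(bad_hdr)[1L],
         ": header does not start with '@'")
  bad_sep <- !startsWith(m[3L, ], "+")
  if (any(bad_sep))
    stop("malformed FASTQ record ", which(bad_sep)[1L],
         ": separator line does not start with '+'")
  mismatch <- nchar(m[2L, ]) != nchar(m[4L, ])
  if (any(mismatch))
    stop("malformed FASTQ record ", which(mismatch)[1L],
         ": sequence/quality length mismatch")
  list(id = sub("^@", "", m[1L, ]), seq = toupper(m[2L, ]), qual = m[4L, ])
}

# nearest odd integer, ties rounding upward
round_odd <- function(x) as.integer(2 * floor(x / 2) + 1)

#' Adaptive k-mer plan
#'
#' Generates up to five odd k-mer sizes for a de Bruijn graph assembler: a
#' fixed minimum (21 by default) plus the three interior quartile points and
#' the maximum of the span from the minimum up to a read-length-derived top.
#' The top `k_max` is the largest odd integer not exceeding
#' `max_read_length - 1` (and an optional assembler-specific `cap`), so
#' every read contains at least two k-mers. Quartile points are rounded to
#' the nearest odd integer, ties upward; duplicates after rounding are
#' collapsed. If `k_max <= k_min` the plan collapses to a singleton.
#'
#' @param stats A [read_stats] object.
#' @param k_min Minimum k-mer size; odd, >= 15. Default 21.
#' @param cap Optional assembler-specific upper bound on k.
#' @return A list of class `kmer_plan` with `k_values`, `k_min`, `k_max`.
#' @examples
#' adaptive_kmers(read_stats(10, 100, 100))$k_values  # 21 41 61 79 99
#' @export
adaptive_kmers <- function(stats, k_min = 21L, cap = NULL) {
  stopifnot(inherits(stats, "read_stats"), k_min %% 2 == 1, k_min >= 15)
  if (stats$max_read_length < 16L)
    stop("reads too short for k-mer planning (max read length ",
         stats$max_read_length, ")")
  top <- stats$max_read_length - 1L
  if (!is.null(cap)) top <- min(top, as.integer(cap))
  k_max <- if (top %% 2L == 1L) top else top - 1L
  if (k_max <= k_min) {
    k <- max(15L, min(k_min, k_max))
    return(kmer_plan(k, k_min = k_min, k_max = k))
  }
  q <- k_min + (1:3) / 4 * (k_max - k_min)
  ks <- unique(c(as.integer(k_min), round_odd(q), k_max))
  kmer_plan(sort(ks), k_min = k_min, k_max = k_max)
}

kmer_plan <- function(k_values, k_min, k_max) {
  stopifnot(all(k_values %% 2 == 1), !is.unsorted(k_values, strictly = TRUE),
            length(k_values) <= 5L, all(k_values <= k_max))
  structure(list(k_values = as.integer(k_values), k_min = as.integer(k_min),
                 k_max = as.integer(k_max)),
            class = "kmer_plan")
}

#' @export
print.kmer_plan <- function(x, ...) {
  cat(sprintf("<kmer_plan: %s>\n", paste(x$k_values, collapse = ",")))
  invisible(x)
}

#' Default single-k assemblers
#'
#' Assemblers run at their single default k-mer size rather than on the
#' adaptive ladder (they accept one k and are slow enough that a five-k
#' sweep is impractical): BinPacker 25, Shannon Cpp 25, TransLig 31,
#' Trinity 25.
#'
#' @return Named integer vector mapping assembler name to its default k.
#' @export
default_k_table <- function() {
  c(BinPacker = 25L, `Shannon Cpp` = 25L, Shannon = 25L,
    TransLig = 31L, Trinity = 25L)
}

#' Per-assembler k-mer cap defaults
#'
#' @return Named integer vector of known upper bounds on k (MEGAHIT 255);
#'   assemblers absent from the table are unbounded.
#' @export
default_k_caps <- function() c(MEGAHIT = 255L)

#' K-mer plan for a named assembler
#'
#' Single-k assemblers in `fixed_k_table` get a singleton plan with their
#' default k; every other assembler gets the adaptive plan from
#' [adaptive_kmers()], bounded by its cap if one is known.
#'
#' @param stats A [read_stats] object.
#' @param assembler_name Assembler identifier.
#' @param fixed_k_table Named map assembler -> fixed k
#'   (default [default_k_table()]).
#' @param caps Named map assembler -> max k (default [default_k_caps()]).
#' @return A `kmer_plan`.
#' @export
plan_for_assembler <- function(stats, assembler_name,
                               fixed_k_table = default_k_table(),
                               caps = default_k_caps()) {
  stopifnot(is.character(assembler_name), length(assembler_name) == 1L)
  if (assembler_name %in% names(fixed_k_table)) {
    k <- as.integer(fixed_k_table[[assembler_name]])
    return(kmer_plan(k, k_min = k, k_max = k))
  }
  cap <- if (assembler_name %in% names(caps)) caps[[assembler_name]] else NULL
  adaptive_kmers(stats, cap = cap)
}
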