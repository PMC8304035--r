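#' Consensus construction parameters
#'
#' @param min_contig_length Contigs shorter than this are dropped before
#'   redundancy reduction (default 200 bp, the usual transcriptome
#'   convention).
#' @param identity_threshold Greedy clustering identity cutoff over the
#'   query (shorter) sequence, in (0.5, 1] (default 0.95).
#' @param word_size Exact-word length used to shortlist candidate
#'   representatives (default 11).
#' @param revcomp Also match queries against the reverse complement of
#'   retained representatives (default `TRUE`; transcripts from unstranded
#'   libraries).
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(min_contig_length = 200L,
                             identity_threshold = 0.95,
                             word_size = 11L,
                             revcomp = TRUE) {
  stopifnot(min_contig_length >= 0, identity_threshold > 0.5,
            identity_threshold <= 1, word_size >= 4,
            is.logical(revcomp), length(revcomp) == 1L)
  structure(list(min_contig_length = as.integer(min_contig_length),
                 identity_threshold = identity_threshold,
                 word_size = as.integer(word_size), revcomp = revcomp),
            class = "consensus_config")
}

#' Merge assemblies into one contig pool
#'
#' Concatenates the contigs of all input assemblies in order. Contig ids are
#' prefixed with their source assembly's label (`"label|id"`) so ids stay
#' unique; total bases are additive; inputs are not modified.
#'
#' @param assemblies Nonempty list of [assembly] objects.
#' @param label Label for the merged assembly.
#' @return An [assembly].
#' @export
merge_assemblies <- function(assemblies, label = "merged") {
  if (!is.list(assemblies) || length(assemblies) == 0L)
    stop("merge requires at least one assembly")
  stopifnot(all(vapply(assemblies, inherits, logical(1), "assembly")))
  ids <- unlist(lapply(assemblies, function(a) paste0(a$label, "|", a$ids)))
  seqs <- unlist(lapply(assemblies, `[[`, "sequences"))
  assembly(ids, seqs, label = label)
}

# word -> positions lookup over a single sequence
seq_words <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0))
  substring(s, 1:(n - w + 1L), w:n)
}

# best ungapped identity of query against one representative (one strand):
# candidate diagonals come from shared words; on each diagonal the full
# overlap is compared and matches counted. Exact containment short-circuits.
ungapped_identity_1 <- function(qc, q, qw, rep_seq, rc, rpos) {
  if (grepl(q, rep_seq, fixed = TRUE)) return(1)
  hits <- which(qw %in% names(rpos))
  if (length(hits) == 0L) return(0)
  offs <- unique(unlist(lapply(hits, function(i) rpos[[qw[i]]] - i),
                        use.names = FALSE))
  nq <- length(qc)
  nr <- length(rc)
  best <- 0L
  for (d in offs) {
    iq <- max(1L, 1L - d):min(nq, nr - d)
    m <- sum(qc[iq] == rc[iq + d])
    if (m > best) best <- m
  }
  best / nq
}

#' Ungapped identity of a query against a representative sequence
#'
#' Identity over the query's length: matched bases of the best ungapped
#' diagonal (diagonals shortlisted by shared words of `word_size`), or 1 for
#' exact substring containment; the better of the two strands when
#' `config$revcomp` is on.
#'
#' @param q Query sequence (typically the shorter of the pair).
#' @param rep_seq Representative (subject) sequence.
#' @param config A [consensus_config].
#' @return Identity in \[0, 1\].
#' @export
estimate_identity <- function(q, rep_seq, config = consensus_config()) {
  w <- config$word_size
  rc <- strsplit(rep_seq, "", fixed = TRUE)[[1L]]
  rw <- seq_words(rep_seq, w)
  rpos <- split(seq_along(rw), rw)
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  ident <- ungapped_identity_1(qc, q, seq_words(q, w), rep_seq, rc, rpos)
  if (config$revcomp && ident < 1) {
    qr <- revcomp(q)
    ident <- max(ident,
                 ungapped_identity_1(strsplit(qr, "", fixed = TRUE)[[1L]],
                                     qr, seq_words(qr, w), rep_seq, rc,
                                     rpos))
  }
  ident
}

#' Greedy redundancy reduction
#'
#' CD-HIT-style incremental clustering: contigs are processed in
#' length-descending order (ties broken by id, ascending) and each contig is
#' compared to already-retained representatives sharing at least one exact
#' word of `word_size` (either strand when `revcomp` is on). A contig whose
#' estimated identity over its own length against any representative reaches
#' `identity_threshold` is discarded; otherwise it becomes a new
#' representative. Identity is the matched-base count of the best ungapped
#' diagonal (or exact substring containment) divided by the query length.
#'
#' @param x A nonempty [assembly].
#' @param config A [consensus_config].
#' @return An [assembly] of retained representatives, in retention order.
#' @export
reduce_redundancy <- function(x, config = consensus_config()) {
  stopifnot(inherits(x, "assembly"), inherits(config, "consensus_config"))
  if (length(x$ids) == 0L) stop("reduce_redundancy of an empty assembly")
  ord <- order(-x$lengths, x$ids)
  ids <- x$ids[ord]
  seqs <- x$sequences[ord]
  w <- config$word_size
  n <- length(seqs)
  # precompute per-contig pieces once: revcomp (one vectorized call),
  # character arrays, word lists and word->position lookups
  seqs_rc <- if (config$revcomp) revcomp(seqs) else NULL
  chars <- strsplit(seqs, "", fixed = TRUE)
  chars_rc <- if (config$revcomp) strsplit(seqs_rc, "", fixed = TRUE)
              else NULL
  words_fwd <- lapply(seqs, seq_words, w = w)
  words_rc <- if (config$revcomp) lapply(seqs_rc, seq_words, w = w)
              else NULL
  wordpos <- vector("list", n)  # filled only for representatives
  word_index <- new.env(parent = emptyenv(), hash = TRUE)
  best_diag <- function(qc, qw, j) {
    rpos <- wordpos[[j]]
    hits <- which(qw %in% names(rpos))
    if (length(hits) == 0L) return(0)
    offs <- unique(unlist(lapply(hits, function(h) rpos[[qw[h]]] - h),
                          use.names = FALSE))
    rc <- chars[[j]]
    nq <- length(qc)
    nr <- length(rc)
    best <- 0L
    for (d in offs) {
      iq <- max(1L, 1L - d):min(nq, nr - d)
      m <- sum(qc[iq] == rc[iq + d])
      if (m > best) best <- m
    }
    best / nq
  }
  reps <- integer(0)
  for (i in seq_len(n)) {
    q <- seqs[i]
    words <- unique(c(words_fwd[[i]],
                      if (config$revcomp) words_rc[[i]]))
    cand <- unique(unlist(lapply(words, function(wd)
      if (!is.null(word_index[[wd]])) word_index[[wd]]), use.names = FALSE))
    discard <- FALSE
    for (j in cand) {
      ident <- if (grepl(q, seqs[j], fixed = TRUE)) 1
               else best_diag(chars[[i]], words_fwd[[i]], j)
      if (ident < 1 && config$revcomp) {
        ident <- if (grepl(seqs_rc[i], seqs[j], fixed = TRUE)) 1
                 else max(ident, best_diag(chars_rc[[i]], words_rc[[i]], j))
      }
      if (ident >= config$identity_threshold) {
        discard <- TRUE
        break
      }
    }
    if (!discard) {
      reps <- c(reps, i)
      wordpos[[i]] <- split(seq_along(words_fwd[[i]]), words_fwd[[i]])
      for (wd in unique(words_fwd[[i]]))
        word_index[[wd]] <- c(word_index[[wd]], i)
    }
  }
  assembly(ids[reps], seqs[reps], label = x$label)
}

#' Build a consensus assembly from candidate assemblies
#'
#' Pipeline: [merge_assemblies()] then [filter_by_length()] at
#' `min_contig_length` then [reduce_redundancy()]. The consensus label is
#' the sorted member labels joined with `"+"`.
#'
#' @param assemblies Nonempty list of [assembly] objects.
#' @param config A [consensus_config].
#' @return The consensus [assembly].
#' @export
build_consensus <- function(assemblies, config = consensus_config()) {
  if (!is.list(assemblies) || length(assemblies) == 0L)
    stop("build_consensus requires at least one assembly")
  label <- paste(sort(vapply(assemblies, `[[`, character(1), "label")),
                 collapse = "+")
  merged <- merge_assemblies(assemblies, label = label)
  kept <- filter_by_length(merged, config$min_contig_length)
  if (length(kept$ids) == 0L)
    stop("empty consensus: no contig reaches the ", config$min_contig_length,
         " bp length threshold")
  reduce_redundancy(kept, config)
}
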