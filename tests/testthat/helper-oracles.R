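# Independent brute-force oracles the implementation is checked against.

# Nx statistic by explicit sort + cumulative sum + first crossing
oracle_nx <- function(lengths, fraction) {
  lens <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(lens))
  lens[which(cum >= fraction * sum(as.numeric(lens)))[1L]]
}

# longest common substring by exhaustive diagonal sweep: on every
# alignment offset, the longest run of equal characters
oracle_lcs <- function(a, b) {
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(ac)
  nb <- length(bc)
  best <- 0L
  for (d in (1L - na):(nb - 1L)) {
    ia <- max(1L, 1L - d):min(na, nb - d)
    runs <- rle(ac[ia] == bc[ia + d])
    hit <- runs$lengths[runs$values]
    if (length(hit) && max(hit) > best) best <- max(hit)
  }
  best
}

# best ungapped identity of q against r over q's length: every diagonal
# (not just word-anchored ones), both strands
oracle_identity <- function(q, r, use_revcomp = TRUE) {
  one_strand <- function(q) {
    qc <- strsplit(q, "", fixed = TRUE)[[1L]]
    rc <- strsplit(r, "", fixed = TRUE)[[1L]]
    nq <- length(qc)
    nr <- length(rc)
    best <- 0L
    for (d in (1L - nq):(nr - 1L)) {
      iq <- max(1L, 1L - d):min(nq, nr - d)
      m <- sum(qc[iq] == rc[iq + d])
      if (m > best) best <- m
    }
    best / nq
  }
  out <- one_strand(q)
  if (use_revcomp) out <- max(out, one_strand(asmsynergy::revcomp(q)))
  out
}

# nearest-odd quartile k by exhaustive search over odd candidates,
# minimizing |target - k|, ties resolved upward
oracle_quartile_k <- function(k_min, k_max, i) {
  target <- k_min + i / 4 * (k_max - k_min)
  cand <- seq(15L, k_max + 2L, by = 2L)
  d <- abs(target - cand)
  hits <- cand[d == min(d)]
  max(hits)
}

# all subsets of size 1..max_size via power-set filtering
oracle_combinations <- function(assemblers, max_size) {
  n <- length(assemblers)
  out <- character(0)
  for (mask in seq_len(2^n - 1L)) {
    members <- assemblers[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (length(members) <= max_size)
      out <- c(out, paste(sort(members), collapse = "+"))
  }
  sort(out)
}

# BH step-up applied literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

random_assembly <- function(n_contigs, len_range = c(1L, 400L),
                            label = "rand") {
  lens <- sample(len_range[1L]:len_range[2L], n_contigs, replace = TRUE)
  seqs <- vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  asmsynergy::assembly(paste0("c", seq_len(n_contigs)), seqs, label = label)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# metric-record table with explicit raw values
make_records <- function(candidates, dataset, alignment, complete, n50,
                         n90) {
  do.call(rbind, lapply(seq_along(candidates), function(i)
    asmsynergy::metric_record(candidates[i], dataset, alignment[i],
                              complete[i], 0L, 0L, 0L, n50[i], n90[i])))
}

write_fastq <- function(path, seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                             quals)), path)
}
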