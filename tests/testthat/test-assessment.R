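test_that("lcs_lengths matches the brute-force oracle", {
  set.seed(41)
  for (case in 1:40) {
    a <- random_seq(sample(10:80, 1))
    b <- random_seq(sample(10:80, 1))
    if (runif(1) < 0.4) {  # force a real shared substring
      ins <- substr(a, 3, 3 + sample(5:20, 1))
      b <- paste0(substr(b, 1, 5), ins, substr(b, 6, nchar(b)))
    }
    expect_equal(lcs_lengths(a, b), oracle_lcs(a, b))
  }
})

test_that("marker recovery classifies complete, fragmented, duplicated", {
  set.seed(43)
  m <- vapply(1:4, function(i) random_seq(120), character(1))
  mk <- marker_set(paste0("m", 1:4), m)

  verbatim <- assembly(paste0("c", 1:4), m)
  r <- marker_recovery(verbatim, mk)
  expect_equal(unname(r), c(4L, 0L, 0L, 0L))

  half <- assembly("c1", paste0(substr(m[1], 1, 60), random_seq(100)))
  r <- marker_recovery(half, mk)
  expect_equal(r[["fragmented"]], 1L)
  expect_equal(r[["missing"]], 3L)

  dup <- assembly(c("c1", "c2"), c(paste0(m[1], random_seq(40)),
                                   paste0(random_seq(40), m[1])))
  r <- marker_recovery(dup, mk)
  expect_equal(r[["complete"]], 1L)
  expect_equal(r[["duplicated"]], 1L)

  # reverse-complement copies still count as complete
  rc <- assembly("c1", revcomp(m[2]))
  expect_equal(marker_recovery(rc, mk)[["complete"]], 1L)
})

test_that("marker recovery coverage agrees with the LCS oracle", {
  set.seed(47)
  for (case in 1:10) {
    truth <- generate_truth(6, c(250L, 400L), seed = case)
    mk <- derive_markers(truth, 4, 150L, seed = case + 100L)
    asm <- simulate_assembly(truth, sim_profile(0.6, 0.5, 0, seed = case))
    got <- marker_recovery(asm, mk)
    best <- vapply(mk$sequences, function(m)
      max(0, vapply(asm$sequences, function(s)
        max(oracle_lcs(m, s), oracle_lcs(revcomp(m), s)),
        integer(1))) / nchar(m), numeric(1))
    expect_equal(got[["complete"]], sum(best >= 0.95))
    expect_equal(got[["fragmented"]], sum(best >= 0.30 & best < 0.95))
    expect_equal(got[["missing"]], sum(best < 0.30))
    expect_equal(sum(got[c("complete", "fragmented", "missing")]),
                 mk$count)
  }
})

test_that("adding contigs never lowers completeness or representation", {
  set.seed(53)
  truth <- generate_truth(20, c(250L, 600L), seed = 9)
  mk <- derive_markers(truth, 10, 150L, seed = 10)
  reads <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(truth, 200, 60, seed = 11, path = reads)
  small <- simulate_assembly(truth, sim_profile(0.4, 0, 0, seed = 12),
                             label = "small")
  extra <- simulate_assembly(truth, sim_profile(0.9, 0, 0, seed = 13),
                             label = "extra")
  sup <- merge_assemblies(list(small, extra), label = "sup")
  expect_gte(marker_recovery(sup, mk)[["complete"]],
             marker_recovery(small, mk)[["complete"]])
  expect_gte(as.numeric(read_representation(sup, reads)),
             as.numeric(read_representation(small, reads)))
})

test_that("read representation scores verbatim, alien and mixed reads", {
  set.seed(59)
  truth <- generate_truth(5, c(300L, 300L), seed = 21)
  reads <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(truth, 50, 80, seed = 22, path = reads)
  expect_equal(as.numeric(read_representation(truth, reads)), 100)

  alien <- assembly("z", random_seq(2000))
  expect_equal(as.numeric(read_representation(alien, reads)), 0)

  # 7 truth reads + 3 alien reads -> 70%
  mixed <- withr::local_tempfile(fileext = ".fastq")
  own <- vapply(1:7, function(i) substr(truth$sequences[1], i * 10, i * 10 + 59),
                character(1))
  write_fastq(mixed, c(own, vapply(1:3, function(i) random_seq(60),
                                   character(1))))
  expect_equal(as.numeric(read_representation(truth, mixed)), 70)

  # permutation invariance
  perm <- withr::local_tempfile(fileext = ".fastq")
  set.seed(60)
  reord <- sample(c(own, vapply(1:3, function(i) random_seq(60),
                                character(1))))
  write_fastq(perm, reord)
  expect_equal(as.numeric(read_representation(truth, perm)), 70)

  # short reads are skipped and tallied; all-short errors
  shorty <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(shorty, c(substr(truth$sequences[1], 1, 60), "ACGTACGT"))
  r <- read_representation(truth, shorty)
  expect_equal(attr(r, "skipped"), 1L)
  write_fastq(shorty, c("ACGTACGT", "ACGT"))
  expect_error(read_representation(truth, shorty), "shorter than k")
})

test_that("assess composes the three raw metrics", {
  set.seed(61)
  truth <- generate_truth(8, c(250L, 500L), seed = 31)
  mk <- derive_markers(truth, 5, 150L, seed = 32)
  reads <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(truth, 100, 70, seed = 33, path = reads)
  rec <- assess(truth, mk, reads, dataset = "ds1")
  expect_equal(rec$alignment_rate, 100)
  expect_equal(rec$complete, 5L)
  expect_equal(rec$missing, 0L)
  expect_equal(rec$n50, oracle_nx(truth$lengths, 0.5))
  expect_equal(rec$n90, oracle_nx(truth$lengths, 0.9))
  expect_lte(rec$n90, rec$n50)

  lens <- assembly(paste0("c", 1:3),
                   vapply(c(1000L, 400L, 400L), strrep, character(1),
                          x = "A"))
  expect_equal(nx_length(lens, 0.5), 1000L)
  expect_equal(nx_length(lens, 0.9), 400L)
})

test_that("metric TSV writer keeps the fixed column order", {
  rec <- metric_record("a", "d", 91.234, 10L, 1L, 2L, 3L, 500L, 200L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(rec, p)
  got <- utils::read.delim(p)
  expect_equal(names(got),
               c("candidate", "dataset", "alignment_rate", "complete",
                 "duplicated", "fragmented", "missing", "n50", "n90"))
  expect_equal(got$alignment_rate, 91.23)
})

test_that("BUSCO short summaries parse to consistent counts", {
  txt <- c(
    "# BUSCO version is: 4.0.6",
    "# Summarized benchmarking in BUSCO notation for file asm.fasta",
    "\tC:62.4%[S:60.0%,D:2.4%],F:10.2%,M:27.4%,n:255",
    "\t159\tComplete BUSCOs (C)",
    "\t6\tComplete and duplicated BUSCOs (D)",
    "\t26\tFragmented BUSCOs (F)",
    "\t70\tMissing BUSCOs (M)",
    "\t255\tTotal BUSCO groups searched")
  r <- parse_busco_summary(txt)
  expect_equal(r$complete_pct, 62.4)
  expect_equal(r$complete, 159L)
  expect_equal(r$duplicated, 6L)
  expect_equal(r$fragmented, 26L)
  expect_equal(r$missing, 70L)
  expect_lt(abs(100 * r$complete / r$total - r$complete_pct), 0.1)

  perfect <- c("\tC:100.0%[S:98.0%,D:2.0%],F:0.0%,M:0.0%,n:50",
               "\t50\tComplete BUSCOs (C)", "\t0\tFragmented BUSCOs (F)",
               "\t0\tMissing BUSCOs (M)", "\t50\tTotal BUSCO groups searched")
  expect_equal(parse_busco_summary(perfect)$missing, 0L)
  expect_error(parse_busco_summary(""), "no BUSCO results block")
})

test_that("aligner summaries yield the printed overall rate", {
  expect_equal(parse_alignment_summary("92.35% overall alignment rate"),
               92.35)
  expect_equal(parse_alignment_summary(
    c("1000 reads; of these:", "100.00% overall alignment rate")), 100)
  expect_error(parse_alignment_summary("no such line"), "overall alignment")
})
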