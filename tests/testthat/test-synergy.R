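test_that("combination enumeration matches power-set filtering", {
  nine <- c("Trans-ABySS", "BinPacker", "IDBA-tran", "Shannon Cpp",
            "rnaSPAdes", "TransLig", "Trinity", "MEGAHIT", "Tadpole")
  combos <- enumerate_combinations(nine, max_size = 3)
  expect_equal(nrow(combos), 129L)
  expect_equal(as.vector(table(combos$tier)), c(9L, 36L, 84L))
  expect_setequal(combos$label, oracle_combinations(nine, 3))

  expect_equal(nrow(enumerate_combinations("solo", 1)), 1L)
  five <- enumerate_combinations(letters[1:5], 2)
  expect_equal(nrow(five), 15L)
  expect_setequal(five$label, oracle_combinations(letters[1:5], 2))
  for (n in 3:12) {
    labs <- enumerate_combinations(paste0("a", 1:n), 3)$label
    expect_equal(length(labs), n + n * (n - 1) / 2 +
                                 n * (n - 1) * (n - 2) / 6)
    expect_setequal(labs, oracle_combinations(paste0("a", 1:n), 3))
  }
  expect_error(enumerate_combinations(c("a", "a")), "duplicate")
})

test_that("combination labels are deterministic and sorted", {
  combos <- enumerate_combinations(c("b", "c", "a"), 2)
  expect_equal(combos$label,
               c("a", "b", "c", "a+b", "a+c", "b+c"))
  expect_true(all(diff(combos$tier) >= 0))
})

test_that("paired t matches the closed form and the stats::t.test oracle", {
  r <- paired_tier_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r$t, 3.4641016, tolerance = 1e-6)
  expect_equal(r$df, 2L)
  expect_equal(r$p, 0.0741799, tolerance = 1e-4)

  same <- paired_tier_test(c(0.1, 0.2), c(0.1, 0.2))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_false(same$degenerate)

  deg <- paired_tier_test(c(0, 0), c(5, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p, .Machine$double.xmin)
  expect_equal(deg$t, Inf)

  expect_error(paired_tier_test(1:3, 1:2), "length")
  expect_error(paired_tier_test(1, 2), "at least 2")

  set.seed(83)
  for (case in 1:20) {
    n <- sample(3:12, 1)
    a <- rnorm(n)
    b <- rnorm(n, 0.5)
    got <- paired_tier_test(a, b)
    want <- stats::t.test(b, a, paired = TRUE)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-9)
    expect_equal(got$p, want$p.value, tolerance = 1e-9)
  }
})

test_that("FDR adjustment reproduces the hand-applied step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(89)
  for (case in 1:20) {
    p <- runif(sample(2:15, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_gte(min(adj - p), 0)
    expect_equal(order(adj, p), order(p))  # monotone with raw ranking
  }
})

test_that("evaluate_all anchors the baseline at zero and stays bounded", {
  dir <- withr::local_tempdir()
  make_fixture(dir, n_assemblers = 3L, n_datasets = 2L, n_transcripts = 40L,
               n_reads = 250L, n_markers = 12L, seed = 404L)
  fx <- load_fixture(dir)
  rep <- evaluate_all(fx$assemblies, fx$markers, fx$reads,
                      baseline = fx$baseline)
  expect_s3_class(rep, "combination_report")
  expect_equal(nrow(rep$rows), 3 + 3 + 1)
  base_row <- rep$rows[rep$rows$label == fx$baseline, ]
  expect_equal(base_row$ds1, 0)
  expect_equal(base_row$ds2, 0)
  expect_true(all(rep$rows$mean_aas >= -0.5 & rep$rows$mean_aas <= 0.5))
  expect_true(all(diff(rep$rows$mean_aas) <= 0))  # ranked descending
  # tier tests: 3 groups x 2 comparisons, adjusted p >= raw p
  expect_equal(nrow(rep$tier_tests), 6L)
  expect_true(all(rep$tier_tests$p_adj >= rep$tier_tests$p))

  tm <- tier_means(rep, names(fx$assemblies$ds1)[2])
  expect_length(tm, 3L)
  expect_error(tier_means(rep, "nope"), "unknown")
})

test_that("identical candidate assemblies all score exactly zero", {
  set.seed(97)
  truth <- generate_truth(25, c(250L, 800L), seed = 55)
  mk <- derive_markers(truth, 10, 150L, seed = 56)
  reads <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(truth, 150, 70, seed = 57, path = reads)
  one <- simulate_assembly(truth, sim_profile(0.8, 0.1, 0.1, seed = 58),
                           label = "A")
  clones <- list(ds1 = list(A = one, B = one, C = one))
  clones$ds1$B$label <- "B"
  clones$ds1$C$label <- "C"
  rep <- evaluate_all(clones, mk, c(ds1 = reads), baseline = "A")
  expect_true(all(rep$rows$mean_aas == 0))
})

test_that("a strict-superset assembler outranks the baseline alone", {
  set.seed(101)
  truth <- generate_truth(30, c(250L, 800L), seed = 61)
  mk <- derive_markers(truth, 12, 150L, seed = 62)
  reads <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(truth, 200, 70, seed = 63, path = reads)
  small <- simulate_assembly(truth, sim_profile(0.5, 0, 0, seed = 64),
                             label = "A")
  # B = A plus extra long true transcripts (long ones cannot lower n50/n90)
  unused <- setdiff(truth$ids, small$ids)
  unused <- unused[order(-truth$lengths[match(unused, truth$ids)])]
  extra_ids <- unused[1:10]
  big <- assembly(c(small$ids, extra_ids),
                  c(small$sequences,
                    truth$sequences[match(extra_ids, truth$ids)]),
                  label = "B")
  rep <- evaluate_all(list(ds1 = list(A = small, B = big)), mk,
                      c(ds1 = reads), baseline = "A", max_size = 2)
  rows <- rep$rows
  expect_gt(rows$mean_aas[rows$label == "B"], 0)
  expect_true(all(rows$mean_aas[rows$label != "A"] >=
                    rows$mean_aas[rows$label == "A"]))
  expect_error(
    evaluate_all(list(ds1 = list(A = small, B = big),
                      ds2 = list(A = small)), mk,
                 c(ds1 = reads, ds2 = reads), baseline = "A", max_size = 2),
    "incomplete design")
})

test_that("report TSVs are written with ranked rows and a bi matrix", {
  dir <- withr::local_tempdir()
  make_fixture(dir, n_assemblers = 3L, n_datasets = 1L, n_transcripts = 30L,
               n_reads = 150L, n_markers = 10L, seed = 505L)
  fx <- load_fixture(dir)
  rep <- evaluate_all(fx$assemblies, fx$markers, fx$reads,
                      baseline = fx$baseline)
  out <- withr::local_tempdir()
  write_report(rep, out)
  ranked <- utils::read.delim(file.path(out, "ranked.tsv"))
  expect_equal(nrow(ranked), nrow(rep$rows))
  expect_true(file.exists(file.path(out, "tier_tests.tsv")))
  bi <- utils::read.delim(file.path(out, "bi_matrix.tsv"))
  expect_equal(nrow(bi), 3L)
})
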