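#' Enumerate assembler combinations
#'
#' All subsets of 1 to `max_size` assemblers, each emitted once, ordered by
#' (size, label). For 9 assemblers and `max_size = 3` this yields
#' 9 + 36 + 84 = 129 combinations.
#'
#' @param assemblers Character vector of unique assembler names.
#' @param max_size Largest combination size (default 3).
#' @return A `data.frame` with columns `label`, `tier` and a list-column
#'   `members` (sorted member names; `label` is the members joined by "+").
#' @export
enumerate_combinations <- function(assemblers, max_size = 3L) {
  stopifnot(is.character(assemblers), length(assemblers) >= 1L)
  if (anyDuplicated(assemblers))
    stop("duplicate assembler name: ",
         assemblers[duplicated(assemblers)][1L])
  stopifnot(max_size >= 1L, max_size <= length(assemblers))
  rows <- list()
  for (size in seq_len(max_size)) {
    sets <- utils::combn(sort(assemblers), size, simplify = FALSE)
    labels <- vapply(sets, paste, character(1), collapse = "+")
    ord <- order(labels)
    rows[[size]] <- data.frame(label = labels[ord], tier = size,
                               stringsAsFactors = FALSE)
    rows[[size]]$members <- sets[ord]
  }
  do.call(rbind, rows)
}

#' Evaluate every assembler combination on every dataset
#'
#' For each dataset and each combination, builds the consensus assembly
#' ([build_consensus()]; a single-assembler combination still passes through
#' the length filter and redundancy reduction), assesses it ([assess()]),
#' then scores all combinations of that dataset jointly against the baseline
#' single-assembler run ([score_dataset()]). Per-candidate AAS values are
#' averaged across datasets and, when two or more datasets are present,
#' single-vs-bi and bi-vs-tri paired t-tests are run per assembler group
#' with BH-FDR correction.
#'
#' @param assemblies Nested named list: `assemblies[[dataset]][[assembler]]`
#'   is an [assembly]. The design must be complete.
#' @param markers A [marker_set], or a named list of marker sets keyed by
#'   dataset.
#' @param reads Named character vector/list mapping dataset to a FASTQ path.
#' @param baseline Baseline assembler name (default `"MEGAHIT"`); must be
#'   one of the assemblers.
#' @param config A [consensus_config].
#' @param max_size Largest combination size (default 3).
#' @param mode Normalization mode, see [normalize_metric()].
#' @return An object of class `combination_report`: list with `rows`
#'   (label, tier, one AAS column per dataset, `mean_aas`; sorted by
#'   `mean_aas` descending, ties by label), `tier_tests` (group, comparison,
#'   t, df, p, p_adj, significance, degenerate), `metrics` (all raw metric
#'   records) and `meta`.
#' @export
evaluate_all <- function(assemblies, markers, reads, baseline = "MEGAHIT",
                         config = consensus_config(), max_size = 3L,
                         mode = "anchored") {
  stopifnot(is.list(assemblies), length(assemblies) >= 1L)
  datasets <- names(assemblies)
  if (is.null(datasets) || any(!nzchar(datasets)))
    stop("assemblies must be a named list keyed by dataset")
  asm_names <- sort(names(assemblies[[1L]]))
  gaps <- character(0)
  for (d in datasets) {
    missing <- setdiff(asm_names, names(assemblies[[d]]))
    extra <- setdiff(names(assemblies[[d]]), asm_names)
    if (length(missing) || length(extra))
      gaps <- c(gaps, sprintf("(%s, %s)", c(missing, extra), d))
  }
  if (length(gaps))
    stop("incomplete design; problem (assembler, dataset) cells: ",
         paste(gaps, collapse = ", "))
  if (!baseline %in% asm_names)
    stop("baseline '", baseline, "' is not among the assemblers")
  combos <- enumerate_combinations(asm_names, max_size = max_size)
  marker_for <- function(d) if (inherits(markers, "marker_set")) markers
                            else markers[[d]]
  scored <- list()
  metrics <- list()
  for (d in datasets) {
    recs <- lapply(seq_len(nrow(combos)), function(i) {
      members <- combos$members[[i]]
      cons <- build_consensus(assemblies[[d]][members], config = config)
      assess(cons, marker_for(d), reads[[d]], dataset = d,
             candidate = combos$label[i])
    })
    recs <- do.call(rbind, recs)
    metrics[[d]] <- recs
    scored[[d]] <- score_dataset(recs, baseline = baseline, mode = mode)
  }
  per_dataset <- do.call(rbind, scored)
  means <- average_across_datasets(per_dataset)
  rows <- combos[, c("label", "tier")]
  for (d in datasets)
    rows[[d]] <- scored[[d]]$aas[match(rows$label, scored[[d]]$candidate)]
  rows$mean_aas <- means$mean_aas[match(rows$label, means$candidate)]
  rows <- rows[order(-rows$mean_aas, rows$label), , drop = FALSE]
  rownames(rows) <- NULL
  report <- structure(list(
    rows = rows, tier_tests = NULL, metrics = do.call(rbind, metrics),
    combos = combos,
    meta = list(baseline = baseline, datasets = datasets,
                assemblers = asm_names, max_size = max_size,
                normalization = mode, pairing = "datasets")),
    class = "combination_report")
  report$tier_tests <- if (length(datasets) >= 2L)
    tier_tests(report, per_dataset) else empty_tier_tests()
  report
}

#' @export
print.combination_report <- function(x, ...) {
  cat(sprintf("<combination_report: %d combinations, %d dataset(s), baseline %s>\n",
              nrow(x$rows), length(x$meta$datasets), x$meta$baseline))
  print(utils::head(x$rows, 10L))
  invisible(x)
}

empty_tier_tests <- function() {
  data.frame(group = character(0), comparison = character(0),
             t = numeric(0), df = numeric(0), p = numeric(0),
             p_adj = numeric(0), significance = character(0),
             degenerate = logical(0), stringsAsFactors = FALSE)
}

# per-dataset mean AAS over the tier-`tier` combinations containing `group`
group_tier_series <- function(report, per_dataset, group, tier) {
  labs <- report$combos$label[report$combos$tier == tier &
    vapply(report$combos$members, function(m) group %in% m, logical(1))]
  sub <- per_dataset[per_dataset$candidate %in% labs, , drop = FALSE]
  m <- tapply(sub$aas, sub$dataset, mean)
  as.numeric(m[report$meta$datasets])
}

tier_tests <- function(report, per_dataset) {
  out <- list()
  for (g in report$meta$assemblers) {
    for (pair in list(c(1L, 2L), c(2L, 3L))) {
      if (pair[2L] > report$meta$max_size) next
      a <- group_tier_series(report, per_dataset, g, pair[1L])
      b <- group_tier_series(report, per_dataset, g, pair[2L])
      tt <- paired_tier_test(a, b)
      out[[length(out) + 1L]] <- data.frame(
        group = g,
        comparison = sprintf("tier%d_vs_tier%d", pair[1L], pair[2L]),
        t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, out)
  tests$p_adj <- fdr_adjust(tests$p)
  tests$significance <- significance_stars(tests$p_adj)
  tests[, c("group", "comparison", "t", "df", "p", "p_adj",
            "significance", "degenerate")]
}

significance_stars <- function(p) {
  ifelse(p < 1e-5, "***", ifelse(p < 1e-3, "**",
                                 ifelse(p < 0.05, "*", "NS")))
}

#' Per-tier mean AAS for combinations containing an assembler
#'
#' For assembler `group_by` among n assemblers: the tier-1 value is its
#' singleton AAS; tier 2 averages the n-1 pairs containing it; tier 3
#' averages the C(n-1, 2) triples.
#'
#' @param report A `combination_report`.
#' @param group_by Assembler name.
#' @return Named numeric vector of mean AAS per tier.
#' @export
tier_means <- function(report, group_by) {
  stopifnot(inherits(report, "combination_report"))
  if (!group_by %in% report$meta$assemblers)
    stop("unknown assembler: ", group_by)
  rows <- report$rows
  members <- report$combos$members[match(rows$label, report$combos$label)]
  keep <- vapply(members, function(m) group_by %in% m, logical(1))
  m <- tapply(rows$mean_aas[keep], rows$tier[keep], mean)
  stats::setNames(as.numeric(m), paste0("tier", names(m)))
}

#' Two-tailed paired t-test
#'
#' Closed-form paired t on positionally paired score lists: `d = b - a`,
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, two-tailed p from the t
#' distribution. All-zero differences give `t = 0, p = 1` by convention;
#' zero variance with nonzero mean gives a signed infinite t and the machine
#' minimum p, flagged `degenerate = TRUE` so full runs never abort on a
#' pathological group.
#'
#' @param scores_a,scores_b Equal-length numeric vectors (length >= 2),
#'   paired by position.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
paired_tier_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("paired score lists differ in length (", length(scores_a),
         " vs ", length(scores_b), ")")
  n <- length(scores_a)
  if (n < 2L) stop("paired t-test needs at least 2 pairs, got ", n)
  d <- scores_b - scores_a
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1L, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L,
                p = .Machine$double.xmin, degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), df = n - 1L),
       degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`min over j >= i of m * p_(j) / j`, clipped at
#' 1), returned in input order.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Write a combination report as TSV files
#'
#' Emits `ranked.tsv` (label, tier, per-dataset AAS, mean AAS),
#' `tier_tests.tsv` (group, comparison, t, df, p, p_adj, significance
#' stars at 0.05 / 0.001 / 0.00001, degeneracy flag) and, when bi-assembly
#' rows exist, `bi_matrix.tsv`, a square assembler-by-assembler matrix of
#' pair AAS values (diagonal = singleton AAS).
#'
#' @param report A `combination_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "combination_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(v) if (is.numeric(v) && !is.integer(v))
      sprintf("%.4f", v) else v)
    df
  }
  paths <- file.path(dir, c("ranked.tsv", "tier_tests.tsv"))
  write_atomic(fmt(report$rows), paths[1L])
  write_atomic(fmt(report$tier_tests), paths[2L])
  if (any(report$rows$tier == 2L) && report$meta$max_size >= 2L) {
    asm <- report$meta$assemblers
    m <- matrix(NA_real_, length(asm), length(asm),
                dimnames = list(asm, asm))
    for (i in seq_len(nrow(report$rows))) {
      mem <- report$combos$members[[
        match(report$rows$label[i], report$combos$label)]]
      if (length(mem) == 1L) m[mem, mem] <- report$rows$mean_aas[i]
      if (length(mem) == 2L) {
        m[mem[1L], mem[2L]] <- report$rows$mean_aas[i]
        m[mem[2L], mem[1L]] <- report$rows$mean_aas[i]
      }
    }
    p <- file.path(dir, "bi_matrix.tsv")
    df <- data.frame(assembler = rownames(m),
                     apply(m, 2, function(v) sprintf("%.4f", v)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_atomic(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# temp-then-rename so partial output never lands under the final name
write_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
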