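#' Normalization context for one metric
#'
#' Holds the anchors used to normalize one raw assessment metric across the
#' candidates of a comparison set: the designated baseline candidate's raw
#' score and the maximum and minimum raw scores over all candidates
#' (baseline included).
#'
#' @param as_base Baseline raw score.
#' @param as_max Maximum raw score in the comparison set.
#' @param as_min Minimum raw score in the comparison set.
#' @param metric Optional metric name, for messages.
#' @return A list of class `norm_context`.
#' @export
norm_context <- function(as_base, as_max, as_min, metric = "metric") {
  if (!(as_min <= as_base && as_base <= as_max))
    stop("invalid normalization context for ", metric,
         ": need as_min <= as_base <= as_max")
  structure(list(metric = metric, as_base = as_base, as_max = as_max,
                 as_min = as_min),
            class = "norm_context")
}

#' Normalize a raw assessment score against a baseline
#'
#' Maps a raw score onto \[-0.5, +0.5\] anchored at the baseline candidate:
#' a score equal to the baseline's is 0; the best score in the comparison
#' set (when above baseline) is +0.5 and the worst (when below) is -0.5,
#' with linear interpolation on each side:
#' \deqn{s = +0.5 (x - b) / (max - b)} for x > b, and
#' \deqn{s = -0.5 (b - x) / (b - min)} for x < b.
#'
#' `mode = "literal"` applies the alternative published forms
#' `x / max * 0.5` (above baseline) and `(x - min) * 0.5` (below) instead;
#' these do not respect the \[-0.5, +0.5\] anchors and are provided for
#' comparison only.
#'
#' @param as_x Raw score of the candidate; must lie within
#'   `[ctx$as_min, ctx$as_max]`.
#' @param ctx A [norm_context].
#' @param mode `"anchored"` (default) or `"literal"`.
#' @return Normalized score; in \[-0.5, +0.5\] under `"anchored"`.
#' @examples
#' ctx <- norm_context(as_base = 10, as_max = 20, as_min = 5)
#' normalize_metric(10, ctx)  # 0
#' normalize_metric(20, ctx)  # 0.5
#' normalize_metric(15, ctx)  # 0.25
#' @export
normalize_metric <- function(as_x, ctx, mode = c("anchored", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ctx, "norm_context"))
  if (as_x < ctx$as_min || as_x > ctx$as_max)
    stop("raw score ", as_x, " outside the normalization context [",
         ctx$as_min, ", ", ctx$as_max, "] for ", ctx$metric)
  if (as_x == ctx$as_base) return(0)
  if (mode == "literal") {
    if (as_x > ctx$as_base) return(as_x / ctx$as_max * 0.5)
    return((as_x - ctx$as_min) * 0.5)
  }
  if (as_x > ctx$as_base)
    0.5 * (as_x - ctx$as_base) / (ctx$as_max - ctx$as_base)
  else
    -0.5 * (ctx$as_base - as_x) / (ctx$as_base - ctx$as_min)
}

#' Score all candidates of one dataset
#'
#' Builds one normalization context per metric (alignment rate, complete
#' marker count, n50, n90) from the supplied metric records, normalizes each
#' candidate's raw scores against the baseline candidate, pre-averages the
#' two contig-length scores, and averages alignment, completeness and the
#' contig component 1:1:1 into the Average Assessment Score (AAS). The
#' baseline's AAS is exactly 0 by construction.
#'
#' @param records Metric-record `data.frame` ([assess()] rows), all with the
#'   same `dataset`, unique `candidate` values, and at least 2 rows.
#' @param baseline Candidate id anchoring the normalization
#'   (default `"MEGAHIT"`).
#' @param mode Normalization mode, see [normalize_metric()].
#' @return `data.frame` with columns `candidate`, `dataset`, `s_alignment`,
#'   `s_completeness`, `s_n50`, `s_n90`, `s_contig`, `aas`.
#' @export
score_dataset <- function(records, baseline = "MEGAHIT",
                          mode = c("anchored", "literal")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), nrow(records) >= 2L)
  if (length(unique(records$dataset)) != 1L)
    stop("score_dataset expects records from a single dataset")
  if (anyDuplicated(records$candidate))
    stop("duplicate candidate id: ",
         records$candidate[duplicated(records$candidate)][1L])
  if (!baseline %in% records$candidate)
    stop("baseline candidate '", baseline, "' absent from records")
  b <- which(records$candidate == baseline)
  norm_col <- function(col) {
    v <- records[[col]]
    ctx <- norm_context(v[b], max(v), min(v), metric = col)
    vapply(v, normalize_metric, numeric(1), ctx = ctx, mode = mode)
  }
  s_al <- norm_col("alignment_rate")
  s_co <- norm_col("complete")
  s_n50 <- norm_col("n50")
  s_n90 <- norm_col("n90")
  s_contig <- (s_n50 + s_n90) / 2
  data.frame(candidate = records$candidate, dataset = records$dataset,
             s_alignment = s_al, s_completeness = s_co, s_n50 = s_n50,
             s_n90 = s_n90, s_contig = s_contig,
             aas = (s_al + s_co + s_contig) / 3,
             stringsAsFactors = FALSE)
}

#' Average AAS across datasets
#'
#' Arithmetic mean of each candidate's AAS over all datasets. The design
#' must be complete: every candidate present in every dataset; no
#' imputation.
#'
#' @param per_dataset `data.frame` of [score_dataset()] rows over one or
#'   more datasets.
#' @return `data.frame` with `candidate` and `mean_aas`, sorted by
#'   `mean_aas` descending, ties by candidate label ascending.
#' @export
average_across_datasets <- function(per_dataset) {
  stopifnot(is.data.frame(per_dataset), nrow(per_dataset) >= 1L)
  datasets <- unique(per_dataset$dataset)
  candidates <- unique(per_dataset$candidate)
  have <- paste(per_dataset$candidate, per_dataset$dataset, sep = "\r")
  want <- expand.grid(candidate = candidates, dataset = datasets,
                      stringsAsFactors = FALSE)
  miss <- !(paste(want$candidate, want$dataset, sep = "\r") %in% have)
  if (any(miss))
    stop("ragged design; missing (candidate, dataset) pairs: ",
         paste(sprintf("(%s, %s)", want$candidate[miss],
                       want$dataset[miss]), collapse = ", "))
  m <- tapply(per_dataset$aas, per_dataset$candidate, mean)
  out <- data.frame(candidate = names(m), mean_aas = as.numeric(m),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_aas, out$candidate), , drop = FALSE]
}

#' Write AAS results as TSV
#'
#' Columns candidate, dataset, the four component scores, s_contig and aas;
#' floats to 4 decimals.
#'
#' @param scores [score_dataset()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aas <- function(scores, path) {
  out <- scores
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.4f", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
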