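#' Phenotype-separation score for one miR-mRNA pair
#'
#' Measures how well an association separates high- and low-invasiveness
#' samples in the (miR abundance, mRNA abundance) plane. Group centroids
#' are the arithmetic means of the labelled samples' log2 abundances per
#' axis (the centroid in log2 space equals the geometric mean on the linear
#' scale); the maximal span is
#' \deqn{d_{Sep,max} = \sqrt{(\max[mRNA]-\min[mRNA])^2 +
#'   (\max[miR]-\min[miR])^2}}
#' with per-axis ranges taken over *all* samples (labelled and unlabelled)
#' by default, and
#' \deqn{d_{Sep,norm} = \frac{\sqrt{(\hat\mu_{mRNA,high}-\hat\mu_{mRNA,low})^2
#'   + (\hat\mu_{miR,high}-\hat\mu_{miR,low})^2}}{d_{Sep,max}}.}
#' The score lies in \eqn{[0, 1]}, is symmetric in the two groups, and is
#' unchanged by adding unlabelled samples inside the existing per-axis
#' ranges.
#'
#' @param mir_values,mrna_values Numeric sample vectors (log2 abundance)
#'   in the same sample order as `labels`.
#' @param labels Character vector of `"high"`, `"low"` or `"unknown"` per
#'   sample (a `data.frame` with columns `sample_id`, `group` is also
#'   accepted when the vectors are named).
#' @param ranges_over_all_samples Use all samples for the per-axis ranges
#'   (default TRUE); otherwise only labelled samples.
#' @return List of class `dsep_result`: the four centroid coordinates,
#'   `d_sep_max` and `d_sep_norm`.
#' @export
d_sep_norm <- function(mir_values, mrna_values, labels,
                       ranges_over_all_samples = TRUE) {
  if (is.data.frame(labels)) {
    if (is.null(names(mir_values)))
      stop("named sample vectors are required with a label table")
    labels <- stats::setNames(labels$group, labels$sample_id)[names(mir_values)]
    labels[is.na(labels)] <- "unknown"
  }
  n <- length(mir_values)
  if (length(mrna_values) != n || length(labels) != n)
    stop("mir_values, mrna_values and labels must have equal length")
  hi <- labels == "high"
  lo <- labels == "low"
  if (!any(hi) || !any(lo))
    stop("need at least one sample in each of the high and low groups")
  use <- if (ranges_over_all_samples) rep(TRUE, n) else (hi | lo)
  span_mir <- max(mir_values[use]) - min(mir_values[use])
  span_mrna <- max(mrna_values[use]) - min(mrna_values[use])
  d_max <- sqrt(span_mrna^2 + span_mir^2)
  if (d_max == 0)
    stop("zero d_sep_max: both axes are constant")
  mu <- list(mir_low = mean(mir_values[lo]), mir_high = mean(mir_values[hi]),
             mrna_low = mean(mrna_values[lo]),
             mrna_high = mean(mrna_values[hi]))
  d <- sqrt((mu$mrna_high - mu$mrna_low)^2 + (mu$mir_high - mu$mir_low)^2)
  structure(list(mu_mir_low = mu$mir_low, mu_mir_high = mu$mir_high,
                 mu_mrna_low = mu$mrna_low, mu_mrna_high = mu$mrna_high,
                 d_sep_max = d_max, d_sep_norm = d / d_max),
            class = "dsep_result")
}

#' @export
print.dsep_result <- function(x, ...) {
  cat(sprintf("<dsep_result> d_sep_norm = %.4f (d_sep_max = %.4f)\n",
              x$d_sep_norm, x$d_sep_max))
  invisible(x)
}

#' Mid-rank percentile ranks
#'
#' `rank_pct(v) = 100 * (rank(v) - 0.5) / n` with ties mid-ranked, so all
#' outputs lie in \eqn{[0, 100)} and a fully tied input ranks at 50.
#'
#' @param values Non-empty numeric vector.
#' @return Percentile ranks in the input order.
#' @export
percentile_ranks <- function(values) {
  if (length(values) == 0) stop("values must be non-empty")
  100 * (rank(values, ties.method = "average") - 0.5) / length(values)
}

#' Phenotype-separation scores for a set of associations
#'
#' Vectorised [d_sep_norm()] over (miR, probe) pairs drawn from a pair of
#' expression matrices, with the percentile rank of each score computed
#' across all supplied pairs (typically every association that passed
#' preprocessing).
#'
#' @param mir_m,mrna_m [expression_matrix()] objects sharing the sample
#'   order.
#' @param pairs Data frame with columns `mir_id`, `probe_id`.
#' @param labels Data frame with columns `sample_id`, `group`.
#' @param ranges_over_all_samples See [d_sep_norm()].
#' @return `pairs` with `d_sep_norm` and `d_sep_rank_pct` columns appended.
#' @export
d_sep_table <- function(mir_m, mrna_m, pairs, labels,
                        ranges_over_all_samples = TRUE) {
  if (!identical(colnames(mir_m), colnames(mrna_m)))
    stop("matrices must share an identical ordered sample list")
  grp <- stats::setNames(labels$group, labels$sample_id)[colnames(mir_m)]
  grp[is.na(grp)] <- "unknown"
  hi <- grp == "high"
  lo <- grp == "low"
  if (!any(hi) || !any(lo))
    stop("need at least one labelled sample per group")
  use <- if (ranges_over_all_samples) rep(TRUE, length(grp)) else (hi | lo)

  row_stats <- function(m) {
    v <- unclass(m)[, use, drop = FALSE]
    list(span = apply(v, 1L, function(x) max(x) - min(x)),
         mu_hi = rowMeans(unclass(m)[, hi, drop = FALSE]),
         mu_lo = rowMeans(unclass(m)[, lo, drop = FALSE]))
  }
  sm <- row_stats(mir_m)
  sp <- row_stats(mrna_m)
  i <- match(pairs$mir_id, rownames(mir_m))
  j <- match(pairs$probe_id, rownames(mrna_m))
  if (anyNA(i) || anyNA(j))
    stop("pairs reference features absent from the matrices")
  d_max <- sqrt(sp$span[j]^2 + sm$span[i]^2)
  if (any(d_max == 0)) stop("zero d_sep_max for at least one pair")
  d <- sqrt((sp$mu_hi[j] - sp$mu_lo[j])^2 + (sm$mu_hi[i] - sm$mu_lo[i])^2)
  pairs$d_sep_norm <- unname(d / d_max)
  pairs$d_sep_rank_pct <- percentile_ranks(pairs$d_sep_norm)
  pairs
}

#' Fill the d_sep columns of a putative table
#'
#' Scores are computed for every association in `all_pairs` (the rank
#' universe: all pairs passing preprocessing) and the putative rows are
#' annotated by (miR, probe) lookup.
#'
#' @param putative Putative table ([build_putative_list()]).
#' @param mir_m,mrna_m Filtered expression matrices.
#' @param all_pairs Data frame of all (mir_id, probe_id) pairs defining
#'   the percentile-rank universe.
#' @param labels Phenotype label table.
#' @return List with `putative` (annotated) and `dsep` (the full scored
#'   pair table).
#' @export
d_sep_annotate <- function(putative, mir_m, mrna_m, all_pairs, labels) {
  scored <- d_sep_table(mir_m, mrna_m,
                        all_pairs[, c("mir_id", "probe_id")], labels)
  key <- paste(scored$mir_id, scored$probe_id)
  idx <- match(paste(putative$mir_id, putative$probe_id), key)
  putative$d_sep_norm <- scored$d_sep_norm[idx]
  putative$d_sep_rank_pct <- scored$d_sep_rank_pct[idx]
  list(putative = putative, dsep = scored)
}
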