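#' Quantile-normalise an expression matrix
#'
#' Forces every sample column to share the same value distribution (the
#' per-rank cross-sample means), preserving within-column ranks. With a
#' single sample the matrix is returned unchanged with a warning.
#'
#' @param m An [expression_matrix()].
#' @return A quantile-normalised [expression_matrix()].
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) {
    warning("quantile normalisation needs >= 2 samples; returning input")
    return(m)
  }
  out <- limma::normalizeQuantiles(unclass(m), ties = FALSE)
  dimnames(out) <- dimnames(m)
  rewrap(out, m)
}

#' Log2-transform abundances
#'
#' @param m An [expression_matrix()].
#' @param offset Pseudo-count added before taking log2 (default 1).
#' @return The transformed [expression_matrix()].
#' @export
log2_transform <- function(m, offset = 1) {
  if (any(unclass(m) + offset <= 0))
    stop("log2 transform requires values + offset > 0")
  rewrap(log2(unclass(m) + offset), m)
}

#' Filter features on abundance and dynamic range
#'
#' Two rules, mirroring low-signal feature removal for a paired miR/mRNA
#' panel:
#'
#' * **abundance** — the `abundance_percentile`-th percentile of *all*
#'   values in the matrix is computed (linear interpolation); a feature is
#'   kept only if its count of samples strictly above that threshold is at
#'   least `floor(min_frac_above * n_samples)` (14 of 57 at the defaults).
#' * **range** — for miR matrices the per-feature range (max - min) must
#'   exceed the 90th percentile of all matrix values (or, with
#'   `mir_range_mode = "ranges"`, the 90th percentile of the per-feature
#'   ranges); for mRNA-probe matrices it must exceed 10% of the global
#'   value range.
#'
#' Thresholds are always computed from the *input* matrix (or taken from
#' `thresholds`, so a previous report can be re-applied); re-filtering
#' retained output with the same thresholds drops nothing further.
#'
#' @param m An [expression_matrix()].
#' @param abundance_percentile Percentile (0-100) defining the low-abundance
#'   threshold over all matrix values. Default 10.
#' @param min_frac_above Minimum fraction of samples that must lie strictly
#'   above the abundance threshold; the sample-count cutoff is
#'   `floor(min_frac_above * n)`. Default 0.25.
#' @param range_percentile Percentile (0-100) of all matrix values used as
#'   the miR range threshold. Default 90.
#' @param mrna_range_frac Fraction of the global value range used as the
#'   mRNA-probe range threshold. Default 0.10.
#' @param mir_range_mode `"abundance"` (threshold = percentile of abundance
#'   values, the default) or `"ranges"` (percentile of per-feature ranges).
#' @param thresholds Optional list with elements `abundance`, `range` and
#'   `min_samples_above` overriding the computed cutoffs.
#' @return A list with `matrix` (the retained [expression_matrix()]) and
#'   `report` (a `filter_report`: input/dropped/retained counts plus the
#'   realised thresholds).
#' @export
filter_features <- function(m, abundance_percentile = 10,
                            min_frac_above = 0.25,
                            range_percentile = 90,
                            mrna_range_frac = 0.10,
                            mir_range_mode = c("abundance", "ranges"),
                            thresholds = NULL) {
  mir_range_mode <- match.arg(mir_range_mode)
  if (nrow(m) == 0) stop("cannot filter an empty matrix")
  vals <- as.vector(unclass(m))
  rng <- apply(unclass(m), 1L, function(v) max(v) - min(v))

  if (is.null(thresholds)) {
    thr_ab <- stats::quantile(vals, abundance_percentile / 100,
                              names = FALSE, type = 7)
    cutoff_n <- as.integer(floor(min_frac_above * ncol(m)))
    thr_rng <- if (feature_kind(m) == "miR") {
      if (mir_range_mode == "abundance")
        stats::quantile(vals, range_percentile / 100, names = FALSE, type = 7)
      else
        stats::quantile(rng, range_percentile / 100, names = FALSE, type = 7)
    } else {
      mrna_range_frac * (max(vals) - min(vals))
    }
  } else {
    thr_ab <- thresholds$abundance
    thr_rng <- thresholds$range
    cutoff_n <- thresholds$min_samples_above
  }

  above <- rowSums(unclass(m) > thr_ab)
  pass_ab <- above >= cutoff_n
  pass_rng <- rng > thr_rng
  keep <- pass_ab & pass_rng

  report <- structure(list(
    n_input = nrow(m),
    n_dropped_abundance = sum(!pass_ab),
    n_dropped_range = sum(pass_ab & !pass_rng),
    n_retained = sum(keep),
    thresholds_used = list(abundance = thr_ab, range = thr_rng,
                           min_samples_above = cutoff_n,
                           mir_range_mode = mir_range_mode)
  ), class = "filter_report")

  if (!any(keep)) {
    stop(sprintf(paste0("all %d features dropped (abundance threshold %.4g, ",
                        "range threshold %.4g, min samples above %d)"),
                 report$n_input, thr_ab, thr_rng, cutoff_n))
  }
  message(sprintf(
    "filter_features [%s]: retained %d/%d (abundance thr %.4g, >= %d samples above; range thr %.4g)",
    feature_kind(m), report$n_retained, report$n_input, thr_ab, cutoff_n,
    thr_rng))
  list(matrix = rewrap(unclass(m)[keep, , drop = FALSE], m), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> input %d | dropped: abundance %d, range %d | retained %d\n",
    x$n_input, x$n_dropped_abundance, x$n_dropped_range, x$n_retained))
  invisible(x)
}

#' Match cohort samples across miR and mRNA tables by barcode
#'
#' Both tables are sample-per-row with a `barcode` first column and numeric
#' feature columns (the compiled-cohort layout). Samples are paired by exact
#' full-length barcode equality; two samples from one patient carry distinct
#' barcodes and are both retained. Unpaired barcodes are reported via
#' `message()`.
#'
#' @param mir_table,mrna_table Data frames with a `barcode` column followed
#'   by numeric feature columns.
#' @return A list of two [expression_matrix()] objects (`mir`, `mrna`)
#'   sharing an identical ordered sample list.
#' @export
match_cohort_samples <- function(mir_table, mrna_table) {
  bc_col <- function(df) {
    if ("barcode" %in% names(df)) df[["barcode"]] else df[[1]]
  }
  dedupe <- function(df, label) {
    b <- bc_col(df)
    if (anyDuplicated(b)) {
      message("duplicate full-length barcodes in the ", label,
              " table; keeping first occurrence")
      df <- df[!duplicated(b), , drop = FALSE]
    }
    df
  }
  mir_table <- dedupe(mir_table, "miR")
  mrna_table <- dedupe(mrna_table, "mRNA")
  b1 <- bc_col(mir_table)
  b2 <- bc_col(mrna_table)
  shared <- sort(intersect(b1, b2))
  if (length(shared) == 0) stop("no shared barcodes between the two tables")
  unpaired <- c(setdiff(b1, shared), setdiff(b2, shared))
  if (length(unpaired))
    message("unpaired cohort barcodes dropped: ",
            paste(unpaired, collapse = ", "))
  to_mat <- function(df, bcs, kind) {
    b <- bc_col(df)
    num <- df[match(bcs, b), setdiff(names(df), "barcode"), drop = FALSE]
    num <- num[, vapply(num, is.numeric, logical(1)), drop = FALSE]
    m <- t(as.matrix(num))
    colnames(m) <- bcs
    expression_matrix(m, kind)
  }
  list(mir = to_mat(mir_table, shared, "miR"),
       mrna = to_mat(mrna_table, shared, "mRNA-probe"))
}
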