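#' Select strong negative associations
#'
#' Keeps the rows lying simultaneously in the upper mutual-information tail
#' and the lower (most negative) Pearson tail: `mi` strictly above the
#' `(100 - mi_top_pct)`-th percentile of the MI values and `pearson_r`
#' strictly below the `r_bottom_pct`-th percentile of the correlations
#' (linear-interpolated quantiles). An `"or"` mode (either tail) is
#' available but off by default. If either distribution is degenerate
#' (all values equal) the selection is empty, with a warning.
#'
#' @param assoc Association table with columns `pearson_r` and `mi`.
#' @param mi_top_pct Upper-tail percentage for MI (default 10).
#' @param r_bottom_pct Lower-tail percentage for the correlation
#'   (default 2.5).
#' @param mode `"and"` (intersection of the two tails, the default) or
#'   `"or"`.
#' @return List with `thresholds` (class `selection_thresholds`: realised
#'   `mi_cutoff`, `r_cutoff` and the percentages) and `selected` (the
#'   subset of `assoc`).
#' @export
select_strong_negative <- function(assoc, mi_top_pct = 10,
                                   r_bottom_pct = 2.5,
                                   mode = c("and", "or")) {
  mode <- match.arg(mode)
  if (nrow(assoc) == 0) stop("association table is empty")
  mi_cut <- stats::quantile(assoc$mi, 1 - mi_top_pct / 100,
                            names = FALSE, type = 7)
  r_cut <- stats::quantile(assoc$pearson_r, r_bottom_pct / 100,
                           names = FALSE, type = 7)
  # strict inequalities at both cutoffs; a 100% tail keeps everything
  in_mi <- if (mi_top_pct >= 100) rep(TRUE, nrow(assoc)) else assoc$mi > mi_cut
  in_r <- if (r_bottom_pct >= 100) rep(TRUE, nrow(assoc))
          else assoc$pearson_r < r_cut
  degen_mi <- max(assoc$mi) == min(assoc$mi)
  degen_r <- max(assoc$pearson_r) == min(assoc$pearson_r)
  if (degen_mi || degen_r)
    warning("degenerate association distribution: empty selection")
  keep <- if (mode == "and") in_mi & in_r else in_mi | in_r
  if (degen_mi || degen_r) keep <- rep(FALSE, nrow(assoc))
  thresholds <- structure(list(mi_cutoff = mi_cut, r_cutoff = r_cut,
                               mi_top_pct = mi_top_pct,
                               r_bottom_pct = r_bottom_pct, mode = mode),
                          class = "selection_thresholds")
  message(sprintf(
    "selection: mi > %.4g and r < %.4g -> %d/%d associations",
    mi_cut, r_cut, sum(keep), nrow(assoc)))
  selected <- assoc[keep, , drop = FALSE]
  rownames(selected) <- NULL
  list(thresholds = thresholds, selected = selected)
}

#' @export
print.selection_thresholds <- function(x, ...) {
  cat(sprintf(
    "<selection_thresholds> mi > %.4g (top %g%%), r < %.4g (bottom %g%%), mode %s\n",
    x$mi_cutoff, x$mi_top_pct, x$r_cutoff, x$r_bottom_pct, x$mode))
  invisible(x)
}

#' Assemble the putative-relationship table
#'
#' A selected (miR, probe) association is emitted once per supporting gene
#' symbol if the (miR-or-family, gene) pair appears in at least one
#' percentile-filtered prediction source. Family-level records (the
#' context+-style source is keyed by miR family) apply to every mature miR
#' of the family. The validated flag is set when the (miR, gene) pair is in
#' the strong-evidence table. Probe-level granularity is preserved: one
#' probe may yield several gene rows and one gene may appear via several
#' probes.
#'
#' @param selected Selected association subset (from
#'   [select_strong_negative()]); mapped with [map_identifiers()] first if
#'   the `gene_symbol` column is absent.
#' @param predictions List with percentile-filtered `targetscan` and
#'   `diana` tables.
#' @param validated Strong-evidence validated table (from
#'   [filter_validated_strong()]).
#' @param idmap An [id_map()].
#' @return Data frame with columns `mir_id`, `probe_id`, `gene_symbol`,
#'   `pearson_r`, `mi_nats`, `targetscan_support`, `diana_support`,
#'   `mirtarbase_validated`, `d_sep_norm`, `d_sep_rank_pct` (the last two
#'   `NA` until filled by [d_sep_annotate()]).
#' @export
build_putative_list <- function(selected, predictions, validated, idmap) {
  if (!"gene_symbol" %in% names(selected))
    selected <- map_identifiers(selected, idmap)
  sel <- selected[!is.na(selected$gene_symbol), , drop = FALSE]

  ts <- predictions$targetscan
  di <- predictions$diana
  # family-level records fan out to every mature miR in the family
  fam_members <- split(idmap$family_mir$mir_id, idmap$family_mir$family)
  ts_keys <- character(0)
  if (!is.null(ts) && nrow(ts) > 0) {
    mature <- fam_members[ts$mir_key]
    len <- lengths(mature)
    direct <- ts$mir_key[len == 0]        # already mature ids
    ts_keys <- c(paste(unlist(mature), rep(ts$gene_symbol, len)),
                 paste(direct, ts$gene_symbol[len == 0]))
  }
  di_keys <- if (!is.null(di) && nrow(di) > 0)
    paste(di$mir_key, di$gene_symbol) else character(0)
  val_keys <- if (!is.null(validated) && nrow(validated) > 0)
    paste(validated$mir_id, validated$gene_symbol) else character(0)

  key <- paste(sel$mir_id, sel$gene_symbol)
  ts_sup <- key %in% ts_keys
  di_sup <- key %in% di_keys
  keep <- ts_sup | di_sup
  out <- data.frame(
    mir_id = sel$mir_id[keep],
    probe_id = sel$probe_id[keep],
    gene_symbol = sel$gene_symbol[keep],
    pearson_r = sel$pearson_r[keep],
    mi_nats = sel$mi[keep],
    targetscan_support = ts_sup[keep],
    diana_support = di_sup[keep],
    mirtarbase_validated = key[keep] %in% val_keys,
    d_sep_norm = NA_real_,
    d_sep_rank_pct = NA_real_,
    stringsAsFactors = FALSE)
  out <- out[order(out$mir_id, out$probe_id, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
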