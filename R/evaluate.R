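#' End-to-end planted-pair recovery on a synthetic study
#'
#' Runs the in-memory screening chain (simulate -> filter -> associate ->
#' select -> integrate) on one synthetic study and scores the putative
#' list against the planted ground truth at the (miR, gene) level:
#' *recall* is the fraction of planted pairs recovered, *precision* the
#' fraction of emitted pairs that were planted.
#'
#' @param config A [sim_config()] describing the study.
#' @param mi_top_pct,r_bottom_pct Selection percentiles (defaults 10 and
#'   2.5).
#' @return List with `recall`, `precision`, `n_putative`, `n_pairs_tested`
#'   and the realised `thresholds`.
#' @export
planted_pair_recovery <- function(config, mi_top_pct = 10,
                                  r_bottom_pct = 2.5) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  panel <- simulate_expression_panel(cfg)
  db <- simulate_prediction_db(panel$truth, cfg,
                               panel[c("probe_gene", "family_mir")])
  fmir <- filter_features(panel$mir)
  fmrna <- filter_features(panel$mrna)
  assoc <- pairwise_associations(fmir$matrix, fmrna$matrix,
                                 mi_params(rng_seed = cfg$rng_seed + 7L))
  sel <- select_strong_negative(assoc, mi_top_pct, r_bottom_pct)
  idmap <- id_map(panel$probe_gene, panel$family_mir)
  preds <- list(
    targetscan = percentile_filter_predictions(db$targetscan, "targetscan"),
    diana = percentile_filter_predictions(db$diana, "diana"))
  put <- build_putative_list(sel$selected, preds,
                             filter_validated_strong(db$validated), idmap)
  gene_of <- stats::setNames(panel$probe_gene$gene_symbol,
                             panel$probe_gene$probe_id)
  truth_keys <- unique(paste(panel$truth$mir_id,
                             gene_of[panel$truth$mrna_id]))
  put_keys <- unique(paste(put$mir_id, put$gene_symbol))
  list(recall = mean(truth_keys %in% put_keys),
       precision = if (length(put_keys) > 0)
         mean(put_keys %in% truth_keys) else NA_real_,
       n_putative = length(put_keys),
       n_pairs_tested = nrow(assoc),
       thresholds = sel$thresholds)
}
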