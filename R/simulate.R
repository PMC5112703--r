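#' Simulation configuration
#'
#' Defines the synthetic study: a melanoma-cell-line-style panel of paired
#' miR and mRNA-probe log2 abundance matrices with planted repressive
#' miR->mRNA relationships, matching prediction/validation tables, GO
#' annotations, phenotype labels and a small barcode-keyed cohort. Defaults
#' mirror the scale of a 57-line panel with 2592 miRs (a large fraction
#' never detected) and tens of thousands of probes.
#'
#' Abundances are generated directly on the log2 scale. Most expressed
#' features are "stable" (baseline mean ~ Normal(6, 2) across features,
#' modest within-feature spread); a fraction of miRs are "on/off" bimodal
#' across samples, emulating lineage-restricted miRs with a large dynamic
#' range -- these are the only miRs with enough signal to support detectable
#' repression, so planted pairs always use them.
#'
#' @param n_samples Number of samples (cell lines). Default 57.
#' @param n_mirs Number of miR features. Default 2592.
#' @param n_mrnas Number of mRNA probes. Default 20000.
#' @param frac_zero_mirs Fraction of miRs with no reads in any sample
#'   (all-zero rows). Default 916/2592.
#' @param frac_bimodal_mirs Fraction of miRs in the high-dynamic-range
#'   on/off regime. Default 0.15.
#' @param n_true_pairs Number of planted repressive miR->mRNA pairs.
#' @param slope_range Interval of repression slopes (log2/log2 units, both
#'   endpoints negative). Default c(-2, -0.5).
#' @param frac_nonlinear Fraction of planted pairs using a monotone
#'   decreasing sigmoidal (logistic) repression rather than a linear one.
#' @param noise_sd Residual noise on target mRNA abundance, log2 units.
#' @param group_effect Centroid shift (log2 units) between the high- and
#'   low-invasiveness groups, applied to the miR of phenotype-linked pairs.
#' @param frac_phenotype_linked Fraction of planted pairs linked to the
#'   phenotype grouping. Default 0.5.
#' @param db_coverage Probability that a planted pair appears in each
#'   prediction source. Default 0.8.
#' @param n_decoys Number of random non-planted pairs added to each
#'   prediction source. Default 5000.
#' @param n_labelled Number of samples with an invasiveness label (split
#'   evenly high/low; the remainder are unknown). Default 24.
#' @param n_cohort_samples,n_cohort_patients Reduced-scale cohort table
#'   sizes; at the defaults (10 samples, 9 patients) one patient
#'   contributes two samples.
#' @param rng_seed Integer seed; identical config + seed gives identical
#'   output, byte for byte.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 57, n_mirs = 2592, n_mrnas = 20000,
                       frac_zero_mirs = 916 / 2592,
                       frac_bimodal_mirs = 0.15,
                       n_true_pairs = 30,
                       slope_range = c(-2, -0.5),
                       frac_nonlinear = 0.3,
                       noise_sd = 0.5,
                       group_effect = 2,
                       frac_phenotype_linked = 0.5,
                       db_coverage = 0.8,
                       n_decoys = 5000,
                       n_labelled = 24,
                       n_cohort_samples = 10,
                       n_cohort_patients = 9,
                       rng_seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_mirs = as.integer(n_mirs),
              n_mrnas = as.integer(n_mrnas),
              frac_zero_mirs = frac_zero_mirs,
              frac_bimodal_mirs = frac_bimodal_mirs,
              n_true_pairs = as.integer(n_true_pairs),
              slope_range = sort(as.numeric(slope_range)),
              frac_nonlinear = frac_nonlinear, noise_sd = noise_sd,
              group_effect = group_effect,
              frac_phenotype_linked = frac_phenotype_linked,
              db_coverage = db_coverage, n_decoys = as.integer(n_decoys),
              n_labelled = as.integer(n_labelled),
              n_cohort_samples = as.integer(n_cohort_samples),
              n_cohort_patients = as.integer(n_cohort_patients),
              rng_seed = as.integer(rng_seed))
  counts <- c("n_samples", "n_mirs", "n_mrnas", "n_true_pairs",
              "n_cohort_samples", "n_cohort_patients")
  for (f in counts)
    if (cfg[[f]] <= 0) stop(f, " must be a positive count")
  fracs <- c("frac_zero_mirs", "frac_bimodal_mirs", "frac_nonlinear",
             "frac_phenotype_linked", "db_coverage")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (any(cfg$slope_range >= 0)) stop("slope_range must be strictly negative")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$n_true_pairs > cfg$n_mirs * cfg$n_mrnas)
    stop("configuration error: n_true_pairs exceeds n_mirs * n_mrnas")
  if (cfg$n_true_pairs > cfg$n_mrnas)
    stop("configuration error: n_true_pairs exceeds the number of mRNAs")
  n_zero <- round(cfg$frac_zero_mirs * cfg$n_mirs)
  if (cfg$n_true_pairs > cfg$n_mirs - n_zero)
    stop("configuration error: not enough expressed miRs for n_true_pairs")
  if (cfg$n_labelled > cfg$n_samples)
    stop("n_labelled cannot exceed n_samples")
  if (cfg$n_cohort_patients > cfg$n_cohort_samples)
    stop("n_cohort_patients cannot exceed n_cohort_samples")
  structure(cfg, class = "sim_config")
}

# deterministic identifier schemes (no RNG)
sim_sample_ids <- function(cfg) sprintf("SIMCL-%02d", seq_len(cfg$n_samples))
sim_mir_ids <- function(cfg) sprintf("sim-miR-%04d", seq_len(cfg$n_mirs))
sim_probe_ids <- function(cfg) sprintf("SIMPROBE_%05d", seq_len(cfg$n_mrnas))

# probe -> gene map: ~1.3 probes per gene on average, deterministic
sim_probe_gene <- function(cfg) {
  gene_idx <- ceiling(seq_len(cfg$n_mrnas) / 1.3)
  data.frame(probe_id = sim_probe_ids(cfg),
             gene_symbol = sprintf("SGENE%05d", gene_idx),
             stringsAsFactors = FALSE)
}

# miR family map: two mature miRs per family, deterministic
sim_family_mir <- function(cfg) {
  data.frame(family = sprintf("sim-miR-fam-%04d",
                              ceiling(seq_len(cfg$n_mirs) / 2)),
             mir_id = sim_mir_ids(cfg), stringsAsFactors = FALSE)
}

# invasiveness group assignment, drawn from its own seeded stream so that
# the panel generator and the annotation generator agree on it
sim_phenotype_assignment <- function(cfg) {
  set.seed(cfg$rng_seed + 101L)
  lab <- rep("unknown", cfg$n_samples)
  idx <- sample(cfg$n_samples, cfg$n_labelled)
  n_high <- ceiling(cfg$n_labelled / 2)
  lab[idx[seq_len(n_high)]] <- "high"
  lab[idx[seq(n_high + 1, length.out = cfg$n_labelled - n_high)]] <- "low"
  names(lab) <- sim_sample_ids(cfg)
  lab
}

#' Generate the paired synthetic expression panel
#'
#' Produces the miR and mRNA-probe log2 abundance matrices and the ground
#' truth of planted repressive pairs. Linear pairs follow
#' `mRNA = intercept + slope * miR + Normal(0, noise_sd)`; sigmoidal pairs
#' follow a monotone-decreasing logistic `a - b / (1 + exp(-s (x - x0)))`
#' with the same additive noise. Phenotype-linked pairs receive a
#' `+group_effect/2` / `-group_effect/2` shift of the miR between the low-
#' and high-invasiveness sample groups *before* the target mRNA is
#' generated, so the shift propagates mechanistically to the target.
#' All abundances are clipped at zero (log2 of zero reads).
#'
#' @param config A [sim_config()].
#' @return A list with elements `mir` and `mrna` ([expression_matrix()]),
#'   `truth` (data frame: `mir_id`, `mrna_id`, `mechanism`, `slope`,
#'   `phenotype_linked`), `probe_gene` and `family_mir` (identifier maps).
#' @export
simulate_expression_panel <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  pheno <- sim_phenotype_assignment(cfg)
  set.seed(cfg$rng_seed)
  n <- cfg$n_samples
  samples <- sim_sample_ids(cfg)
  mir_ids <- sim_mir_ids(cfg)
  probe_ids <- sim_probe_ids(cfg)

  ## --- miR matrix -------------------------------------------------------
  n_zero <- round(cfg$frac_zero_mirs * cfg$n_mirs)
  zero_idx <- sample(cfg$n_mirs, n_zero)
  expressed <- setdiff(seq_len(cfg$n_mirs), zero_idx)
  n_bimodal <- min(length(expressed),
                   max(round(cfg$frac_bimodal_mirs * cfg$n_mirs),
                       cfg$n_true_pairs))
  bimodal_idx <- sample(expressed, n_bimodal)
  stable_idx <- setdiff(expressed, bimodal_idx)

  mir <- matrix(0, cfg$n_mirs, n, dimnames = list(mir_ids, samples))
  if (length(stable_idx)) {
    mu <- stats::rnorm(length(stable_idx), 6, 2)
    sdv <- abs(stats::rnorm(length(stable_idx), 0.5, 0.25)) + 0.15
    mir[stable_idx, ] <- matrix(
      stats::rnorm(length(stable_idx) * n, mean = rep(mu, n),
                   sd = rep(sdv, n)), ncol = n)
  }
  for (i in bimodal_idx) {
    hi <- stats::rnorm(1, 9, 1.5)
    p_on <- stats::runif(1, 0.3, 0.7)
    on <- stats::runif(n) < p_on
    v <- ifelse(on, stats::rnorm(n, hi, 0.8), stats::rnorm(n, 0.5, 0.4))
    mir[i, ] <- v
  }
  mir <- pmax(mir, 0)

  ## --- planted pairs ----------------------------------------------------
  true_mirs <- sample(bimodal_idx, cfg$n_true_pairs)
  true_mrnas <- sample(cfg$n_mrnas, cfg$n_true_pairs)
  n_sig <- round(cfg$frac_nonlinear * cfg$n_true_pairs)
  mech <- rep("linear", cfg$n_true_pairs)
  if (n_sig > 0) mech[sample(cfg$n_true_pairs, n_sig)] <- "sigmoidal"
  slopes <- stats::runif(cfg$n_true_pairs, cfg$slope_range[1],
                         cfg$slope_range[2])
  n_ph <- round(cfg$frac_phenotype_linked * cfg$n_true_pairs)
  ph_linked <- rep(FALSE, cfg$n_true_pairs)
  if (n_ph > 0) ph_linked[sample(cfg$n_true_pairs, n_ph)] <- TRUE

  # phenotype shift on the miR (high-invasive lines lose the miR)
  shift <- ifelse(pheno == "high", -cfg$group_effect / 2,
                  ifelse(pheno == "low", cfg$group_effect / 2, 0))
  for (p in which(ph_linked))
    mir[true_mirs[p], ] <- pmax(mir[true_mirs[p], ] + shift, 0)

  ## --- mRNA matrix ------------------------------------------------------
  mu <- stats::rnorm(cfg$n_mrnas, 7, 1.5)
  sdv <- stats::runif(cfg$n_mrnas, 0.3, 1.5)
  mrna <- matrix(stats::rnorm(cfg$n_mrnas * n, mean = rep(mu, n),
                              sd = rep(sdv, n)),
                 ncol = n, dimnames = list(probe_ids, samples))
  # clip the background before planting: planted targets follow their
  # generative formula exactly (noise_sd = 0 gives an exactly linear pair)
  mrna <- pmax(mrna, 0)

  for (p in seq_len(cfg$n_true_pairs)) {
    x <- mir[true_mirs[p], ]
    target_mean <- stats::rnorm(1, 8, 1)
    eps <- stats::rnorm(n, 0, cfg$noise_sd)
    y <- if (mech[p] == "linear") {
      (target_mean - slopes[p] * mean(x)) + slopes[p] * x + eps
    } else {
      b <- abs(slopes[p]) * (max(x) - min(x))
      s <- 2 / (stats::sd(x) + 1e-9)
      x0 <- stats::median(x)
      lg <- 1 / (1 + exp(-s * (x - x0)))
      (target_mean + b * mean(lg)) - b * lg + eps
    }
    mrna[true_mrnas[p], ] <- y
  }

  truth <- data.frame(mir_id = mir_ids[true_mirs],
                      mrna_id = probe_ids[true_mrnas],
                      mechanism = mech, slope = slopes,
                      phenotype_linked = ph_linked,
                      stringsAsFactors = FALSE)
  list(mir = expression_matrix(mir, "miR"),
       mrna = expression_matrix(mrna, "mRNA-probe"),
       truth = truth,
       probe_gene = sim_probe_gene(cfg),
       family_mir = sim_family_mir(cfg))
}

# score regions for the two synthetic prediction sources: the full score
# distribution spans each source's plausible range; genuinely repressive
# pairs score in the high-confidence tail (the region that survives the
# default 15% / 30% percentile filters)
.ts_full <- c(-1.20, -0.01)
.ts_true <- c(-1.20, -1.05)
.di_full <- c(0.02, 0.98)
.di_true <- c(0.80, 0.98)

#' Generate synthetic target-prediction and validation tables
#'
#' Each planted pair enters each prediction source with probability
#' `db_coverage`, scored inside that source's high-confidence region
#' (most-negative tail for the context+-style score, upper tail for the
#' miTG-style score); `n_decoys` random non-planted (miR, gene) pairs per
#' source draw scores from the full score range. A random subset of planted
#' pairs is emitted as experimentally validated interactions with a method
#' drawn from luciferase reporter assay, qRT-PCR, Western blot or
#' microarray (the last being weak evidence).
#'
#' @param truth Ground-truth pair table from [simulate_expression_panel()].
#' @param config The same [sim_config()].
#' @param idmap List with `probe_gene` and `family_mir` data frames (as
#'   returned by [simulate_expression_panel()]).
#' @return List with `targetscan`, `diana` (columns `mir_key`,
#'   `gene_symbol`, `score`) and `validated` (columns `mir_id`,
#'   `gene_symbol`, `method`).
#' @export
simulate_prediction_db <- function(truth, config, idmap) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  if (nrow(truth) == 0) stop("truth table must be non-empty")
  set.seed(cfg$rng_seed + 1L)
  gene_of <- stats::setNames(idmap$probe_gene$gene_symbol,
                             idmap$probe_gene$probe_id)
  fam_of <- stats::setNames(idmap$family_mir$family, idmap$family_mir$mir_id)
  truth$gene_symbol <- unname(gene_of[truth$mrna_id])
  true_keys <- paste(truth$mir_id, truth$gene_symbol)

  in_ts <- stats::runif(nrow(truth)) < cfg$db_coverage
  in_di <- stats::runif(nrow(truth)) < cfg$db_coverage
  ts <- data.frame(mir_key = unname(fam_of[truth$mir_id[in_ts]]),
                   gene_symbol = truth$gene_symbol[in_ts],
                   score = stats::runif(sum(in_ts), .ts_true[1], .ts_true[2]),
                   stringsAsFactors = FALSE)
  di <- data.frame(mir_key = truth$mir_id[in_di],
                   gene_symbol = truth$gene_symbol[in_di],
                   score = stats::runif(sum(in_di), .di_true[1], .di_true[2]),
                   stringsAsFactors = FALSE)

  genes <- unique(idmap$probe_gene$gene_symbol)
  mirs <- idmap$family_mir$mir_id
  draw_decoys <- function() {
    out <- NULL
    need <- cfg$n_decoys
    while (need > 0) {
      cand <- data.frame(mir_id = sample(mirs, need, replace = TRUE),
                         gene_symbol = sample(genes, need, replace = TRUE),
                         stringsAsFactors = FALSE)
      cand <- cand[!(paste(cand$mir_id, cand$gene_symbol) %in% true_keys), ,
                   drop = FALSE]
      cand <- cand[!duplicated(paste(cand$mir_id, cand$gene_symbol)), ,
                   drop = FALSE]
      out <- rbind(out, cand)
      out <- out[!duplicated(paste(out$mir_id, out$gene_symbol)), ,
                 drop = FALSE]
      need <- cfg$n_decoys - nrow(out)
    }
    out
  }
  dts <- draw_decoys()
  ts <- rbind(ts, data.frame(mir_key = unname(fam_of[dts$mir_id]),
                             gene_symbol = dts$gene_symbol,
                             score = stats::runif(nrow(dts), .ts_full[1],
                                                  .ts_full[2]),
                             stringsAsFactors = FALSE))
  ddi <- draw_decoys()
  di <- rbind(di, data.frame(mir_key = ddi$mir_id,
                             gene_symbol = ddi$gene_symbol,
                             score = stats::runif(nrow(ddi), .di_full[1],
                                                  .di_full[2]),
                             stringsAsFactors = FALSE))

  methods <- c("Luciferase reporter assay", "qRT-PCR", "Western blot",
               "Microarray")
  is_val <- stats::runif(nrow(truth)) < 0.5
  validated <- data.frame(mir_id = truth$mir_id[is_val],
                          gene_symbol = truth$gene_symbol[is_val],
                          method = sample(methods, sum(is_val),
                                          replace = TRUE),
                          stringsAsFactors = FALSE)
  list(targetscan = ts, diana = di, validated = validated)
}

#' Generate synthetic GO annotations and phenotype labels
#'
#' The GO table contains categories whose names include the substrings
#' `epith`, `mesench`, `pigment` and `melan` plus non-matching categories,
#' with member counts below 5, within 5-500 and above 500 (so the size
#' filter is exercised in both directions). Phenotype labels mark
#' `n_labelled` samples (default 24 of 57) as high- or low-invasiveness;
#' the rest are unknown.
#'
#' @param config A [sim_config()].
#' @return List with `go` (data frame: `term_id`, `name`, `members` -- a
#'   list column of gene symbols) and `labels` (data frame: `sample_id`,
#'   `group`).
#' @export
simulate_annotations <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  pheno <- sim_phenotype_assignment(cfg)
  set.seed(cfg$rng_seed + 2L)
  genes <- unique(sim_probe_gene(cfg)$gene_symbol)
  spec <- list(
    c("epithelial to mesenchymal transition", 60),
    c("mesenchymal cell differentiation", 35),
    c("epithelium development", 501),
    c("melanin biosynthetic process", 4),
    c("melanocyte differentiation", 25),
    c("pigmentation", 120),
    c("regulation of pigment cell proliferation", 12),
    c("cell cycle", 300),
    c("dna repair", 90),
    c("ribosome biogenesis", 3),
    c("immune response", 550),
    c("oxidative phosphorylation", 45))
  go <- data.frame(term_id = sprintf("GO:%07d", seq_along(spec)),
                   name = vapply(spec, `[`, "", 1),
                   stringsAsFactors = FALSE)
  sizes <- pmin(as.integer(vapply(spec, `[`, "", 2)), length(genes))
  go$members <- I(lapply(sizes, function(k) sample(genes, k)))
  labels <- data.frame(sample_id = names(pheno), group = unname(pheno),
                       stringsAsFactors = FALSE)
  list(go = go, labels = labels)
}

#' Generate a reduced-scale barcode-keyed cohort
#'
#' Emulates a matched tumour cohort: two sample-per-row tables (miR and
#' mRNA) keyed by synthetic patient/sample barcodes with partial overlap,
#' where at least one patient contributes two distinct samples.
#'
#' @param config A [sim_config()].
#' @return List with `mir_table` and `mrna_table` data frames (`barcode`
#'   column plus numeric feature columns).
#' @export
simulate_cohort <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  set.seed(cfg$rng_seed + 3L)
  patients <- sprintf("SIMTCGA-%02d", seq_len(cfg$n_cohort_patients))
  # one sample per patient, plus repeat samples for the first patient(s)
  n_extra <- cfg$n_cohort_samples - cfg$n_cohort_patients
  vial <- c(rep("-01", cfg$n_cohort_patients), rep("-06", n_extra))
  barcodes <- paste0(c(patients, patients[seq_len(n_extra)]), vial)
  mirs <- sprintf("sim-miR-%04d", 1:6)
  genes <- sprintf("SGENE%05d", 1:8)
  mk <- function(bcs, feats) {
    m <- matrix(round(stats::rnorm(length(bcs) * length(feats), 8, 2), 4),
                nrow = length(bcs), dimnames = list(NULL, feats))
    data.frame(barcode = bcs, m, check.names = FALSE,
               stringsAsFactors = FALSE)
  }
  # partial overlap: each table misses one (different) single-sample
  # patient, so the duplicate-sample patient stays present in both
  drop_mir <- min(2L, length(barcodes))
  drop_mrna <- min(3L, length(barcodes))
  mir_table <- mk(barcodes[-drop_mir], mirs)
  mrna_table <- mk(barcodes[-drop_mrna], genes)
  list(mir_table = mir_table, mrna_table = mrna_table)
}

#' Generate the complete synthetic study
#'
#' Convenience wrapper running all generators off one configuration.
#'
#' @param config A [sim_config()] or a list of its arguments.
#' @return List with `mir`, `mrna`, `truth`, `probe_gene`, `family_mir`,
#'   `targetscan`, `diana`, `validated`, `go`, `labels`, `cohort`.
#' @export
simulate_study <- function(config = sim_config()) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  panel <- simulate_expression_panel(cfg)
  db <- simulate_prediction_db(panel$truth, cfg,
                               idmap = panel[c("probe_gene", "family_mir")])
  ann <- simulate_annotations(cfg)
  cohort <- simulate_cohort(cfg)
  c(panel, db, ann, list(cohort = cohort))
}

#' Write a simulated study to TSV files
#'
#' Everything is written as headered TSV (the GO table as ragged
#' tab-separated member lists, see [write_go_table()]).
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    mir = write_expression(sim$mir, file.path(dir, "mir_abundance.tsv")),
    mrna = write_expression(sim$mrna, file.path(dir, "mrna_abundance.tsv")),
    truth = w(sim$truth, "ground_truth.tsv"),
    probe_gene = w(sim$probe_gene, "probe_gene_map.tsv"),
    family_mir = w(sim$family_mir, "family_mir_map.tsv"),
    targetscan = w(sim$targetscan, "targetscan_predictions.tsv"),
    diana = w(sim$diana, "diana_predictions.tsv"),
    validated = w(sim$validated, "validated_interactions.tsv"),
    labels = w(sim$labels, "phenotype_labels.tsv"),
    go = write_go_table(sim$go, file.path(dir, "go_annotations.tsv")),
    cohort_mir = w(sim$cohort$mir_table, "cohort_mir.tsv"),
    cohort_mrna = w(sim$cohort$mrna_table, "cohort_mrna.tsv"))
  invisible(paths)
}
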