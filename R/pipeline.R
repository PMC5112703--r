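#' Pipeline configuration
#'
#' Builds (and validates) the single declarative configuration driving
#' [run_pipeline()]. `x` may be a list, a YAML file or a JSON file. A
#' configuration either names every input table under `inputs` or carries a
#' `simulate` block ([sim_config()] arguments) from which all inputs are
#' generated. All randomness flows from the top-level `seed`.
#'
#' Sections and defaults:
#' * `seed` (1), `out_dir` ("mirassoc_run")
#' * `simulate`: list of [sim_config()] arguments, or `NULL`
#' * `inputs`: paths `mir`, `mrna`, `targetscan`, `diana`, `validated`,
#'   `go`, `labels`, `probe_gene`, `family_mir`
#' * `preprocess`: `abundance_percentile` 10, `min_frac_above` 0.25,
#'   `range_percentile` 90, `mrna_range_frac` 0.10, `mir_range_mode`
#'   "abundance", `quantile_normalize_mrna` FALSE, `log2_offset` NULL
#'   (set to e.g. 1 when inputs are on the raw scale)
#' * `mi`: `k` 4, `noise_amplitude` 1e-8
#' * `selection`: `mi_top_pct` 10, `r_bottom_pct` 2.5, `mode` "and"
#' * `predictions`: `targetscan_pct` 15, `diana_pct` 30
#' * `go`: `substrings` epith/mesench/pigment/melan, `min_size` 5,
#'   `max_size` 500
#'
#' @param x List, or path to a YAML/JSON configuration file.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (inherits(x, "pipeline_config")) return(x)
  if (is.character(x)) {
    x <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::fromJSON(x, simplifyVector = TRUE) else yaml::read_yaml(x)
  }
  defaults <- list(
    seed = 1L,
    out_dir = "mirassoc_run",
    simulate = NULL,
    inputs = NULL,
    preprocess = list(abundance_percentile = 10, min_frac_above = 0.25,
                      range_percentile = 90, mrna_range_frac = 0.10,
                      mir_range_mode = "abundance",
                      quantile_normalize_mrna = FALSE, log2_offset = NULL),
    mi = list(k = 4, noise_amplitude = 1e-8),
    selection = list(mi_top_pct = 10, r_bottom_pct = 2.5, mode = "and"),
    predictions = list(targetscan_pct = 15, diana_pct = 30),
    go = list(substrings = c("epith", "mesench", "pigment", "melan"),
              min_size = 5, max_size = 500))
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  pct <- c(cfg$selection$mi_top_pct, cfg$selection$r_bottom_pct,
           cfg$predictions$targetscan_pct, cfg$predictions$diana_pct)
  if (any(pct <= 0 | pct >= 100))
    stop("all percentiles must lie strictly between 0 and 100")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("configuration needs either a simulate block or input paths")
  structure(cfg, class = "pipeline_config")
}

# canonical file layout inside out_dir
pipeline_paths <- function(cfg) {
  o <- cfg$out_dir
  list(
    inputs_dir = file.path(o, "inputs"),
    filtered_mir = file.path(o, "filtered_mir.tsv"),
    filtered_mrna = file.path(o, "filtered_mrna.tsv"),
    filter_report_mir = file.path(o, "filter_report_mir.json"),
    filter_report_mrna = file.path(o, "filter_report_mrna.json"),
    associations = file.path(o, "associations.tsv"),
    selected = file.path(o, "selected.tsv"),
    thresholds = file.path(o, "selection_thresholds.json"),
    putative = file.path(o, "putative.tsv"),
    enrichment_mir = file.path(o, "enrichment_mir.tsv"),
    enrichment_go = file.path(o, "enrichment_go.tsv"),
    dsep = file.path(o, "dsep.tsv"),
    manifest = file.path(o, "manifest.json"))
}

# input paths: simulated layout when a simulate block is present
pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    d <- pipeline_paths(cfg)$inputs_dir
    list(mir = file.path(d, "mir_abundance.tsv"),
         mrna = file.path(d, "mrna_abundance.tsv"),
         truth = file.path(d, "ground_truth.tsv"),
         targetscan = file.path(d, "targetscan_predictions.tsv"),
         diana = file.path(d, "diana_predictions.tsv"),
         validated = file.path(d, "validated_interactions.tsv"),
         go = file.path(d, "go_annotations.tsv"),
         labels = file.path(d, "phenotype_labels.tsv"),
         probe_gene = file.path(d, "probe_gene_map.tsv"),
         family_mir = file.path(d, "family_mir_map.tsv"))
  } else cfg$inputs
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

load_manifest <- function(cfg) {
  p <- pipeline_paths(cfg)$manifest
  if (file.exists(p)) jsonlite::fromJSON(p, simplifyVector = TRUE)
  else list(stages_run = character(0))
}

save_manifest <- function(manifest, cfg) {
  jsonlite::write_json(manifest, pipeline_paths(cfg)$manifest,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  manifest
}

stage_simulate <- function(cfg, manifest) {
  sim_args <- if (is.null(cfg$simulate)) list() else cfg$simulate
  sim_args$rng_seed <- cfg$seed
  sim <- simulate_study(do.call(sim_config, sim_args))
  paths <- write_simulation(sim, pipeline_paths(cfg)$inputs_dir)
  manifest$simulate <- list(
    n_samples = ncol(sim$mir), n_mirs = nrow(sim$mir),
    n_mrnas = nrow(sim$mrna), n_true_pairs = nrow(sim$truth),
    files = as.list(paths))
  manifest
}

stage_preprocess <- function(cfg, manifest) {
  inp <- pipeline_inputs(cfg)
  pp <- cfg$preprocess
  mir <- read_expression(inp$mir, "miR")
  mrna <- read_expression(inp$mrna, "mRNA-probe")
  if (!is.null(pp$log2_offset)) {
    mir <- log2_transform(mir, pp$log2_offset)
    mrna <- log2_transform(mrna, pp$log2_offset)
  }
  if (isTRUE(pp$quantile_normalize_mrna)) mrna <- quantile_normalize(mrna)
  f_mir <- filter_features(mir, pp$abundance_percentile, pp$min_frac_above,
                           pp$range_percentile, pp$mrna_range_frac,
                           pp$mir_range_mode)
  f_mrna <- filter_features(mrna, pp$abundance_percentile, pp$min_frac_above,
                            pp$range_percentile, pp$mrna_range_frac,
                            pp$mir_range_mode)
  pth <- pipeline_paths(cfg)
  write_expression(f_mir$matrix, pth$filtered_mir)
  write_expression(f_mrna$matrix, pth$filtered_mrna)
  jsonlite::write_json(unclass(f_mir$report), pth$filter_report_mir,
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(f_mrna$report), pth$filter_report_mrna,
                       auto_unbox = TRUE, digits = NA)
  manifest$preprocess <- list(mir = unclass(f_mir$report),
                              mrna = unclass(f_mrna$report))
  manifest
}

stage_associate <- function(cfg, manifest) {
  pth <- pipeline_paths(cfg)
  mir <- read_expression(pth$filtered_mir, "miR")
  mrna <- read_expression(pth$filtered_mrna, "mRNA-probe")
  params <- mi_params(cfg$mi$k, cfg$mi$noise_amplitude,
                      rng_seed = cfg$seed + 7L)
  assoc <- pairwise_associations(mir, mrna, params)
  write_tsv(assoc, pth$associations)
  manifest$associate <- list(n_pairs = nrow(assoc), k = params$k,
                             noise_amplitude = params$noise_amplitude)
  manifest
}

stage_select <- function(cfg, manifest) {
  pth <- pipeline_paths(cfg)
  assoc <- read_tsv(pth$associations)
  sel <- select_strong_negative(assoc, cfg$selection$mi_top_pct,
                                cfg$selection$r_bottom_pct,
                                cfg$selection$mode)
  write_tsv(sel$selected, pth$selected)
  jsonlite::write_json(unclass(sel$thresholds), pth$thresholds,
                       auto_unbox = TRUE, digits = NA)
  manifest$select <- c(unclass(sel$thresholds),
                       list(n_selected = nrow(sel$selected)))
  manifest
}

stage_integrate <- function(cfg, manifest) {
  inp <- pipeline_inputs(cfg)
  pth <- pipeline_paths(cfg)
  ts <- percentile_filter_predictions(
    load_predictions(inp$targetscan, "targetscan"),
    percentile = cfg$predictions$targetscan_pct)
  di <- percentile_filter_predictions(
    load_predictions(inp$diana, "diana"),
    percentile = cfg$predictions$diana_pct)
  validated <- filter_validated_strong(read_tsv(inp$validated))
  idmap <- read_id_map(inp$probe_gene, inp$family_mir)
  selected <- read_tsv(pth$selected)
  putative <- build_putative_list(map_identifiers(selected, idmap),
                                  list(targetscan = ts, diana = di),
                                  validated, idmap)
  write_tsv(putative, pth$putative)
  manifest$integrate <- list(
    targetscan_cutoff = attr(ts, "cutoff"), diana_cutoff = attr(di, "cutoff"),
    n_targetscan = nrow(ts), n_diana = nrow(di),
    n_validated_strong = nrow(validated), n_putative = nrow(putative))
  manifest
}

stage_enrich <- function(cfg, manifest) {
  inp <- pipeline_inputs(cfg)
  pth <- pipeline_paths(cfg)
  ts <- percentile_filter_predictions(
    load_predictions(inp$targetscan, "targetscan"),
    percentile = cfg$predictions$targetscan_pct)
  di <- percentile_filter_predictions(
    load_predictions(inp$diana, "diana"),
    percentile = cfg$predictions$diana_pct)
  idmap <- read_id_map(inp$probe_gene, inp$family_mir)
  putative <- read_tsv(pth$putative)
  universe <- map_identifiers(read_tsv(pth$associations), idmap)
  enr <- mir_active_enrichment(putative, list(targetscan = ts, diana = di),
                               universe, idmap)
  write_tsv(enr, pth$enrichment_mir)

  go <- read_go_table(inp$go)
  bundles <- list(EMP = c("epith", "mesench"),
                  Pigmentation = c("pigment", "melan"))
  bg <- unique(universe$gene_symbol[!is.na(universe$gene_symbol)])
  targets <- unique(putative$gene_symbol)
  go_rows <- lapply(names(bundles), function(b) {
    cats <- select_go_categories(go, bundles[[b]], cfg$go$min_size,
                                 cfg$go$max_size)
    if (length(targets) == 0)
      return(data.frame(bundle = b, n_categories = nrow(cats),
                        fraction_annotated = NA_real_, fold = NA_real_))
    e <- go_target_enrichment(targets, cats, bg)
    data.frame(bundle = b, n_categories = nrow(cats),
               fraction_annotated = e$fraction_annotated, fold = e$fold,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, go_rows), pth$enrichment_go)
  manifest$enrich <- list(n_mir_rows = nrow(enr),
                          n_target_genes = length(targets))
  manifest
}

stage_dsep <- function(cfg, manifest) {
  inp <- pipeline_inputs(cfg)
  pth <- pipeline_paths(cfg)
  mir <- read_expression(pth$filtered_mir, "miR")
  mrna <- read_expression(pth$filtered_mrna, "mRNA-probe")
  labels <- read_tsv(inp$labels)
  assoc <- read_tsv(pth$associations)
  putative <- read_tsv(pth$putative)
  ann <- d_sep_annotate(putative, mir, mrna, assoc, labels)
  write_tsv(ann$putative, pth$putative)
  sel_keys <- paste(read_tsv(pth$selected)$mir_id,
                    read_tsv(pth$selected)$probe_id)
  scored_sel <- ann$dsep[paste(ann$dsep$mir_id, ann$dsep$probe_id) %in%
                           sel_keys, , drop = FALSE]
  write_tsv(scored_sel, pth$dsep)
  manifest$dsep <- list(n_scored = nrow(ann$dsep),
                        n_selected_scored = nrow(scored_sel))
  manifest
}

pipeline_stage_funs <- list(
  simulate = stage_simulate, preprocess = stage_preprocess,
  associate = stage_associate, select = stage_select,
  integrate = stage_integrate, enrich = stage_enrich, dsep = stage_dsep)

#' Run the association-mining pipeline
#'
#' Executes (a subset of) the stages `simulate` -> `preprocess` ->
#' `associate` -> `select` -> `integrate` -> `enrich` -> `dsep`, writing
#' every stage table as TSV under `out_dir` together with a JSON manifest
#' holding all realised data-driven thresholds and row counts. Running
#' individual stages sequentially on each other's outputs reproduces a full
#' run byte for byte; identical config + seed gives identical outputs.
#'
#' @param config A [pipeline_config()], list, or YAML/JSON path.
#' @param stages Character vector of stages to run; default all (with
#'   `simulate` included only when the configuration has a simulate block).
#' @return The manifest, an object of class `mirassoc_run`, invisibly on
#'   error paths and visibly otherwise.
#' @export
run_pipeline <- function(config, stages = NULL) {
  cfg <- pipeline_config(config)
  all_stages <- names(pipeline_stage_funs)
  if (is.null(stages)) {
    stages <- if (is.null(cfg$simulate)) setdiff(all_stages, "simulate")
    else all_stages
  }
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- load_manifest(cfg)
  manifest$seed <- cfg$seed
  for (st in stages) {
    t0 <- Sys.time()
    manifest <- tryCatch(
      pipeline_stage_funs[[st]](cfg, manifest),
      error = function(e) {
        save_manifest(manifest, cfg)  # partial manifest
        stop(sprintf("pipeline stage '%s' failed: %s", st,
                     conditionMessage(e)), call. = FALSE)
      })
    manifest$stages_run <- union(manifest$stages_run, st)
    message(sprintf("stage %-10s done in %.2fs", st,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    save_manifest(manifest, cfg)
  }
  structure(manifest, class = "mirassoc_run")
}

#' @export
print.mirassoc_run <- function(x, ...) {
  cat("<mirassoc_run> stages:", paste(x$stages_run, collapse = " > "), "\n")
  if (!is.null(x$preprocess))
    cat(sprintf("  retained %d miRs, %d probes\n",
                x$preprocess$mir$n_retained, x$preprocess$mrna$n_retained))
  if (!is.null(x$associate))
    cat(sprintf("  %d associations\n", x$associate$n_pairs))
  if (!is.null(x$select))
    cat(sprintf("  selected %d (mi > %.4g, r < %.4g)\n",
                x$select$n_selected, x$select$mi_cutoff, x$select$r_cutoff))
  if (!is.null(x$integrate))
    cat(sprintf("  putative relationships: %d\n", x$integrate$n_putative))
  invisible(x)
}

#' @export
summary.mirassoc_run <- function(object, ...) {
  print(object)
  if (!is.null(object$integrate))
    cat(sprintf(
      "  prediction cutoffs: context+ < %.4g, miTG > %.4g; validated-strong %d\n",
      object$integrate$targetscan_cutoff, object$integrate$diana_cutoff,
      object$integrate$n_validated_strong))
  if (!is.null(object$dsep))
    cat(sprintf("  d_sep scored pairs: %d\n", object$dsep$n_scored))
  invisible(object)
}
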