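# one-sided hypergeometric tail P(X >= obs) when drawing n from an urn of
# N with K successes
hyper_tail_p <- function(obs, K, N, n) {
  stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-miR enrichment of active associations
#'
#' For each prediction source and each miR present in the association
#' universe, counts the predicted (miR, gene) pairs whose gene is
#' represented among the retained probes (`n_predicted_in_universe`) and
#' how many of those are *active*, i.e. appear in the putative table
#' (`n_active`). The background fraction is the pooled
#' `total active / total predicted-in-universe` across all miRs; fold
#' enrichment is the per-miR observed fraction over that background, with a
#' one-sided hypergeometric tail probability `P(X >= n_active)` as a
#' significance companion (drawing `n_predicted_in_universe` pairs from the
#' pooled urn). miRs with no predicted pair in the universe are omitted.
#'
#' @param putative Putative-relationship table from [build_putative_list()].
#' @param predictions List of percentile-filtered prediction tables
#'   (`targetscan`, `diana`).
#' @param universe Mapped association table covering all retained pairs
#'   (from [map_identifiers()]).
#' @param idmap An [id_map()] (needed to fan family-level records out to
#'   mature miRs).
#' @return Data frame with one row per (source, miR): counts, fractions,
#'   `fold_enrichment` and `p_hypergeometric`.
#' @export
mir_active_enrichment <- function(putative, predictions, universe, idmap) {
  if (nrow(universe) == 0) stop("association universe is empty")
  uni_genes <- unique(universe$gene_symbol[!is.na(universe$gene_symbol)])
  uni_mirs <- unique(universe$mir_id)
  fam_members <- split(idmap$family_mir$mir_id, idmap$family_mir$family)

  # mature-miR-level predicted pairs for one source
  mature_pairs <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0)
      return(data.frame(mir_id = character(), gene_symbol = character()))
    mat <- fam_members[tab$mir_key]
    len <- lengths(mat)
    out <- data.frame(
      mir_id = c(unlist(mat, use.names = FALSE), tab$mir_key[len == 0]),
      gene_symbol = c(rep(tab$gene_symbol, len), tab$gene_symbol[len == 0]),
      stringsAsFactors = FALSE)
    out[!duplicated(paste(out$mir_id, out$gene_symbol)), , drop = FALSE]
  }

  act_keys <- if (nrow(putative) > 0)
    unique(paste(putative$mir_id, putative$gene_symbol)) else character(0)

  res <- lapply(names(predictions), function(src) {
    pp <- mature_pairs(predictions[[src]])
    pp <- pp[pp$mir_id %in% uni_mirs & pp$gene_symbol %in% uni_genes, ,
             drop = FALSE]
    if (nrow(pp) == 0) return(NULL)
    pp$active <- paste(pp$mir_id, pp$gene_symbol) %in% act_keys
    n_pred <- tapply(pp$active, pp$mir_id, length)
    n_act <- tapply(pp$active, pp$mir_id, sum)
    total_pred <- nrow(pp)
    total_act <- sum(pp$active)
    bg <- total_act / total_pred
    obs <- as.numeric(n_act) / as.numeric(n_pred)
    data.frame(
      source = src,
      mir_id = names(n_pred),
      n_predicted_in_universe = as.integer(n_pred),
      n_active = as.integer(n_act),
      observed_fraction = obs,
      background_fraction = bg,
      fold_enrichment = if (bg > 0) obs / bg else NA_real_,
      p_hypergeometric = hyper_tail_p(as.integer(n_act), total_act,
                                      total_pred, as.integer(n_pred)),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(source = character(), mir_id = character(),
                      n_predicted_in_universe = integer(),
                      n_active = integer(), observed_fraction = numeric(),
                      background_fraction = numeric(),
                      fold_enrichment = numeric(),
                      p_hypergeometric = numeric(),
                      stringsAsFactors = FALSE)
  out[order(out$source, -out$fold_enrichment, out$p_hypergeometric), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Select GO categories by name substring and size
#'
#' Keeps categories whose name contains at least one of the substrings
#' (case-insensitive, fixed matching) and whose member count lies within
#' `[min_size, max_size]`.
#'
#' @param go GO table (`term_id`, `name`, `members` list column).
#' @param substrings Character vector of name substrings; defaults to the
#'   epithelial-mesenchymal plasticity and pigmentation/melanogenesis set
#'   `c("epith", "mesench", "pigment", "melan")`.
#' @param min_size,max_size Inclusive member-count bounds (defaults 5 and
#'   500).
#' @return The selected subset of `go`.
#' @export
select_go_categories <- function(go,
                                 substrings = c("epith", "mesench",
                                                "pigment", "melan"),
                                 min_size = 5, max_size = 500) {
  nm <- tolower(go$name)
  hit <- Reduce(`|`, lapply(tolower(substrings),
                            function(s) grepl(s, nm, fixed = TRUE)))
  size <- lengths(go$members)
  out <- go[hit & size >= min_size & size <= max_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GO annotation enrichment of a target list
#'
#' Computes the fraction of target genes annotated to the union of the
#' selected categories' members, and the fold over the same fraction in the
#' background gene set.
#'
#' @param target_genes Character vector of gene symbols (must be a subset
#'   of `background_genes`; empty is an error).
#' @param categories Selected GO categories ([select_go_categories()]).
#' @param background_genes Character vector of background gene symbols.
#' @return List with `fraction_annotated` and `fold`.
#' @export
go_target_enrichment <- function(target_genes, categories,
                                 background_genes) {
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  if (length(target_genes) == 0)
    stop("empty target set: enrichment undefined")
  if (!all(target_genes %in% background_genes))
    stop("target_genes must be a subset of background_genes")
  members <- unique(unlist(categories$members, use.names = FALSE))
  frac <- mean(target_genes %in% members)
  bg_frac <- mean(background_genes %in% members)
  fold <- if (bg_frac > 0) frac / bg_frac else if (frac == 0) 0 else Inf
  list(fraction_annotated = frac, fold = fold)
}

#' Write/read the ragged GO annotation TSV
#'
#' Each line is `term_id <TAB> name <TAB> member1 <TAB> member2 ...`.
#'
#' @param go GO table with a `members` list column.
#' @param path File path.
#' @return `path` (write) or the GO table (read).
#' @export
write_go_table <- function(go, path) {
  lines <- vapply(seq_len(nrow(go)), function(i) {
    paste(c(go$term_id[i], go$name[i], go$members[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_go_table
#' @export
read_go_table <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    term_id = vapply(parts, `[`, "", 1),
    name = vapply(parts, `[`, "", 2),
    members = I(lapply(parts, function(p) p[-(1:2)])),
    stringsAsFactors = FALSE)
}
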