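#' Load a target-prediction table
#'
#' Reads a TSV with columns `mir_key`, `gene_symbol`, `score`. Score
#' semantics depend on the source: for `targetscan` (context+-style) more
#' negative is better; for `diana` (miTG-style) larger is better.
#' Duplicate (mir_key, gene_symbol) rows are aggregated to the best score
#' for the source.
#'
#' @param path TSV path.
#' @param source `"targetscan"` or `"diana"`.
#' @return Data frame of prediction records with a `source` attribute; an
#'   empty table (with a warning) for an empty file.
#' @export
load_predictions <- function(path, source = c("targetscan", "diana")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty prediction table: ", path)
    out <- data.frame(mir_key = character(), gene_symbol = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    attr(out, "source") <- source
    return(out)
  }
  need <- c("mir_key", "gene_symbol", "score")
  if (!all(need %in% names(df)))
    stop("prediction TSV needs columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$score)) {
    suppressWarnings(df$score <- as.numeric(df$score))
    if (anyNA(df$score)) stop("non-numeric score in ", path)
  }
  out <- aggregate_predictions(df[need], source)
  attr(out, "source") <- source
  out
}

# best score per pair: most negative (targetscan) or largest (diana)
aggregate_predictions <- function(df, source) {
  f <- if (source == "targetscan") min else max
  agg <- stats::aggregate(score ~ mir_key + gene_symbol, data = df, FUN = f)
  agg <- agg[order(agg$mir_key, agg$gene_symbol), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Percentile-filter prediction records
#'
#' Keeps the highest-confidence `percentile`% of records: the most negative
#' scores for `targetscan` (default 15), the largest for `diana` (default
#' 30). The cutoff is the linear-interpolated quantile of the score
#' distribution, applied with strict inequality on the favourable side;
#' the realised cutoff is attached as attribute `cutoff` and reported.
#'
#' @param records Prediction table from [load_predictions()] (single
#'   source).
#' @param source `"targetscan"` or `"diana"`; defaults to the table's
#'   `source` attribute.
#' @param percentile Percentage of records to keep (0 < percentile < 100);
#'   default 15 for targetscan, 30 for diana.
#' @return The filtered table with attributes `source` and `cutoff`.
#' @export
percentile_filter_predictions <- function(records, source = NULL,
                                          percentile = NULL) {
  if (is.null(source)) source <- attr(records, "source")
  if (is.null(source)) stop("source must be given or carried by the table")
  source <- match.arg(source, c("targetscan", "diana"))
  if (!is.null(attr(records, "source")) &&
      !identical(attr(records, "source"), source))
    stop("mixed sources: table is tagged ", attr(records, "source"))
  if (is.null(percentile))
    percentile <- if (source == "targetscan") 15 else 30
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  if (nrow(records) == 0) return(records)
  if (source == "targetscan") {
    cutoff <- stats::quantile(records$score, percentile / 100,
                              names = FALSE, type = 7)
    keep <- records$score < cutoff
  } else {
    cutoff <- stats::quantile(records$score, 1 - percentile / 100,
                              names = FALSE, type = 7)
    keep <- records$score > cutoff
  }
  message(sprintf("%s: realised score cutoff %s %.4g (kept %d/%d)",
                  source, if (source == "targetscan") "<" else ">",
                  cutoff, sum(keep), nrow(records)))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- source
  attr(out, "cutoff") <- cutoff
  out
}

#' Keep only strong-evidence validated interactions
#'
#' Retains records whose experimental method is one of *Luciferase reporter
#' assay*, *qRT-PCR* or *Western blot*, matched exactly after trimming and
#' case-folding. Idempotent.
#'
#' @param records Data frame with columns `mir_id`, `gene_symbol`,
#'   `method`.
#' @return The subset with strong-evidence methods.
#' @export
filter_validated_strong <- function(records) {
  strong <- c("luciferase reporter assay", "qrt-pcr", "western blot")
  meth <- tolower(trimws(records$method))
  out <- records[meth %in% strong, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read identifier maps
#'
#' @param probe_gene_path TSV with columns `probe_id`, `gene_symbol`.
#' @param family_mir_path TSV with columns `family`, `mir_id`.
#' @return List of class `id_map` with elements `probe_gene`, `family_mir`.
#' @export
read_id_map <- function(probe_gene_path, family_mir_path) {
  pg <- utils::read.delim(probe_gene_path, sep = "\t",
                          stringsAsFactors = FALSE)
  fm <- utils::read.delim(family_mir_path, sep = "\t",
                          stringsAsFactors = FALSE)
  id_map(pg, fm)
}

#' Construct an identifier map
#'
#' @param probe_gene Data frame `probe_id` -> `gene_symbol` (a probe may
#'   map to several genes).
#' @param family_mir Data frame `family` -> `mir_id` (a family maps to its
#'   mature miRs).
#' @return List of class `id_map`.
#' @export
id_map <- function(probe_gene, family_mir) {
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(probe_gene)),
            all(c("family", "mir_id") %in% names(family_mir)))
  structure(list(probe_gene = probe_gene, family_mir = family_mir),
            class = "id_map")
}

#' Annotate an association table with gene symbols and miR families
#'
#' Probes fan out to every mapped gene symbol (one annotated row per gene);
#' miRs gain their family key. Rows without any probe mapping are retained
#' with `gene_symbol = NA` and flagged `mapped = FALSE`; the number of
#' unmapped probes is reported.
#'
#' @param assoc Association table from [pairwise_associations()] (or any
#'   data frame with `mir_id` and `probe_id`).
#' @param idmap An [id_map()].
#' @return The annotated table with columns `gene_symbol`, `family`,
#'   `mapped` appended.
#' @export
map_identifiers <- function(assoc, idmap) {
  out <- merge(assoc, idmap$probe_gene, by = "probe_id", all.x = TRUE,
               sort = FALSE)
  fam <- idmap$family_mir[!duplicated(idmap$family_mir$mir_id), ]
  out <- merge(out, fam, by = "mir_id", all.x = TRUE, sort = FALSE)
  out$mapped <- !is.na(out$gene_symbol)
  n_un <- length(unique(out$probe_id[!out$mapped]))
  if (n_un > 0)
    message(n_un, " probe(s) without a gene mapping (rows flagged, kept)")
  out <- out[order(out$mir_id, out$probe_id,
                   out$gene_symbol, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
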