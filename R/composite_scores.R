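#' @title Composite immune scores
#' @name composite_scores
#' @description
#' Per-sample composite scores built on the expression and enrichment
#' matrices: cytolytic activity (CYT), T-cell infiltration score (TIS),
#' CD8/Treg ratio, pathway signatures (4-1BB, IFN-alpha, antigen
#' presentation machinery), and the mean infiltration across the immune
#' cell-type panel.
NULL

#' Cytolytic activity score (CYT)
#'
#' Geometric mean of perforin and granzyme A expression:
#' `sqrt((PRF1 + eps) * (GZMA + eps))`. Computed on the expression scale the
#' matrix carries (linear normalized values by default); the pseudocount
#' guards against zeros.
#'
#' @param expr `ExpressionMatrix`.
#' @param pseudocount eps >= 0, default 0.01.
#' @param genes the two cytolytic gene symbols, default `c("PRF1", "GZMA")`.
#' @return named numeric vector, one CYT value per sample.
#' @export
cyt_score <- function(expr, pseudocount = 0.01, genes = c("PRF1", "GZMA")) {
  stopifnot(length(genes) == 2L, pseudocount >= 0)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    stop("cytolytic gene(s) absent from the matrix: ", paste(missing, collapse = ", "))
  v <- unclass(expr)[genes, , drop = FALSE]
  sqrt((v[1L, ] + pseudocount) * (v[2L, ] + pseudocount))
}

#' Default T-cell subset rows for the infiltration score
#'
#' The nine T subsets averaged by the T-cell infiltration score. The panel's
#' generic "CD8 T" entry is represented by the activated CD8 subset.
#' @return character vector of 9 cell-type names.
#' @export
default_tis_sets <- function() {
  c("Activated CD8 T cell", "Central memory CD4 T cell",
    "Effector memory CD4 T cell", "Central memory CD8 T cell",
    "Effector memory CD8 T cell", "Type 1 T helper cell",
    "Type 2 T helper cell", "Type 17 T helper cell", "Regulatory T cell")
}

#' T-cell infiltration score (TIS)
#'
#' Each named enrichment row is z-scored across samples (sample sd, ddof 1;
#' a zero-variance row becomes all zeros with a warning), and TIS is the
#' per-sample mean of the standardized rows.
#'
#' @param enrich `EnrichmentMatrix`.
#' @param tis_set_names the rows to average, default [default_tis_sets()].
#' @return named numeric vector, one TIS value per sample.
#' @export
tis_score <- function(enrich, tis_set_names = default_tis_sets()) {
  missing <- setdiff(tis_set_names, rownames(enrich))
  if (length(missing) > 0L)
    stop("TIS rows absent from enrichment matrix: ", paste(missing, collapse = ", "))
  z <- t(apply(unclass(enrich)[tis_set_names, , drop = FALSE], 1L, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance row in TIS input; standardized to zeros")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }))
  stats::setNames(colMeans(z), colnames(enrich))
}

#' CD8/Treg digital ratio
#'
#' ssGSEA scores can be negative, so a raw ratio is ill-behaved. Each of the
#' two rows is min-max rescaled across samples to `[delta, 1]` and the ratio
#' of rescaled CD8 over rescaled Treg is returned (strictly positive,
#' bounded by `[delta, 1/delta]`).
#'
#' @param enrich `EnrichmentMatrix`.
#' @param cd8_name,treg_name row names of the two cell types.
#' @param delta lower bound of the rescale, default 0.01.
#' @return named numeric vector of per-sample ratios.
#' @export
cd8_treg_ratio <- function(enrich, cd8_name = "Activated CD8 T cell",
                           treg_name = "Regulatory T cell", delta = 0.01) {
  for (nm in c(cd8_name, treg_name)) {
    if (!nm %in% rownames(enrich))
      stop("row absent from enrichment matrix: ", nm)
  }
  rescale <- function(v, label) {
    rng <- range(v)
    if (diff(rng) == 0)
      stop("zero-variance row '", label, "': ratio undefined under min-max rescaling")
    delta + (1 - delta) * (v - rng[1L]) / diff(rng)
  }
  cd8 <- rescale(unclass(enrich)[cd8_name, ], cd8_name)
  treg <- rescale(unclass(enrich)[treg_name, ], treg_name)
  cd8 / treg
}

#' Pathway signature scores
#'
#' Delegates to the ssGSEA engine restricted to named sets (e.g. the 4-1BB
#' signaling pathway, interferon-alpha response, and antigen presentation
#' machinery signatures supplied via GMT).
#'
#' @param expr `ExpressionMatrix`.
#' @param sets `GeneSetCollection`.
#' @param names which sets to score.
#' @param cfg [ssgsea_config()].
#' @return `EnrichmentMatrix` restricted to `names`.
#' @export
pathway_scores <- function(expr, sets, names, cfg = ssgsea_config()) {
  missing <- setdiff(names, base::names(sets))
  if (length(missing) > 0L)
    stop("gene set(s) not in collection: ", paste(missing, collapse = ", "),
         "; available: ", paste(base::names(sets), collapse = ", "))
  score_matrix(expr, as_gene_sets(sets[names]), cfg)
}

#' Mean infiltration across the immune cell-type panel
#'
#' @param enrich `EnrichmentMatrix`.
#' @param cell_type_names the rows designated as cell types (default: all).
#' @return named numeric vector, per-sample arithmetic mean.
#' @export
overall_infiltration <- function(enrich, cell_type_names = rownames(enrich)) {
  missing <- setdiff(cell_type_names, rownames(enrich))
  if (length(missing) > 0L)
    stop("cell-type rows absent from enrichment matrix: ",
         paste(missing, collapse = ", "))
  colMeans(unclass(enrich)[cell_type_names, , drop = FALSE])
}

#' Default antigen presentation machinery (MHC-I) gene set
#'
#' A compact 8-gene MHC class I processing/presentation signature used when
#' the GMT input supplies none. Configuration, not ground truth: override by
#' shipping an `APM` set in the GMT.
#' @return character vector of gene symbols.
#' @export
default_apm_genes <- function() {
  c("HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2", "TAPBP", "PSMB9")
}

#' Assemble the composite score table
#'
#' One row per sample with CYT, TIS, CD8/Treg ratio, mean panel
#' infiltration, single-gene IFN-gamma expression (if `IFNG` is measured)
#' and any pathway rows found in `pathways`.
#'
#' @param expr `ExpressionMatrix`.
#' @param enrich cell-type `EnrichmentMatrix`.
#' @param pathways optional pathway `EnrichmentMatrix` ([pathway_scores()]).
#' @param cell_type_names rows of `enrich` forming the infiltration panel.
#' @param tis_set_names see [tis_score()].
#' @param cd8_name,treg_name see [cd8_treg_ratio()].
#' @param pseudocount see [cyt_score()].
#' @return data.frame, one row per sample.
#' @export
composite_score_table <- function(expr, enrich, pathways = NULL,
                                  cell_type_names = rownames(enrich),
                                  tis_set_names = default_tis_sets(),
                                  cd8_name = "Activated CD8 T cell",
                                  treg_name = "Regulatory T cell",
                                  pseudocount = 0.01) {
  samples <- colnames(enrich)
  out <- data.frame(sample_id = samples,
                    cyt = unname(cyt_score(expr, pseudocount)[samples]),
                    tis = unname(tis_score(enrich, tis_set_names)[samples]),
                    cd8_treg_ratio = unname(cd8_treg_ratio(enrich, cd8_name, treg_name)[samples]),
                    overall_infiltration = unname(overall_infiltration(enrich, cell_type_names)[samples]),
                    stringsAsFactors = FALSE)
  if ("IFNG" %in% rownames(expr))
    out$ifng <- unclass(expr)["IFNG", samples]
  if (!is.null(pathways)) {
    for (nm in rownames(pathways)) {
      col <- gsub("[^A-Za-z0-9]+", "_", tolower(nm))
      out[[col]] <- unclass(pathways)[nm, samples]
    }
  }
  out
}
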