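#' @title Single-sample gene set enrichment (ssGSEA) engine
#' @name ssgsea_engine
#' @description
#' From-scratch implementation of the per-sample rank-weighted running-sum
#' enrichment score. For a sample with N measured genes and a set of m member
#' genes, genes are ordered by decreasing within-sample rank and the score is
#' the sum over positions i = 1..N of P_in(i) - P_out(i), where
#' P_in(i) = sum of r_j^alpha over set members at positions <= i divided by
#' the same sum over all members, and P_out(i) is the fraction of the N - m
#' non-members already passed. Rank values (not raw expression) are used as
#' weights, so raw scores are invariant to any strictly increasing per-sample
#' transform of tie-free expression.
NULL

#' ssGSEA engine configuration
#'
#' @param alpha rank-weight exponent in `[0, 1]`; 0.25 is the published
#'   default of the method family.
#' @param normalize divide the full raw score matrix by its global
#'   (max - min)? Recorded in output metadata; note this couples samples.
#' @param tie_policy `"stable_ordinal"` (ties broken by lexicographic gene
#'   symbol; bit-reproducible) or `"average_rank"` (tied values share the
#'   mean rank; use for parity with reference implementations).
#' @param min_set_size sets with fewer measured members are skipped (row of
#'   `NA`) with a warning.
#' @return list of class `SsgseaConfig`.
#' @export
ssgsea_config <- function(alpha = 0.25, normalize = TRUE,
                          tie_policy = c("stable_ordinal", "average_rank"),
                          min_set_size = 2L) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            min_set_size >= 1L)
  structure(list(alpha = alpha, normalize = isTRUE(normalize),
                 tie_policy = tie_policy, min_set_size = as.integer(min_set_size)),
            class = "SsgseaConfig")
}

#' Within-sample rank transform
#'
#' Ranks each sample's expression values so the highest expression gets rank
#' N. Under `stable_ordinal` ties are broken by lexicographic gene symbol
#' (the lexicographically earlier symbol gets the lower rank); under
#' `average_rank` tied values share their mean rank.
#'
#' @param expr `ExpressionMatrix` (needs >= 2 genes).
#' @param tie_policy see [ssgsea_config()].
#' @return numeric matrix of ranks, same dimnames as `expr`.
#' @export
rank_transform <- function(expr, tie_policy = c("stable_ordinal", "average_rank")) {
  tie_policy <- match.arg(tie_policy)
  values <- unclass(expr)
  if (nrow(values) < 2L) stop("rank transform needs >= 2 genes")
  if (tie_policy == "average_rank") {
    ranks <- apply(values, 2L, rank, ties.method = "average")
  } else {
    # order() is stable; ordering by (value, symbol) makes the earlier symbol
    # hit the lower rank among ties
    sym <- rownames(values)
    ranks <- apply(values, 2L, function(v) {
      o <- order(v, sym, method = "radix")
      r <- integer(length(v))
      r[o] <- seq_along(v)
      as.numeric(r)
    })
  }
  dimnames(ranks) <- dimnames(values)
  ranks
}

#' Enrichment score for one gene set in one sample
#'
#' @param ranks named numeric vector of within-sample ranks (one sample).
#' @param gene_set character vector of member symbols; members absent from
#'   `ranks` are dropped with a warning.
#' @param alpha rank-weight exponent.
#' @param min_set_size minimum surviving member count.
#' @return the running-sum enrichment score (scalar), or `NA_real_` if the
#'   set shrinks below `min_set_size` after intersection.
#' @export
enrichment_score <- function(ranks, gene_set, alpha = 0.25, min_set_size = 2L) {
  if (is.null(names(ranks))) stop("ranks must be a named vector")
  present <- gene_set %in% names(ranks)
  if (!all(present)) {
    warning("dropping ", sum(!present), " set member(s) absent from the matrix: ",
            paste(utils::head(gene_set[!present], 5L), collapse = ", "))
    gene_set <- gene_set[present]
  }
  m <- length(gene_set)
  n <- length(ranks)
  if (m >= n) stop("gene set covers all measured genes; P_out denominator is zero")
  if (m < min_set_size) {
    warning("gene set has ", m, " measured member(s) (< min_set_size); skipping")
    return(NA_real_)
  }
  ord <- order(ranks, decreasing = TRUE)
  in_set <- names(ranks)[ord] %in% gene_set
  w <- ranks[ord]^alpha
  p_in <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
  p_out <- cumsum(!in_set) / (n - m)
  sum(p_in - p_out)
}

#' ssGSEA score matrix
#'
#' Scores every (set, sample) pair. If `cfg$normalize` is on and the raw
#' matrix has nonzero range, every entry is divided by the global
#' (max - min) of the raw matrix, so the output range is exactly 1.
#'
#' @param expr `ExpressionMatrix`.
#' @param sets `GeneSetCollection` (or named list of character vectors).
#' @param cfg [ssgsea_config()].
#' @return sets x samples numeric matrix, class `EnrichmentMatrix`, with
#'   attributes `alpha`, `normalized`, `tie_policy`.
#' @export
score_matrix <- function(expr, sets, cfg = ssgsea_config()) {
  values <- unclass(expr)
  ranks <- rank_transform(expr, cfg$tie_policy)
  n <- nrow(values)
  measured <- rownames(values)
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(values),
                   dimnames = list(names(sets), colnames(values)))
  w_all <- ranks^cfg$alpha
  for (si in seq_along(sets)) {
    gs <- sets[[si]]
    present <- gs %in% measured
    if (!all(present)) {
      warning("set '", names(sets)[si], "': dropping ", sum(!present),
              " member(s) absent from the matrix")
      gs <- gs[present]
    }
    m <- length(gs)
    if (m >= n)
      stop("set '", names(sets)[si], "' covers all measured genes; score undefined")
    if (m < cfg$min_set_size) {
      warning("set '", names(sets)[si], "' has ", m,
              " measured member(s) (< min_set_size); row set to NA")
      next
    }
    member <- measured %in% gs
    for (j in seq_len(ncol(values))) {
      ord <- order(ranks[, j], decreasing = TRUE)
      in_set <- member[ord]
      w <- w_all[ord, j]
      p_in <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
      p_out <- cumsum(!in_set) / (n - m)
      scores[si, j] <- sum(p_in - p_out)
    }
  }
  if (all(is.na(scores))) stop("all gene sets were skipped; no scores computed")
  normalized <- FALSE
  if (cfg$normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) {
      scores <- scores / diff(rng)
      normalized <- TRUE
    }
  }
  structure(scores, alpha = cfg$alpha, normalized = normalized,
            tie_policy = cfg$tie_policy,
            class = c("EnrichmentMatrix", class(scores)))
}

#' Write an enrichment matrix as TSV with metadata header
#'
#' Header lines `# alpha`, `# normalized`, `# tie_policy` precede a
#' sets x samples table.
#'
#' @param enrich `EnrichmentMatrix`.
#' @param path output path.
#' @export
write_enrichment <- function(enrich, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# alpha=", attr(enrich, "alpha")),
    paste0("# normalized=", tolower(as.character(isTRUE(attr(enrich, "normalized"))))),
    paste0("# tie_policy=", attr(enrich, "tie_policy"))
  ), con)
  df <- data.frame(set = rownames(enrich),
                   as.data.frame(unclass(enrich), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an enrichment matrix written by [write_enrichment()]
#' @param path TSV path with `#` metadata header lines.
#' @return `EnrichmentMatrix`.
#' @export
read_enrichment <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1L]]
    meta[[kv[[1L]]]] <- kv[[2L]]
  }
  df <- utils::read.delim(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  structure(m, alpha = as.numeric(meta$alpha),
            normalized = identical(meta$normalized, "true"),
            tie_policy = meta$tie_policy,
            class = c("EnrichmentMatrix", class(m)))
}
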