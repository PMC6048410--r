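#' @title Immunophenotype classification
#' @name immunophenotype
#' @description
#' Hierarchical clustering of samples into high/median/low (H/M/L)
#' infiltration tiers, median-split dichotomization of per-sample scores,
#' and crossed 4-level survival classes.
NULL

#' Cluster samples into H/M/L infiltration tiers
#'
#' Cell-type rows are z-scored (so no cell type dominates by scale), samples
#' are clustered hierarchically and the tree is cut at `k = 3`. Clusters are
#' relabeled H/M/L by descending mean overall infiltration, so H always has
#' the largest panel mean and L the smallest. Two distance modes are
#' provided: Euclidean with Ward linkage (`ward.D2` on z-scored rows) and
#' Pearson dissimilarity `1 - r` with Ward linkage.
#'
#' @param enrich cell-type `EnrichmentMatrix` (>= 3 samples).
#' @param distance `"euclidean"` or `"pearson"`.
#' @param linkage only `"ward"` is supported.
#' @param k number of tiers, fixed design default 3.
#' @return factor of labels `H`/`M`/`L` named by sample, with attributes
#'   `distance`, `linkage`, `tier_means`.
#' @export
cluster_infiltration <- function(enrich, distance = c("euclidean", "pearson"),
                                 linkage = "ward", k = 3L) {
  distance <- match.arg(distance)
  if (!identical(linkage, "ward")) stop("only Ward linkage is supported")
  m <- unclass(enrich)
  if (ncol(m) < k) stop("k = ", k, " exceeds sample count ", ncol(m))
  row_sd <- apply(m, 1L, stats::sd)
  if (any(row_sd == 0)) {
    warning("dropping ", sum(row_sd == 0), " zero-variance row(s) before clustering")
    m <- m[row_sd > 0, , drop = FALSE]
    if (nrow(m) == 0L) stop("all rows have zero variance; clustering degenerate")
  }
  z <- t(scale(t(m)))
  d <- if (distance == "euclidean") stats::dist(t(z)) else stats::as.dist(1 - stats::cor(z))
  hc <- stats::hclust(d, method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  infil <- overall_infiltration(enrich)
  tier_means <- vapply(seq_len(k), function(g) mean(infil[raw == g]), numeric(1L))
  lab_levels <- if (k == 3L) c("H", "M", "L") else paste0("T", seq_len(k))
  relabel <- lab_levels[rank(-tier_means, ties.method = "first")]
  labels <- factor(relabel[raw], levels = lab_levels)
  names(labels) <- colnames(enrich)
  attr(labels, "distance") <- distance
  attr(labels, "linkage") <- "ward"
  attr(labels, "tier_means") <- stats::setNames(sort(tier_means, decreasing = TRUE), lab_levels)
  labels
}

#' Median split into Hi/Lo strata
#'
#' Hi receives values strictly greater than the median; Lo receives the rest
#' (the median itself falls in Lo). For n distinct values this yields
#' |Hi| = floor(n / 2) when n is odd and splits evenly (Hi gets the smaller
#' half at ties) when values repeat at the median.
#'
#' @param values named numeric vector of per-sample scores (>= 2 samples).
#' @return factor with levels `Lo`, `Hi`, named like `values`.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("median split needs >= 2 samples")
  if (length(unique(values)) == 1L) stop("all values identical; median split undefined")
  med <- stats::median(values)
  f <- factor(ifelse(values > med, "Hi", "Lo"), levels = c("Lo", "Hi"))
  names(f) <- names(values)
  f
}

#' Cross two Hi/Lo splits into 4-level classes
#'
#' @param split_a,split_b factors from [median_split()] over the same sample
#'   universe (names must match as sets).
#' @param name_a,name_b optional score names used in the labels.
#' @return factor with levels like `NK_Hi.41BB_Hi` (a x b Cartesian product),
#'   named by sample.
#' @export
cross_classes <- function(split_a, split_b, name_a = "A", name_b = "B") {
  na <- names(split_a); nb <- names(split_b)
  if (is.null(na) || is.null(nb)) stop("splits must be named by sample")
  sym_diff <- union(setdiff(na, nb), setdiff(nb, na))
  if (length(sym_diff) > 0L)
    stop("sample universes differ; symmetric difference: ",
         paste(utils::head(sym_diff, 10L), collapse = ", "))
  b <- split_b[na]
  lev <- as.vector(outer(c("Hi", "Lo"), c("Hi", "Lo"),
                         function(x, y) paste0(name_a, "_", x, ".", name_b, "_", y)))
  lab <- paste0(name_a, "_", as.character(split_a), ".", name_b, "_", as.character(b))
  # all 4 levels kept even when unoccupied: the partition structure matters
  f <- factor(lab, levels = lev)
  names(f) <- na
  f
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement used to benchmark cluster recovery against a
#' generator's planted tiers. 1 means identical partitions, 0 is the
#' expectation under random labeling.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
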