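# Independent oracles, deliberately coded without reusing any engine code:
# plain loops and enumeration only. They define expected values; the package
# is checked against them, never the other way around.

# Brute-force ssGSEA running sum: explicit per-position loop.
oracle_ssgsea_one <- function(values_one_sample, gene_set, alpha,
                              tie_policy = "stable_ordinal") {
  genes <- names(values_one_sample)
  if (tie_policy == "average_rank") {
    r <- rank(values_one_sample, ties.method = "average")
  } else {
    ord_asc <- order(values_one_sample, genes, method = "radix")
    r <- numeric(length(genes))
    r[ord_asc] <- seq_along(genes)
  }
  names(r) <- genes
  gene_set <- intersect(gene_set, genes)
  n <- length(genes)
  m <- length(gene_set)
  walk <- genes[order(r, decreasing = TRUE)]
  denom_in <- 0
  for (g in gene_set) denom_in <- denom_in + r[[g]]^alpha
  es <- 0
  hit <- 0
  miss <- 0
  for (i in seq_len(n)) {
    g <- walk[[i]]
    if (g %in% gene_set) hit <- hit + r[[g]]^alpha else miss <- miss + 1
    es <- es + hit / denom_in - miss / (n - m)
  }
  es
}

oracle_ssgsea_matrix <- function(values, sets, alpha, normalize = FALSE,
                                 tie_policy = "stable_ordinal") {
  out <- matrix(NA_real_, length(sets), ncol(values),
                dimnames = list(names(sets), colnames(values)))
  for (si in seq_along(sets)) {
    for (j in seq_len(ncol(values))) {
      v <- values[, j]
      names(v) <- rownames(values)
      out[si, j] <- oracle_ssgsea_one(v, sets[[si]], alpha, tie_policy)
    }
  }
  if (normalize) out <- out / (max(out) - min(out))
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(g1, g2)
  us <- apply(idx, 2L, function(ix) u_of(pooled[ix], pooled[-ix]))
  p <- 2 * min(mean(us <= u_obs + 1e-12), mean(us >= u_obs - 1e-12))
  min(p, 1)
}

# Fisher exact p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    stats::dhyper(a, c1, n - c1, r1), numeric(1L))
  p_obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand one-way ANOVA from the sum-of-squares table.
oracle_anova_f <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1L)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Product-limit estimator, longhand.
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = et, surv = NA_real_)
  for (i in seq_along(et)) {
    n_i <- sum(time >= et[i])
    d_i <- sum(time == et[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    out$surv[i] <- s
  }
  out
}
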