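# Three tiers with random per-row centroids: separable both by distance in
# z-space (euclidean) and by profile shape (pearson).
planted_enrichment <- function(n_per_tier = 20L, n_types = 8L, seed = 1L,
                               spread = 3) {
  set.seed(seed)
  n <- n_per_tier * 3L
  tier <- rep(1:3, each = n_per_tier)
  centroids <- matrix(rnorm(n_types * 3, sd = spread), n_types, 3)
  m <- centroids[, tier] + matrix(rnorm(n_types * n, sd = 0.5), n_types, n)
  dimnames(m) <- list(sprintf("CT%02d", seq_len(n_types)),
                      sprintf("S%03d", seq_len(n)))
  list(enrich = fake_enrichment(m), tier = tier)
}

test_that("well-separated planted tiers are recovered exactly (both metrics)", {
  pl <- planted_enrichment(seed = 4)
  for (dist in c("euclidean", "pearson")) {
    labels <- cluster_infiltration(pl$enrich, distance = dist)
    expect_equal(adjusted_rand_index(labels, pl$tier), 1.0)
  }
})

test_that("H/M/L relabeling orders tiers by mean infiltration", {
  pl <- planted_enrichment(seed = 9)
  labels <- cluster_infiltration(pl$enrich)
  infil <- overall_infiltration(pl$enrich)
  means <- tapply(infil, labels, mean)
  expect_true(means[["H"]] > means[["M"]])
  expect_true(means[["M"]] > means[["L"]])
})

test_that("clustering is deterministic and duplicate samples co-cluster", {
  pl <- planted_enrichment(n_per_tier = 5L, seed = 2)
  m <- unclass(pl$enrich)
  dup <- cbind(m, m)
  colnames(dup) <- c(colnames(m), paste0(colnames(m), "_dup"))
  labels <- cluster_infiltration(fake_enrichment(dup))
  orig <- labels[colnames(m)]
  copies <- labels[paste0(colnames(m), "_dup")]
  expect_identical(as.character(orig), as.character(copies))
  # permutation invariance of the sample order
  perm <- sample(ncol(m))
  lp <- cluster_infiltration(fake_enrichment(m[, perm]))
  expect_identical(as.character(lp[colnames(m)]),
                   as.character(cluster_infiltration(pl$enrich)[colnames(m)]))
})

test_that("degenerate clustering input errors", {
  const <- fake_enrichment(matrix(1, 4, 5,
    dimnames = list(paste0("t", 1:4), paste0("s", 1:5))))
  expect_error(suppressWarnings(cluster_infiltration(const)), "zero variance")
  small <- fake_enrichment(matrix(rnorm(4), 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(cluster_infiltration(small), "exceeds sample count")
})

test_that("median split follows the Hi-strictly-greater convention", {
  expect_error(median_split(c(a = 1)), ">= 2")
  expect_error(median_split(c(a = 2, b = 2)), "identical")

  s199 <- median_split(stats::setNames(seq_len(199), paste0("s", 1:199)))
  expect_equal(sum(s199 == "Hi"), 99L)
  expect_equal(sum(s199 == "Lo"), 100L)
  s359 <- median_split(stats::setNames(seq_len(359), paste0("s", 1:359)))
  expect_equal(sum(s359 == "Hi"), 179L)
  expect_equal(sum(s359 == "Lo"), 180L)

  tie <- median_split(c(a = 1, b = 2, c = 2, d = 3))  # median 2 goes Lo
  expect_identical(names(tie)[tie == "Hi"], "d")

  # invariance under strictly increasing transforms
  set.seed(6)
  v <- stats::setNames(rnorm(101), paste0("s", 1:101))
  expect_identical(median_split(v), median_split(exp(v)))
  expect_identical(median_split(v), median_split(rank(v)))
})

test_that("crossed classes partition the cohort", {
  set.seed(8)
  v1 <- stats::setNames(rnorm(359), paste0("s", 1:359))
  v2 <- stats::setNames(rnorm(359), paste0("s", 1:359))
  a <- median_split(v1); b <- median_split(v2)
  cc <- cross_classes(a, b, "NK", "P41BB")
  expect_equal(sum(table(cc)), 359L)
  expect_equal(nlevels(cc), 4L)

  same <- cross_classes(a, a, "A", "B")
  expect_equal(as.integer(table(same)[c("A_Hi.B_Lo", "A_Lo.B_Hi")]), c(0L, 0L))
  compl <- a
  levels(compl) <- rev(levels(compl))
  opp <- cross_classes(a, compl, "A", "B")
  expect_equal(as.integer(table(opp)[c("A_Hi.B_Hi", "A_Lo.B_Lo")]), c(0L, 0L))

  expect_error(cross_classes(a, b[-1]), "symmetric difference")
})

test_that("adjusted Rand index behaves as a recovery benchmark", {
  x <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(x, x), 1)
  relab <- c("c", "a", "b")[x]
  expect_equal(adjusted_rand_index(x, relab), 1)
  set.seed(10)
  y <- sample(1:3, 30, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(x, y)), 0.35)
})
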