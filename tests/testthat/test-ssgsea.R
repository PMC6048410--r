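test_that("rank transform obeys the stated ordering and tie conventions", {
  expr <- toy_expr()  # g1 > g2 > g3 in both samples
  r <- rank_transform(expr)
  expect_equal(unname(r[, "sampA"]), c(3, 2, 1))

  tied <- as_expression_matrix(matrix(c(5, 5, 1, 2), 2, 2,
    dimnames = list(c("gB", "gA"), c("s1", "s2"))))
  r_ord <- rank_transform(tied, "stable_ordinal")
  # lexicographic tie-break: gA gets the lower rank
  expect_equal(r_ord["gA", "s1"], 1)
  expect_equal(r_ord["gB", "s1"], 2)
  r_avg <- rank_transform(tied, "average_rank")
  expect_equal(unname(r_avg[, "s1"]), c(1.5, 1.5))

  # rank invariance under strictly increasing transform (tie-free)
  expr2 <- random_expr(20, 3, seed = 5)
  expect_equal(rank_transform(expr2),
               rank_transform(as_expression_matrix(exp(unclass(expr2)))))
})

test_that("enrichment score matches hand-evaluated running sums", {
  ranks <- c(g1 = 3, g2 = 2, g3 = 1)
  expect_equal(enrichment_score(ranks, "g1", alpha = 0.25, min_set_size = 1L), 1.5)
  expect_equal(enrichment_score(ranks, "g3", alpha = 0.25, min_set_size = 1L), -1.5)
  expect_error(enrichment_score(ranks, c("g1", "g2", "g3"), 0.25), "covers all")
  expect_warning(es <- enrichment_score(ranks, "g1", 0.25, min_set_size = 2L),
                 "min_set_size")
  expect_true(is.na(es))
  expect_warning(enrichment_score(ranks, c("g1", "g2", "nope"), 0.25), "absent")
})

test_that("score_matrix reproduces the singleton toy and normalization identity", {
  expr <- toy_expr()
  cfg <- ssgsea_config(normalize = FALSE, min_set_size = 1L)
  em <- score_matrix(expr, as_gene_sets(list(TOP = "g1")), cfg)
  expect_equal(unname(unclass(em)[1L, ]), c(1.5, 1.5))

  expr2 <- random_expr(30, 4, seed = 7)
  sets <- random_sets(rownames(expr2), 5, seed = 8)
  em_n <- score_matrix(expr2, sets, ssgsea_config(normalize = TRUE))
  expect_equal(max(em_n) - min(em_n), 1)
  expect_true(isTRUE(attr(em_n, "normalized")))
})

test_that("engine equals the brute-force oracle on random instances", {
  for (seed in 1:5) {
    expr <- random_expr(50, 5, seed = 100 + seed)
    sets <- random_sets(rownames(expr), 4, seed = 200 + seed)
    got <- score_matrix(expr, sets, ssgsea_config(normalize = FALSE))
    want <- oracle_ssgsea_matrix(unclass(expr), sets, alpha = 0.25)
    expect_lt(max(abs(got - want)), 1e-10)
  }
  # average-rank tie policy with planted ties
  set.seed(42)
  m <- matrix(sample(1:5, 40, replace = TRUE), 20, 2,
              dimnames = list(sprintf("G%02d", 1:20), c("s1", "s2")))
  expr <- as_expression_matrix(m * 1.0)
  sets <- random_sets(rownames(expr), 3, seed = 43)
  got <- score_matrix(expr, sets, ssgsea_config(normalize = FALSE,
                                                tie_policy = "average_rank"))
  want <- oracle_ssgsea_matrix(unclass(expr), sets, 0.25,
                               tie_policy = "average_rank")
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("raw scores are sample-independent and antisymmetric on reversal", {
  expr <- random_expr(25, 6, seed = 31)
  sets <- random_sets(rownames(expr), 3, seed = 32)
  cfg <- ssgsea_config(normalize = FALSE)
  full <- score_matrix(expr, sets, cfg)
  sub <- score_matrix(as_expression_matrix(unclass(expr)[, 1:3]), sets, cfg)
  expect_equal(unclass(full)[, 1:3], unclass(sub), tolerance = 1e-12,
               ignore_attr = TRUE)

  # reversing the ranking swaps top/bottom singleton scores with sign flip
  expr3 <- toy_expr()
  rev3 <- as_expression_matrix(unclass(expr3)[, , drop = FALSE] * 0 +
                                 max(unclass(expr3)) - unclass(expr3) + 1)
  cfg1 <- ssgsea_config(normalize = FALSE, min_set_size = 1L)
  top_fwd <- score_matrix(expr3, as_gene_sets(list(S = "g1")), cfg1)
  bot_rev <- score_matrix(rev3, as_gene_sets(list(S = "g3")), cfg1)
  expect_equal(unclass(top_fwd)[1, ], unclass(bot_rev)[1, ], tolerance = 1e-12)
})

test_that("degenerate set handling follows the contract", {
  expr <- random_expr(10, 2, seed = 77)
  sets <- as_gene_sets(list(tiny = rownames(expr)[1L],
                            ok = rownames(expr)[2:5]))
  expect_warning(em <- score_matrix(expr, sets, ssgsea_config(normalize = FALSE)),
                 "min_set_size")
  expect_true(all(is.na(unclass(em)["tiny", ])))
  expect_false(anyNA(unclass(em)["ok", ]))
  all_genes <- as_gene_sets(list(all = rownames(expr)))
  expect_error(score_matrix(expr, all_genes, ssgsea_config()), "covers all")
})

test_that("enrichment TSV round trip preserves scores and metadata", {
  expr <- random_expr(15, 3, seed = 9)
  em <- score_matrix(expr, random_sets(rownames(expr), 3, seed = 10),
                     ssgsea_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(em, path)
  back <- read_enrichment(path)
  expect_equal(unclass(back), unclass(em), tolerance = 1e-10)
  expect_equal(attr(back, "alpha"), 0.25)
  expect_identical(attr(back, "tie_policy"), "stable_ordinal")
})
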