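test_that("expression TSV round trip preserves values exactly", {
  path <- write_tsv_fixture(c("gene\tsampA\tsampB",
                              "g1\t3\t30", "g2\t2\t20", "g3\t1\t10"))
  expr <- read_expression(path)
  expect_equal(dim(expr), c(3L, 2L))
  expect_identical(unclass(expr), unclass(toy_expr()))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, out)
  expect_identical(unclass(read_expression(out)), unclass(expr))
})

test_that("duplicated gene rows collapse by per-sample maximum with a warning", {
  path <- write_tsv_fixture(c("gene\ts1", "gA\t1", "gB\t7", "gA\t5"))
  expect_warning(expr <- read_expression(path), "duplicated gene")
  expect_equal(unname(unclass(expr)["gA", "s1"]), 5)
  expect_equal(nrow(expr), 2L)
})

test_that("expression validation rejects bad input", {
  neg <- write_tsv_fixture(c("gene\ts1\ts2", "g1\t1\t2", "g2\t-3\t4"))
  expect_error(read_expression(neg), "g2")
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(as_expression_matrix(m), "duplicate gene")
  expect_error(as_expression_matrix(matrix(1:2, 1, 2,
    dimnames = list("g", c("s1", "s2")))), "2 genes")
})

test_that("MTX triplet input matches the equivalent TSV", {
  expr <- random_expr(6, 3, seed = 11)
  mtx <- withr::local_tempfile(fileext = ".mtx")
  gpath <- withr::local_tempfile(); spath <- withr::local_tempfile()
  Matrix::writeMM(Matrix::Matrix(unclass(expr), sparse = TRUE), mtx)
  writeLines(rownames(expr), gpath)
  writeLines(colnames(expr), spath)
  got <- read_expression(mtx, format = "mtx", genes_path = gpath, samples_path = spath)
  expect_equal(unclass(got), unclass(expr), tolerance = 1e-12)
})

test_that("GMT parsing follows the format contract", {
  path <- write_tsv_fixture(c("CD8_T\tdesc\tCD8A\tGZMB",
                              "SET2\tna\tX\tY\tZ"))
  sets <- read_gmt(path)
  expect_named(sets, c("CD8_T", "SET2"))
  expect_identical(sets$CD8_T, c("CD8A", "GZMB"))
  expect_identical(attr(sets, "descriptions")[["CD8_T"]], "desc")

  dup <- write_tsv_fixture("S\tna\tA\tA")
  expect_warning(sets2 <- read_gmt(dup), "duplicated")
  expect_length(sets2$S, 1L)

  expect_error(read_gmt(write_tsv_fixture("ONLYNAME\tdesc")), "line 1")
  expect_error(read_gmt(write_tsv_fixture("S\tdesc\t")), "empty member")
})

test_that("GMT round trip preserves sets and member order", {
  sets <- as_gene_sets(list(A = c("z", "a", "m"), B = c("q", "b")),
                       descriptions = c(A = "first", B = "second"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back$A, c("z", "a", "m"))
  expect_identical(back$B, c("q", "b"))
})

test_that("clinical table validates and maps sidedness", {
  path <- write_tsv_fixture(c("sample_id\tos_days\tevent\tside",
                              "s1\t100\t1\tcecum",
                              "s2\t250\t0\trectum",
                              "s3\t7\t1\tsigmoid"))
  clin <- read_clinical(path)
  expect_equal(nrow(clin), 3L)
  expect_identical(clin$side, c("right", "left", "left"))

  bad_event <- write_tsv_fixture(c("sample_id\tos_days\tevent\tside",
                                   "s1\t10\t2\tcecum"))
  expect_error(read_clinical(bad_event), "event")
  missing_col <- write_tsv_fixture(c("sample_id\tos_days\tevent", "s1\t10\t1"))
  expect_error(read_clinical(missing_col), "side")
  frac_days <- write_tsv_fixture(c("sample_id\tos_days\tevent\tside",
                                   "s1\t10.5\t1\tcecum"))
  expect_error(read_clinical(frac_days), "os_days")
  odd_side <- write_tsv_fixture(c("sample_id\tos_days\tevent\tside",
                                  "s1\t10\t1\tappendix"))
  expect_warning(clin2 <- read_clinical(odd_side), "unrecognized")
  expect_identical(clin2$side, "unknown")
})

test_that("cohort join keeps exactly the shared samples, order-independent", {
  expr <- random_expr(5, 4, seed = 3)
  clin <- as_clinical_table(data.frame(
    sample_id = c("S03", "S01", "ZZZ"), os_days = c(10L, 20L, 30L),
    event = c(1L, 0L, 1L), side = c("left", "right", "left")))
  al <- align_cohort(expr, clin)
  expect_setequal(colnames(al$expr), c("S01", "S03"))
  expect_identical(colnames(al$expr), al$clinical$sample_id)
  al2 <- align_cohort(expr, clin[c(3, 2, 1), ])
  expect_identical(unclass(al$expr), unclass(al2$expr))
  expect_error(align_cohort(expr, clin[3, ]), "no samples shared")
})
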