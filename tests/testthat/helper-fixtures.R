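# Small in-code fixtures shared across test files.

toy_expr <- function() {
  m <- matrix(c(3, 30, 2, 20, 1, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("sampA", "sampB")))
  as_expression_matrix(m)
}

# deterministic random expression matrix with unique values (tie-free)
random_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(exp(stats::rnorm(n_genes * n_samples)), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  as_expression_matrix(m)
}

random_sets <- function(genes, n_sets, min_size = 3L, max_size = 10L, seed) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes, sample(min_size:max_size, 1L)))
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  as_gene_sets(sets)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# enrichment-like matrix with chosen values and class attributes
fake_enrichment <- function(m) {
  structure(m, alpha = 0.25, normalized = FALSE, tie_policy = "stable_ordinal",
            class = c("EnrichmentMatrix", class(m)))
}
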