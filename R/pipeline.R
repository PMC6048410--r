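#' @title End-to-end pipeline
#' @name pipeline_cli
#' @description
#' Orchestrates data IO -> ssGSEA -> composite scores -> immunophenotype ->
#' cohort statistics -> survival from one configuration, writing per-stage
#' TSV artifacts, Kaplan-Meier plots and a machine-readable JSON summary.
#' Deterministic for a fixed seed: identical config + seed reproduce the
#' summary byte for byte.
NULL

coerce_config_value <- function(v) {
  v <- trimws(v)
  if (v %in% c("true", "TRUE")) return(TRUE)
  if (v %in% c("false", "FALSE")) return(FALSE)
  if (grepl(",", v, fixed = TRUE)) return(trimws(strsplit(v, ",", fixed = TRUE)[[1L]]))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' Read a flat key-value run configuration
#'
#' One `key: value` pair per line; `#` starts a comment; comma-separated
#' values become character vectors; `true`/`false` and numbers are coerced.
#' This deliberately supports only the flat subset of YAML the pipeline
#' needs, so no YAML dependency is required.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    cfg[[trimws(m[[2L]])]] <- coerce_config_value(m[[3L]])
  }
  cfg
}

result_row <- function(score, grouping, res) {
  data.frame(score = score, grouping = grouping, test = res$test_name,
             n = paste(res$group_sizes, collapse = "/"),
             statistic = if (is.na(res$statistic)) NA_real_ else res$statistic,
             p_value = res$p_value,
             direction = if (is.na(res$direction)) NA_real_ else res$direction,
             stringsAsFactors = FALSE)
}

#' Run the full immune-landscape pipeline
#'
#' Either `expression`/`gmt`/`clinical` paths or `simulate: true` must be
#' configured (exactly one of the two modes). Stages: read/simulate ->
#' ssGSEA over the cell-type panel -> composite scores -> H/M/L clustering
#' -> sidedness and cluster contrasts, VEGFA couplings, mutation x cluster
#' tables -> median-split survival analyses. Artifacts written under
#' `out_dir`: `enrichment.tsv`, `scores.tsv`, `classes.tsv`, `stats.tsv`,
#' `km_curves.pdf`, `summary.json` (and, in simulate mode, the generated
#' inputs plus `truth.tsv`).
#'
#' @param config named list (see [read_run_config()]) or path to a config
#'   file. Recognized keys: `expression`, `gmt`, `clinical`, `simulate`,
#'   `n_samples`, `seed`, `alpha`, `normalize`, `tie_policy`, `distance`,
#'   `pathway_sets`, `out_dir`.
#' @return the summary list, invisibly written as JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_run_config(config)
  out_dir <- config$out_dir %||% stop("config must name out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  simulate <- isTRUE(config$simulate)
  has_paths <- !is.null(config$expression)
  if (simulate == has_paths)
    stop("configure exactly one of: simulate mode, or expression/gmt/clinical paths")

  log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

  if (simulate) {
    gcfg <- generator_config(n_samples = as.integer(config$n_samples %||% 200L),
                             seed = seed)
    sim <- generate_cohort(gcfg)
    expr <- sim$expr; clinical <- sim$clinical; sets <- sim$sets
    cell_type_names <- sim$cell_type_names
    pathway_names <- sim$pathway_names
    write_expression(expr, file.path(out_dir, "expression.tsv"))
    write_gmt(sets, file.path(out_dir, "sets.gmt"))
    write_clinical(clinical, file.path(out_dir, "clinical.tsv"))
    write_truth(sim$truth, file.path(out_dir, "truth.tsv"))
  } else {
    expr <- read_expression(config$expression)
    sets <- read_gmt(config$gmt)
    clinical <- read_clinical(config$clinical)
    # explicit pathway_sets are taken at face value so a typo fails loudly in
    # pathway_scores; the defaults are filtered to what the GMT provides
    pathway_names <- config$pathway_sets %||%
      intersect(c("41BB signaling pathway", "Interferon-a response", "APM"),
                names(sets))
    cell_type_names <- setdiff(names(sets), pathway_names)
  }
  log_stage("data_io", "expression %d genes x %d samples; %d gene sets; %d clinical rows",
            nrow(expr), ncol(expr), length(sets), nrow(clinical))

  aligned <- align_cohort(expr, clinical)
  expr <- aligned$expr; clinical <- aligned$clinical

  scfg <- ssgsea_config(alpha = config$alpha %||% 0.25,
                        normalize = config$normalize %||% TRUE,
                        tie_policy = config$tie_policy %||% "stable_ordinal")
  enrich <- score_matrix(expr, as_gene_sets(sets[cell_type_names]), scfg)
  write_enrichment(enrich, file.path(out_dir, "enrichment.tsv"))
  log_stage("ssgsea", "%d cell-type sets scored (alpha=%.2f)", nrow(enrich), scfg$alpha)

  pathways <- NULL
  if (length(pathway_names) > 0L)
    pathways <- pathway_scores(expr, sets, pathway_names, scfg)

  scores <- composite_score_table(expr, enrich, pathways,
                                  cell_type_names = cell_type_names)
  utils::write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("composite_scores", "%d score columns for %d samples",
            ncol(scores) - 1L, nrow(scores))

  clusters <- cluster_infiltration(enrich, distance = config$distance %||% "euclidean")
  classes <- data.frame(sample_id = names(clusters), cluster = as.character(clusters),
                        stringsAsFactors = FALSE)
  log_stage("immunophenotype", "tiers H/M/L = %s",
            paste(table(clusters)[c("H", "M", "L")], collapse = "/"))

  ## contrasts
  side_known <- clinical$side %in% c("left", "right")
  side <- factor(clinical$side[side_known], levels = c("left", "right"))
  stats_rows <- list()
  score_cols <- setdiff(names(scores), "sample_id")
  for (sc in score_cols) {
    v <- scores[[sc]][side_known]
    stats_rows[[length(stats_rows) + 1L]] <-
      result_row(sc, "side", compare_groups(v, side, "mann_whitney"))
  }
  for (sc in c("cyt", if ("ifng" %in% score_cols) "ifng")) {
    stats_rows[[length(stats_rows) + 1L]] <-
      result_row(sc, "cluster_HML", anova_oneway(scores[[sc]], clusters[scores$sample_id]))
  }
  stats_tab <- do.call(rbind, stats_rows)

  ## VEGFA coupling by side
  correlations <- list()
  if ("VEGFA" %in% rownames(expr) && "Activated CD8 T cell" %in% rownames(enrich)) {
    vegfa <- unclass(expr)["VEGFA", clinical$sample_id]
    cd8 <- unclass(enrich)["Activated CD8 T cell", clinical$sample_id]
    for (sd_ in c("right", "left")) {
      ix <- clinical$side == sd_
      if (sum(ix) >= 3L) {
        cr <- correlate(vegfa[ix], cd8[ix], "pearson")
        correlations[[paste0("vegfa_cd8_", sd_)]] <-
          list(r = cr$r, p_value = cr$p_value, n = cr$n)
      }
    }
  }

  ## mutation x cluster contingency
  mutation_tests <- list()
  for (mut in intersect(c("EGFR", "BRAF", "KRAS", "TP53"), names(clinical))) {
    tab <- table(clusters[clinical$sample_id], clinical[[mut]])
    if (all(dim(tab) >= 2L)) {
      ct <- contingency_test(tab)
      mutation_tests[[mut]] <- list(test = ct$test_name, statistic = ct$statistic,
                                    p_value = ct$p_value)
    }
  }

  ## survival: H/M/L log-rank plus median splits of configured scores
  surv_results <- list()
  km_curves <- list()
  lr <- logrank_test(clinical$os_days, clinical$event, clusters[clinical$sample_id])
  surv_results[["cluster_HML"]] <- list(logrank_chisq = lr$statistic, df = lr$df,
                                        logrank_p = lr$p_value)
  for (lab in levels(clusters))
    km_curves[[paste0("cluster_", lab)]] <-
      km_estimate(clinical$os_days[clusters[clinical$sample_id] == lab],
                  clinical$event[clusters[clinical$sample_id] == lab])
  surv_scores <- intersect(config$survival_scores %||%
                             c("overall_infiltration", "p41bb" , "41bb_signaling_pathway",
                               "interferon_a_response"),
                           score_cols)
  for (sc in surv_scores) {
    split <- median_split(stats::setNames(scores[[sc]], scores$sample_id))
    labels <- split[clinical$sample_id]
    lr <- logrank_test(clinical$os_days, clinical$event, labels)
    cx <- cox_univariate(clinical$os_days, clinical$event,
                         as.integer(labels == "Hi"))
    surv_results[[sc]] <- list(n_hi = sum(labels == "Hi"), n_lo = sum(labels == "Lo"),
                               logrank_chisq = lr$statistic, logrank_p = lr$p_value,
                               cox_log_hr = cx$coef, cox_hr = cx$hr, cox_se = cx$se,
                               cox_p = cx$p_value)
    classes[[paste0("split_", sc)]] <- as.character(split[classes$sample_id])
    for (lev in c("Hi", "Lo"))
      km_curves[[paste0(sc, "_", lev)]] <-
        km_estimate(clinical$os_days[labels == lev], clinical$event[labels == lev])
  }
  utils::write.table(classes, file.path(out_dir, "classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(stats_tab, file.path(out_dir, "stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  km_plot_window(km_curves, t_max = 4000, file = file.path(out_dir, "km_curves.pdf"))
  log_stage("survival", "%d stratifications analyzed", length(surv_results))

  summary <- list(
    schema_version = "1.0",
    seed = seed,
    mode = if (simulate) "simulate" else "files",
    ssgsea = list(alpha = scfg$alpha, normalized = attr(enrich, "normalized"),
                  tie_policy = scfg$tie_policy),
    shapes = list(genes = nrow(expr), samples = ncol(expr),
                  cell_type_sets = length(cell_type_names),
                  pathway_sets = length(pathway_names)),
    cluster_sizes = as.list(stats::setNames(as.integer(table(clusters)),
                                            names(table(clusters)))),
    contrasts = stats_tab,
    correlations = correlations,
    mutation_tests = mutation_tests,
    survival = surv_results)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
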