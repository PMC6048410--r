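#' @title Synthetic cohort generator
#' @name synthetic_cohort
#' @description
#' Generates expression + clinical cohorts with known ground truth that
#' emulate the statistical structure the sidedness analysis assumes: planted
#' per-sample infiltration tiers driving signature-gene expression, a
#' right-vs-left infiltration shift in T subsets, a left shift in
#' CD56-bright NK / 4-1BB / IFN-alpha signaling, a right-side-only negative
#' VEGFA-CD8 coupling, and survival whose hazard depends on chosen latent
#' scores. The generator writes the same TSV/GMT formats the readers
#' consume, so it is a drop-in upstream for the whole pipeline; its latent
#' truth is stored alongside (never consumed by) the pipeline under test.
NULL

#' The 27-type immune cell panel
#'
#' Names and default marker-signature sizes for the innate and adaptive
#' immune cell types scored by the pipeline.
#' @return data.frame with columns `name`, `size`.
#' @export
default_cell_types <- function() {
  names <- c(
    "Natural killer cell", "CD56dim natural killer cell",
    "CD56bright natural killer cell", "Plasmacytoid dendritic cell",
    "Immature dendritic cell", "Activated dendritic cell", "Neutrophil",
    "Monocyte", "Mast cell", "Eosinophil", "Macrophage",
    "Immature B cell", "Activated B cell", "Central memory CD4 T cell",
    "Effector memory CD4 T cell", "Activated CD4 T cell",
    "Central memory CD8 T cell", "Effector memory CD8 T cell",
    "Activated CD8 T cell", "Natural killer T cell",
    "T follicular helper cell", "Gamma delta T cell",
    "Type 1 T helper cell", "Type 2 T helper cell", "Type 17 T helper cell",
    "Regulatory T cell")
  sizes <- c(24, 15, 12, 30, 18, 21, 14, 26, 11, 8, 28,
             19, 25, 16, 20, 17, 13, 22, 29, 10,
             23, 9, 27, 15, 12, 18)
  # a generic T-cell signature completes the 27-type panel
  data.frame(name = c(names, "T cell"), size = c(sizes, 31),
             stringsAsFactors = FALSE)
}

#' The nine T subsets shifted upward on the right side by default
#' @return character vector of cell-type names.
#' @export
default_right_shift_types <- function() default_tis_sets()

#' Generator configuration
#'
#' Defaults encode the cohort structure the analysis assumes: a study-like
#' right-side fraction, three infiltration tiers, log-normal expression
#' noise, a right-side T-subset shift, a left-side CD56-bright NK / 4-1BB /
#' IFN-alpha shift, right-only VEGFA-CD8 coupling, and exponential survival
#' with uniform censoring over the 0-4000-day follow-up window.
#'
#' @param n_samples cohort size.
#' @param p_right probability a sample is right-sided (study-like 0.36).
#' @param cell_types data.frame `name`,`size`; default [default_cell_types()].
#' @param n_background_genes unrelated genes, default 2000. Signature genes
#'   must stay a small minority of the matrix as they are in a real
#'   transcriptome: ranks are zero-sum within a sample, so an unrealistically
#'   signature-heavy matrix makes the 27 signatures compete for rank mass
#'   and compresses between-sample enrichment differences.
#' @param tier_multipliers infiltration multipliers, default `c(0.2, 1, 3)`
#'   (low/median/high).
#' @param tier_probs sampling probabilities for the tiers (low/median/high).
#' @param kappa signature amplification per unit infiltration, default 1.
#' @param sigma log-normal expression noise sd, default 0.3.
#' @param delta_right log-shift applied to `right_shift_types` on the right
#'   side, default 0.5.
#' @param delta_left_nk log-shift applied to CD56-bright NK and the 4-1BB /
#'   IFN-alpha pathway blocks on the left side, default 0.3.
#' @param right_shift_types which cell types get `delta_right`.
#' @param w_vegfa right-side-only VEGFA-CD8 coupling strength, default 1.
#' @param mu_vegfa VEGFA baseline log-expression, default 2.
#' @param lambda0 baseline hazard per day, default 5e-4 (median survival
#'   ~1400 days at baseline).
#' @param beta named log-hazard coefficients on z-scored latent covariates;
#'   available names: `"overall_f"` (mean infiltration fraction) and any
#'   cell-type/pathway name (its latent f). Default
#'   `c(overall_f = -0.3)`: infiltrated tumors fare better.
#' @param censor_max uniform censoring upper bound in days, default 4000.
#' @param include_pathways also plant 4-1BB / IFN-alpha / APM signature
#'   blocks (scored as pathways, not cell types), default TRUE.
#' @param include_mutations add EGFR/BRAF/KRAS/TP53 mutation flags, with
#'   EGFR mutation odds increasing with infiltration tier, default TRUE.
#' @param seed RNG seed; all randomness flows from it.
#' @return list of class `GeneratorConfig`.
#' @export
generator_config <- function(n_samples = 200L, p_right = 0.36,
                             cell_types = default_cell_types(),
                             n_background_genes = 2000L,
                             tier_multipliers = c(0.2, 1, 3),
                             tier_probs = c(0.26, 0.41, 0.33),
                             kappa = 1.0, sigma = 0.3,
                             delta_right = 0.5, delta_left_nk = 0.3,
                             right_shift_types = default_right_shift_types(),
                             w_vegfa = 1.0, mu_vegfa = 2.0,
                             lambda0 = 5e-4, beta = c(overall_f = -0.3),
                             censor_max = 4000,
                             include_pathways = TRUE,
                             include_mutations = TRUE,
                             seed = 1L) {
  stopifnot(n_samples >= 2L, p_right >= 0, p_right <= 1,
            all(tier_probs >= 0), abs(sum(tier_probs) - 1) < 1e-8,
            length(tier_multipliers) == length(tier_probs),
            sigma > 0, lambda0 > 0, censor_max > 0, kappa >= 0, w_vegfa >= 0)
  structure(list(n_samples = as.integer(n_samples), p_right = p_right,
                 cell_types = cell_types,
                 n_background_genes = as.integer(n_background_genes),
                 tier_multipliers = tier_multipliers, tier_probs = tier_probs,
                 kappa = kappa, sigma = sigma,
                 delta_right = delta_right, delta_left_nk = delta_left_nk,
                 right_shift_types = right_shift_types,
                 w_vegfa = w_vegfa, mu_vegfa = mu_vegfa,
                 lambda0 = lambda0, beta = beta, censor_max = censor_max,
                 include_pathways = isTRUE(include_pathways),
                 include_mutations = isTRUE(include_mutations),
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

sanitize_prefix <- function(name) {
  toupper(gsub("[^A-Za-z0-9]+", "", abbreviate(gsub("[^A-Za-z0-9 ]", "", name), 8L)))
}

#' Draw survival times from an exponential hazard with uniform censoring
#'
#' T ~ Exp(lambda0 * exp(linpred)), C ~ U(0, censor_max); uses the current
#' RNG state (seed management belongs to the caller).
#'
#' @param linpred per-sample log relative hazard.
#' @param lambda0 baseline hazard per day.
#' @param censor_max censoring upper bound (days).
#' @return data.frame `os_days` (integer >= 1), `event`.
#' @export
simulate_survival <- function(linpred, lambda0, censor_max) {
  n <- length(linpred)
  t_event <- stats::rexp(n, rate = lambda0 * exp(linpred))
  t_cens <- stats::runif(n, 0, censor_max)
  event <- as.integer(t_event <= t_cens)
  os <- pmax(1L, as.integer(round(pmin(t_event, t_cens))))
  data.frame(os_days = os, event = event)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' @param cfg [generator_config()].
#' @return list with elements `expr` (`ExpressionMatrix`), `clinical`
#'   (`ClinicalTable`), `sets` (`GeneSetCollection`: one set per cell type
#'   and pathway, listing exactly the true signature genes), `truth`
#'   (data.frame of all latent variables) and `pathway_names`.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  side <- ifelse(stats::runif(n) < cfg$p_right, "right", "left")
  tier_idx <- sample.int(length(cfg$tier_multipliers), n, replace = TRUE,
                         prob = cfg$tier_probs)
  u <- cfg$tier_multipliers[tier_idx]

  blocks <- cfg$cell_types
  blocks$kind <- "cell_type"
  if (cfg$include_pathways) {
    pw <- data.frame(name = c("41BB signaling pathway", "Interferon-a response", "APM"),
                     size = c(15L, 20L, 8L), kind = "pathway",
                     stringsAsFactors = FALSE)
    blocks <- rbind(blocks, pw)
  }
  if (anyDuplicated(blocks$name)) stop("duplicate block names in generator config")

  # latent infiltration fractions f[c, s] = u_s * exp(side shift) * lognormal jitter
  left_shift_types <- c("CD56bright natural killer cell",
                        "41BB signaling pathway", "Interferon-a response")
  f <- matrix(NA_real_, nrow = nrow(blocks), ncol = n,
              dimnames = list(blocks$name, samples))
  for (ci in seq_len(nrow(blocks))) {
    nm <- blocks$name[ci]
    delta <- numeric(n)
    if (nm %in% cfg$right_shift_types) delta[side == "right"] <- cfg$delta_right
    if (nm %in% left_shift_types) delta[side == "left"] <- cfg$delta_left_nk
    f[ci, ] <- u * exp(delta) * exp(stats::rnorm(n, 0, sqrt(0.1)))
  }

  # gene universe: per-block signatures, special genes, background
  prefixes <- vapply(blocks$name, sanitize_prefix, character(1L))
  if (anyDuplicated(prefixes)) {
    dup <- duplicated(prefixes)
    prefixes[dup] <- paste0(prefixes[dup], seq_len(sum(dup)))
  }
  sig_genes <- lapply(seq_len(nrow(blocks)), function(ci)
    sprintf("%s_G%02d", prefixes[ci], seq_len(blocks$size[ci])))
  names(sig_genes) <- blocks$name
  special <- c("PRF1", "GZMA", "IFNG", "VEGFA")
  bg_genes <- sprintf("BG_G%04d", seq_len(cfg$n_background_genes))
  all_genes <- c(unlist(sig_genes, use.names = FALSE), special, bg_genes)
  stopifnot(!anyDuplicated(all_genes))

  b <- stats::rlnorm(length(all_genes), meanlog = 2, sdlog = 0.5)
  names(b) <- all_genes
  noise <- function(rows) matrix(exp(stats::rnorm(rows * n, 0, cfg$sigma)), rows, n)

  expr <- matrix(NA_real_, nrow = length(all_genes), ncol = n,
                 dimnames = list(all_genes, samples))
  for (ci in seq_len(nrow(blocks))) {
    g <- sig_genes[[ci]]
    expr[g, ] <- outer(b[g], 1 + cfg$kappa * f[ci, ]) * noise(length(g))
  }
  f_cd8 <- f["Activated CD8 T cell", ]
  for (g in c("PRF1", "GZMA", "IFNG"))
    expr[g, ] <- b[g] * (1 + cfg$kappa * f_cd8) * exp(stats::rnorm(n, 0, cfg$sigma))
  expr["VEGFA", ] <- exp(cfg$mu_vegfa - cfg$w_vegfa * f_cd8 * (side == "right") +
                           stats::rnorm(n, 0, cfg$sigma))
  expr[bg_genes, ] <- outer(b[bg_genes], rep(1, n)) * noise(length(bg_genes))

  # survival: log-hazard from z-scored latent covariates named in beta
  covars <- rbind(overall_f = colMeans(f[blocks$kind == "cell_type", , drop = FALSE]), f)
  linpred <- numeric(n)
  for (nm in names(cfg$beta)) {
    if (!nm %in% rownames(covars)) stop("beta names a latent covariate not generated: ", nm)
    linpred <- linpred + cfg$beta[[nm]] * as.numeric(scale(covars[nm, ]))
  }
  surv <- simulate_survival(linpred, cfg$lambda0, cfg$censor_max)

  clinical <- data.frame(sample_id = samples, os_days = surv$os_days,
                         event = surv$event, side = side,
                         stringsAsFactors = FALSE)
  if (cfg$include_mutations) {
    p_egfr <- stats::plogis(-1.5 + 0.6 * tier_idx)
    clinical$EGFR <- as.integer(stats::runif(n) < p_egfr)
    clinical$BRAF <- as.integer(stats::runif(n) < 0.10)
    clinical$KRAS <- as.integer(stats::runif(n) < 0.40)
    clinical$TP53 <- as.integer(stats::runif(n) < 0.50)
  }

  truth <- data.frame(sample_id = samples, side = side, tier = tier_idx,
                      tier_multiplier = u, log_hazard = linpred,
                      os_days = surv$os_days, event = surv$event,
                      stringsAsFactors = FALSE)
  ft <- t(f)
  colnames(ft) <- paste0("f.", gsub("[^A-Za-z0-9]+", "_", blocks$name))
  truth <- cbind(truth, as.data.frame(ft))
  rownames(truth) <- NULL

  desc <- stats::setNames(
    ifelse(blocks$kind == "pathway", "synthetic pathway signature",
           "synthetic cell-type signature"), blocks$name)
  list(expr = as_expression_matrix(expr),
       clinical = as_clinical_table(clinical),
       sets = as_gene_sets(sig_genes, descriptions = desc),
       truth = truth,
       cell_type_names = blocks$name[blocks$kind == "cell_type"],
       pathway_names = blocks$name[blocks$kind == "pathway"])
}

#' Write the generator's latent truth as TSV
#' @param truth data.frame from [generate_cohort()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
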