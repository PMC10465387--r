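#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a bulk tumour expression cohort with the structure
#' the downstream analysis assumes: log-normal TPM-scale expression, three
#' (by default) sample clusters expressed through the regulator panel,
#' planted prognostic genes with ordered cluster means, proportional-hazards
#' survival driven by a latent risk score, per-sample mutations, MSI
#' categories and immunophenoscore columns.
#'
#' Cluster structure: regulators are split round-robin into `k_true` blocks;
#' block j is shifted up by `cluster_shift` (log scale) in cluster j.
#' Prognostic genes share an ordered profile: gene g in cluster z has offset
#' `w_g * cluster_shift * a_z` where `a` is an equispaced grid on [-1, 1]
#' over clusters and `w_g ~ U(0.75, 1.25)`, so every planted gene separates
#' all cluster pairs and all share one risk orientation.
#'
#' The latent `true_score` is the centred per-sample mean of planted
#' prognostic-gene log expression; survival times are exponential with
#' hazard `baseline_hazard * exp(log_hr_per_unit_score * true_score)` under
#' independent uniform censoring tuned to `censor_rate_target`.
#'
#' @param n_samples cohort size.
#' @param n_background_genes genes with no planted structure.
#' @param n_regulators size of the regulator panel (48 uses the packaged
#'   catalog names).
#' @param n_prognostic_genes planted prognostic genes.
#' @param k_true number of planted sample clusters.
#' @param cluster_probs mixing proportions, length `k_true`, summing to 1.
#' @param cluster_shift log-scale mean offset expressing cluster membership.
#' @param noise_sd log-scale residual standard deviation.
#' @param log_hr_per_unit_score planted Cox coefficient (beta*).
#' @param baseline_hazard baseline exponential hazard per day.
#' @param censor_rate_target expected fraction censored, in (0, 1).
#' @param mutation_gene_freqs named per-gene mutation probabilities.
#' @param mutation_score_coef log-multiplier per unit score applied to
#'   mutation probabilities (0 disables score-dependent enrichment).
#' @param msi_score_coef,ips_score_coef strength of score dependence for MSI
#'   logits and IPS means.
#' @param seed integer seed that fully determines all outputs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 300,
                       n_background_genes = 500,
                       n_regulators = 48,
                       n_prognostic_genes = 30,
                       k_true = 3,
                       cluster_probs = rep(1 / k_true, k_true),
                       cluster_shift = 1.5,
                       noise_sd = 0.5,
                       log_hr_per_unit_score = 0.8,
                       baseline_hazard = 0.001,
                       censor_rate_target = 0.3,
                       mutation_gene_freqs = c(APC = 0.7, TP53 = 0.5,
                                               TTN = 0.4, KRAS = 0.4,
                                               PIK3CA = 0.25, SMAD4 = 0.15,
                                               FBXW7 = 0.12, BRAF = 0.10),
                       mutation_score_coef = 0,
                       msi_score_coef = 1,
                       ips_score_coef = 0.5,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_background_genes = as.integer(n_background_genes),
              n_regulators = as.integer(n_regulators),
              n_prognostic_genes = as.integer(n_prognostic_genes),
              k_true = as.integer(k_true),
              cluster_probs = cluster_probs,
              cluster_shift = cluster_shift,
              noise_sd = noise_sd,
              log_hr_per_unit_score = log_hr_per_unit_score,
              baseline_hazard = baseline_hazard,
              censor_rate_target = censor_rate_target,
              mutation_gene_freqs = mutation_gene_freqs,
              mutation_score_coef = mutation_score_coef,
              msi_score_coef = msi_score_coef,
              ips_score_coef = ips_score_coef,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 1, cfg$n_background_genes >= 1,
            cfg$n_regulators >= 1, cfg$n_prognostic_genes >= 1)
  if (cfg$k_true < 2) stop("k_true must be >= 2")
  if (cfg$k_true > cfg$n_samples) stop("k_true exceeds n_samples")
  if (length(cfg$cluster_probs) != cfg$k_true)
    stop("cluster_probs must have length k_true")
  if (abs(sum(cfg$cluster_probs) - 1) > 1e-9)
    stop("cluster_probs must sum to 1")
  if (any(cfg$cluster_probs <= 0)) stop("cluster_probs must be positive")
  if (cfg$cluster_shift < 0) stop("cluster_shift must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (cfg$censor_rate_target <= 0 || cfg$censor_rate_target >= 1)
    stop("censor_rate_target must be in (0, 1)")
  if (length(cfg$mutation_gene_freqs) &&
      (any(cfg$mutation_gene_freqs < 0) || any(cfg$mutation_gene_freqs > 1)))
    stop("mutation_gene_freqs must lie in [0, 1]")
  invisible(cfg)
}

sim_gene_ids <- function(cfg) {
  regs <- if (cfg$n_regulators == 48) {
    regulator_catalog()$gene
  } else {
    sprintf("REG%03d", seq_len(cfg$n_regulators))
  }
  list(regulators = regs,
       prognostic = sprintf("PRG%03d", seq_len(cfg$n_prognostic_genes)),
       background = sprintf("BG%04d", seq_len(cfg$n_background_genes)))
}

#' Generate a synthetic cohort
#'
#' @param config a [sim_config()].
#' @return list with `expression` (TPM [expression_matrix()]), `clinical`
#'   (data.frame), `catalog` (`regulator_catalog`) and `truth` (list:
#'   `cluster_labels`, `prognostic_gene_ids`, `true_beta`, `true_score`).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  k <- config$k_true
  ids <- sim_gene_ids(config)
  genes <- c(ids$regulators, ids$prognostic, ids$background)
  samples <- sprintf("S%04d", seq_len(n))

  z <- sample.int(k, n, replace = TRUE, prob = config$cluster_probs)

  # baseline log-abundance per gene; heavier mean for regulators so the
  # panel sits in a realistic expression range
  mu <- stats::rnorm(length(genes), mean = 3, sd = 1)
  names(mu) <- genes

  delta <- matrix(0, length(genes), k, dimnames = list(genes, NULL))
  reg_block <- ((seq_along(ids$regulators) - 1L) %% k) + 1L
  for (j in seq_len(k))
    delta[ids$regulators[reg_block == j], j] <- config$cluster_shift
  a <- seq(-1, 1, length.out = k)
  w <- stats::runif(length(ids$prognostic), 0.75, 1.25)
  delta[ids$prognostic, ] <- outer(w, a) * config$cluster_shift

  eps <- matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
                length(genes), n, dimnames = list(genes, samples))
  loglat <- mu + delta[, z] + eps
  dimnames(loglat) <- list(genes, samples)
  vals <- exp(loglat)

  true_score <- colMeans(loglat[ids$prognostic, , drop = FALSE])
  true_score <- true_score - mean(true_score)

  beta <- config$log_hr_per_unit_score
  rate <- config$baseline_hazard * exp(beta * true_score)
  t_event <- stats::rexp(n, rate = rate)
  cmax <- solve_censor_horizon(t_event, config$censor_rate_target)
  t_cens <- stats::runif(n, 0, cmax)
  os_time <- pmax(pmin(t_event, t_cens), 1e-8)
  os_event <- as.integer(t_event <= t_cens)

  msi <- draw_msi(true_score, config$msi_score_coef)
  ips_base <- stats::rnorm(n, mean = 6, sd = 1)
  ips <- sapply(c("ips_ctla4_pos_pd1_pos", "ips_ctla4_pos_pd1_neg",
                  "ips_ctla4_neg_pd1_pos", "ips_ctla4_neg_pd1_neg"),
                function(nm) ips_base - config$ips_score_coef * true_score +
                  stats::rnorm(n, sd = 0.3))

  clinical <- data.frame(
    sample_id = samples,
    os_time = os_time,
    os_event = os_event,
    age = round(stats::rnorm(n, 65, 10)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stage = sample(1:4, n, replace = TRUE, prob = c(0.2, 0.35, 0.3, 0.15)),
    msi = msi,
    ips,
    cohort = "synthetic",
    stringsAsFactors = FALSE)

  expr <- expression_matrix(sweep(vals, 2, colSums(vals), "/") * 1e6, "TPM")

  catalog <- if (config$n_regulators == 48) {
    regulator_catalog()
  } else {
    df <- data.frame(gene = ids$regulators,
                     modification = rep_len(c("m6A", "m5C", "m1A"),
                                            config$n_regulators),
                     role = rep_len(c("writer", "reader", "eraser"),
                                    config$n_regulators),
                     stringsAsFactors = FALSE)
    class(df) <- c("regulator_catalog", "data.frame")
    df
  }

  list(expression = expr,
       clinical = clinical,
       catalog = catalog,
       truth = list(cluster_labels = stats::setNames(z, samples),
                    prognostic_gene_ids = ids$prognostic,
                    true_beta = beta,
                    true_score = stats::setNames(true_score, samples)))
}

# Solve the uniform-censoring horizon c so that the expected censored
# fraction mean_i P(C < T_i) with C ~ U(0, c) hits the target.
solve_censor_horizon <- function(t_event, target) {
  f <- function(cc) mean(pmin(t_event / cc, 1)) - target
  lo <- min(t_event) * 1e-3
  hi <- max(t_event) / max(target, 1e-6) * 10
  while (f(hi) > 0) hi <- hi * 10
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

draw_msi <- function(score, coef) {
  levels <- c("MSS", "MSI-L", "MSI-H")
  base <- c(0.55, 0.25, 0.20)
  orient <- c(1, 0, -1)
  vapply(score, function(s) {
    p <- base * exp(orient * coef * s)
    sample(levels, 1, prob = p / sum(p))
  }, character(1))
}

#' Generate a per-sample mutation table
#'
#' Bernoulli mutation events per (sample, gene) at the configured
#' frequencies, optionally enriched in high-score samples through the
#' multiplier `exp(mutation_score_coef * true_score)` (probabilities capped
#' at 1). One row per event with a drawn variant class.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element from [generate_cohort()].
#' @return data.frame with columns `sample_id`, `gene`, `variant_class`.
#' @export
generate_mutations <- function(config, truth) {
  validate_sim_config(config)
  freqs <- config$mutation_gene_freqs
  samples <- names(truth$true_score)
  if (is.null(samples)) stop("truth must carry named true_score")
  set.seed(config$seed + 104729L)  # offset stream, still seed-determined
  classes <- c("missense", "nonsense", "frameshift_del", "multi_hit", "silent")
  class_p <- c(0.6, 0.15, 0.1, 0.1, 0.05)
  rows <- list()
  mult <- exp(config$mutation_score_coef * truth$true_score)
  for (g in names(freqs)) {
    p <- pmin(freqs[[g]] * mult, 1)
    hit <- stats::runif(length(samples)) < p
    if (any(hit)) {
      rows[[g]] <- data.frame(
        sample_id = samples[hit],
        gene = g,
        variant_class = sample(classes, sum(hit), replace = TRUE,
                               prob = class_p),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sample_id = character(), gene = character(),
                      variant_class = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$gene), , drop = FALSE]
}

#' Generate synthetic immune-signature gene sets
#'
#' Random gene sets drawn from the cohort's background genes, stand-ins for
#' published immune cell-type signatures in tests and the synthetic
#' pipeline.
#'
#' @export
generate_immune_sets <- function(genes, n_sets = 10, set_size = 25,
                                 seed = 1L) {
  if (set_size > length(genes)) stop("set_size exceeds available genes")
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) sort(sample(genes, set_size)))
  names(sets) <- sprintf("immune_sig_%02d", seq_len(n_sets))
  sets
}
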