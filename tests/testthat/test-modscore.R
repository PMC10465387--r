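sim_for_score <- function(seed = 1, n = 150) {
  cfg <- sim_config(n_samples = n, n_background_genes = 50,
                    n_prognostic_genes = 20, seed = seed)
  coh <- generate_cohort(cfg)
  list(cfg = cfg, coh = coh, le = log2_transform(coh$expression))
}

test_that("rank-1 signature data collapses onto a single component", {
  set.seed(1)
  base <- rnorm(30)
  m <- outer(c(1, 2, 3, -1, 0.5), base) +
    matrix(rnorm(150, sd = 1e-8), 5, 30)
  dimnames(m) <- list(paste0("g", 1:5), sprintf("s%02d", 1:30))
  cl <- data.frame(sample_id = colnames(m), os_time = rexp(30, 0.1) + 1,
                   os_event = rbinom(30, 1, 0.8))
  ms <- suppressWarnings(
    compute_score(expression_matrix(m, "LOG2"), paste0("g", 1:5), cl))
  expect_lt(stats::sd(ms$pc2), 1e-6 * stats::sd(ms$pc1))
  expect_gt(abs(stats::cor(ms$score, base)), 0.999)
  expect_gte(sum(ms$explained), 0.999)
})

test_that("duplicating every sample leaves per-sample scores unchanged", {
  d <- sim_for_score(seed = 2, n = 60)
  genes <- d$coh$truth$prognostic_gene_ids
  ms <- compute_score(d$le, genes, d$coh$clinical)
  m2 <- cbind(unclass(d$le), unclass(d$le))
  colnames(m2) <- c(colnames(d$le), paste0(colnames(d$le), "_dup"))
  cl2 <- rbind(d$coh$clinical,
               transform(d$coh$clinical,
                         sample_id = paste0(sample_id, "_dup")))
  ms2 <- compute_score(expression_matrix(m2, "LOG2"), genes, cl2)
  r <- abs(stats::cor(ms$score, ms2$score[names(ms$score)]))
  expect_gt(r, 1 - 1e-10)
})

test_that("the score tracks the planted risk and is risk-oriented", {
  d <- sim_for_score(seed = 3, n = 200)
  ms <- compute_score(d$le, d$coh$truth$prognostic_gene_ids,
                      d$coh$clinical)
  rho <- stats::cor(ms$score[names(d$coh$truth$true_score)],
                    d$coh$truth$true_score, method = "spearman")
  expect_gte(abs(rho), 0.8)
  expect_gt(rho, 0)   # orientation: high score = high risk
  fit <- cox_univariate(ms$score, d$coh$clinical$os_time,
                        d$coh$clinical$os_event)
  expect_gte(fit$beta, 0)
  expect_true(sum(ms$explained) > 0 && sum(ms$explained) <= 1)
})

test_that("group assignment follows the median and shifts with translation", {
  sc <- stats::setNames(as.numeric(1:10), paste0("s", 1:10))
  g <- assign_groups(sc, method = "median")
  expect_equal(sum(g$group == "low"), 5L)
  expect_equal(names(g$group)[g$group == "low"], paste0("s", 1:5))
  g2 <- assign_groups(sc + 100, method = "median")
  expect_equal(g2$cutpoint, g$cutpoint + 100)
  expect_equal(unname(g2$group), unname(g$group))
  expect_error(assign_groups(rep(1, 10) + 0 * sc), "identical")
})

test_that("the optimal log-rank cut lands between planted risk groups", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    grp <- rep(0:1, each = n / 2)
    sc <- stats::setNames(grp * 3 + rnorm(n, sd = 0.3), sprintf("s%02d", 1:n))
    cl <- data.frame(sample_id = names(sc),
                     os_time = rexp(n, 0.01 * exp(1.5 * grp)),
                     os_event = 1)
    g <- assign_groups(sc, cl, method = "logrank_opt")
    g$cutpoint > max(sc[grp == 0]) - 0.5 && g$cutpoint < min(sc[grp == 1]) + 0.5
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("frozen projection reproduces training scores exactly", {
  d <- sim_for_score(seed = 4, n = 80)
  genes <- d$coh$truth$prognostic_gene_ids
  ms <- compute_score(d$le, genes, d$coh$clinical)
  proj <- apply_score(ms, d$le)
  expect_equal(proj$score, ms$score, tolerance = 1e-10)
})

test_that("dropping one signature gene perturbs scores within its loading bound", {
  d <- sim_for_score(seed = 5, n = 80)
  genes <- d$coh$truth$prognostic_gene_ids
  ms <- compute_score(d$le, genes, d$coh$clinical)
  drop <- genes[1]
  le_dropped <- d$le[setdiff(rownames(d$le), drop), ]
  proj <- suppressWarnings(apply_score(ms, le_dropped))
  # bound: removing g changes the projection of each sample by at most
  # |loading_g| * max|z_g| per component (plus re-z-scoring wobble, absent
  # here because the other genes' z-scores are unchanged)
  zmax <- max(abs(scale(unclass(d$le)[drop, ])))
  bound <- sum(abs(ms$loadings[drop, ])) * zmax + 1e-8
  expect_lte(max(abs(proj$score - ms$score)), bound)
})

test_that("external validation separates survival in held-out cohorts", {
  d <- sim_for_score(seed = 6, n = 200)
  ms <- compute_score(d$le, d$coh$truth$prognostic_gene_ids,
                      d$coh$clinical)
  ok <- vapply(1:5, function(s) {
    cfg2 <- sim_config(n_samples = 150, n_background_genes = 50,
                       n_prognostic_genes = 20, seed = 600 + s)
    coh2 <- generate_cohort(cfg2)
    val <- validate_external(ms, log2_transform(coh2$expression),
                             coh2$clinical)
    val$logrank$p < 0.05
  }, logical(1))
  expect_gte(sum(ok), 4)
})

test_that("projection fails cleanly without enough shared genes", {
  d <- sim_for_score(seed = 7, n = 60)
  genes <- d$coh$truth$prognostic_gene_ids
  ms <- compute_score(d$le, genes, d$coh$clinical)
  other <- d$le[setdiff(rownames(d$le), genes), ]
  expect_error(apply_score(ms, other), "fewer than 3")
})
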