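toy_mutations <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s3"),
    gene = c("APC", "TP53", "TTN", "APC", "KRAS"),
    variant_class = c("missense", "nonsense", "silent", "missense",
                      "missense"),
    stringsAsFactors = FALSE)
}

test_that("TMB counts rows, honours the class filter and flags absentees", {
  m <- toy_mutations()
  tmb <- compute_tmb(m, c("s1", "s2", "s3", "s4"))
  expect_equal(tmb$tmb, c(3, 1, 1, 0))
  expect_equal(tmb$no_mutation_data, c(FALSE, FALSE, FALSE, TRUE))
  tmb2 <- compute_tmb(m, "s1", class_filter = c("missense", "nonsense"))
  expect_equal(tmb2$tmb, 2)
  tmb3 <- compute_tmb(m, c("s1", "s2"), per_mb = 2)
  expect_equal(tmb3$tmb, c(1.5, 0.5))
  expect_error(compute_tmb(m, character()), "empty")
  expect_true(all(tmb$tmb_group[tmb$tmb <= attr(tmb, "cutpoint")] == "low"))
})

test_that("mutation summary reports per-group rates and rankings", {
  m <- toy_mutations()
  grp <- stats::setNames(c("a", "a", "a", "a"), c("s1", "s2", "s3", "s4"))
  ms <- mutation_summary(m, grp)
  expect_equal(unname(ms$rates["a"]), 0.75)
  g2 <- stats::setNames(rep(c("x", "y"), 2), c("s1", "s2", "s3", "s4"))
  ms2 <- mutation_summary(m, g2)  # x = {s1, s3} all mutated; y: s4 is not
  expect_equal(unname(ms2$rates), c(1, 0.5))
  expect_equal(ms2$genes$gene[ms2$genes$group == "x"][1], "APC")
  expect_error(mutation_summary(m, unname(grp)), "named")
})

test_that("planted gene frequencies rank correctly at realistic n", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_samples = 400, n_background_genes = 10,
                      n_prognostic_genes = 5,
                      mutation_gene_freqs = c(APC = 0.7, TP53 = 0.5,
                                              TTN = 0.4),
                      seed = 300 + s)
    coh <- generate_cohort(cfg)
    m <- generate_mutations(cfg, coh$truth)
    grp <- stats::setNames(rep("all", 400), coh$clinical$sample_id)
    tab <- mutation_summary(m, grp)$genes
    identical(tab$gene[1:3], c("APC", "TP53", "TTN"))
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("collapsing identical strata reproduces the two-group log-rank", {
  set.seed(1)
  n <- 80
  cl <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   os_time = rexp(n, 0.02), os_event = rbinom(n, 1, 0.8))
  fa <- stats::setNames(rep(c("lo", "hi"), each = n / 2), cl$sample_id)
  fb <- fa  # second factor identical: strata collapse pairwise
  expect_warning(skm <- stratified_km(cl, fa, fb), "empty stratum")
  two <- logrank_test(cl$os_time, cl$os_event, fa)
  expect_equal(skm$logrank$chi2, two$chi2, tolerance = 1e-10)
  expect_equal(length(skm$curves), 2L)
})

test_that("score-driven hazard dominates strata regardless of TMB level", {
  cfg <- sim_config(n_samples = 400, n_background_genes = 10,
                    n_prognostic_genes = 5, log_hr_per_unit_score = 1,
                    seed = 11)
  coh <- generate_cohort(cfg)
  m <- generate_mutations(cfg, coh$truth)  # TMB independent of score
  sc <- coh$truth$true_score
  grp <- stats::setNames(
    factor(ifelse(sc > stats::median(sc), "high", "low")), names(sc))
  tmb <- compute_tmb(m, coh$clinical$sample_id)
  tmbg <- stats::setNames(tmb$tmb_group, tmb$sample_id)
  skm <- stratified_km(coh$clinical, grp, tmbg)
  expect_lt(skm$logrank$p, 0.001)
  # low-score strata must out-survive high-score strata at the median time
  med <- stats::median(coh$clinical$os_time)
  s_at <- vapply(skm$curves, function(cv) {
    i <- findInterval(med, cv$time)
    if (i == 0) 1 else cv$surv[i]
  }, numeric(1))
  lows <- grep("^low/", names(s_at)); highs <- grep("^high/", names(s_at))
  expect_gt(min(s_at[lows]), max(s_at[highs]))
})

test_that("group comparisons dispatch to the right tests", {
  a <- c(1, 2, 3, 4); b <- c(101, 102, 103, 104)
  cmp <- compare_groups(c(a, b), rep(c("g1", "g2"), each = 4))
  expect_equal(cmp$test, "wilcoxon")
  # fully separated 4v4: exact two-sided rank-sum p = 2 / choose(8, 4)
  expect_equal(cmp$p, 2 / choose(8, 4), tolerance = 1e-12)
  expect_lt(cmp$p, 0.05)
  k <- compare_groups(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(k$test, "kruskal")
  expect_equal(k$statistic, 0, tolerance = 1e-12)
  ch <- compare_groups(rep(c("MSS", "MSI-H"), c(30, 10)),
                       rep(c("hi", "lo"), 20))
  expect_equal(ch$test, "chi2")
  expect_error(compare_groups(1:4, rep("one", 4)), ">= 2 groups")
})

test_that("null rank-sum p-values are uniform across seeds", {
  set.seed(2)
  ps <- replicate(100, {
    v <- rnorm(40)
    compare_groups(v, sample(rep(1:2, 20)))$p
  })
  # exact rank-sum p-values are discrete, so check calibration by moments
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.1)
})

test_that("score-immune correlation recovers exact monotone relations", {
  set.seed(3)
  sc <- stats::setNames(rnorm(30), sprintf("s%02d", 1:30))
  enr <- structure(list(scores = rbind(same = sc, anti = -sc,
                                       noise = rnorm(30)),
                        alpha = 0.25, normalized = FALSE),
                   class = "enrichment_result")
  colnames(enr$scores) <- names(sc)
  res <- score_immune_correlation(sc, enr)
  expect_equal(res$rho[res$set == "same"], 1, tolerance = 1e-12)
  expect_equal(res$rho[res$set == "anti"], -1, tolerance = 1e-12)
  expect_error(score_immune_correlation(sc * 0, enr), "constant")
})

test_that("independent enrichment rows yield calibrated discoveries", {
  set.seed(4)
  sc <- stats::setNames(rnorm(60), sprintf("s%02d", 1:60))
  rows <- matrix(rnorm(50 * 60), 50,
                 dimnames = list(sprintf("set%02d", 1:50), names(sc)))
  enr <- structure(list(scores = rows, alpha = 0.25, normalized = FALSE),
                   class = "enrichment_result")
  res <- score_immune_correlation(sc, enr)
  expect_lt(mean(abs(res$rho)), 0.2)
  expect_lte(sum(res$p_adj < 0.05), 2)
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  universe <- sprintf("u%04d", 1:1000)
  hits <- universe[1:50]
  ann <- list(target = c(universe[48:50], universe[900:906]),
              cold = universe[500:509])
  res <- ora_hypergeometric(hits, ann, universe)
  want <- oracle_hyper_tail(3, 10, 50, 1000)
  expect_equal(res$p[res$set == "target"], want, tolerance = 1e-12)
  # extreme overlap: a fully-hit set reaches the minimal achievable tail
  ann2 <- list(full = hits[1:10])
  res2 <- ora_hypergeometric(hits, ann2, universe)
  expect_equal(res2$p, oracle_hyper_tail(10, 10, 50, 1000),
               tolerance = 1e-12)
  expect_error(ora_hypergeometric(c("zzz"), ann, universe), "outside")
  expect_error(ora_hypergeometric(character(), ann, universe), "empty hit")
})

test_that("uniformly drawn hits give uniform enrichment p-values", {
  set.seed(5)
  universe <- sprintf("u%03d", 1:500)
  ann <- list(s = universe[1:40])
  ps <- replicate(200, {
    ora_hypergeometric(sample(universe, 30), ann, universe)$p
  })
  # discrete p-values: check the mean is near 0.5 rather than KS
  expect_lt(abs(mean(ps) - 0.5), 0.12)
})

test_that("the ddCt fold-change formula matches its closed forms", {
  expect_equal(ddct_fold_change(20, 18, 20, 18), 1)
  expect_equal(ddct_fold_change(19, 18, 20, 18), 2)
  expect_equal(ddct_fold_change(20, 18, 22, 18), 4)
})
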