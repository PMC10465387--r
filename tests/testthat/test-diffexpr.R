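two_group_matrix <- function(n_genes, na, nb, delta_genes = integer(),
                             delta = 0, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (na + nb), mean = 5, sd = sd), n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(na + nb))))
  m[delta_genes, seq_len(na)] <- m[delta_genes, seq_len(na)] + delta
  list(x = expression_matrix(m, "LOG2"),
       labels = rep(c("A", "B"), c(na, nb)))
}

test_that("forcing d0 = 0 recovers the ordinary pooled two-sample t", {
  d <- two_group_matrix(50, 8, 8, seed = 1)
  res <- moderated_pairwise(d$x, d$labels, "A", "B", d0 = 0)
  for (g in c(1, 17, 42)) {
    tt <- t.test(unclass(d$x)[g, 1:8], unclass(d$x)[g, 9:16],
                 var.equal = TRUE)
    expect_equal(res$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("a huge d0 collapses the denominator to the prior scale", {
  d <- two_group_matrix(200, 6, 6, seed = 2)
  res <- moderated_pairwise(d$x, d$labels, "A", "B", d0 = 1e12)
  s0 <- attr(res, "s0_sq")
  want <- res$mean_diff / sqrt(s0 * (1 / 6 + 1 / 6))
  expect_equal(res$t, want, tolerance = 1e-4)
})

test_that("moderated results agree with limma's empirical Bayes machinery", {
  skip_if_not_installed("limma")
  # heteroscedastic genes so the prior df is finite and shrinkage is real
  set.seed(3)
  sds <- sqrt(1 / stats::rgamma(300, shape = 4, rate = 4))
  m <- matrix(rnorm(300 * 20, mean = 5, sd = rep(sds, 20)), 300,
              dimnames = list(sprintf("g%04d", 1:300),
                              sprintf("s%03d", 1:20)))
  m[1:10, 1:10] <- m[1:10, 1:10] + 2
  labels <- rep(c("A", "B"), each = 10)
  d <- list(x = expression_matrix(m, "LOG2"), labels = labels)
  res <- moderated_pairwise(d$x, d$labels, "A", "B")
  expect_true(is.finite(attr(res, "d0")))
  design <- stats::model.matrix(~ 0 + factor(d$labels))
  colnames(design) <- c("A", "B")
  fit <- limma::lmFit(unclass(d$x), design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(A - B,
                                                        levels = design))
  fit <- limma::eBayes(fit)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("BH adjustment preserves the raw p-value ordering", {
  d <- two_group_matrix(500, 5, 5, delta_genes = 1:20, delta = 1.5, seed = 4)
  res <- moderated_pairwise(d$x, d$labels, "A", "B")
  o <- order(res$p)
  expect_true(all(diff(res$p_adj[o]) >= -1e-15))
  expect_true(all(res$p_adj >= 0 & res$p_adj <= 1))
})

test_that("null raw p-values are calibrated", {
  d <- two_group_matrix(5000, 10, 10, seed = 5)
  res <- moderated_pairwise(d$x, d$labels, "A", "B")
  frac <- mean(res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(frac - 0.05), 3 * se + 0.005)
})

test_that("a strong planted effect is always discovered", {
  for (s in 1:5) {
    d <- two_group_matrix(200, 20, 20, delta_genes = 1, delta = 5, seed = s)
    res <- moderated_pairwise(d$x, d$labels, "A", "B")
    expect_true(res$deg[1])
  }
})

test_that("zero-variance genes are flagged with p = 1", {
  d <- two_group_matrix(30, 4, 4, seed = 6)
  m <- unclass(d$x); m[3, ] <- 7
  x <- expression_matrix(m, "LOG2")
  res <- moderated_pairwise(x, d$labels, "A", "B")
  expect_true(res$zero_variance[3])
  expect_equal(res$p[3], 1)
  expect_error(moderated_pairwise(d$x, rep(c("A", "B"), c(1, 7)), "A", "B"),
               ">= 2 samples")
})

test_that("the Venn overlap rule intersects per-contrast DEG sets", {
  fake <- function(genes, sig) {
    data.frame(gene = genes, p_adj = ifelse(genes %in% sig, 1e-5, 0.5))
  }
  r1 <- fake(c("A", "B", "C"), c("A", "B"))
  r2 <- fake(c("A", "B", "C"), c("B", "C"))
  expect_equal(overlap_degs(list(r1, r2)), "B")
  r3 <- fake(c("A", "B", "C"), character())
  expect_equal(overlap_degs(list(r1, r2, r3)), character(0))
  expect_error(overlap_degs(list()), "empty")
})

test_that("planted all-contrast genes are recovered exactly by the overlap", {
  set.seed(7)
  n <- c(15, 15, 15)
  labels <- rep(c("A", "B", "C"), n)
  m <- matrix(rnorm(300 * sum(n), 5), 300,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d",
                                                               1:sum(n))))
  all3 <- 1:30          # distinct mean in every cluster
  onepair <- 31:60      # differs in A only
  m[all3, labels == "A"] <- m[all3, labels == "A"] + 3
  m[all3, labels == "C"] <- m[all3, labels == "C"] - 3
  m[onepair, labels == "A"] <- m[onepair, labels == "A"] + 3
  x <- expression_matrix(m, "LOG2")
  de <- pairwise_contrasts(x, labels)
  degs <- overlap_degs(de, alpha = 0.001)
  expect_setequal(degs, sprintf("g%03d", all3))
})
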