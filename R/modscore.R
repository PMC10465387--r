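#' Per-sample modification score from prognostic-gene PCA
#'
#' Signature genes are z-scored across samples, the sample-by-gene matrix is
#' decomposed by PCA, and each of the first two components is sign-oriented
#' so that its univariate Cox coefficient on overall survival is
#' non-negative (high score = higher hazard). The per-sample score is the
#' sum of the two oriented projections; samples are dichotomised at the
#' median by default.
#'
#' @param x an [expression_matrix()] on the LOG2 scale.
#' @param genes signature genes (>= 3 must be present in `x`).
#' @param clinical clinical table (`sample_id`, `os_time`, `os_event`)
#'   covering the samples of `x`.
#' @param cut_method `"median"` (default) or `"logrank_opt"`.
#' @return object of class `mod_score`: per-sample `score`, `pc1`, `pc2`,
#'   `group`, plus frozen model pieces (`loadings`, `center`, `scale`,
#'   `signs`, `explained`, `cutpoint`, `cut_method`).
#' @export
compute_score <- function(x, genes, clinical,
                          cut_method = c("median", "logrank_opt")) {
  cut_method <- match.arg(cut_method)
  if (expr_unit(x) != "LOG2") stop("expression must be on the LOG2 scale")
  genes <- intersect(genes, rownames(x))
  if (length(genes) < 3) stop("need >= 3 usable signature genes")
  if (ncol(x) < 3) stop("need >= 3 samples")
  idx <- match(colnames(x), clinical$sample_id)
  if (any(is.na(idx))) stop("sample(s) missing from clinical table")
  cl <- clinical[idx, ]

  m <- unclass(x)[genes, , drop = FALSE]
  ctr <- rowMeans(m)
  scl <- apply(m, 1, stats::sd)
  usable <- scl > 0
  if (sum(usable) < 3) stop("fewer than 3 non-constant signature genes")
  if (!all(usable)) {
    warning("dropping constant signature gene(s): ",
            paste(genes[!usable], collapse = ", "))
    m <- m[usable, , drop = FALSE]
    genes <- genes[usable]; ctr <- ctr[usable]; scl <- scl[usable]
  }
  z <- (m - ctr) / scl

  pca <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  rank2 <- ncol(pca$rotation) >= 2 && pca$sdev[2] > 1e-10
  pc1 <- pca$x[, 1]
  pc2 <- if (rank2) pca$x[, 2] else {
    warning("signature matrix has rank < 2; PC2 set to 0")
    stats::setNames(rep(0, ncol(z)), colnames(z))
  }
  signs <- c(orient_sign(pc1, cl), if (rank2) orient_sign(pc2, cl) else 1)
  pc1 <- signs[1] * pc1
  pc2 <- signs[2] * pc2
  score <- pc1 + pc2

  loadings <- pca$rotation[, 1:2, drop = FALSE]
  if (!rank2) loadings[, 2] <- 0
  loadings <- sweep(loadings, 2, signs, "*")
  rownames(loadings) <- genes

  grp <- assign_groups(score, cl, method = cut_method)
  structure(list(score = score, pc1 = pc1, pc2 = pc2,
                 group = grp$group, cutpoint = grp$cutpoint,
                 cut_method = cut_method,
                 loadings = loadings, center = ctr, scale = scl,
                 signs = signs, explained = ev[1:2]),
            class = "mod_score")
}

# +1 if the component's Cox beta on OS is already >= 0, else -1
orient_sign <- function(pc, clinical) {
  fit <- cox_univariate(pc, clinical$os_time, clinical$os_event)
  if (fit$beta < 0) -1 else 1
}

#' Dichotomise scores into high/low groups
#'
#' `median`: cut at the sample median, ties assigned to the low group.
#' `logrank_opt`: cut maximising the two-group log-rank statistic over
#' candidate cutpoints keeping each group at least 30% of samples.
#'
#' @param score named per-sample scores.
#' @param clinical clinical table covering the scored samples (used by
#'   `logrank_opt`).
#' @param method `"median"` or `"logrank_opt"`.
#' @return list with `group` (factor high/low) and `cutpoint`.
#' @export
assign_groups <- function(score, clinical = NULL,
                          method = c("median", "logrank_opt")) {
  method <- match.arg(method)
  if (length(score) < 4) stop("need >= 4 samples")
  if (max(score) == min(score)) stop("all scores identical")
  if (method == "median") {
    cut <- stats::median(score)
  } else {
    if (is.null(clinical)) stop("logrank_opt needs the clinical table")
    idx <- match(names(score), clinical$sample_id)
    if (any(is.na(idx))) stop("scored sample(s) missing from clinical table")
    cl <- clinical[idx, ]
    s <- sort(unique(score))
    lo <- stats::quantile(score, 0.3, names = FALSE)
    hi <- stats::quantile(score, 0.7, names = FALSE)
    cand <- s[s >= lo & s < hi]
    if (!length(cand)) cand <- stats::median(score)
    stat <- vapply(cand, function(cc) {
      g <- score > cc
      if (!any(g) || all(g)) return(-Inf)
      logrank_test(cl$os_time, cl$os_event, g)$chi2
    }, numeric(1))
    cut <- cand[which.max(stat)]
  }
  group <- factor(ifelse(score > cut, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0)) stop("degenerate cut: one group is empty")
  list(group = stats::setNames(group, names(score)), cutpoint = cut)
}

#' Project a frozen score model onto a new cohort
#'
#' Signature genes are z-scored within the new cohort and projected through
#' the frozen (sign-oriented) loadings; no refitting. Missing signature
#' genes are dropped with a warning (at least 3 must overlap).
#'
#' @param model a fitted `mod_score`.
#' @param x new-cohort [expression_matrix()] on the LOG2 scale.
#' @return list with per-sample `score`, `pc1`, `pc2` and `genes_used`.
#' @export
apply_score <- function(model, x) {
  if (expr_unit(x) != "LOG2") stop("expression must be on the LOG2 scale")
  sig <- rownames(model$loadings)
  shared <- intersect(sig, rownames(x))
  if (length(shared) < 3)
    stop("fewer than 3 signature genes in the new cohort (missing: ",
         paste(utils::head(setdiff(sig, shared), 5), collapse = ", "), ")")
  if (length(shared) < length(sig))
    warning("dropping ", length(sig) - length(shared),
            " signature gene(s) absent from the new cohort")
  m <- unclass(x)[shared, , drop = FALSE]
  ctr <- rowMeans(m)
  scl <- apply(m, 1, stats::sd)
  if (any(scl == 0)) stop("constant signature gene(s) in the new cohort: ",
                          paste(shared[scl == 0], collapse = ", "))
  z <- (m - ctr) / scl
  proj <- t(z) %*% model$loadings[shared, , drop = FALSE]
  list(score = stats::setNames(proj[, 1] + proj[, 2], colnames(x)),
       pc1 = proj[, 1], pc2 = proj[, 2], genes_used = shared)
}

#' @export
print.mod_score <- function(x, ...) {
  cat(sprintf(paste0("<mod_score> %d samples, %d signature genes; ",
                     "PC1+PC2 explain %.1f%% variance; cut = %.3f (%s)\n"),
              length(x$score), nrow(x$loadings),
              100 * sum(x$explained), x$cutpoint, x$cut_method))
  invisible(x)
}
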