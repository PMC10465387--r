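#' Moderated two-group differential expression
#'
#' Per gene, a two-group comparison on log2 expression with empirical-Bayes
#' variance moderation: the pooled residual variance s_g^2 (d = n_a + n_b - 2
#' df) is shrunk towards a global prior, `s~_g^2 = (d0 s0^2 + d s_g^2) /
#' (d0 + d)`, with the prior df d0 and scale s0^2 estimated by a
#' method-of-moments fit to log s_g^2 across genes. The moderated t statistic
#' `dmean / (s~_g sqrt(1/n_a + 1/n_b))` is referred to a t distribution on
#' d0 + d df; p-values are BH-adjusted across genes.
#'
#' Genes with zero variance in both groups get p = 1 and a flag.
#'
#' @param x an [expression_matrix()] on the LOG2 scale.
#' @param labels per-sample group labels aligned with `colnames(x)`.
#' @param a,b the two labels to contrast (mean difference is a - b).
#' @param alpha adjusted-p cutoff used for the `deg` flag (default 0.001).
#' @param d0 optional forced prior df (0 recovers the ordinary pooled t,
#'   `Inf` the fully shrunk limit); `NULL` estimates it from the data.
#' @return data.frame (gene, mean_diff, s2, t, df, p, p_adj, deg,
#'   zero_variance) with attributes `d0` and `s0_sq`.
#' @export
moderated_pairwise <- function(x, labels, a, b, alpha = 0.001, d0 = NULL) {
  if (expr_unit(x) != "LOG2") stop("expression must be on the LOG2 scale")
  if (length(labels) != ncol(x)) stop("labels length must match samples")
  ia <- which(labels == a); ib <- which(labels == b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need >= 2 samples")
  m <- unclass(x)
  xa <- m[, ia, drop = FALSE]; xb <- m[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  mean_a <- rowMeans(xa); mean_b <- rowMeans(xb)
  va <- rowSums((xa - mean_a)^2) / (na - 1)
  vb <- rowSums((xb - mean_b)^2) / (nb - 1)
  d <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / d
  zerovar <- s2 <= 0

  fit <- fit_logvar_prior(s2[!zerovar], d, d0_override = d0)
  d0 <- fit$d0; s0_sq <- fit$s0_sq
  s2_tilde <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)

  diff <- mean_a - mean_b
  se <- sqrt(s2_tilde * (1 / na + 1 / nb))
  tstat <- diff / se
  dft <- d0 + d
  p <- if (is.infinite(dft)) 2 * stats::pnorm(-abs(tstat)) else
    2 * stats::pt(-abs(tstat), df = dft)
  tstat[zerovar & diff == 0] <- 0
  p[zerovar] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(m), mean_diff = diff, s2 = s2,
                    t = tstat, df = dft, p = p, p_adj = p_adj,
                    deg = p_adj < alpha, zero_variance = zerovar,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "contrast") <- c(a = as.character(a), b = as.character(b))
  out
}

# Method-of-moments fit of the scaled inverse-chi-square prior on gene
# variances, via the moments of log s^2 (Smyth-style): with
# z = log s^2, E z = log s0^2 + digamma(d/2) - log(d/2)
#               - (digamma(d0/2) - log(d0/2)),
# var z = trigamma(d/2) + trigamma(d0/2).
fit_logvar_prior <- function(s2, d, d0_override = NULL) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  if (!is.null(d0_override)) {
    d0 <- d0_override
  } else {
    t2 <- stats::var(e) - trigamma(d / 2)
    d0 <- if (is.na(t2) || t2 <= 0) Inf else 2 * trigamma_inverse(t2)
  }
  # d0 = Inf means no excess dispersion beyond chi-square sampling noise:
  # the prior scale is then just the average sample variance
  s0_sq <- if (is.infinite(d0)) mean(s2)
  else if (d0 == 0) exp(mean(e))
  else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x on y > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Intersect DEG lists across contrasts
#'
#' The Venn-overlap rule: genes flagged (adjusted p < alpha) in *every*
#' supplied contrast, sorted by gene id.
#'
#' @param results list of [moderated_pairwise()] results.
#' @param alpha adjusted-p cutoff (default 0.001).
#' @export
overlap_degs <- function(results, alpha = 0.001) {
  if (!length(results)) stop("empty contrast list")
  sets <- lapply(results, function(r) r$gene[r$p_adj < alpha])
  sort(Reduce(intersect, sets))
}

#' All pairwise cluster contrasts
#'
#' Runs [moderated_pairwise()] for every unordered pair of cluster labels.
#'
#' @export
pairwise_contrasts <- function(x, labels, alpha = 0.001) {
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- lapply(pairs, function(p)
    moderated_pairwise(x, labels, p[1], p[2], alpha = alpha))
  names(res) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  res
}
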