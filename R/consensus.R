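#' Parameters for resampling consensus clustering
#'
#' @param k_range candidate cluster numbers (integers >= 2).
#' @param reps number of resampling iterations.
#' @param p_item fraction of samples drawn (without replacement) per
#'   iteration.
#' @param distance sample-sample distance: `one_minus_pearson` (default) or
#'   `euclidean`.
#' @param linkage hierarchical linkage: `average` (default) or `ward`.
#' @param seed integer seed.
#' @export
consensus_params <- function(k_range = 2:9, reps = 100, p_item = 0.8,
                             distance = c("one_minus_pearson", "euclidean"),
                             linkage = c("average", "ward"),
                             seed = 1L) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (min(k_range) < 2) stop("min(k_range) must be >= 2")
  if (reps < 2 && !(reps == 1 && p_item == 1))
    stopifnot(reps >= 2)
  if (p_item <= 0 || p_item > 1) stop("p_item must be in (0, 1]")
  structure(list(k_range = as.integer(sort(unique(k_range))),
                 reps = as.integer(reps), p_item = p_item,
                 distance = distance, linkage = linkage,
                 seed = as.integer(seed)),
            class = "consensus_params")
}

# z-score each gene (row) across samples; constant rows dropped
zscore_rows <- function(x) {
  m <- unclass(x)
  sds <- apply(m, 1, stats::sd)
  keep <- is.finite(sds) & sds > 0
  m <- m[keep, , drop = FALSE]
  (m - rowMeans(m)) / sds[keep]
}

sample_dist <- function(z, distance) {
  if (distance == "one_minus_pearson") {
    stats::as.dist(1 - stats::cor(z))
  } else {
    stats::dist(t(z))
  }
}

hclust_method <- function(linkage) {
  if (linkage == "average") "average" else "ward.D2"
}

#' Build one consensus matrix
#'
#' For `reps` iterations, draw `ceiling(p_item * n)` samples without
#' replacement, cluster them hierarchically into `k` groups, and accumulate
#' co-clustering counts. The consensus entry for a pair is the fraction of
#' co-sampled iterations in which the pair landed in the same cluster; pairs
#' never co-sampled get 0 with a warning. Final labels come from
#' hierarchically clustering `1 - M`.
#'
#' @param x an [expression_matrix()] (genes x samples); features are
#'   z-scored across samples before distances.
#' @param k number of clusters.
#' @param params a [consensus_params()].
#' @return list with `M` (consensus matrix) and `labels`.
#' @export
build_consensus <- function(x, k, params = consensus_params()) {
  n <- ncol(x)
  if (k > n) stop("k exceeds the number of samples")
  if (n < 2 * k) stop("need at least 2k samples")
  z <- zscore_rows(x)
  set.seed(params$seed + k)  # per-k stream so each k is reproducible alone
  m_draw <- ceiling(params$p_item * n)
  I <- matrix(0, n, n)
  N <- matrix(0, n, n)
  meth <- hclust_method(params$linkage)
  for (r in seq_len(params$reps)) {
    for (try in 1:10) {
      idx <- sort(sample.int(n, m_draw))
      zi <- z[, idx, drop = FALSE]
      # need at least k distinct columns for a k-cut
      if (ncol(unique(t(zi))) >= k) break
      if (try == 10) stop("could not draw a resample with k distinct samples")
    }
    hc <- stats::hclust(sample_dist(zi, params$distance), method = meth)
    lab <- stats::cutree(hc, k = k)
    co <- outer(lab, lab, "==") * 1
    I[idx, idx] <- I[idx, idx] + co
    N[idx, idx] <- N[idx, idx] + 1
  }
  M <- matrix(0, n, n)
  seen <- N > 0
  M[seen] <- I[seen] / N[seen]
  if (any(!seen[upper.tri(seen)]))
    warning("pair(s) never co-sampled; consensus set to 0")
  diag(M) <- 1
  dimnames(M) <- list(colnames(x), colnames(x))
  hc_final <- stats::hclust(stats::as.dist(1 - M), method = meth)
  labels <- stats::cutree(hc_final, k = k)
  list(M = M, labels = labels)
}

#' Empirical CDF and area under it for a consensus matrix
#'
#' The CDF is taken over the upper-triangle entries; the area is the exact
#' integral of the right-continuous empirical CDF over [0, 1].
#'
#' @param M consensus matrix.
#' @return list with `cdf` (an [stats::ecdf()]) and `area`.
#' @export
cdf_and_area <- function(M) {
  if (nrow(M) < 2) stop("need at least 2 samples")
  vals <- M[upper.tri(M)]
  F <- stats::ecdf(vals)
  grid <- sort(unique(c(vals, 1)))
  prev <- c(0, utils::head(grid, -1))
  area <- sum((grid - prev) * F(prev))
  list(cdf = F, area = area)
}

#' Select the number of clusters from CDF areas
#'
#' The relative area change is `area(k_min)` at the smallest k and
#' `(area(k) - area(k-1)) / area(k-1)` afterwards; the chosen k is the
#' largest k whose relative change is at least `threshold`. `force_k`
#' overrides the rule.
#'
#' @param areas named numeric vector of CDF areas, names = k.
#' @param threshold relative-change threshold (default 0.10).
#' @param force_k optional manual override.
#' @return list with `chosen_k` and `delta_area`.
#' @export
select_k <- function(areas, threshold = 0.10, force_k = NULL) {
  if (!length(areas)) stop("empty areas")
  ks <- as.integer(names(areas))
  if (any(is.na(ks))) stop("areas must be named by k")
  o <- order(ks)
  ks <- ks[o]; areas <- areas[o]
  delta <- c(areas[1], diff(areas) / utils::head(areas, -1))
  names(delta) <- ks
  if (!is.null(force_k)) {
    if (!force_k %in% ks) stop("force_k outside k_range")
    return(list(chosen_k = as.integer(force_k), delta_area = delta,
                forced = TRUE))
  }
  ok <- which(delta >= threshold)
  chosen <- if (length(ok)) ks[max(ok)] else ks[1]
  list(chosen_k = as.integer(chosen), delta_area = delta, forced = FALSE)
}

#' Full consensus clustering run over a k range
#'
#' @inheritParams build_consensus
#' @param params a [consensus_params()].
#' @param threshold delta-area threshold passed to [select_k()].
#' @param force_k optional manual k override.
#' @return object of class `consensus_run`: per-k matrices, labels, areas,
#'   delta areas, `chosen_k` and the labels at the chosen k.
#' @export
consensus_cluster <- function(x, params = consensus_params(),
                              threshold = 0.10, force_k = NULL) {
  runs <- lapply(params$k_range, function(k) build_consensus(x, k, params))
  names(runs) <- params$k_range
  areas <- vapply(runs, function(r) cdf_and_area(r$M)$area, numeric(1))
  sel <- select_k(areas, threshold = threshold, force_k = force_k)
  structure(list(k_range = params$k_range,
                 matrices = lapply(runs, `[[`, "M"),
                 labels = lapply(runs, `[[`, "labels"),
                 areas = areas,
                 delta_area = sel$delta_area,
                 chosen_k = sel$chosen_k,
                 chosen_labels = runs[[as.character(sel$chosen_k)]]$labels,
                 params = params),
            class = "consensus_run")
}

#' @export
print.consensus_run <- function(x, ...) {
  cat(sprintf("<consensus_run> k in {%s}, chosen k = %d\n",
              paste(x$k_range, collapse = ","), x$chosen_k))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between partitions; 1 iff identical up to
#' relabeling, about 0 for independent labelings.
#'
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == maxi, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}
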