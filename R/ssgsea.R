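#' Single-sample gene-set enrichment scores
#'
#' Per sample, genes are ranked by expression (descending, ties broken by
#' gene id for determinism) and given absolute-rank weights
#' `r_i = n - rank + 1`. The enrichment score of a set S is the summed
#' difference between the weighted cumulative in-set fraction (weights
#' `r_i^alpha`, normalised over S) and the cumulative out-of-set fraction,
#' accumulated down the whole ranked list.
#'
#' Sets that match fewer than 2 genes of the matrix are dropped with a
#' warning; a set matching every gene is an error (no out-of-set genes).
#'
#' @param x an [expression_matrix()].
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param alpha rank-weight exponent (>= 0, default 0.25).
#' @return object of class `enrichment_result`: `scores` (set x sample
#'   matrix), `alpha`, `normalized` flag.
#' @export
ssgsea_scores <- function(x, sets, alpha = 0.25) {
  if (alpha < 0) stop("alpha must be >= 0")
  genes <- rownames(x)
  n <- length(genes)
  matched <- lapply(sets, intersect, genes)
  sizes <- lengths(matched)
  if (any(sizes == n))
    stop("gene set(s) covering every gene: ",
         paste(names(sets)[sizes == n], collapse = ", "))
  drop <- sizes < 2
  if (any(drop)) {
    warning("dropping gene set(s) with < 2 matched genes: ",
            paste(names(sets)[drop], collapse = ", "))
    matched <- matched[!drop]
  }
  if (!length(matched)) stop("no usable gene sets")

  scores <- matrix(NA_real_, length(matched), ncol(x),
                   dimnames = list(names(matched), colnames(x)))
  m <- unclass(x)
  for (s in seq_len(ncol(m))) {
    v <- m[, s]
    if (max(v) == min(v))
      stop("all-constant expression in sample ", colnames(m)[s])
    # stable order: value descending, gene id ascending on ties
    ord <- order(-v, genes, method = "radix")
    w <- (n - seq_len(n) + 1)^alpha   # absolute-rank weight at each position
    member_at <- genes[ord]
    for (g in seq_along(matched)) {
      ind <- member_at %in% matched[[g]]
      p_in <- cumsum(w * ind) / sum(w * ind)
      p_out <- cumsum(!ind) / (n - sum(ind))
      scores[g, s] <- sum(p_in - p_out)
    }
  }
  structure(list(scores = scores, alpha = alpha, normalized = FALSE),
            class = "enrichment_result")
}

#' Min-max normalise enrichment scores per set
#'
#' Maps each set's scores onto [0, 1]; constant rows map to 0 with a
#' warning. Idempotent.
#'
#' @param res an `enrichment_result`.
#' @export
minmax_normalize <- function(res) {
  sc <- res$scores
  if (ncol(sc) < 2) stop("need >= 2 samples")
  for (i in seq_len(nrow(sc))) {
    rng <- range(sc[i, ])
    if (rng[1] == rng[2]) {
      warning("constant enrichment row '", rownames(sc)[i], "' mapped to 0")
      sc[i, ] <- 0
    } else {
      sc[i, ] <- (sc[i, ] - rng[1]) / (rng[2] - rng[1])
    }
  }
  structure(list(scores = sc, alpha = res$alpha, normalized = TRUE),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d sets x %d samples (alpha = %g%s)\n",
              nrow(x$scores), ncol(x$scores), x$alpha,
              if (x$normalized) ", min-max normalized" else ""))
  invisible(x)
}
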