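#' Tumor mutation burden per sample
#'
#' Counts mutation rows per sample after an optional variant-class filter;
#' samples absent from the table get 0 with a flag, and samples are split
#' into high/low TMB at the median (ties to low).
#'
#' @param mutations MAF-lite data.frame (`sample_id`, `gene`,
#'   `variant_class`).
#' @param samples character vector of samples to profile.
#' @param class_filter variant classes counted (default: all present).
#' @param per_mb optional capture size in megabases; when supplied, `tmb`
#'   is the count divided by it.
#' @return data.frame (sample_id, tmb, no_mutation_data, tmb_group) with
#'   attribute `cutpoint`.
#' @export
compute_tmb <- function(mutations, samples, class_filter = NULL,
                        per_mb = NULL) {
  if (!length(samples)) stop("empty sample list")
  m <- mutations
  if (!is.null(class_filter)) m <- m[m$variant_class %in% class_filter, ]
  counts <- table(factor(m$sample_id, levels = samples))
  tmb <- as.numeric(counts)
  if (!is.null(per_mb)) tmb <- tmb / per_mb
  absent <- !samples %in% mutations$sample_id
  cut <- stats::median(tmb)
  out <- data.frame(sample_id = samples, tmb = tmb,
                    no_mutation_data = absent,
                    tmb_group = factor(ifelse(tmb > cut, "high", "low"),
                                       levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  attr(out, "cutpoint") <- cut
  out
}

#' Per-group mutation summary
#'
#' For each group: fraction of samples carrying at least one mutation, and
#' per-gene mutation frequencies ranked by recurrence, plus variant-class
#' tallies.
#'
#' @param mutations MAF-lite data.frame.
#' @param groups named factor/character assigning each sample to a group;
#'   names are the group's full sample list (so never-mutated samples count
#'   in the denominator).
#' @return list with `rates` (per-group mutated fraction) and `genes`
#'   (per-group gene frequency table) and `classes`.
#' @export
mutation_summary <- function(mutations, groups) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  lev <- unique(as.character(groups))
  if (any(table(groups) == 0)) stop("empty group")
  mutated <- unique(mutations$sample_id)
  rates <- vapply(lev, function(g) {
    ss <- names(groups)[groups == g]
    mean(ss %in% mutated)
  }, numeric(1))
  genes <- do.call(rbind, lapply(lev, function(g) {
    ss <- names(groups)[groups == g]
    mg <- mutations[mutations$sample_id %in% ss, ]
    freq <- sort(vapply(split(mg$sample_id, mg$gene),
                        function(s) length(unique(s)) / length(ss),
                        numeric(1)), decreasing = TRUE)
    if (!length(freq)) return(NULL)
    data.frame(group = g, gene = names(freq), freq = unname(freq),
               rank = seq_along(freq), stringsAsFactors = FALSE)
  }))
  classes <- do.call(rbind, lapply(lev, function(g) {
    ss <- names(groups)[groups == g]
    mg <- mutations[mutations$sample_id %in% ss, ]
    tab <- sort(table(mg$variant_class), decreasing = TRUE)
    if (!length(tab)) return(NULL)
    data.frame(group = g, variant_class = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  list(rates = rates, genes = genes, classes = classes)
}

#' Stratified Kaplan-Meier analysis over two binary factors
#'
#' Builds the four combination strata (empty ones dropped with a warning),
#' estimates a KM curve per stratum and tests the overall difference with a
#' log-rank test across strata.
#'
#' @param clinical clinical table (`sample_id`, `os_time`, `os_event`).
#' @param factor_a,factor_b named binary factors over the clinical samples.
#' @return list with `curves` (per-stratum [km_estimate()] output),
#'   `logrank`, `strata` (per-sample stratum labels).
#' @export
stratified_km <- function(clinical, factor_a, factor_b) {
  ids <- clinical$sample_id
  fa <- factor_a[ids]; fb <- factor_b[ids]
  if (any(is.na(fa)) || any(is.na(fb)))
    stop("factors must cover every clinical sample")
  if (nlevels(factor(fa)) != 2 || nlevels(factor(fb)) != 2)
    stop("both factors must be binary")
  strata <- interaction(fa, fb, sep = "/", drop = FALSE)
  empty <- levels(strata)[table(strata) == 0]
  if (length(empty)) {
    warning("dropping empty stratum(s): ", paste(empty, collapse = ", "))
    strata <- droplevels(strata)
  }
  if (nlevels(strata) < 2) stop("fewer than 2 non-empty strata")
  curves <- lapply(levels(strata), function(s) {
    sel <- strata == s
    km_estimate(clinical$os_time[sel], clinical$os_event[sel])
  })
  names(curves) <- levels(strata)
  lr <- logrank_test(clinical$os_time, clinical$os_event, strata)
  list(curves = curves, logrank = lr,
       strata = stats::setNames(strata, ids))
}

#' Group comparison by rank-sum, Kruskal-Wallis or chi-square
#'
#' Two groups of numeric values are compared with the Wilcoxon rank-sum
#' test (exact for small tie-free samples, normal approximation with
#' continuity and tie correction otherwise), three or more with
#' Kruskal-Wallis; categorical values against groups with a chi-square test
#' on the contingency table.
#'
#' @param values numeric (wilcoxon/kruskal) or categorical (chi2) vector.
#' @param groups group labels aligned with `values`.
#' @param test `"auto"` picks by the shape of the input.
#' @param name variable name carried into the result.
#' @return one-row data.frame (variable, test, n_groups, statistic, p).
#' @export
compare_groups <- function(values, groups,
                           test = c("auto", "wilcoxon", "kruskal", "chi2"),
                           name = "value") {
  test <- match.arg(test)
  g <- factor(groups)
  if (any(table(g) == 0) || nlevels(g) < 2)
    stop("every group needs >= 1 observation and >= 2 groups")
  if (test == "auto")
    test <- if (!is.numeric(values)) "chi2"
            else if (nlevels(g) == 2) "wilcoxon" else "kruskal"
  res <- switch(test,
    wilcoxon = {
      if (nlevels(g) != 2) stop("wilcoxon needs exactly 2 groups")
      ht <- stats::wilcox.test(values ~ g)
      c(ht$statistic, ht$p.value)
    },
    kruskal = {
      ht <- stats::kruskal.test(values, g)
      c(ht$statistic, ht$p.value)
    },
    chi2 = {
      tab <- table(values, g)
      ht <- suppressWarnings(stats::chisq.test(tab))
      c(ht$statistic, ht$p.value)
    })
  data.frame(variable = name, test = test, n_groups = nlevels(g),
             statistic = unname(res[1]), p = unname(res[2]),
             stringsAsFactors = FALSE)
}

#' Spearman correlation between score and immune enrichment
#'
#' Per gene set, Spearman's rho between the per-sample score and the set's
#' enrichment scores, with BH adjustment across sets.
#'
#' @param scores named per-sample scores.
#' @param enrichment an `enrichment_result` (sets x samples).
#' @return data.frame (set, rho, p, p_adj).
#' @export
score_immune_correlation <- function(scores, enrichment) {
  sc <- enrichment$scores
  shared <- intersect(names(scores), colnames(sc))
  if (length(shared) < 5) stop("need >= 5 paired samples")
  if (stats::sd(scores[shared]) == 0) stop("constant score vector")
  res <- do.call(rbind, lapply(rownames(sc), function(s) {
    ct <- suppressWarnings(
      stats::cor.test(scores[shared], sc[s, shared], method = "spearman"))
    data.frame(set = s, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Hypergeometric over-representation of annotation sets
#'
#' For each annotation set (intersected with the universe), the upper-tail
#' probability of observing at least the seen overlap with the hit list,
#' BH-adjusted across sets.
#'
#' @param hit_genes genes of interest (must lie in `universe`).
#' @param annotation named list of gene sets.
#' @param universe background gene ids.
#' @return data.frame (set, overlap, set_size, n_hits, universe_size, p,
#'   p_adj), sorted by p.
#' @export
ora_hypergeometric <- function(hit_genes, annotation, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(hit_genes)) stop("empty hit list")
  universe <- unique(universe)
  bad <- setdiff(hit_genes, universe)
  if (length(bad)) stop("hit gene(s) outside the universe: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  hit_genes <- unique(hit_genes)
  N <- length(universe); n <- length(hit_genes)
  res <- do.call(rbind, lapply(names(annotation), function(s) {
    set <- intersect(annotation[[s]], universe)
    k <- length(intersect(set, hit_genes))
    p <- stats::phyper(k - 1, length(set), N - length(set), n,
                       lower.tail = FALSE)
    data.frame(set = s, overlap = k, set_size = length(set), n_hits = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}

#' Relative expression by the 2^-ddCt rule
#'
#' `ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl)`;
#' fold change `2^-ddCt`.
#'
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
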