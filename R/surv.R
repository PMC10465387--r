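#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times.
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame (time, n_risk, n_event, n_censor, surv) of class
#'   `surv_curve`; one row per distinct observed time.
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("surv_curve", "data.frame")
  out
}

check_surv_input <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(!is.finite(times)) || any(times <= 0)) stop("times must be > 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  invisible(TRUE)
}

#' Log-rank (Mantel-Haenszel) test across groups
#'
#' @return list (chi2, df, p, n_groups); with no events at all, p = 1 with a
#'   warning.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (sum(events) == 0) {
    warning("no events; log-rank p set to 1")
    return(list(chi2 = 0, df = nlevels(g) - 1L, p = 1,
                n_groups = nlevels(g)))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n_groups = nlevels(g))
}

#' Univariate Cox proportional-hazards regression
#'
#' Efron tie handling by default (Breslow available for cross-checks).
#' A constant covariate returns beta = 0, p = 1 with a flag; monotone
#' likelihood (perfect separation) warnings flag the fit as not converged.
#'
#' @param x covariate values.
#' @param times,events survival outcome.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return one-row data.frame (covariate, beta, hr, se, z, p, converged,
#'   iterations, flag).
#' @export
cox_univariate <- function(x, times, events, ties = c("efron", "breslow"),
                           name = "x") {
  ties <- match.arg(ties)
  check_surv_input(times, events)
  if (length(x) != length(times)) stop("covariate length mismatch")
  if (any(!is.finite(x))) stop("covariate must be finite")
  if (sum(events) < 1) stop("need >= 1 event")
  if (stats::sd(x) == 0) {
    return(data.frame(covariate = name, beta = 0, hr = 1, se = NA_real_,
                      z = NA_real_, p = 1, converged = TRUE, iterations = 0L,
                      flag = "constant_covariate", stringsAsFactors = FALSE))
  }
  flag <- ""
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        flag <<- "monotone_likelihood"
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  data.frame(covariate = name,
             beta = unname(stats::coef(fit)),
             hr = unname(exp(stats::coef(fit))),
             se = unname(s$coefficients[, "se(coef)"]),
             z = unname(s$coefficients[, "z"]),
             p = unname(s$coefficients[, "Pr(>|z|)"]),
             converged = flag == "",
             iterations = fit$iter,
             flag = flag, stringsAsFactors = FALSE)
}

#' Univariate Cox screen of candidate prognostic genes
#'
#' Fits a univariate Cox model per gene on its (LOG2) expression and keeps
#' genes with raw p below the threshold.
#'
#' @param x an [expression_matrix()].
#' @param clinical clinical table with `sample_id`, `os_time`, `os_event`.
#' @param genes candidate genes (must be rows of `x`).
#' @param p_threshold raw-p cutoff (default 0.05).
#' @return list with `genes` (passing gene ids) and `table` (per-gene Cox
#'   results).
#' @export
prognostic_filter <- function(x, clinical, genes, p_threshold = 0.05) {
  if (!length(genes)) stop("empty candidate gene list")
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("gene(s) absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must be in (0, 1]")
  idx <- match(clinical$sample_id, colnames(x))
  if (any(is.na(idx))) stop("clinical samples missing from matrix")
  m <- unclass(x)[, idx, drop = FALSE]
  tab <- do.call(rbind, lapply(genes, function(g)
    cox_univariate(m[g, ], clinical$os_time, clinical$os_event, name = g)))
  list(genes = tab$covariate[tab$p < p_threshold & tab$flag == ""],
       table = tab)
}
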