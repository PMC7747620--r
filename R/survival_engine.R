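#' Median stratification of a per-sample expression vector
#'
#' Splits samples at the cohort median (type-7 quantile, the usual
#' midpoint-of-order-statistics convention).  A sample is labelled `high`
#' iff its value is strictly above the median; ties at the median go to
#' `low`, which guarantees `n_low >= n_high` and determinism.
#'
#' @param values Numeric vector of expression values, one per sample;
#'   names are used as sample ids when present.
#' @param sample_ids Optional explicit sample ids.
#' @return An object of class `"stratification"`: list with `labels`
#'   (factor with levels high/low/mixed/excluded), `threshold`, `n_high`,
#'   `n_low`.
#' @export
median_stratify <- function(values, sample_ids = names(values)) {
  if (length(values) < 4L) stop("median_stratify needs >= 4 samples")
  if (any(!is.finite(values))) stop("non-finite expression value")
  med <- stats::median(values)
  if (all(values == values[1L]))
    stop("degenerate stratification: constant expression vector")
  lab <- ifelse(values > med, "high", "low")
  new_stratification(lab, sample_ids, threshold = med)
}

new_stratification <- function(lab, sample_ids, threshold) {
  labels <- factor(lab, levels = c("high", "low", "mixed", "excluded"))
  if (!is.null(sample_ids)) names(labels) <- sample_ids
  structure(list(labels = labels,
                 threshold = threshold,
                 n_high = sum(labels == "high"),
                 n_low = sum(labels == "low")),
            class = "stratification")
}

#' Combine per-miRNA stratifications into all-high / all-low groups
#'
#' A sample is `high` iff it is high for every miRNA in the combination and
#' `low` iff low for every one; all other samples are `mixed` and excluded
#' from downstream survival comparisons.  For a single stratification this
#' is the identity.
#'
#' @param strat_list List of `"stratification"` objects over identical
#'   samples (e.g. from [median_stratify()] applied to each miRNA).
#' @return A `"stratification"`; attribute `degenerate` is `TRUE` when one
#'   of the two groups is empty (the caller decides how to treat it).
#' @export
combo_stratify <- function(strat_list) {
  if (!length(strat_list)) stop("empty combination")
  labs <- lapply(strat_list, function(s) as.character(s$labels))
  n <- length(labs[[1L]])
  if (any(vapply(labs, length, 1L) != n))
    stop("stratifications cover different sample sets")
  ids <- names(strat_list[[1L]]$labels)
  all_high <- Reduce(`&`, lapply(labs, function(l) l == "high"))
  all_low <- Reduce(`&`, lapply(labs, function(l) l == "low"))
  lab <- ifelse(all_high, "high", ifelse(all_low, "low", "mixed"))
  out <- new_stratification(lab, ids,
                            threshold = vapply(strat_list, `[[`, 0,
                                               "threshold"))
  attr(out, "degenerate") <- out$n_high == 0L || out$n_low == 0L
  out
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("Stratification: %d high / %d low / %d mixed (threshold%s %s)\n",
              x$n_high, x$n_low, sum(x$labels == "mixed"),
              if (length(x$threshold) > 1L) "s" else "",
              paste(signif(x$threshold, 4), collapse = ", ")))
  invisible(x)
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (0 = right-censored).
#' @param mask Optional logical vector selecting the subjects to use.
#' @return Object of class `"km_curve"`: data.frame with one row per
#'   distinct observed time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`).
#' @export
km_curve <- function(time, event, mask = NULL) {
  if (!is.null(mask)) {
    time <- time[mask]
    event <- event[mask]
  }
  n <- length(time)
  if (n == 0L) stop("km_curve: no subjects")
  stopifnot(length(event) == n, all(event %in% c(0, 1)), all(time > 0))
  ut <- sort(unique(time))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), 0)
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_curve", "data.frame"), n = n)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, %d distinct times\n",
              attr(x, "n"), sum(x$n_event), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Plot a Kaplan-Meier curve (or a list of curves) as step functions
#' @param x `"km_curve"` object or a named list of them.
#' @param col Line colours.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.km_curve <- function(x, col = "black", ...) {
  plot_km_list(list(x), col = col, ...)
}

#' @rdname plot.km_curve
#' @param curves Named list of `"km_curve"` objects.
#' @export
plot_km_list <- function(curves, col = seq_along(curves), ...) {
  xmax <- max(vapply(curves, function(k) max(k$time), 0))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "Time", ylab = "Survival probability", ...)
  for (i in seq_along(curves)) {
    k <- curves[[i]]
    graphics::lines(stats::stepfun(k$time, c(1, k$surv)), do.points = FALSE,
                    col = col[i])
    cens <- k$time[k$n_censor > 0]
    if (length(cens)) {
      s <- stats::stepfun(k$time, c(1, k$surv))(cens)
      graphics::points(cens, s, pch = 3, col = col[i])
    }
  }
  if (!is.null(names(curves)))
    graphics::legend("topright", legend = names(curves), col = col, lty = 1,
                     bty = "n")
  invisible(curves)
}

# Per-distinct-event-time risk/event sums shared by the log-rank test and
# the Cox fit.  z is the 0/1 group indicator (1 = high).
event_time_tables <- function(time, event, z) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; z <- z[ord]
  et <- unique(time[event == 1])
  if (!length(et)) stop("no information: no events observed")
  # subjects at risk at t: time >= t.  With times sorted ascending,
  # cumulative sums from the end give the risk-set sums.
  idx <- findInterval(et, time, left.open = TRUE) + 1L  # first index with time >= et
  rc_n <- rev(cumsum(rev(rep(1, length(time)))))
  rc_z <- rev(cumsum(rev(z)))
  N <- rc_n[idx]
  N1 <- rc_z[idx]
  d <- vapply(et, function(t) sum(time == t & event == 1), 0)
  d1 <- vapply(et, function(t) sum(time == t & event == 1 & z == 1), 0)
  list(et = et, N = N, N1 = N1, d = d, d1 = d1,
       time = time, event = event, z = z)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic: observed minus expected events in one
#' group summed over distinct event times, with hypergeometric variance.
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @param group Two-level grouping (factor, character or 0/1); subjects with
#'   `NA` group are excluded.
#' @return List with `chi2`, `p`, `observed`, `expected` (for the first
#'   group level), `n` per group and `n_events`.
#' @export
logrank_test <- function(time, event, group) {
  keep <- !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- group[keep]
  g <- factor(group)
  if (nlevels(g) != 2L) stop("logrank_test needs exactly two non-empty groups")
  z <- as.integer(g == levels(g)[1L])
  tab <- event_time_tables(time, event, z)
  O <- sum(tab$d1)
  E <- sum(tab$d * tab$N1 / tab$N)
  ok <- tab$N > 1
  V <- sum((tab$d * (tab$N1 / tab$N) * (1 - tab$N1 / tab$N) *
              (tab$N - tab$d) / (tab$N - 1))[ok])
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, observed = O, expected = E, var = V,
       n = table(g), n_events = sum(event))
}

# Efron-corrected partial log-likelihood, gradient and hessian for a single
# binary covariate, evaluated at beta.  tab comes from event_time_tables().
cox_efron_derivs <- function(beta, tab) {
  w1 <- exp(beta)                       # risk weight for z = 1
  S0 <- tab$N1 * w1 + (tab$N - tab$N1)  # sum over risk set of exp(beta z)
  S1 <- tab$N1 * w1                     # sum of z exp(beta z); S2 == S1
  D0 <- tab$d1 * w1 + (tab$d - tab$d1)  # same sums over tied events
  D1 <- tab$d1 * w1
  # expand l = 0 .. d_t - 1 per event time
  j <- rep(seq_along(tab$et), tab$d)
  l <- sequence(tab$d) - 1
  frac <- l / tab$d[j]
  phi <- S0[j] - frac * D0[j]
  eta <- S1[j] - frac * D1[j]
  loglik <- beta * sum(tab$d1) - sum(log(phi))
  grad <- sum(tab$d1) - sum(eta / phi)
  hess <- -sum(eta / phi - (eta / phi)^2)  # S2==S1, ed2==ed1 for binary z
  list(loglik = loglik, grad = grad, hess = hess)
}

#' Cox proportional-hazards fit for a binary group indicator
#'
#' Maximizes the Cox partial likelihood with the Efron correction for tied
#' event times by Newton-Raphson (convergence `|delta beta| < 1e-8`, max 100
#' iterations).  The hazard ratio is reported with the `high` group in the
#' numerator and `low` as reference.  A monotone likelihood (all events in
#' one group before any in the other) is reported as a divergent fit with
#' `|beta|` capped at 15 and `monotone = TRUE`, not as an error.  Log-rank
#' fields are filled by [logrank_test()] on the same subjects.
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @param group Grouping with levels `"high"`/`"low"` (or any two-level
#'   factor whose first level is treated as `high`); `NA` excluded.
#' @return Object of class `"cox_binary"`: list with `beta`, `hr`, `se_beta`,
#'   `z`, `p_wald`, `logrank_chi2`, `logrank_p`, `n_high`, `n_low`,
#'   `n_events`, `iterations`, `converged`, `monotone`, `loglik`.
#' @export
cox_binary_fit <- function(time, event, group) {
  keep <- !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- as.character(group)[keep]
  lev <- if (all(group %in% c("high", "low"))) c("high", "low")
         else levels(factor(group))
  g <- factor(group, levels = lev)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("cox_binary_fit needs two non-empty groups")
  if (sum(event) < 1L) stop("no information: no events observed")
  z <- as.integer(g == lev[1L])
  tab <- event_time_tables(time, event, z)

  beta <- 0; converged <- FALSE; monotone <- FALSE
  cap <- 15
  d <- cox_efron_derivs(beta, tab)
  for (it in seq_len(100L)) {
    if (d$hess >= 0) break  # flat likelihood (no usable contrast)
    step <- -d$grad / d$hess
    if (!is.finite(step)) break
    step <- max(min(step, 5), -5)  # damp huge first steps
    beta_new <- beta + step
    d_new <- cox_efron_derivs(beta_new, tab)
    halvings <- 0L
    while (d_new$loglik < d$loglik - 1e-12 && halvings < 20L) {
      step <- step / 2
      beta_new <- beta + step
      d_new <- cox_efron_derivs(beta_new, tab)
      halvings <- halvings + 1L
    }
    beta <- beta_new; d <- d_new
    if (abs(beta) > cap) {
      beta <- sign(beta) * cap
      d <- cox_efron_derivs(beta, tab)
      monotone <- TRUE
      break
    }
    if (abs(step) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  se <- if (d$hess < 0) sqrt(-1 / d$hess) else NA_real_
  lr <- logrank_test(time, event, g)
  zstat <- if (is.finite(se)) beta / se else NA_real_
  structure(list(beta = beta, hr = exp(beta), se_beta = se, z = zstat,
                 p_wald = if (is.finite(zstat))
                   2 * stats::pnorm(-abs(zstat)) else NA_real_,
                 logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 n_high = sum(z == 1L), n_low = sum(z == 0L),
                 n_events = sum(event), iterations = it,
                 converged = converged, monotone = monotone,
                 loglik = d$loglik),
            class = "cox_binary")
}

#' @export
print.cox_binary <- function(x, ...) {
  cat("Cox proportional-hazards fit (binary group, Efron ties)\n")
  cat(sprintf("  n_high = %d, n_low = %d, events = %d\n",
              x$n_high, x$n_low, x$n_events))
  cat(sprintf("  beta = %.4f (se %.4f), HR = %.3f\n", x$beta, x$se_beta, x$hr))
  cat(sprintf("  log-rank chi2 = %.3f, p = %.3g\n", x$logrank_chi2,
              x$logrank_p))
  if (x$monotone)
    cat("  WARNING: monotone likelihood, |beta| capped at 15\n")
  invisible(x)
}

#' @export
coef.cox_binary <- function(object, ...) c(beta = object$beta)

#' @export
summary.cox_binary <- function(object, conf.level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  data.frame(beta = object$beta, hr = object$hr, se_beta = object$se_beta,
             hr_lower = exp(object$beta - q * object$se_beta),
             hr_upper = exp(object$beta + q * object$se_beta),
             logrank_chi2 = object$logrank_chi2,
             logrank_p = object$logrank_p,
             n_high = object$n_high, n_low = object$n_low,
             n_events = object$n_events)
}

# One median-split survival comparison of a single feature vector against
# (time, event): the workhorse of both the miRNA screen and the target-gene
# survival criterion.  Returns NULL on degenerate stratification.
feature_survival <- function(values, time, event) {
  strat <- tryCatch(median_stratify(values), error = function(e) NULL)
  if (is.null(strat)) return(NULL)
  survival_from_strat(strat, time, event)
}

survival_from_strat <- function(strat, time, event) {
  lab <- as.character(strat$labels)
  use <- lab %in% c("high", "low")
  if (strat$n_high == 0L || strat$n_low == 0L) return(NULL)
  if (sum(event[use]) == 0L) return(NULL)
  g <- factor(lab[use], levels = c("high", "low"))
  tryCatch(cox_binary_fit(time[use], event[use], g), error = function(e) NULL)
}
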