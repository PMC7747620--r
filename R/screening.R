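#' Screening configuration
#'
#' Thresholds of the three-stage discovery cascade.  Defaults follow the
#' published screen: log-rank p < 0.05, HR > 1 (strict), mean RPM > 1, and
#' a pair counts as synergistic when its all-high vs all-low HR exceeds
#' 1.5 times each member's single-miRNA HR.  `min_group_size` guards
#' against inflated hazard ratios from tiny all-high/all-low groups.
#' No multiple-testing correction is applied by default, matching the raw
#' log-rank thresholds of the original screen; set `bh_correct = TRUE` to
#' apply Benjamini-Hochberg within the single-miRNA screen.
#'
#' @param p_threshold Log-rank significance threshold.
#' @param hr_threshold Hazard-ratio threshold (strict) for the oncomiR
#'   screen and combination selection.
#' @param rpm_threshold Minimum mean expression (RPM) for a miRNA to enter
#'   the screen.
#' @param synergy_fold Pair-vs-single HR fold requirement (strict).
#' @param max_combo_size Largest combination size searched; `NULL` = all.
#' @param min_group_size Minimum size of each of the all-high and all-low
#'   groups for a combination to qualify in [select_best()].
#' @param bh_correct Apply BH adjustment to the oncomiR screen p-values.
#' @param seed Optional integer recorded in run manifests.
#' @return List of class `"screen_config"`.
#' @export
screen_config <- function(p_threshold = 0.05, hr_threshold = 1,
                          rpm_threshold = 1, synergy_fold = 1.5,
                          max_combo_size = NULL, min_group_size = 10,
                          bh_correct = FALSE, seed = NULL) {
  stopifnot(p_threshold > 0, hr_threshold > 0, rpm_threshold > 0,
            synergy_fold > 1, min_group_size >= 0)
  structure(list(p_threshold = p_threshold, hr_threshold = hr_threshold,
                 rpm_threshold = rpm_threshold, synergy_fold = synergy_fold,
                 max_combo_size = max_combo_size,
                 min_group_size = min_group_size, bh_correct = bh_correct,
                 seed = seed),
            class = "screen_config")
}

#' Single-miRNA oncomiR screen
#'
#' For every miRNA row: median-stratify the cohort, run the log-rank test
#' and the binary Cox fit, and flag the miRNA as a passing oncomiR when
#' mean expression > `rpm_threshold`, log-rank p < `p_threshold` and
#' HR > `hr_threshold` (high expression = worse outcome).  Per-miRNA
#' failures (degenerate stratification, no events) are recorded as
#' non-passing with a reason rather than raised.
#'
#' @param expr_mirna miRNA expression matrix (RPM), features x samples,
#'   sample-aligned with `clinical`.
#' @param clinical Clinical data frame (`sample_id`, `time`, `event`).
#' @param config A [screen_config()].
#' @return Data frame of class `"oncomir_screen"`, one row per miRNA with
#'   `mirna_id`, `mean_rpm`, `beta`, `hr`, `logrank_chi2`, `logrank_p`,
#'   `n_high`, `n_low`, `n_events`, `passes`, `reason`; passing rows first,
#'   sorted by p ascending.
#' @export
screen_oncomirs <- function(expr_mirna, clinical, config = screen_config()) {
  check_aligned(expr_mirna, clinical)
  if (ncol(expr_mirna) < 4L) stop("screen needs >= 4 samples")
  time <- clinical$time; event <- clinical$event
  rows <- lapply(rownames(expr_mirna), function(m) {
    v <- expr_mirna[m, ]
    rec <- data.frame(mirna_id = m, mean_rpm = mean(v), beta = NA_real_,
                      hr = NA_real_, logrank_chi2 = NA_real_,
                      logrank_p = NA_real_, n_high = NA_integer_,
                      n_low = NA_integer_, n_events = NA_integer_,
                      passes = FALSE, reason = "", stringsAsFactors = FALSE)
    if (rec$mean_rpm <= config$rpm_threshold) {
      rec$reason <- "low expression"
      return(rec)
    }
    fit <- feature_survival(v, time, event)
    if (is.null(fit)) {
      rec$reason <- "degenerate stratification"
      return(rec)
    }
    rec$beta <- fit$beta; rec$hr <- fit$hr
    rec$logrank_chi2 <- fit$logrank_chi2; rec$logrank_p <- fit$logrank_p
    rec$n_high <- fit$n_high; rec$n_low <- fit$n_low
    rec$n_events <- fit$n_events
    rec
  })
  out <- do.call(rbind, rows)
  p_use <- if (config$bh_correct) bh_adjust_na(out$logrank_p) else out$logrank_p
  ok <- !is.na(out$hr)
  out$passes <- ok & p_use < config$p_threshold & out$hr > config$hr_threshold
  out$reason[ok & !out$passes & out$reason == ""] <- "not significant"
  out <- out[order(!out$passes, out$logrank_p, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("oncomir_screen", "data.frame")
  out
}

bh_adjust_na <- function(p) {
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  adj
}

check_aligned <- function(expr, clinical) {
  if (ncol(expr) != nrow(clinical) ||
      !all(colnames(expr) == clinical$sample_id))
    stop("expression and clinical tables are not sample-aligned; ",
         "run align_samples() first")
  invisible(TRUE)
}

#' Apply the synergy pass rule to hazard-ratio summaries
#'
#' The pair criterion, exposed separately (and vectorized) so hazard ratios
#' printed in published screens can be checked through the same code path
#' used on fresh data: the pair HR must strictly exceed `synergy_fold`
#' times each single-miRNA HR, with pair log-rank p below `p_threshold`.
#'
#' @param pair_hr All-high vs all-low hazard ratio of the pair.
#' @param hr_a,hr_b Single-miRNA hazard ratios of the two members.
#' @param pair_p Log-rank p-value of the pair comparison.
#' @param config A [screen_config()].
#' @return Logical vector.
#' @export
synergy_passes <- function(pair_hr, hr_a, hr_b, pair_p,
                           config = screen_config()) {
  !is.na(pair_hr) & !is.na(hr_a) & !is.na(hr_b) & !is.na(pair_p) &
    pair_hr > config$synergy_fold * hr_a &
    pair_hr > config$synergy_fold * hr_b &
    pair_p < config$p_threshold
}

#' Pairwise synergy screen
#'
#' Evaluates every unordered pair of passing oncomiRs: patients high for
#' both miRNAs form the all-high group, low for both the all-low group
#' (mixed patients are excluded), and the pair passes when its all-high vs
#' all-low HR strictly exceeds `synergy_fold` times each member's
#' single-miRNA HR with log-rank p below `p_threshold`.
#'
#' @param mirna_ids Character vector of candidate miRNA ids (typically the
#'   passing set of [screen_oncomirs()]).
#' @param expr_mirna Aligned miRNA expression matrix.
#' @param clinical Aligned clinical data frame.
#' @param config A [screen_config()].
#' @return Data frame of class `"synergy_screen"`, one row per pair:
#'   `mirna_a`, `mirna_b`, `pair_p`, `pair_hr`, `hr_a`, `hr_b`, `n_high`,
#'   `n_low`, `passes`, `degenerate`, `reason`.
#' @export
synergy_screen <- function(mirna_ids, expr_mirna, clinical,
                           config = screen_config()) {
  check_aligned(expr_mirna, clinical)
  mirna_ids <- sort(unique(mirna_ids))
  if (length(mirna_ids) < 2L) stop("synergy screen needs >= 2 miRNAs")
  missing <- setdiff(mirna_ids, rownames(expr_mirna))
  if (length(missing)) stop("miRNA not in expression matrix: ", missing[1L])
  time <- clinical$time; event <- clinical$event
  strats <- lapply(mirna_ids, function(m) median_stratify(expr_mirna[m, ]))
  names(strats) <- mirna_ids
  singles <- vapply(mirna_ids, function(m) {
    fit <- survival_from_strat(strats[[m]], time, event)
    if (is.null(fit)) NA_real_ else fit$hr
  }, 0)
  pairs <- utils::combn(mirna_ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    strat <- combo_stratify(strats[c(a, b)])
    rec <- data.frame(mirna_a = a, mirna_b = b, pair_p = NA_real_,
                      pair_hr = NA_real_, hr_a = singles[[a]],
                      hr_b = singles[[b]], n_high = strat$n_high,
                      n_low = strat$n_low, passes = FALSE,
                      degenerate = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    if (isTRUE(attr(strat, "degenerate")) ||
        min(strat$n_high, strat$n_low) < config$min_group_size) {
      rec$degenerate <- TRUE
      rec$reason <- "degenerate groups"
      return(rec)
    }
    fit <- survival_from_strat(strat, time, event)
    if (is.null(fit)) {
      rec$degenerate <- TRUE
      rec$reason <- "no events in groups"
      return(rec)
    }
    rec$pair_p <- fit$logrank_p
    rec$pair_hr <- fit$hr
    rec
  })
  out <- do.call(rbind, rows)
  out$passes <- synergy_passes(out$pair_hr, out$hr_a, out$hr_b, out$pair_p,
                               config)
  out$reason[!out$passes & !out$degenerate] <- "fails synergy criterion"
  out <- out[order(!out$passes, out$pair_p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("synergy_screen", "data.frame")
  out
}

#' Exhaustive additive combination search
#'
#' Evaluates every non-empty subset of the selected miRNAs (up to
#' `max_combo_size`) by comparing the patients above the median for every
#' member (all-high) against those below for every member (all-low).
#' Degenerate combinations (empty or undersized groups) are flagged but
#' retained so the HR-vs-size distribution can be plotted with or without
#' them.
#'
#' @param mirna_ids miRNA candidates, typically the union of miRNAs over
#'   passing synergy pairs.
#' @param expr_mirna Aligned miRNA expression matrix.
#' @param clinical Aligned clinical data frame.
#' @param config A [screen_config()].
#' @return Data frame of class `"combo_search"`, one row per subset:
#'   `combo_id` (member ids joined by `+`), `k`, `beta`, `hr`, `log2_hr`,
#'   `logrank_chi2`, `logrank_p`, `n_high`, `n_low`, `degenerate`.
#' @export
additive_search <- function(mirna_ids, expr_mirna, clinical,
                            config = screen_config()) {
  check_aligned(expr_mirna, clinical)
  mirna_ids <- sort(unique(mirna_ids))
  if (length(mirna_ids) > 25L)
    stop(length(mirna_ids), " candidate miRNAs would mean 2^",
         length(mirna_ids), " subsets; set max_combo_size or shrink the set")
  kmax <- min(length(mirna_ids),
              if (is.null(config$max_combo_size)) length(mirna_ids)
              else config$max_combo_size)
  time <- clinical$time; event <- clinical$event
  strats <- lapply(mirna_ids, function(m) median_stratify(expr_mirna[m, ]))
  names(strats) <- mirna_ids
  rows <- list()
  for (k in seq_len(kmax)) {
    subsets <- utils::combn(mirna_ids, k, simplify = FALSE)
    for (s in subsets) {
      strat <- combo_stratify(strats[s])
      rec <- data.frame(combo_id = paste(s, collapse = "+"), k = k,
                        beta = NA_real_, hr = NA_real_, log2_hr = NA_real_,
                        logrank_chi2 = NA_real_, logrank_p = NA_real_,
                        n_high = strat$n_high, n_low = strat$n_low,
                        degenerate = FALSE, stringsAsFactors = FALSE)
      fit <- if (isTRUE(attr(strat, "degenerate"))) NULL
             else survival_from_strat(strat, time, event)
      if (is.null(fit)) {
        rec$degenerate <- TRUE
      } else {
        rec$beta <- fit$beta; rec$hr <- fit$hr
        rec$log2_hr <- log2(fit$hr)
        rec$logrank_chi2 <- fit$logrank_chi2
        rec$logrank_p <- fit$logrank_p
        rec$degenerate <- fit$monotone
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("combo_search", "data.frame")
  out
}

#' Boxplot of combination hazard ratios by combination size
#'
#' The additive-effect view: log2 hazard ratio of every non-degenerate
#' combination, grouped by the number of miRNAs combined.
#'
#' @param x A `"combo_search"` data frame.
#' @param highlight Optional `combo_id` drawn as a filled point.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.combo_search <- function(x, highlight = NULL, ...) {
  ok <- !x$degenerate & is.finite(x$log2_hr)
  graphics::boxplot(log2_hr ~ k, data = x[ok, , drop = FALSE],
                    xlab = "miRNAs combined", ylab = "log2 hazard ratio", ...)
  graphics::stripchart(log2_hr ~ k, data = x[ok, , drop = FALSE],
                       vertical = TRUE, add = TRUE, pch = 1, method = "jitter")
  if (!is.null(highlight)) {
    h <- x[x$combo_id == highlight, , drop = FALSE]
    if (nrow(h)) graphics::points(h$k, h$log2_hr, pch = 19, col = "red",
                                  cex = 1.4)
  }
  invisible(x)
}

#' Select the best qualifying combination
#'
#' Among non-degenerate combinations with log-rank p < `p_threshold`,
#' HR > `hr_threshold` and both groups at least `min_group_size`, returns
#' the maximum-HR combination; ties broken by smaller p, then smaller size,
#' then lexicographic combination id.
#'
#' @param combos A `"combo_search"` data frame.
#' @param config A [screen_config()].
#' @return One-row data frame, or a zero-row data frame with attribute
#'   `report` when nothing qualifies.
#' @export
select_best <- function(combos, config = screen_config()) {
  if (!nrow(combos)) stop("select_best: no combinations supplied")
  ok <- !combos$degenerate & !is.na(combos$hr) &
    combos$logrank_p < config$p_threshold & combos$hr > config$hr_threshold &
    pmin(combos$n_high, combos$n_low) >= config$min_group_size
  q <- combos[ok, , drop = FALSE]
  if (!nrow(q)) {
    out <- combos[0L, , drop = FALSE]
    attr(out, "report") <- "no significant combination"
    return(out)
  }
  ord <- order(-q$hr, q$logrank_p, q$k, q$combo_id)
  out <- q[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}
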