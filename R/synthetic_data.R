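#' Configuration of the synthetic TCGA-like cohort
#'
#' Describes a cohort generator with known ground truth: per-feature
#' log-normal miRNA expression; right-censored survival whose hazard is
#' proportional, with log-hazard `sum_j beta_j z_j + sum_jk gamma_jk z_j z_k`
#' where `z_j = 1` iff the patient is above the population median of
#' miRNA j; target genes log-linearly anti-correlated with their regulator
#' miRNA; and gene sets enriched in the true targets.  Defaults emulate the
#' cervical-carcinoma screening setting: ~300 patients, 200 miRNAs of which
#' three are planted prognostic oncomiRs with pairwise synergy, exponential
#' baseline hazard 1/1500 per day and ~70% right-censoring.
#'
#' @param n_patients,n_mirnas,n_genes Cohort dimensions.
#' @param baseline_hazard Baseline hazard per day.
#' @param weibull_shape Shape of the baseline hazard; 1 = exponential.
#' @param main_effects Named numeric: per-planted-miRNA log hazard ratio of
#'   high vs low status.
#' @param interaction_effects Named numeric: pairwise log-hazard
#'   interactions, names `"miRa+miRb"`.
#' @param censor_rate Target censoring fraction, achieved through an
#'   independent uniform censoring horizon calibrated against the baseline
#'   hazard.
#' @param expr_meanlog_range Range of per-feature log-normal mean-log
#'   parameters for unplanted features.
#' @param expr_sdlog Log-normal sd-log, all features.
#' @param planted_meanlog Mean-log of planted miRNAs (kept well above the
#'   RPM filter).
#' @param targets_per_mirna True target genes per planted miRNA.
#' @param target_slope,target_noise_sd,target_intercept Log-linear model of
#'   a planted target gene: `a + b * log(miRNA) + N(0, sd)`, with `b < 0`.
#' @param validated_frac Fraction of true-target evidence rows marked
#'   database-validated (the rest get a high prediction-tool count).
#' @param missing_evidence_rate Fraction of true targets handed weak
#'   evidence (a planted miss).
#' @param decoy_evidence_rate Decoy (non-target) evidence rows with strong
#'   evidence, as a fraction of the true rows.
#' @param planted_set_size,planted_set_frac Planted gene-set size and its
#'   fraction of true-target content.
#' @param n_random_sets,random_set_sizes Background gene sets.
#' @param seed Base RNG seed.
#' @return List of class `"synthetic_config"`; includes the deterministic
#'   feature naming and the target map.
#' @export
synthetic_config <- function(n_patients = 300, n_mirnas = 200,
                             n_genes = 1000, baseline_hazard = 1 / 1500,
                             weibull_shape = 1,
                             main_effects = NULL, interaction_effects = NULL,
                             censor_rate = 0.7,
                             expr_meanlog_range = c(-2, 6), expr_sdlog = 1,
                             planted_meanlog = 3,
                             targets_per_mirna = 20, target_slope = -0.8,
                             target_noise_sd = 0.3, target_intercept = 8,
                             validated_frac = 0.5,
                             missing_evidence_rate = 0.1,
                             decoy_evidence_rate = 0.15,
                             planted_set_size = 50, planted_set_frac = 0.8,
                             n_random_sets = 99,
                             random_set_sizes = c(20, 80), seed = 1L) {
  stopifnot(baseline_hazard > 0, censor_rate > 0, censor_rate < 1,
            weibull_shape > 0, target_slope < 0, n_patients >= 4)
  mirna_ids <- sprintf("miR-sim-%03d", seq_len(n_mirnas))
  gene_ids <- sprintf("gene-sim-%04d", seq_len(n_genes))
  if (is.null(main_effects)) {
    # calibrated once by simulation so the planted single / pair / triple
    # median-split hazard ratios land near the magnitudes reported for the
    # real cervical-carcinoma cohort (~1.7 / ~2.8 / ~3.9)
    main_effects <- stats::setNames(rep(log(1.25), 3L), mirna_ids[1:3])
  }
  if (is.null(interaction_effects)) {
    planted <- names(main_effects)
    if (length(planted) >= 2L) {
      pr <- utils::combn(planted[seq_len(min(3L, length(planted)))], 2L)
      interaction_effects <- stats::setNames(
        rep(log(1.35), ncol(pr)), apply(pr, 2L, paste, collapse = "+"))
    } else interaction_effects <- stats::setNames(numeric(0), character(0))
  }
  if (!all(names(main_effects) %in% mirna_ids))
    stop("main_effects name an unknown miRNA")
  planted <- names(main_effects)
  n_tgt <- length(planted) * targets_per_mirna
  if (n_tgt > n_genes) stop("more planted targets than genes")
  target_map <- stats::setNames(
    lapply(seq_along(planted), function(i)
      gene_ids[((i - 1L) * targets_per_mirna + 1L):(i * targets_per_mirna)]),
    planted)
  structure(list(n_patients = n_patients, n_mirnas = n_mirnas,
                 n_genes = n_genes, baseline_hazard = baseline_hazard,
                 weibull_shape = weibull_shape, main_effects = main_effects,
                 interaction_effects = interaction_effects,
                 censor_rate = censor_rate,
                 expr_meanlog_range = expr_meanlog_range,
                 expr_sdlog = expr_sdlog, planted_meanlog = planted_meanlog,
                 targets_per_mirna = targets_per_mirna,
                 target_slope = target_slope,
                 target_noise_sd = target_noise_sd,
                 target_intercept = target_intercept,
                 validated_frac = validated_frac,
                 missing_evidence_rate = missing_evidence_rate,
                 decoy_evidence_rate = decoy_evidence_rate,
                 planted_set_size = planted_set_size,
                 planted_set_frac = planted_set_frac,
                 n_random_sets = n_random_sets,
                 random_set_sizes = random_set_sizes,
                 mirna_ids = mirna_ids, gene_ids = gene_ids,
                 target_map = target_map, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Uniform censoring horizon c_max hitting the target censor rate exactly in
# expectation: P(censored) is averaged over the 2^k equiprobable high/low
# patterns of the planted miRNAs (k is small), each contributing
# E_C[S(C)] = (1/c_max) int_0^c_max exp(-lambda_z t^shape) dt.
censoring_horizon <- function(config) {
  k <- length(config$main_effects)
  if (k > 12L) stop("censoring calibration supports at most 12 planted miRNAs")
  pat <- if (k) as.matrix(expand.grid(rep(list(0:1), k))) else
    matrix(0, nrow = 1L, ncol = 0L)
  lp <- rep(0, nrow(pat))
  if (k) {
    colnames(pat) <- names(config$main_effects)
    lp <- pat %*% config$main_effects
    for (pr in names(config$interaction_effects)) {
      ab <- strsplit(pr, "+", fixed = TRUE)[[1L]]
      lp <- lp + config$interaction_effects[[pr]] * pat[, ab[1L]] * pat[, ab[2L]]
    }
  }
  lambdas <- config$baseline_hazard * exp(as.numeric(lp))
  shape <- config$weibull_shape
  p_cens <- function(cmax) {
    mean(vapply(lambdas, function(l)
      stats::integrate(function(t) exp(-l * t^shape), 0, cmax,
                       rel.tol = 1e-9)$value / cmax, 0))
  }
  scale0 <- (1 / config$baseline_hazard)^(1 / shape)
  stats::uniroot(function(cm) p_cens(cm) - config$censor_rate,
                 c(scale0 * 1e-4, scale0 * 1e4), tol = 1e-8)$root
}

#' Simulate a miRNA expression + survival cohort with planted effects
#'
#' Expression is i.i.d. log-normal per feature.  High/low status `z_j` is
#' taken against the population median `exp(meanlog_j)` (the pipeline
#' re-estimates medians from the data; the small mismatch is deliberate
#' realism).  Survival is proportional-hazards with baseline
#' `h0(t) = lambda0 * shape * t^(shape-1)` (exponential for shape 1) and
#' an independent uniform censoring horizon.
#'
#' @param config A [synthetic_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return List of class `"sim_cohort"`: `expr` (miRNA matrix, RPM-like),
#'   `clinical` (`sample_id`, `time`, `event`), `truth` (planted answer
#'   key: `prognostic_mirnas`, `synergistic_pairs`, `target_map`,
#'   `true_targets`).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_patients
  ids <- sprintf("patient-%03d", seq_len(n))
  meanlog <- stats::runif(config$n_mirnas, config$expr_meanlog_range[1L],
                          config$expr_meanlog_range[2L])
  names(meanlog) <- config$mirna_ids
  meanlog[names(config$main_effects)] <- config$planted_meanlog
  expr <- matrix(stats::rlnorm(config$n_mirnas * n,
                               meanlog = rep(meanlog, times = n),
                               sdlog = config$expr_sdlog),
                 nrow = config$n_mirnas, ncol = n,
                 dimnames = list(config$mirna_ids, ids))
  z <- expr > exp(meanlog)  # population-median status, feature x patient
  lp <- rep(0, n)
  for (m in names(config$main_effects))
    lp <- lp + config$main_effects[[m]] * z[m, ]
  for (pr in names(config$interaction_effects)) {
    ab <- strsplit(pr, "+", fixed = TRUE)[[1L]]
    lp <- lp + config$interaction_effects[[pr]] * z[ab[1L], ] * z[ab[2L], ]
  }
  lambda <- config$baseline_hazard * exp(lp)
  shape <- config$weibull_shape
  e <- stats::rexp(n)
  t_event <- (e / lambda)^(1 / shape)
  cmax <- censoring_horizon(config)
  exp_events <- n * (1 - config$censor_rate)  # exact under the calibration
  if (exp_events < 10)
    stop("config implies an (almost) all-censored cohort: expected ",
         round(exp_events, 1), " events")
  t_cens <- stats::runif(n, 0, cmax)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  if (sum(event) < 10)
    stop("simulated cohort has fewer than 10 events")
  clinical <- data.frame(sample_id = ids, time = time, event = event,
                         stringsAsFactors = FALSE)
  truth <- list(prognostic_mirnas = names(config$main_effects),
                synergistic_pairs = names(config$interaction_effects),
                target_map = config$target_map,
                true_targets = unique(unlist(config$target_map)))
  structure(list(expr = expr, clinical = clinical, truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d miRNAs, %d events (%.0f%% censored)\n",
              nrow(x$clinical), nrow(x$expr), sum(x$clinical$event),
              100 * mean(1 - x$clinical$event)))
  cat("  planted oncomiRs:",
      paste(x$truth$prognostic_mirnas, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate an mRNA matrix with planted anti-correlated target genes
#'
#' A planted target gene g of regulator miRNA m has log expression
#' `a + b * log(x_m) + N(0, sd)` with `b < 0`; the stored matrix is on the
#' natural (non-negative) scale.  Non-target genes are independent
#' log-normal.  The achieved log-scale Pearson correlation of each planted
#' gene with its regulator is attached as attribute `achieved_pearson`.
#'
#' @param config A [synthetic_config()].
#' @param expr_mirna The simulated miRNA matrix.
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return Numeric mRNA matrix (genes x samples).
#' @export
simulate_targets <- function(config, expr_mirna, seed = config$seed + 1L) {
  set.seed(seed)
  n <- ncol(expr_mirna)
  mat <- matrix(stats::rlnorm(
    config$n_genes * n,
    meanlog = rep(stats::runif(config$n_genes, 0, 6), times = n),
    sdlog = config$expr_sdlog),
    nrow = config$n_genes, ncol = n,
    dimnames = list(config$gene_ids, colnames(expr_mirna)))
  achieved <- numeric(0)
  for (m in names(config$target_map)) {
    if (!m %in% rownames(expr_mirna))
      stop("target_map miRNA absent from miRNA matrix: ", m)
    lx <- log(expr_mirna[m, ])
    for (g in config$target_map[[m]]) {
      lg <- config$target_intercept + config$target_slope * lx +
        stats::rnorm(n, 0, config$target_noise_sd)
      mat[g, ] <- exp(lg)
      achieved[g] <- stats::cor(lx, lg)
    }
  }
  attr(mat, "achieved_pearson") <- achieved
  mat
}

#' Build a miRNA-target evidence table with planted truth and decoys
#'
#' True (regulator, target) pairs get strong evidence: database-validated
#' with probability `validated_frac`, otherwise a prediction-tool count of
#' 5-12; a fraction `missing_evidence_rate` is instead handed weak evidence
#' (tool count 0-4, not validated).  Decoy rows pair planted miRNAs with
#' random non-target genes and carry strong evidence, so they must be
#' rejected on the correlation / survival criteria.
#'
#' @param config A [synthetic_config()].
#' @param truth Ground truth from [simulate_cohort()] (`$truth`).
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return Evidence data.frame (`mirna_id`, `gene_id`, `validated`,
#'   `tool_count`).
#' @export
make_evidence <- function(config, truth, seed = config$seed + 2L) {
  set.seed(seed)
  rows <- list()
  for (m in names(truth$target_map)) {
    for (g in truth$target_map[[m]]) {
      if (stats::runif(1) < config$missing_evidence_rate) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = m, gene_id = g, validated = 0,
          tool_count = sample(0:4, 1L), stringsAsFactors = FALSE)
      } else if (stats::runif(1) < config$validated_frac) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = m, gene_id = g, validated = 1,
          tool_count = sample(0:12, 1L), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = m, gene_id = g, validated = 0,
          tool_count = sample(5:12, 1L), stringsAsFactors = FALSE)
      }
    }
  }
  true_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), gene_id = character(),
               validated = numeric(), tool_count = numeric(),
               stringsAsFactors = FALSE)
  non_targets <- setdiff(config$gene_ids, truth$true_targets)
  n_decoy <- min(round(config$decoy_evidence_rate * nrow(true_df)),
                 length(non_targets))
  if (n_decoy > 0L) {
    decoys <- data.frame(
      mirna_id = sample(names(truth$target_map), n_decoy, replace = TRUE),
      gene_id = sample(non_targets, n_decoy),
      validated = stats::rbinom(n_decoy, 1L, config$validated_frac),
      stringsAsFactors = FALSE)
    decoys$tool_count <- ifelse(decoys$validated == 1,
                                sample(0:12, n_decoy, replace = TRUE),
                                sample(5:12, n_decoy, replace = TRUE))
    true_df <- rbind(true_df, decoys)
  }
  validate_evidence(true_df, where = "synthetic evidence")
}

#' Build gene-set collections with one planted enriched set
#'
#' The planted set draws `planted_set_frac` of its members from the true
#' target genes and the remainder from non-targets; the background sets are
#' uniform draws from the gene universe.
#'
#' @param config A [synthetic_config()].
#' @param truth Ground truth from [simulate_cohort()] (`$truth`).
#' @param seed RNG seed (defaults to `config$seed + 3`).
#' @return Named list of gene sets; the planted set is named
#'   `"planted_set"` and recorded in attribute `planted`.
#' @export
make_genesets <- function(config, truth, seed = config$seed + 3L) {
  set.seed(seed)
  n_true <- round(config$planted_set_frac * config$planted_set_size)
  n_true <- min(n_true, length(truth$true_targets))
  non_targets <- setdiff(config$gene_ids, truth$true_targets)
  planted <- c(sample(truth$true_targets, n_true),
               sample(non_targets, config$planted_set_size - n_true))
  sets <- list(planted_set = planted)
  sizes <- pmin(sample(config$random_set_sizes[1L]:config$random_set_sizes[2L],
                       config$n_random_sets, replace = TRUE),
                length(config$gene_ids))
  for (i in seq_len(config$n_random_sets))
    sets[[sprintf("random_set_%03d", i)]] <- sample(config$gene_ids,
                                                    sizes[i])
  attr(sets, "description") <- c("planted enriched set",
                                 rep("background set",
                                     config$n_random_sets))
  attr(sets, "planted") <- "planted_set"
  sets
}
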