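#' Run the full prognostic-miRNA discovery pipeline
#'
#' Wires the stages in order: sample alignment, single-miRNA oncomiR
#' screen, pairwise synergy screen, exhaustive additive combination search
#' with best-combination selection, target inference for the selected
#' signature, and over-representation analysis of the passing targets.
#' Any stage with an empty result short-circuits the later stages
#' gracefully, recording the reason in the manifest.
#'
#' Inputs are given either as in-memory objects / file paths, or generated
#' from a [synthetic_config()] via `simulate`.
#'
#' @param expr_mirna miRNA matrix or TSV path.
#' @param clinical Clinical data frame or TSV path.
#' @param expr_mrna Optional mRNA matrix or TSV path (needed for target
#'   inference).
#' @param evidence Optional evidence data frame or TSV path.
#' @param collections Optional gene-set collection(s): named list of
#'   character vectors, a GMT path, or a named list of either.
#' @param simulate Optional [synthetic_config()]; generates all inputs.
#' @param screen A [screen_config()].
#' @param target A [target_config()].
#' @param top_n Number of top enriched terms kept for the overlap matrix.
#' @param output_dir Optional directory; when given, every stage result is
#'   written as TSV plus a JSON run manifest.
#' @return Object of class `"mircombo_run"`: list with `manifest` and the
#'   per-stage results (`oncomirs`, `synergy`, `combos`, `best`, `targets`,
#'   `network`, `enrichment`, `top`, `overlap`, plus `truth` for simulated
#'   runs).
#' @export
run_pipeline <- function(expr_mirna = NULL, clinical = NULL,
                         expr_mrna = NULL, evidence = NULL,
                         collections = NULL, simulate = NULL,
                         screen = screen_config(), target = target_config(),
                         top_n = 30L, output_dir = NULL) {
  t0 <- Sys.time()
  digests <- list()
  truth <- NULL
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "synthetic_config"))
    cohort <- simulate_cohort(simulate)
    expr_mirna <- cohort$expr
    clinical <- cohort$clinical
    truth <- cohort$truth
    expr_mrna <- simulate_targets(simulate, expr_mirna)
    evidence <- make_evidence(simulate, truth)
    collections <- list(synthetic = make_genesets(simulate, truth))
    digests$simulated_seed <- simulate$seed
  } else {
    if (is.character(expr_mirna)) {
      digests$expr_mirna <- unname(tools::md5sum(expr_mirna))
      expr_mirna <- read_expression(expr_mirna)
    }
    if (is.character(clinical)) {
      digests$clinical <- unname(tools::md5sum(clinical))
      clinical <- read_clinical(clinical)
    }
    if (is.character(expr_mrna)) {
      digests$expr_mrna <- unname(tools::md5sum(expr_mrna))
      expr_mrna <- read_expression(expr_mrna)
    }
    if (is.character(evidence)) {
      digests$evidence <- unname(tools::md5sum(evidence))
      evidence <- read_evidence(evidence)
    }
    if (is.character(collections)) {
      digests$collections <- unname(tools::md5sum(collections))
      collections <- list(gmt = read_gmt(collections))
    }
  }
  if (is.null(expr_mirna) || is.null(clinical))
    stop("run_pipeline needs a miRNA expression matrix and a clinical table")

  al <- align_samples(expr_mirna, clinical)
  expr_mirna <- al$expr; clinical <- al$clinical
  if (!is.null(expr_mrna)) {
    al2 <- align_samples(expr_mrna, clinical)
    if (al2$n_common < al$n_common) {
      expr_mrna <- al2$expr
      al3 <- align_samples(expr_mirna, al2$clinical)
      expr_mirna <- al3$expr; clinical <- al3$clinical
    } else expr_mrna <- al2$expr
  }

  counts <- list(n_samples = ncol(expr_mirna), n_mirnas = nrow(expr_mirna))
  res <- list(truth = truth)
  short_circuit <- NULL

  res$oncomirs <- screen_oncomirs(expr_mirna, clinical, screen)
  passing <- res$oncomirs$mirna_id[res$oncomirs$passes]
  counts$oncomirs_passing <- length(passing)

  if (length(passing) < 2L) {
    short_circuit <- "fewer than two passing oncomiRs; synergy screen skipped"
  } else {
    res$synergy <- synergy_screen(passing, expr_mirna, clinical, screen)
    pairs_pass <- res$synergy[res$synergy$passes, , drop = FALSE]
    counts$pairs_evaluated <- nrow(res$synergy)
    counts$pairs_passing <- nrow(pairs_pass)
    selected <- sort(unique(c(pairs_pass$mirna_a, pairs_pass$mirna_b)))
    counts$selected_mirnas <- length(selected)
    if (!length(selected)) {
      short_circuit <- "no synergistic pair; additive search skipped"
    } else {
      res$combos <- additive_search(selected, expr_mirna, clinical, screen)
      counts$combos_evaluated <- nrow(res$combos)
      res$best <- select_best(res$combos, screen)
      counts$best_combo <- if (nrow(res$best)) res$best$combo_id else
        "none"
      if (!nrow(res$best))
        short_circuit <- "no significant combination"
    }
  }

  signature <- if (!is.null(res$best) && nrow(res$best))
    strsplit(res$best$combo_id, "+", fixed = TRUE)[[1L]] else character(0)
  if (length(signature) && !is.null(expr_mrna) && !is.null(evidence)) {
    res$targets <- infer_targets(signature, expr_mirna, expr_mrna, clinical,
                                 evidence, target)
    counts$target_candidates <- nrow(res$targets)
    counts$targets_passing <- sum(res$targets$passes)
    res$network <- export_network(res$targets)
    query <- unique(res$targets$gene_id[res$targets$passes])
    if (length(query) && !is.null(collections)) {
      res$enrichment <- run_enrichment(query, collections,
                                       universe = rownames(expr_mrna))
      counts$significant_terms <- sum(res$enrichment$significant)
      res$top <- suppressWarnings(top_terms(res$enrichment, top_n))
      res$overlap <- overlap_matrix(res$top)
    } else if (!length(query)) {
      short_circuit <- c(short_circuit, "no passing target gene; enrichment skipped")
    }
  } else if (!length(signature) && is.null(short_circuit)) {
    short_circuit <- "empty signature; target inference skipped"
  }

  manifest <- list(
    config = list(screen = unclass(screen), target = unclass(target),
                  top_n = top_n),
    seed = screen$seed %||% (if (!is.null(simulate)) simulate$seed else NULL),
    input_digests = digests,
    counts = counts,
    short_circuit = short_circuit,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  res$manifest <- manifest
  out <- structure(res, class = "mircombo_run")
  if (!is.null(output_dir)) write_run(out, output_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_run <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  if (!is.null(run$oncomirs)) write_results(run$oncomirs, p("oncomirs.tsv"))
  if (!is.null(run$synergy)) write_results(run$synergy, p("synergy_pairs.tsv"))
  if (!is.null(run$combos)) write_results(run$combos, p("combinations.tsv"))
  if (!is.null(run$best) && nrow(run$best))
    write_results(run$best, p("best_combination.tsv"))
  if (!is.null(run$targets)) write_results(run$targets, p("targets_audit.tsv"))
  if (!is.null(run$network)) write_results(run$network$edges,
                                           p("network_edges.tsv"))
  if (!is.null(run$enrichment))
    write_results(run$enrichment, p("enrichment.tsv"))
  if (!is.null(run$overlap)) {
    om <- data.frame(term_id = rownames(run$overlap), run$overlap,
                     check.names = FALSE)
    write_results(om, p("overlap_matrix.tsv"))
  }
  write_results(run$manifest, p("manifest.json"), format = "json")
  invisible(output_dir)
}

#' @export
print.mircombo_run <- function(x, ...) {
  m <- x$manifest
  cat("mircombo pipeline run\n")
  cat(sprintf("  samples: %d, miRNAs screened: %d\n",
              m$counts$n_samples, m$counts$n_mirnas))
  cat(sprintf("  passing oncomiRs: %s\n",
              m$counts$oncomirs_passing %||% "-"))
  cat(sprintf("  synergistic pairs: %s (of %s evaluated)\n",
              m$counts$pairs_passing %||% "-",
              m$counts$pairs_evaluated %||% "-"))
  cat(sprintf("  combinations evaluated: %s\n",
              m$counts$combos_evaluated %||% "-"))
  cat(sprintf("  best combination: %s", m$counts$best_combo %||% "-"))
  if (!is.null(x$best) && nrow(x$best))
    cat(sprintf(" (HR %.2f, log-rank p %.3g)", x$best$hr,
                x$best$logrank_p))
  cat("\n")
  if (!is.null(m$counts$targets_passing))
    cat(sprintf("  passing target genes: %d of %d candidates\n",
                m$counts$targets_passing, m$counts$target_candidates))
  if (!is.null(m$counts$significant_terms))
    cat(sprintf("  significant enriched terms: %d\n",
                m$counts$significant_terms))
  if (!is.null(m$short_circuit))
    cat("  note:", paste(m$short_circuit, collapse = "; "), "\n")
  invisible(x)
}
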