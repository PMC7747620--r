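#' Target-inference configuration
#'
#' Thresholds of the three target criteria: (1) at least one of the
#' Pearson/Spearman/Kendall correlations between miRNA and gene expression
#' below `correlation_threshold`; (2) median-split log-rank p of the gene
#' below `target_p_threshold`; (3) the pair is database-validated or
#' supported by at least `min_tools` prediction tools ("more than four"
#' reads as >= 5 of 12).
#'
#' @param correlation_threshold Negative correlation cutoff (strict `<`).
#' @param target_p_threshold Gene survival significance cutoff.
#' @param min_tools Minimum prediction-tool count when not validated.
#' @param log_transform Correlate on `log2(x + 1)` expression (the usual
#'   scale for expression correlation); rank-based coefficients are
#'   unaffected either way.
#' @return List of class `"target_config"`.
#' @export
target_config <- function(correlation_threshold = -0.3,
                          target_p_threshold = 0.05, min_tools = 5,
                          log_transform = TRUE) {
  stopifnot(correlation_threshold < 0, target_p_threshold > 0,
            min_tools >= 1, min_tools <= 12)
  structure(list(correlation_threshold = correlation_threshold,
                 target_p_threshold = target_p_threshold,
                 min_tools = min_tools, log_transform = log_transform),
            class = "target_config")
}

#' Pearson, Spearman and Kendall correlation of two paired vectors
#'
#' Pearson on values, Spearman on average ranks, Kendall as tau-b (the
#' tie-corrected form).
#'
#' @param x,y Paired numeric vectors, `n >= 5`, both non-constant.
#' @return Named numeric vector `c(pearson, spearman, kendall)`.
#' @export
triple_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors required")
  if (length(x) < 5L) stop("triple_correlation needs n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  c(pearson = stats::cor(x, y, method = "pearson"),
    spearman = stats::cor(x, y, method = "spearman"),
    kendall = stats::cor(x, y, method = "kendall"))
}

#' Infer target genes of signature miRNAs
#'
#' For each (miRNA, gene) row of the evidence table whose miRNA is in
#' `mirna_ids` and whose gene is present in the mRNA matrix: compute the
#' three expression correlations, the gene's own median-split log-rank p,
#' and apply the three target criteria (see [target_config()]).  Every
#' candidate is returned with its failure reasons for audit; the passing
#' subset is the inferred target list.
#'
#' @param mirna_ids Signature miRNA ids.
#' @param expr_mirna,expr_mrna Expression matrices sharing the sample set
#'   (and order) of `clinical`.
#' @param clinical Clinical data frame.
#' @param evidence Evidence data.frame ([read_evidence()]).
#' @param config A [target_config()].
#' @return Data frame of class `"target_audit"`: `mirna_id`, `gene_id`,
#'   `pearson`, `spearman`, `kendall`, `target_logrank_p`, `validated`,
#'   `tool_count`, `passes`, `failure_reasons`.
#' @export
infer_targets <- function(mirna_ids, expr_mirna, expr_mrna, clinical,
                          evidence, config = target_config()) {
  check_aligned(expr_mirna, clinical)
  check_aligned(expr_mrna, clinical)
  evidence <- validate_evidence(evidence)
  ev <- evidence[evidence$mirna_id %in% mirna_ids, , drop = FALSE]
  n_missing_gene <- sum(!ev$gene_id %in% rownames(expr_mrna))
  ev <- ev[ev$gene_id %in% rownames(expr_mrna), , drop = FALSE]
  missing_mirna <- setdiff(unique(ev$mirna_id), rownames(expr_mirna))
  if (length(missing_mirna))
    stop("signature miRNA absent from expression matrix: ", missing_mirna[1L])
  tf <- if (config$log_transform) function(v) log2(v + 1) else identity
  time <- clinical$time; event <- clinical$event

  # gene survival p computed once per distinct gene
  genes <- unique(ev$gene_id)
  gene_p <- vapply(genes, function(g) {
    fit <- feature_survival(expr_mrna[g, ], time, event)
    if (is.null(fit)) NA_real_ else fit$logrank_p
  }, 0)

  rows <- lapply(seq_len(nrow(ev)), function(i) {
    m <- ev$mirna_id[i]; g <- ev$gene_id[i]
    cors <- tryCatch(triple_correlation(tf(expr_mirna[m, ]),
                                        tf(expr_mrna[g, ])),
                     error = function(e) c(pearson = NA_real_,
                                           spearman = NA_real_,
                                           kendall = NA_real_))
    p <- gene_p[[g]]
    reasons <- character()
    cor_ok <- !all(is.na(cors)) &&
      min(cors, na.rm = TRUE) < config$correlation_threshold
    if (!cor_ok) reasons <- c(reasons, "correlation")
    surv_ok <- !is.na(p) && p < config$target_p_threshold
    if (!surv_ok) reasons <- c(reasons, "survival")
    evid_ok <- ev$validated[i] == 1 || ev$tool_count[i] >= config$min_tools
    if (!evid_ok) reasons <- c(reasons, "insufficient evidence")
    data.frame(mirna_id = m, gene_id = g,
               pearson = unname(cors["pearson"]),
               spearman = unname(cors["spearman"]),
               kendall = unname(cors["kendall"]),
               target_logrank_p = p, validated = ev$validated[i],
               tool_count = ev$tool_count[i],
               passes = cor_ok && surv_ok && evid_ok,
               failure_reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), gene_id = character(),
               pearson = numeric(), spearman = numeric(),
               kendall = numeric(), target_logrank_p = numeric(),
               validated = numeric(), tool_count = numeric(),
               passes = logical(), failure_reasons = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped_genes") <- n_missing_gene
  class(out) <- c("target_audit", "data.frame")
  out
}

#' Export the miRNA-target interaction network
#'
#' @param targets A `"target_audit"` data frame; only passing rows become
#'   edges.
#' @return List with `edges` (data.frame: `mirna_id`, `gene_id`,
#'   `min_correlation`, `evidence_type`), `counts` (targets per miRNA) and
#'   `overlap` (number of genes targeted by more than one miRNA).
#' @export
export_network <- function(targets) {
  pass <- targets[targets$passes, , drop = FALSE]
  if (!nrow(pass)) {
    return(list(edges = data.frame(mirna_id = character(),
                                   gene_id = character(),
                                   min_correlation = numeric(),
                                   evidence_type = character(),
                                   stringsAsFactors = FALSE),
                counts = integer(0), overlap = 0L))
  }
  min_cor <- pmin(pass$pearson, pass$spearman, pass$kendall, na.rm = TRUE)
  etype <- ifelse(pass$validated == 1 & pass$tool_count >= 5, "both",
                  ifelse(pass$validated == 1, "validated", "predicted"))
  edges <- data.frame(mirna_id = pass$mirna_id, gene_id = pass$gene_id,
                      min_correlation = min_cor, evidence_type = etype,
                      stringsAsFactors = FALSE)
  counts <- table(edges$mirna_id)
  per_gene <- rowSums(table(edges$gene_id, edges$mirna_id) > 0)
  list(edges = edges,
       counts = stats::setNames(as.integer(counts), names(counts)),
       overlap = sum(per_gene > 1L))
}
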