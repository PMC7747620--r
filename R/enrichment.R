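#' Hypergeometric over-representation test for one gene set
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and an annotated gene set against a finite universe:
#' p = P(X >= k) with X ~ Hypergeometric(N, K, n), where N is the universe
#' size, K the (universe-restricted) set size, n the query size and k the
#' observed overlap.
#'
#' @param query_genes Character vector of query gene ids; ids outside the
#'   universe are dropped with a warning.
#' @param gene_set Character vector; intersected with the universe to get K.
#' @param universe Character vector of background gene ids.
#' @return List with `k`, `K`, `n`, `N`, `p`, `overlap_genes`.
#' @export
hypergeom_ora <- function(query_genes, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query_genes <- unique(query_genes)
  if (!length(query_genes)) stop("empty query")
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query_genes <- intersect(query_genes, universe)
    if (!length(query_genes)) stop("no query genes left inside the universe")
  }
  set_u <- intersect(unique(gene_set), universe)
  overlap <- intersect(query_genes, set_u)
  k <- length(overlap); K <- length(set_u)
  n <- length(query_genes); N <- length(universe)
  p <- if (k == 0L) 1 else
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = min(p, 1), overlap_genes = overlap)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with monotone enforcement; output order matches input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p) | p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis across gene-set collections
#'
#' Runs [hypergeom_ora()] for every set in every collection and applies BH
#' adjustment within each collection (databases such as GO, KEGG and
#' Reactome are corrected separately, matching per-database top-term
#' reporting).
#'
#' @param query_genes Query gene ids (e.g. the passing target genes).
#' @param collections Either a single gene-set collection (named list of
#'   character vectors, as from [read_gmt()]) or a named list of such
#'   collections, one per database.
#' @param universe Background gene ids (recommended: all genes in the
#'   aligned expression matrix).
#' @param alpha Significance cutoff on the adjusted p-value.
#' @return Data frame of class `"enrichment_result"`: `database`, `term_id`,
#'   `k`, `K`, `n`, `N`, `p`, `adj_p`, `significant`,
#'   `overlap_genes` (`;`-joined); sorted by `adj_p` then `p`.
#' @export
run_enrichment <- function(query_genes, collections, universe,
                           alpha = 0.05) {
  if (!length(collections)) stop("run_enrichment needs >= 1 collection")
  if (!is.list(collections[[1L]]))
    collections <- list(sets = collections)
  if (is.null(names(collections)))
    names(collections) <- paste0("db", seq_along(collections))
  res <- lapply(names(collections), function(db) {
    coll <- collections[[db]]
    rows <- lapply(names(coll), function(term) {
      r <- hypergeom_ora(query_genes, coll[[term]], universe)
      data.frame(database = db, term_id = term, k = r$k, K = r$K, n = r$n,
                 N = r$N, p = r$p,
                 overlap_genes = paste(sort(r$overlap_genes),
                                       collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d$adj_p <- bh_adjust(d$p)
    d
  })
  out <- do.call(rbind, res)
  out$significant <- out$adj_p < alpha
  out <- out[order(out$adj_p, out$p, out$term_id),
             c("database", "term_id", "k", "K", "n", "N", "p", "adj_p",
               "significant", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Top enriched terms
#'
#' @param results An `"enrichment_result"` data frame (already sorted by
#'   adjusted p).
#' @param n Number of terms to keep; if fewer are available, all are
#'   returned with a warning.
#' @export
top_terms <- function(results, n = 10L) {
  if (n > nrow(results)) {
    warning("only ", nrow(results), " terms available; returning all")
    n <- nrow(results)
  }
  utils::head(results, n)
}

#' Jaccard overlap matrix of top enriched terms
#'
#' For each pair of terms, the Jaccard index of their overlap-gene sets —
#' the computable core behind grouped ("GSOAP-style") enrichment displays.
#'
#' @param top An `"enrichment_result"` data frame (typically from
#'   [top_terms()]).
#' @return Symmetric matrix with unit diagonal, dimnames = term ids.
#' @export
overlap_matrix <- function(top) {
  sets <- strsplit(top$overlap_genes, ";", fixed = TRUE)
  sets <- lapply(sets, function(s) s[nzchar(s)])
  m <- length(sets)
  out <- diag(1, m)
  dimnames(out) <- list(top$term_id, top$term_id)
  if (m < 2L) return(out)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      u <- length(union(sets[[i]], sets[[j]]))
      out[i, j] <- out[j, i] <-
        if (u == 0L) 0 else length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  out
}
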