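#' Read a feature-by-sample expression matrix from TSV
#'
#' Expression matrices are plain delimited text with a header row of sample
#' ids and a first column of feature ids (miRNA matrices in RPM, mRNA
#' matrices in any normalized unit).  Files written with samples in rows can
#' be read by setting `orientation = "samples"`.
#'
#' @param path Path to the delimited file.
#' @param orientation `"features"` (default) if features are in rows,
#'   `"samples"` if the file is transposed.
#' @param sep Field separator; tab is the canonical dialect, `","` is
#'   accepted for CSV exports.
#' @return A numeric matrix, features in rows and samples in columns, with
#'   unique `rownames`/`colnames` and finite non-negative values.
#' @export
read_expression <- function(path, orientation = c("features", "samples"),
                            sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("expression file needs an id column plus at least one sample: ", path)
  ids <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(ids, colnames(mat))))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or non-finite cell at row '%s', column '%s' in %s",
                 ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]], path))
  }
  if (orientation == "samples") num <- t(num)
  validate_expression(num, where = path)
  message(sprintf("read_expression: %d features x %d samples from %s",
                  nrow(num), ncol(num), path))
  num
}

validate_expression <- function(mat, where = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression must be a numeric matrix: ", where)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs feature and sample ids: ", where)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate feature id in ", where, ": ",
         rownames(mat)[duplicated(rownames(mat))][1L])
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample id in ", where, ": ",
         colnames(mat)[duplicated(colnames(mat))][1L])
  if (any(!is.finite(mat))) stop("non-finite expression value in ", where)
  if (any(mat < 0)) stop("negative expression value in ", where)
  invisible(mat)
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix, features in rows.
#' @param path Output path.
#' @param sep Field separator.
#' @param id_column Header for the feature-id column.
#' @export
write_expression <- function(mat, path, sep = "\t", id_column = "feature_id") {
  validate_expression(mat)
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical follow-up table from TSV
#'
#' Expects columns `sample_id`, `time` (positive, days) and `event`
#' (1 = event observed, 0 = right-censored); any extra covariate columns are
#' preserved.  Rows with missing or non-positive time, or missing event, are
#' dropped and counted in the exclusion report attached as
#' `attr(x, "report")`.  An event value outside {0, 1} is an error rather
#' than an exclusion, since it signals a mis-coded file.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator.
#' @return A `data.frame` with attribute `report`, a list with `n_read`,
#'   `n_kept` and `dropped`.
#' @export
read_clinical <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = c("NA", "N/A", ""))
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  df$time <- suppressWarnings(as.numeric(df$time))
  ev_raw <- df$event
  df$event <- suppressWarnings(as.numeric(df$event))
  bad_event <- !is.na(df$event) & !(df$event %in% c(0, 1))
  if (any(bad_event))
    stop("event values must be 0 or 1; found '", ev_raw[which(bad_event)[1L]],
         "' for sample ", df$sample_id[which(bad_event)[1L]])
  keep <- !is.na(df$time) & df$time > 0 & !is.na(df$event)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample_id in clinical table: ",
         out$sample_id[duplicated(out$sample_id)][1L])
  attr(out, "report") <- list(n_read = nrow(df), n_kept = nrow(out),
                              dropped = sum(!keep))
  message(sprintf("read_clinical: kept %d of %d rows (%d dropped) from %s",
                  nrow(out), nrow(df), sum(!keep), path))
  out
}

#' Write a clinical table as TSV
#' @param clinical Data frame with `sample_id`, `time`, `event`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_clinical <- function(clinical, path, sep = "\t") {
  utils::write.table(clinical, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix and clinical table to their common samples
#'
#' Both outputs are restricted to the intersection of sample ids, in the
#' same order (that of the expression matrix).  The dropped counts are
#' logged and attached as attribute `alignment`.
#'
#' @param expr Numeric expression matrix (features x samples).
#' @param clinical Clinical data frame with `sample_id`.
#' @return A list with elements `expr`, `clinical` and `n_common`.
#' @export
align_samples <- function(expr, clinical) {
  validate_expression(expr)
  common <- intersect(colnames(expr), clinical$sample_id)
  if (length(common) == 0L)
    stop("no samples shared between expression matrix and clinical table")
  common <- colnames(expr)[colnames(expr) %in% common]
  expr2 <- expr[, common, drop = FALSE]
  clin2 <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  message(sprintf(
    "align_samples: %d common samples (%d expression-only, %d clinical-only dropped)",
    length(common), ncol(expr) - length(common),
    nrow(clinical) - length(common)))
  list(expr = expr2, clinical = clin2, n_common = length(common))
}

format_pct <- function(n, total) {
  # round-half-even to 1 decimal; trailing ".0" dropped to match the usual
  # cohort-table style ("2%" not "2.0%")
  p <- round(100 * n / total, 1)
  s <- formatC(p, format = "f", digits = 1)
  s <- sub("\\.0$", "", s)
  paste0(s, "%")
}

#' Summarize categorical clinical covariates as counts and percentages
#'
#' Produces the usual cohort-characteristics table: for each requested
#' categorical column, per-category counts with percentages of `total_n`
#' rounded (half-even) to one decimal.  `NA` values form their own "N/A"
#' category.
#'
#' @param clinical Clinical data frame.
#' @param vars Character vector of column names to tabulate; defaults to all
#'   non-mandatory columns.
#' @param total_n Denominator for percentages; defaults to `nrow(clinical)`.
#' @return A data.frame with columns `variable`, `category`, `n`, `pct`.
#' @export
summarize_clinical <- function(clinical, vars = NULL, total_n = nrow(clinical)) {
  if (is.null(vars))
    vars <- setdiff(names(clinical), c("sample_id", "time", "event"))
  if (!length(vars)) stop("no categorical covariate columns to summarize")
  rows <- lapply(vars, function(v) {
    x <- clinical[[v]]
    x <- ifelse(is.na(x), "N/A", as.character(x))
    tab <- table(x)
    data.frame(variable = v, category = names(tab), n = as.integer(tab),
               pct = format_pct(as.integer(tab), total_n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a miRNA-gene interaction evidence table
#'
#' One row per candidate interaction: `mirna_id`, `gene_id`, `validated`
#' (1 if recorded in a curated interaction database such as miRTarBase) and
#' `tool_count` (number of prediction tools, 0-12, supporting the pair).
#'
#' @param path Path to the delimited file.
#' @param sep Field separator.
#' @return Validated data.frame of evidence rows.
#' @export
read_evidence <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("evidence file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  validate_evidence(df, where = path)
}

validate_evidence <- function(df, where = "evidence table") {
  need <- c("mirna_id", "gene_id", "validated", "tool_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(where, " missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!df$validated %in% c(0, 1)))
    stop("validated must be 0/1 in ", where)
  if (any(is.na(df$tool_count) | df$tool_count < 0 | df$tool_count > 12 |
            df$tool_count != floor(df$tool_count)))
    stop("tool_count must be an integer in [0, 12] in ", where)
  key <- paste(df$mirna_id, df$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (miRNA, gene) pair in %s: (%s, %s)",
                 where, d$mirna_id, d$gene_id))
  }
  rownames(df) <- NULL
  df
}

#' Write an evidence table as TSV
#' @param evidence Evidence data.frame.
#' @param path Output path.
#' @export
write_evidence <- function(evidence, path) {
  validate_evidence(evidence)
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' GMT lines are tab separated: set name, description, then gene ids.
#'
#' @param path Path to the `.gmt` file.
#' @param universe Optional character vector; when supplied, each set is
#'   checked to be a subset of it.
#' @return A named list of character vectors with attribute `description`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("malformed GMT line ", which(bad)[1L],
                     " (need name, description, >=1 gene): ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name in ", path, ": ",
         names(sets)[duplicated(names(sets))][1L])
  if (!is.null(universe)) {
    for (nm in names(sets)) {
      extra <- setdiff(sets[[nm]], universe)
      if (length(extra))
        stop("gene set '", nm, "' contains ids outside the universe: ",
             paste(utils::head(extra, 3L), collapse = ", "))
    }
  }
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), description, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write pipeline results as TSV or JSON
#'
#' Data frames go to TSV; any list structure goes to JSON.
#'
#' @param results A data.frame or list.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`; guessed from the extension by default.
#' @export
write_results <- function(results, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  format <- match.arg(format, c("tsv", "json"))
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    if (!is.data.frame(results)) results <- as.data.frame(results)
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read JSON results written by [write_results()]
#' @param path Path to the JSON file.
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
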