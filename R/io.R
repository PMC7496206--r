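#' Tabular input/output
#'
#' All pipeline tables are plain tab-separated text with a header row, so a
#' run can be inspected and diffed with standard command-line tools.
#'
#' @name io_formats
NULL

#' Build / validate a three-condition expression matrix
#'
#' An expression matrix is a data frame with columns `id`, `low`, `moderate`,
#' `high`: one abundance (FPKM for genes, RPM for miRNAs) per entity and
#' glucose condition.
#'
#' @param id Character entity ids (unique, non-empty).
#' @param low,moderate,high Non-negative abundances.
#' @return A validated data frame.
#' @export
expression_matrix <- function(id, low, moderate, high) {
  validate_expression(data.frame(
    id = as.character(id), low = low, moderate = moderate, high = high,
    stringsAsFactors = FALSE
  ))
}

#' @rdname expression_matrix
#' @param x A data frame to validate.
#' @export
validate_expression <- function(x) {
  need <- c("id", "low", "moderate", "high")
  if (!all(need %in% names(x)))
    stop("expression matrix needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id)) stop("duplicate entity ids", call. = FALSE)
  if (any(x$id == "" | is.na(x$id))) stop("empty entity id", call. = FALSE)
  vals <- as.matrix(x[, c("low", "moderate", "high")])
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0))
    stop("abundances must be non-negative and complete", call. = FALSE)
  x[, need]
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, need = NULL) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(need) && !all(need %in% names(x)))
    stop(path, " is missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  x
}

#' Read / write expression matrices
#'
#' @param path File path of a TSV with columns `id`, `low`, `moderate`,
#'   `high`.
#' @return `read_expression()` returns a validated expression data frame;
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path) {
  validate_expression(read_tsv(path, c("id", "low", "moderate", "high")))
}

#' @rdname read_expression
#' @param x Expression matrix data frame.
#' @export
write_expression <- function(x, path) write_tsv(validate_expression(x), path)

#' Read experimental miRNA-target interaction evidence
#'
#' Expected columns: `mirna`, `gene`, `evidence_class` in `{strong, weak}`
#' (strong: reporter assay / Western blot class; weak: CLIP-seq class).
#'
#' @param path TSV path.
#' @param strict If `TRUE`, malformed rows abort; otherwise they are skipped
#'   with a warning naming the offending line numbers.
#' @return Data frame `mirna`, `gene`, `evidence_class`.
#' @export
load_experimental <- function(path, strict = FALSE) {
  x <- read_tsv(path, c("mirna", "gene", "evidence_class"))
  bad <- x$mirna == "" | x$gene == "" |
    !x$evidence_class %in% c("strong", "weak")
  if (any(bad)) {
    msg <- paste0("malformed experimental rows at lines: ",
                  paste(which(bad) + 1L, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, " (skipped)", call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  x[, c("mirna", "gene", "evidence_class")]
}

#' Read per-tool target-prediction tables
#'
#' @param paths Named list/vector of TSV paths; names must be tools from
#'   `{miranda, pita, targetscan, rnahybrid}`. Each file has columns `mirna`,
#'   `gene`, `score`, `mfe` (kcal/mol, <= 0 by convention).
#' @param strict Abort on malformed rows instead of skipping.
#' @return Data frame `mirna`, `gene`, `tool`, `score`, `mfe`.
#' @export
load_predictions <- function(paths, strict = FALSE) {
  tools <- c("miranda", "pita", "targetscan", "rnahybrid")
  if (is.null(names(paths)) || !all(names(paths) %in% tools))
    stop("prediction paths must be named by tool: ",
         paste(tools, collapse = ", "), call. = FALSE)
  out <- lapply(names(paths), function(tool) {
    x <- read_tsv(paths[[tool]], c("mirna", "gene", "score", "mfe"))
    if (nrow(x) == 0L)
      return(data.frame(mirna = character(), gene = character(),
                        tool = character(), score = numeric(),
                        mfe = numeric(), stringsAsFactors = FALSE))
    bad <- x$mirna == "" | x$gene == "" | !is.finite(x$score) |
      !is.finite(x$mfe)
    if (any(bad)) {
      msg <- paste0(tool, ": malformed prediction rows at lines: ",
                    paste(which(bad) + 1L, collapse = ", "))
      if (strict) stop(msg, call. = FALSE)
      warning(msg, " (skipped)", call. = FALSE)
      x <- x[!bad, , drop = FALSE]
    }
    data.frame(mirna = x$mirna, gene = x$gene, tool = tool,
               score = x$score, mfe = x$mfe, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a TF-to-miRNA regulation table
#'
#' Expected columns: `tf_gene`, `mirna`, `sign` in
#' `{activate, repress, unknown}`.
#'
#' @param path TSV path.
#' @return Data frame `tf_gene`, `mirna`, `sign`.
#' @export
read_tf_table <- function(path) {
  x <- read_tsv(path, c("tf_gene", "mirna", "sign"))
  bad <- !x$sign %in% c("activate", "repress", "unknown")
  if (any(bad)) {
    warning("unknown regulation signs coerced to 'unknown'", call. = FALSE)
    x$sign[bad] <- "unknown"
  }
  x[, c("tf_gene", "mirna", "sign")]
}

#' Read gene keyword/term annotations
#'
#' Expected columns: `gene`, `categories` (comma-separated subset of
#' G,O,E,C; may be empty), `terms` (comma-separated term ids; may be empty).
#'
#' @param path TSV path.
#' @return Data frame `gene`, `categories`, `terms` (list columns parsed by
#'   [annotation_categories()] / [annotation_terms()]).
#' @export
read_annotations <- function(path) {
  read_tsv(path, c("gene", "categories", "terms"))
}

split_csv_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ",", fixed = TRUE), function(v) v[nzchar(v)])
}

#' @rdname read_annotations
#' @param annotations Annotation data frame.
#' @export
annotation_categories <- function(annotations) {
  stats::setNames(split_csv_field(annotations$categories), annotations$gene)
}

#' @rdname read_annotations
#' @export
annotation_terms <- function(annotations) {
  stats::setNames(split_csv_field(annotations$terms), annotations$gene)
}

#' Read / write GMT term-set files
#'
#' The GMT format is one term per line: term id, description, then member
#' gene ids, all tab-separated.
#'
#' @param path GMT file path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(
    lapply(fields, function(f) unique(f[-(1:2)])),
    vapply(fields, `[[`, "", 1L)
  )
}

#' @rdname read_gmt
#' @param term_sets Named list of character vectors.
#' @export
write_gmt <- function(term_sets, path) {
  lines <- vapply(names(term_sets), function(nm) {
    paste(c(nm, "na", term_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
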