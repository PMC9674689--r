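#' Tabular I/O for expression matrices and sample phenotype tables
#'
#' The pipeline works on two plain-text inputs: a genes-by-samples matrix of
#' log2-normalized expression (TSV, first row = sample ids, first column =
#' gene ids) and a per-sample phenotype table (columns `sample_id`, `class`,
#' and optionally `stage`, `os_time`, `os_event`). Both are the shapes the
#' UCSC Xena / GDC cohort files take after decompression; `.gz` paths are
#' read and written transparently. No normalization is performed: values are
#' taken as already log2 scale.
#'
#' An expression matrix is represented as a plain numeric matrix whose
#' rownames are gene ids and colnames are sample ids; a phenotype table is a
#' data.frame. [validate_expression_matrix()] enforces the container
#' invariants at every boundary.
#'
#' @name io_tables
NULL

#' Validate an expression matrix container
#'
#' Checks the invariants every pipeline stage relies on: numeric matrix,
#' unique non-empty gene and sample ids, all values finite (missing values
#' are rejected, never imputed).
#'
#' @param m numeric matrix, genes in rows, samples in columns, with dimnames.
#' @return `m`, invisibly, if valid; otherwise an error naming the offender.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression data must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix requires gene ids as rownames and sample ids as colnames")
  }
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g) > 0) {
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s) > 0) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(m) || any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  invisible(m)
}

open_text <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a genes-by-samples expression TSV
#'
#' First row holds sample ids, first column gene ids, body numeric. Duplicate
#' ids and non-numeric or empty cells are hard errors that name the offending
#' gene/sample, so malformed cohort files fail loudly at the door.
#'
#' @param path path to a TSV (optionally `.gz`).
#' @return numeric matrix with gene-id rownames and sample-id colnames.
#' @seealso [write_expression_tsv()] for the exact-round-trip writer.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  if (ncol(df) < 2L) stop("expression file needs a gene-id column plus at least one sample")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L)
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) | !nzchar(trimws(col)))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or missing value at gene '%s', sample '%s' (cell '%s')",
                   gene_ids[bad[1L]], sample_ids[j], col[bad[1L]]))
    }
    vals[, j] <- x
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' Values are formatted with 17 significant digits so that
#' `read_expression_tsv(write_expression_tsv(m))` is the identity to machine
#' precision.
#'
#' @param m validated expression matrix.
#' @param path output path; `.gz` suffix triggers gzip.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  validate_expression_matrix(m)
  con <- open_text(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Collapse a free-text tumor stage string to I--IV
#'
#' Sub-stage suffixes ("Stage IA", "Stage IIB") collapse to the main stage.
#' The Roman numerals are tested in the order IV, III, II, I so that the
#' longest numeral wins; strings matching none (including "not reported" and
#' empty) map to `NA`.
#'
#' @param x character vector of stage strings.
#' @return character vector with values in `c("I","II","III","IV")` or `NA`.
#' @export
parse_stage <- function(x) {
  out <- rep(NA_character_, length(x))
  for (stage in c("IV", "III", "II", "I")) {
    hit <- is.na(out) & grepl(stage, x, fixed = TRUE)
    out[hit] <- stage
  }
  out
}

#' Read a sample phenotype TSV
#'
#' Required columns: `sample_id` and `class` (values `tumor`/`normal`,
#' case-insensitive; anything else is a hard error). Optional columns:
#' `stage` (collapsed to I--IV via [parse_stage()]), `os_time` (non-negative
#' days) and `os_event` (0 = alive/censored, 1 = dead). `os_time` and
#' `os_event` must be present or absent together in each row.
#'
#' @param path path to a TSV (optionally `.gz`).
#' @return data.frame with columns `sample_id`, `class`, `stage`, `os_time`,
#'   `os_event` (missing optional fields are `NA`).
#' @export
read_phenotype_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  need <- c("sample_id", "class")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0) {
    stop("phenotype file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))

  cls <- tolower(trimws(df$class))
  bad <- setdiff(unique(cls), c("tumor", "normal"))
  if (length(bad) > 0) {
    stop("invalid class value(s): ", paste(bad, collapse = ", "),
         " (expected 'tumor' or 'normal')")
  }

  n <- nrow(df)
  stage <- if ("stage" %in% colnames(df)) parse_stage(df$stage) else rep(NA_character_, n)
  num_col <- function(name) {
    if (!name %in% colnames(df)) return(rep(NA_real_, n))
    raw <- trimws(df[[name]])
    out <- suppressWarnings(as.numeric(raw))
    bad <- nzchar(raw) & !raw %in% c("NA", "na") & is.na(out)
    if (any(bad)) {
      stop(sprintf("non-numeric %s for sample '%s': '%s'",
                   name, df$sample_id[which(bad)[1L]], raw[which(bad)[1L]]))
    }
    out
  }
  os_time <- num_col("os_time")
  os_event <- num_col("os_event")
  mismatch <- xor(is.na(os_time), is.na(os_event))
  if (any(mismatch)) {
    stop("os_time and os_event must be present together (sample '",
         df$sample_id[which(mismatch)[1L]], "')")
  }
  if (any(os_time < 0, na.rm = TRUE)) stop("negative os_time")
  if (!all(os_event %in% c(0, 1) | is.na(os_event))) {
    stop("os_event must be 0 (censored) or 1 (dead)")
  }

  data.frame(sample_id = df$sample_id, class = cls, stage = stage,
             os_time = os_time, os_event = os_event,
             stringsAsFactors = FALSE)
}

#' Write a phenotype table as TSV
#'
#' @param ann phenotype data.frame as returned by [read_phenotype_tsv()].
#' @param path output path; `.gz` suffix triggers gzip.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(ann, path) {
  stopifnot(all(c("sample_id", "class") %in% colnames(ann)))
  cols <- intersect(c("sample_id", "class", "stage", "os_time", "os_event"),
                    colnames(ann))
  con <- open_text(path, "w")
  on.exit(close(con))
  utils::write.table(ann[, cols, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Align an expression matrix with a phenotype table
#'
#' Restricts both to their shared sample ids, kept in matrix column order,
#' and reports (via `message()`) how many samples were dropped from each
#' side. An empty intersection is a hard error.
#'
#' @param matrix validated expression matrix.
#' @param annotations phenotype data.frame with a `sample_id` column.
#' @return list with elements `matrix` and `annotations`, both restricted to
#'   the shared samples in the same order.
#' @export
align_samples <- function(matrix, annotations) {
  validate_expression_matrix(matrix)
  shared <- colnames(matrix)[colnames(matrix) %in% annotations$sample_id]
  if (length(shared) == 0L) {
    stop("no shared sample ids between expression matrix and annotations")
  }
  dropped_m <- ncol(matrix) - length(shared)
  dropped_a <- nrow(annotations) - length(shared)
  if (dropped_m > 0 || dropped_a > 0) {
    message(sprintf("align: dropped %d matrix sample(s) and %d annotation row(s)",
                    dropped_m, dropped_a))
  }
  ann <- annotations[match(shared, annotations$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(matrix = matrix[, shared, drop = FALSE], annotations = ann)
}
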