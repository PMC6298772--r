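# All tables are TSV (plate readings and Ct tables are CSV) with a mandatory
# header, "." decimal point, UTF-8. Labels are opaque case-sensitive strings.

#' Construct a guide library
#'
#' @param guide_id Character vector of unique sgRNA identifiers.
#' @param gene Character vector of target gene symbols; control guides carry
#'   the reserved label `"CONTROL"`.
#' @param sequence Optional character vector of guide sequences.
#' @param is_control Logical; defaults to `gene == "CONTROL"`.
#' @return A `guide_library` data frame.
#' @export
guide_library <- function(guide_id, gene, sequence = NA_character_,
                          is_control = NULL) {
  guide_id <- as.character(guide_id)
  gene <- as.character(gene)
  if (anyDuplicated(guide_id)) {
    dup <- unique(guide_id[duplicated(guide_id)])
    stop("duplicate guide_id: ", paste(dup, collapse = ", "))
  }
  if (any(is.na(gene) | !nzchar(gene))) {
    stop("every guide needs a non-empty gene label")
  }
  if (is.null(is_control)) is_control <- gene == CONTROL_GENE
  out <- data.frame(
    guide_id = guide_id, gene = gene,
    sequence = as.character(sequence),
    is_control = as.logical(is_control),
    stringsAsFactors = FALSE
  )
  class(out) <- c("guide_library", "data.frame")
  out
}

#' Read a guide library from a TSV file
#'
#' Requires columns `guide_id` and `gene`; `sequence` and `is_control` are
#' optional, any other column is ignored with a warning.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `guide_library` data frame.
#' @export
read_guide_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  need <- c("guide_id", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(need, "sequence", "is_control"))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  guide_library(
    df$guide_id, df$gene,
    sequence = if ("sequence" %in% names(df)) df$sequence else NA_character_,
    is_control = if ("is_control" %in% names(df))
      tolower(df$is_control) %in% c("true", "1") else NULL
  )
}

#' Construct a screen count matrix
#'
#' @param counts Non-negative integer matrix, guides x samples, with row and
#'   column names.
#' @param reference_sample Column name of the plasmid-library reference.
#' @return A `screen_counts` object.
#' @export
screen_counts <- function(counts, reference_sample) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry guide (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate guide ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!reference_sample %in% colnames(counts)) {
    stop("reference sample '", reference_sample, "' not among samples: ",
         paste(colnames(counts), collapse = ", "))
  }
  structure(list(counts = counts, reference_sample = reference_sample),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen_counts:", nrow(x$counts), "guides x", ncol(x$counts),
      "samples; reference =", x$reference_sample, "\n")
  invisible(x)
}

#' Read a screen count matrix from a TSV file
#'
#' First column must be `guide_id`; remaining columns are integer read
#' counts, one per sample. Non-integer cells are a hard error reporting the
#' offending row and column.
#'
#' @param path Path to a tab-separated counts file.
#' @param reference_sample Sample (column) holding the plasmid library.
#' @return A `screen_counts` object.
#' @export
read_count_matrix <- function(path, reference_sample) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  if (names(df)[1] != "guide_id") stop("first column must be guide_id")
  if (ncol(df) < 2) stop("no sample columns found")
  ids <- df$guide_id
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, names(df)[-1]))
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("non-integer count '%s' at row %d, column '%s'",
                   df[[j + 1L]][bad[1]], bad[1], colnames(m)[j]))
    }
    m[, j] <- v
  }
  screen_counts(m, reference_sample)
}

# read a genes-or-markers x samples numeric TSV (first column = row label)
read_labelled_matrix <- function(path, label) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(df) < 2) stop("no sample columns found in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate ", label, " labels in ", path)
  m <- as.matrix(df[-1])
  if (anyDuplicated(colnames(m))) stop("duplicate sample labels in ", path)
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("non-finite or non-numeric values in ", path)
  }
  rownames(m) <- ids
  m
}

#' Read an expression matrix (genes x samples) from TSV
#'
#' @param path Path to a TSV whose first column holds gene symbols.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_table <- function(path) {
  m <- read_labelled_matrix(path, "gene")
  if (any(m < 0)) stop("expression values must be non-negative")
  m
}

#' Read an RPPA phosphoprotein matrix (markers x samples) from TSV
#'
#' @param path Path to a TSV whose first column holds marker ids.
#' @return Numeric matrix with marker rownames and sample colnames.
#' @export
read_rppa_table <- function(path) {
  read_labelled_matrix(path, "marker")
}

#' Read a sample annotation table from TSV
#'
#' One row per sample: a `sample_id` column, logical (TRUE/FALSE or 0/1)
#' mutation flags named after genes, and an optional `tissue` label.
#'
#' @param path Path to a tab-separated annotation file.
#' @return Data frame with unique `sample_id` and logical flag columns.
#' @export
read_sample_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in annotation")
  for (nm in setdiff(names(df), c("sample_id", "tissue"))) {
    df[[nm]] <- df[[nm]] %in% c(TRUE, 1, "1", "TRUE", "true", "True")
  }
  df
}

#' Read plate-reader viability readings from CSV
#'
#' Expects columns `cell_line`, `condition`, `dose`, `replicate`, `signal`
#' and optionally `timepoint`. Replicate indices must be unique within each
#' (cell_line, condition, dose, timepoint) group.
#'
#' @param path Path to a comma-separated readings file.
#' @return A data frame of plate readings.
#' @export
read_plate_readings <- function(path) {
  df <- read.csv(path, header = TRUE, check.names = FALSE)
  need <- c("cell_line", "condition", "dose", "replicate", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"timepoint" %in% names(df)) df$timepoint <- NA_real_
  if (any(!is.finite(df$signal))) stop("non-finite signal values")
  if (any(df$dose < 0)) stop("doses must be non-negative")
  tp <- ifelse(is.na(df$timepoint), "none", as.character(df$timepoint))
  key <- interaction(df$cell_line, df$condition, df$dose, tp, drop = TRUE)
  if (any(tapply(df$replicate, key, anyDuplicated) > 0)) {
    stop("replicate indices must be unique within each well group")
  }
  df
}

#' Read a qPCR Ct table from CSV
#'
#' Expects columns `gene`, `condition`, `replicate`, `ct`.
#'
#' @param path Path to a comma-separated Ct file.
#' @return A data frame of cycle thresholds.
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, header = TRUE, check.names = FALSE)
  need <- c("gene", "condition", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a tabular result to TSV
#'
#' Floating-point columns are serialized at full double precision (15
#' significant digits), so a write/read round trip reproduces values to well
#' under 1e-9 relative error.
#'
#' @param table A data frame (any classed data frame is accepted).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(table, path) {
  df <- as.data.frame(table)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.na(v)) "NA" else sprintf("%.15g", v)
      }, character(1))
    }
  }
  ok <- try(write.table(df, path, sep = "\t", quote = FALSE,
                        row.names = FALSE, fileEncoding = "UTF-8"),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write to ", path)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_results_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Write a labelled numeric matrix to TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Header for the row-label column.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_results_table(df, path)
}
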