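#' Read a log2 expression matrix
#'
#' Reads a genes-by-samples matrix of log2 intensities from a tab-separated
#' file. Two dialects are supported: `"plain_tsv"` (first column gene id,
#' header row of sample ids) and `"geo_series_matrix"` (a GEO series-matrix
#' text file; only the block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` is parsed — sample characteristics lines are
#' ignored, the design table is supplied separately).
#'
#' The matrix must be complete: a missing or non-numeric cell is an error
#' (imputation is out of scope), and duplicate gene or sample identifiers are
#' errors naming the offenders. Row order is preserved from the file.
#'
#' @param path Path to the file.
#' @param dialect `"plain_tsv"` or `"geo_series_matrix"`.
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per sample, in file order.
#' @export
read_expression <- function(path, dialect = c("plain_tsv", "geo_series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "geo_series_matrix") {
    b <- grep("^!series_matrix_table_begin", lines)
    e <- grep("^!series_matrix_table_end", lines)
    if (length(b) != 1L || length(e) != 1L || e <= b + 1L) {
      stop("no series_matrix_table block found in ", path, call. = FALSE)
    }
    lines <- gsub('"', "", lines[(b + 1L):(e - 1L)], fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  # ragged or malformed cells surface as located errors below, not as
  # parser warnings
  body <- suppressWarnings(readr::read_tsv(
    I(paste(lines, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE, name_repair = "minimal"
  ))
  gene_ids <- body[[1L]]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow(body), length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- body[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      i <- bad[[1L]]
      what <- if (is.na(col[[i]]) || col[[i]] %in% c("", "NA")) {
        "missing value"
      } else {
        paste0("non-numeric value '", col[[i]], "'")
      }
      stop(what, " at gene '", gene_ids[[i]], "' (row ", i, "), sample '",
           sample_ids[[j]], "' (column ", j + 1L, ")", call. = FALSE)
    }
    vals[, j] <- num
  }
  out <- dplyr::bind_cols(tibble::tibble(gene = gene_ids),
                          tibble::as_tibble(vals))
  validate_expression(out)
}

#' Validate an expression tibble
#'
#' Checks the invariants of the expression container: a `gene` character
#' column, unique gene and sample ids, all-numeric body, no missing values.
#'
#' @param expression A tibble as returned by [read_expression()].
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_expression <- function(expression) {
  stopifnot(is.data.frame(expression))
  if (!identical(names(expression)[[1L]], "gene")) {
    stop("first column must be 'gene'", call. = FALSE)
  }
  if (ncol(expression) < 2L) stop("no sample columns", call. = FALSE)
  dup_g <- unique(expression$gene[duplicated(expression$gene)])
  if (length(dup_g)) {
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  smp <- names(expression)[-1L]
  dup_s <- unique(smp[duplicated(smp)])
  if (length(dup_s)) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  num <- vapply(expression[-1L], is.numeric, logical(1L))
  if (!all(num)) {
    stop("non-numeric sample columns: ",
         paste(smp[!num], collapse = ", "), call. = FALSE)
  }
  if (anyNA(expression)) stop("missing values in expression matrix", call. = FALSE)
  expression
}

#' Read a factorial design table
#'
#' Reads the sample-to-cell assignment: columns `sample_id`, `condition`,
#' `time`, `replicate`. Condition labels must come from the declared
#' vocabulary (default the four arms PBS / MPL / QS21 / AS01); time labels
#' are taken in order of first appearance unless `times` declares an order.
#'
#' @param path Path to a TSV file.
#' @param conditions Allowed condition labels.
#' @param times Optional ordered vector of allowed time labels.
#' @return A tibble with columns `sample_id`, `condition`, `time`,
#'   `replicate`; `time` is a factor with the declared level order.
#' @export
read_design <- function(path,
                        conditions = c("PBS", "MPL", "QS21", "AS01"),
                        times = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_design(d, conditions = conditions, times = times)
}

#' Validate a design tibble
#'
#' @inheritParams read_design
#' @param design A data frame with columns `sample_id`, `condition`, `time`,
#'   `replicate`.
#' @return The validated design tibble.
#' @export
validate_design <- function(design,
                            conditions = c("PBS", "MPL", "QS21", "AS01"),
                            times = NULL) {
  need <- c("sample_id", "condition", "time", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("design is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  design <- tibble::as_tibble(design)[need]
  design$sample_id <- as.character(design$sample_id)
  design$condition <- as.character(design$condition)
  dup <- unique(design$sample_id[duplicated(design$sample_id)])
  if (length(dup)) {
    stop("duplicate sample ids in design: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(design$condition, conditions)
  if (length(bad)) {
    stop("unknown condition labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tl <- if (is.null(times)) unique(as.character(design$time)) else times
  bad_t <- setdiff(as.character(design$time), tl)
  if (length(bad_t)) {
    stop("unknown time labels: ", paste(bad_t, collapse = ", "), call. = FALSE)
  }
  design$time <- factor(as.character(design$time), levels = tl)
  rep_ok <- is.numeric(design$replicate) &&
    all(design$replicate >= 1 & design$replicate == round(design$replicate))
  if (!rep_ok) stop("replicate must be a positive integer", call. = FALSE)
  design$replicate <- as.integer(design$replicate)
  design
}

#' Align an expression matrix with a design table
#'
#' Reorders the sample columns of the expression tibble to the design row
#' order. Samples present in the matrix but absent from the design are
#' dropped with a warning; a design sample missing from the matrix is an
#' error. Alignment is idempotent.
#'
#' @param expression Expression tibble ([read_expression()]).
#' @param design Design tibble ([read_design()]).
#' @return A list with elements `expression` and `design`, aligned.
#' @export
align_samples <- function(expression, design) {
  expression <- validate_expression(expression)
  smp <- names(expression)[-1L]
  missing_in_expr <- setdiff(design$sample_id, smp)
  if (length(missing_in_expr)) {
    stop("design samples absent from expression matrix: ",
         paste(missing_in_expr, collapse = ", "), call. = FALSE)
  }
  if (!length(intersect(design$sample_id, smp))) {
    stop("no samples shared between expression matrix and design",
         call. = FALSE)
  }
  extra <- setdiff(smp, design$sample_id)
  if (length(extra)) {
    warning("dropping ", length(extra),
            " sample(s) absent from design: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  list(
    expression = expression[c("gene", design$sample_id)],
    design = design
  )
}

#' Write a result table
#'
#' Serializes any result tibble as TSV or JSON with a deterministic column
#' order (as given) and numeric columns rounded to `digits` significant
#' digits (default 6). `digits = NULL` writes the shortest representation
#' that round-trips the double exactly.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param digits Significant digits for numeric columns, or `NULL` for full
#'   round-trip precision.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("tsv", "json"), digits = 6) {
  format <- match.arg(format)
  x <- tibble::as_tibble(x)
  if (!is.null(digits)) {
    x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.double),
                                        ~ signif(.x, digits)))
  }
  if (format == "tsv") {
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

# internal: genes x samples numeric matrix with rownames
as_expression_matrix <- function(expression) {
  m <- as.matrix(expression[-1L])
  rownames(m) <- expression$gene
  storage.mode(m) <- "double"
  m
}
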