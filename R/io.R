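#' Read a delimited matrix with missing-value dialects
#'
#' Parses a rectangular CSV/TSV grid into a [masked_matrix()]. Cells equal to
#' one of `missing_tokens` (after whitespace trimming) become non-given
#' entries; every other cell must parse as a real number. Ragged rows,
#' unparseable cells, and rows or columns that end up fully missing raise
#' descriptive errors.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` (default) infers `","` for `.csv`
#'   and tab otherwise.
#' @param header Logical; first row holds column labels.
#' @param index_column Logical; first column holds row labels.
#' @param missing_tokens Character vector of cell values denoting a missing
#'   entry (default: empty string, `"NA"`, `"NaN"`).
#' @return A [masked_matrix()]; row/column labels, when present, are kept as
#'   `dimnames` of its `values`.
#' @export
read_masked_matrix <- function(path, delim = NULL, header = FALSE,
                               index_column = FALSE,
                               missing_tokens = c("", "NA", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  # sentinel keeps trailing empty fields that strsplit would drop
  cells <- strsplit(paste0(lines, delim, "\r"), delim, fixed = TRUE)
  cells <- lapply(cells, function(x) trimws(x[-length(x)]))
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    stop(sprintf("ragged rows in %s: widths %s", path,
                 paste(unique(widths), collapse = ", ")), call. = FALSE)
  }
  col_labels <- NULL
  row_labels <- NULL
  if (header) {
    col_labels <- cells[[1L]]
    cells <- cells[-1L]
    if (length(cells) == 0L) stop("no data rows in ", path, call. = FALSE)
  }
  grid <- do.call(rbind, cells)
  if (index_column) {
    row_labels <- grid[, 1L]
    grid <- grid[, -1L, drop = FALSE]
    if (header) col_labels <- col_labels[-1L]
  }
  if (ncol(grid) == 0L) stop("no data columns in ", path, call. = FALSE)

  given <- !(grid %in% missing_tokens)
  dim(given) <- dim(grid)
  values <- suppressWarnings(as.numeric(grid))
  dim(values) <- dim(grid)
  bad <- given & is.na(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("cell (%d, %d) of %s is not numeric: '%s'",
                 idx[1], idx[2], path, grid[idx[1], idx[2]]), call. = FALSE)
  }
  values[!given] <- NA_real_
  if (any(rowSums(given) == 0L)) {
    stop("matrix in ", path, " has a fully-missing row", call. = FALSE)
  }
  if (any(colSums(given) == 0L)) {
    stop("matrix in ", path, " has a fully-missing column", call. = FALSE)
  }
  if (!is.null(row_labels) || !is.null(col_labels)) {
    dimnames(values) <- list(row_labels, col_labels)
  }
  masked_matrix(values, given)
}

#' Write a matrix as delimited text
#'
#' Serializes a dense matrix or a [masked_matrix()] (masked entries written
#' as `missing_token`). Numbers are formatted with 17 significant digits, so
#' a write/read round trip reproduces finite doubles exactly.
#'
#' @param M Numeric matrix or [masked_matrix()].
#' @param path Output path.
#' @param delim Field delimiter; `NULL` infers from the extension as in
#'   [read_masked_matrix()].
#' @param missing_token String written at masked positions (default `""`).
#' @param header,index_column Write `dimnames` of the matrix as a label row /
#'   column when `TRUE`.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(M, path, delim = NULL, missing_token = "",
                         header = FALSE, index_column = FALSE) {
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is_masked_matrix(M)) {
    vals <- M$values
    given <- M$given
  } else {
    vals <- as_trop_matrix(M)
    given <- matrix(TRUE, nrow(vals), ncol(vals))
  }
  txt <- matrix(missing_token, nrow(vals), ncol(vals))
  txt[given] <- sprintf("%.17g", vals[given])
  if (index_column) {
    labels <- rownames(vals)
    if (is.null(labels)) labels <- paste0("row", seq_len(nrow(vals)))
    txt <- cbind(labels, txt)
  }
  body <- apply(txt, 1, paste, collapse = delim)
  if (header) {
    labels <- colnames(vals)
    if (is.null(labels)) labels <- paste0("col", seq_len(ncol(vals)))
    if (index_column) labels <- c("", labels)
    body <- c(paste(labels, collapse = delim), body)
  }
  writeLines(body, path)
  invisible(path)
}

#' Save / load a fitted model
#'
#' Serializes an `"stmf_model"` to a self-describing JSON container holding
#' the factors, rank, column permutation, error trace and configuration, so
#' that prediction and evaluation can run without refitting. Doubles are
#' written at full precision.
#'
#' @param model An `"stmf_model"` from [stmf()].
#' @param path JSON file path.
#' @return `write_stmf_model` returns `path` invisibly; `read_stmf_model`
#'   returns the reconstructed `"stmf_model"`.
#' @export
write_stmf_model <- function(model, path) {
  if (!inherits(model, "stmf_model")) {
    stop("`model` must be an stmf_model", call. = FALSE)
  }
  payload <- list(
    container = "stmf_model",
    version = 1L,
    rank = model$rank,
    U = ser_matrix(model$U),
    V = ser_matrix(model$V),
    column_permutation = model$column_permutation,
    error_trace = model$error_trace,
    sweeps = model$sweeps,
    config = unclass(model$config)
  )
  # digits = I(17): significant digits, enough for exact double round trips
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_stmf_model
#' @export
read_stmf_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$container, "stmf_model")) {
    stop(path, " is not an stmf model container", call. = FALSE)
  }
  cfg <- payload$config
  config <- stmf_config(rank = cfg$rank, max_iter = cfg$max_iter,
                        init = cfg$init,
                        acol_subset_size = cfg$acol_subset_size,
                        ordering = cfg$ordering, seed = cfg$seed,
                        improvement_tolerance = cfg$improvement_tolerance,
                        update_order = cfg$update_order)
  structure(list(U = deser_matrix(payload$U), V = deser_matrix(payload$V),
                 rank = as.integer(payload$rank),
                 column_permutation = as.integer(payload$column_permutation),
                 error_trace = as.numeric(payload$error_trace),
                 sweeps = as.integer(payload$sweeps),
                 config = config),
            class = "stmf_model")
}

# explicit dim + column-major data: shape survives JSON round trips even for
# single-row/column matrices
ser_matrix <- function(M) list(dim = dim(M), data = as.vector(M))

deser_matrix <- function(x) {
  matrix(as.numeric(x$data), nrow = x$dim[1], ncol = x$dim[2])
}

#' Write and read a logical mask as delimited 0/1 text
#'
#' Sidecar format for held-out-entry masks: `1` marks a masked (test)
#' position, `0` an observed one.
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @param delim Delimiter; `NULL` infers from the extension.
#' @return `write_mask`: `path`, invisibly; `read_mask`: a logical matrix.
#' @export
write_mask <- function(mask, path, delim = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  storage <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  write_matrix(storage, path, delim = delim)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, delim = NULL) {
  M <- read_masked_matrix(path, delim = delim)
  if (any(!M$given)) stop("mask file has missing cells: ", path, call. = FALSE)
  vals <- M$values
  if (!all(vals %in% c(0, 1))) {
    stop("mask file must contain only 0/1: ", path, call. = FALSE)
  }
  matrix(vals == 1, nrow(vals), ncol(vals))
}
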