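#' Read an observations-by-features matrix
#'
#' Supports delimited text (CSV/TSV, first row = feature names, optional
#' first column of row names) and MatrixMarket coordinate files with
#' plain-text sidecar files of row and column names (`<path>.rownames` /
#' `<path>.colnames`, one name per line). Single-cell matrices are often
#' stored genes x cells; set `observations_in_rows = FALSE` to transpose
#' on read.
#'
#' @param path File path; format inferred from the extension (`.csv`,
#'   `.tsv`/`.txt`, `.mtx`) unless `format` is given.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @param observations_in_rows Logical; if `FALSE` the parsed matrix is
#'   transposed so observations end up in rows.
#' @param row_names Logical; whether the first column of a delimited file
#'   holds row names.
#' @return A numeric matrix with `dimnames` when names are available.
#' @export
read_matrix <- function(path, format = NULL, observations_in_rows = TRUE,
                        row_names = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  m <- if (format == "mtx") {
    mm <- as.matrix(Matrix::readMM(path))
    rn <- paste0(path, ".rownames")
    cn <- paste0(path, ".colnames")
    if (file.exists(rn)) {
      nms <- readLines(rn)
      if (length(nms) != nrow(mm)) {
        stop("row-name sidecar has ", length(nms), " entries for ",
             nrow(mm), " rows", call. = FALSE)
      }
      rownames(mm) <- nms
    }
    if (file.exists(cn)) {
      nms <- readLines(cn)
      if (length(nms) != ncol(mm)) {
        stop("column-name sidecar has ", length(nms), " entries for ",
             ncol(mm), " columns", call. = FALSE)
      }
      colnames(mm) <- nms
    }
    mm
  } else {
    delim <- if (format == "csv") "," else "\t"
    tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    if (nrow(tb) == 0L || ncol(tb) == 0L) {
      stop("no data parsed from ", path, call. = FALSE)
    }
    rn <- NULL
    if (row_names && !is.numeric(tb[[1L]])) {
      rn <- as.character(tb[[1L]])
      tb <- tb[, -1L, drop = FALSE]
    }
    bad <- !vapply(tb, is.numeric, logical(1L))
    if (any(bad)) {
      stop("non-numeric cells in column(s): ",
           paste(names(tb)[bad], collapse = ", "), call. = FALSE)
    }
    mm <- as.matrix(tb)
    rownames(mm) <- rn
    mm
  }
  if (!observations_in_rows) m <- t(m)
  m
}

#' Write a matrix in a supported format
#'
#' Companion to [read_matrix()]; round-trips exactly at the precision of
#' the text representation (17 significant digits for delimited formats).
#' @param x Numeric matrix.
#' @inheritParams read_matrix
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"),
                    path)
    if (!is.null(rownames(x))) writeLines(rownames(x), paste0(path, ".rownames"))
    if (!is.null(colnames(x))) writeLines(colnames(x), paste0(path, ".colnames"))
  } else {
    tb <- tibble::as_tibble(x, .name_repair = "minimal")
    if (is.null(colnames(x))) names(tb) <- paste0("V", seq_len(ncol(x)))
    if (!is.null(rownames(x))) tb <- dplyr::bind_cols(tibble::tibble(row = rownames(x)), tb)
    delim <- if (format == "csv") "," else "\t"
    readr::write_delim(tb, path, delim = delim)
  }
  invisible(path)
}

#' Count-matrix preprocessing conventions for scRNA-seq
#'
#' Optional quality-control filtering followed by per-cell total-count
#' normalisation, a `log2(x + 1)` transform, and selection of the
#' highest-variance features. All steps are off by default so the function
#' is the identity unless options are set explicitly; the QC thresholds
#' have no privileged defaults and must be chosen by the analyst.
#'
#' @param x Cells x genes non-negative count matrix.
#' @param min_features Drop cells expressing fewer than this many genes.
#' @param min_counts Drop cells with a smaller total count.
#' @param max_mito_frac Drop cells whose summed counts over mitochondrial
#'   genes (identified by `mito_prefix` on the column name) exceed this
#'   fraction of the cell total.
#' @param mito_prefix Gene-name prefix marking mitochondrial genes.
#' @param normalize Logical; divide each cell by its total count and
#'   multiply by `target_scale`.
#' @param target_scale Scale after normalisation; default is the median
#'   cell total.
#' @param log2p1 Logical; apply `log2(x + 1)` after normalisation.
#' @param top_var Keep only this many highest-variance columns (ties broken
#'   by column order); `NULL` keeps all.
#' @return The processed matrix (cells in rows).
#' @export
preprocess_matrix <- function(x, min_features = NULL, min_counts = NULL,
                              max_mito_frac = NULL, mito_prefix = "MT-",
                              normalize = FALSE, target_scale = NULL,
                              log2p1 = FALSE, top_var = NULL) {
  x <- as.matrix(x)
  count_mode <- !is.null(min_features) || !is.null(min_counts) ||
    !is.null(max_mito_frac) || normalize
  if (count_mode && any(x < 0)) {
    stop("count matrix must be non-negative", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(x))
  totals <- rowSums(x)
  if (!is.null(min_features)) keep <- keep & rowSums(x > 0) >= min_features
  if (!is.null(min_counts)) keep <- keep & totals >= min_counts
  if (!is.null(max_mito_frac)) {
    mito <- startsWith(colnames(x) %||% character(ncol(x)), mito_prefix)
    frac <- if (any(mito)) rowSums(x[, mito, drop = FALSE]) / pmax(totals, 1) else 0
    keep <- keep & frac <= max_mito_frac
  }
  if (!any(keep)) stop("all cells removed by QC filtering", call. = FALSE)
  x <- x[keep, , drop = FALSE]
  if (normalize) {
    totals <- rowSums(x)
    if (is.null(target_scale)) target_scale <- stats::median(totals)
    x <- x / pmax(totals, .Machine$double.eps) * target_scale
  }
  if (log2p1) x <- log2(x + 1)
  if (!is.null(top_var)) {
    v <- apply(x, 2L, stats::var)
    ord <- order(-v)  # stable: ties keep column order
    x <- x[, sort(ord[seq_len(min(top_var, ncol(x)))]), drop = FALSE]
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
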