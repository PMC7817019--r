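#' Read an expression matrix
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx`}{Matrix Market coordinate file (1-based indices) with
#'     companion one-column label files `<prefix>_barcodes.tsv` (cells)
#'     and `<prefix>_genes.tsv` (genes), where `<prefix>` strips the
#'     `.mtx` suffix. Stored cells x genes; if the label files match the
#'     transposed orientation instead, the matrix is transposed with a
#'     message.}
#'   \item{`csv` / `tsv`}{Dense table, header row = gene labels, first
#'     column = cell labels.}
#'   \item{`h5`}{HDF5 container with datasets `/X` (dense, cells x genes)
#'     or sparse group `/X` (`data`, `indices`, `indptr`, `shape`; CSR
#'     over cells), plus `/obs_names` and `/var_names`.}
#' }
#'
#' @param path input file.
#' @param format one of `"auto"` (by extension), `"mtx"`, `"csv"`,
#'   `"tsv"`, `"h5"`.
#' @return Expression matrix, cells in rows (sparse for `mtx`/sparse-h5,
#'   dense otherwise), with cell/gene dimnames.
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "csv", "tsv", "h5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     txt = "tsv", h5 = "h5", hdf5 = "h5",
                     stop(sprintf("cannot infer format of '%s'", path),
                          call. = FALSE))
  switch(format,
         mtx = .read_mtx(path),
         csv = .read_delim(path, ","),
         tsv = .read_delim(path, "\t"),
         h5 = .read_h5(path))
}

.label_paths <- function(path) {
  prefix <- sub("\\.mtx$", "", path)
  list(cells = paste0(prefix, "_barcodes.tsv"),
       genes = paste0(prefix, "_genes.tsv"))
}

.read_labels <- function(p) {
  if (!file.exists(p)) return(NULL)
  readLines(p)
}

.read_mtx <- function(path) {
  m <- tryCatch(as(Matrix::readMM(path), "CsparseMatrix"),
                error = function(e)
                  stop(sprintf("malformed Matrix Market file '%s': %s",
                               path, conditionMessage(e)), call. = FALSE))
  lp <- .label_paths(path)
  cells <- .read_labels(lp$cells)
  genes <- .read_labels(lp$genes)
  if (!is.null(cells) && !is.null(genes)) {
    if (length(cells) == nrow(m) && length(genes) == ncol(m)) {
      # stored cells x genes
    } else if (length(cells) == ncol(m) && length(genes) == nrow(m)) {
      message("matrix stored genes x cells; transposing to cells x genes")
      m <- Matrix::t(m)
    } else {
      stop(sprintf(
        "label length mismatch: %d barcodes / %d genes vs %d x %d matrix",
        length(cells), length(genes), nrow(m), ncol(m)), call. = FALSE)
    }
    dimnames(m) <- list(cells, genes)
  }
  if (prod(dim(m)) == 0L) stop("empty matrix", call. = FALSE)
  as(m, "generalMatrix")
}

.read_delim <- function(path, sep) {
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L)
    stop(sprintf("empty or malformed table '%s'", path), call. = FALSE)
  cells <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- cells
  m
}

.read_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading HDF5 requires the rhdf5 package", call. = FALSE)
  contents <- rhdf5::h5ls(path)
  cells <- as.character(rhdf5::h5read(path, "obs_names"))
  genes <- as.character(rhdf5::h5read(path, "var_names"))
  if ("X" %in% contents$name[contents$otype == "H5I_GROUP"]) {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    shape <- as.integer(rhdf5::h5read(path, "X/shape"))
    # p are row pointers (CSR over cells), j the gene indices
    m <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                              dims = shape)
  } else {
    m <- rhdf5::h5read(path, "X")
  }
  if (nrow(m) != length(cells) || ncol(m) != length(genes))
    stop("label length mismatch in HDF5 container", call. = FALSE)
  dimnames(m) <- list(cells, genes)
  if (.is_sparse(m)) as(m, "generalMatrix") else m
}

#' Write an expression matrix
#'
#' Inverse of [read_matrix()]; all writers preserve full double precision
#' so `read_matrix(write_matrix(x))` reproduces `x` exactly. For `mtx`,
#' companion `<prefix>_barcodes.tsv` / `<prefix>_genes.tsv` label files
#' are written next to the matrix.
#'
#' @param x expression matrix, cells in rows.
#' @param path output file.
#' @param format as in [read_matrix()].
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("auto", "mtx", "csv", "tsv", "h5")) {
  format <- match.arg(format)
  x <- .as_input_matrix(x, "x")
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     txt = "tsv", h5 = "h5", hdf5 = "h5",
                     stop(sprintf("cannot infer format of '%s'", path),
                          call. = FALSE))
  switch(format,
         mtx = .write_mtx(x, path),
         csv = .write_delim(x, path, ","),
         tsv = .write_delim(x, path, "\t"),
         h5 = .write_h5(x, path))
  invisible(path)
}

# Matrix Market coordinate writer at full double precision
# (Matrix::writeMM truncates to %g precision, which breaks float
# round-trips; the format itself is three columns after a header).
.write_mtx <- function(x, path) {
  xs <- as(as(x, "CsparseMatrix"), "generalMatrix")
  tr <- Matrix::mat2triplet(xs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(xs), ncol(xs), length(tr$x)), con)
  if (length(tr$x))
    writeLines(sprintf("%d %d %.17g", tr$i, tr$j, tr$x), con)
  lp <- .label_paths(path)
  if (!is.null(rownames(x))) writeLines(rownames(x), lp$cells)
  if (!is.null(colnames(x))) writeLines(colnames(x), lp$genes)
  invisible(path)
}

.write_delim <- function(x, path, sep) {
  xd <- .dense(x)
  cells <- rownames(xd) %||% sprintf("cell%04d", seq_len(nrow(xd)))
  genes <- colnames(xd) %||% sprintf("gene%04d", seq_len(ncol(xd)))
  body <- matrix(sprintf("%.17g", xd), nrow(xd), ncol(xd))
  dt <- data.frame(cell = cells, body, stringsAsFactors = FALSE)
  names(dt) <- c("cell", genes)
  data.table::fwrite(dt, path, sep = sep, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_h5 <- function(x, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("writing HDF5 requires the rhdf5 package", call. = FALSE)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  cells <- rownames(x) %||% sprintf("cell%04d", seq_len(nrow(x)))
  genes <- colnames(x) %||% sprintf("gene%04d", seq_len(ncol(x)))
  if (.is_sparse(x)) {
    xr <- as(Matrix::t(x), "CsparseMatrix")  # CSC of t(x) == CSR of x
    rhdf5::h5createGroup(path, "X")
    rhdf5::h5write(xr@x, path, "X/data")
    rhdf5::h5write(xr@i, path, "X/indices")
    rhdf5::h5write(xr@p, path, "X/indptr")
    rhdf5::h5write(dim(x), path, "X/shape")
  } else {
    rhdf5::h5write(.dense(x), path, "X")
  }
  rhdf5::h5write(cells, path, "obs_names")
  rhdf5::h5write(genes, path, "var_names")
  rhdf5::H5close()
  invisible(path)
}
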