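#' Read a MatrixMarket cell-by-peak dataset
#'
#' Reads a sparse count matrix in MatrixMarket coordinate format together
#' with its barcode and peak sidecar files (the deposit format of processed
#' scATAC-seq count matrices on GEO). The on-disk orientation is
#' auto-detected from the sidecar lengths: if the matrix is peaks-by-cells
#' it is transposed so that the result is always cells-by-peaks. A square
#' matrix with equally long sidecars is ambiguous and requires
#' `orientation` to be given explicitly.
#'
#' @param matrix_path Path to the `.mtx` or `.mtx.gz` file.
#' @param barcodes_path Path to a one-column barcode file (optionally with
#'   further tab-separated columns; the first is used).
#' @param peaks_path Path to the peak sidecar: either one peak string per
#'   line (`chr1:100-500` or `chr1_100_500`) or a 3+ column BED-like TSV.
#' @param kind What the entries count: `"reads"`, `"fragments"` or
#'   `"binary"`.
#' @param orientation `"auto"` (default), `"cells_x_peaks"` or
#'   `"peaks_x_cells"`.
#' @return A [count_matrix].
#' @export
read_mtx_dataset <- function(matrix_path, barcodes_path, peaks_path,
                             kind = c("fragments", "reads", "binary"),
                             orientation = c("auto", "cells_x_peaks",
                                             "peaks_x_cells")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  for (f in c(matrix_path, barcodes_path, peaks_path))
    if (!file.exists(f)) stop("file not found: ", f)
  m <- Matrix::readMM(matrix_path)
  barcodes <- read_sidecar_column(barcodes_path)
  peaks <- read_peak_sidecar(peaks_path)
  nb <- length(barcodes); np <- nrow(peaks)
  if (orientation == "auto") {
    if (nrow(m) == nb && ncol(m) == np) {
      orientation <- "cells_x_peaks"
    } else if (nrow(m) == np && ncol(m) == nb) {
      if (nb == np)
        stop("square matrix with equal sidecar lengths: orientation is ",
             "ambiguous, pass orientation= explicitly")
      orientation <- "peaks_x_cells"
    } else if (nrow(m) != nb && nrow(m) != np) {
      stop("dimension mismatch: matrix has ", nrow(m), " x ", ncol(m),
           " but barcodes sidecar has ", nb, " entries and peaks sidecar ",
           np)
    } else {
      bad <- if (nrow(m) == nb) "peaks" else "barcodes"
      stop("dimension mismatch in the ", bad, " sidecar (matrix ",
           nrow(m), " x ", ncol(m), ", barcodes ", nb, ", peaks ", np, ")")
    }
  }
  if (orientation == "peaks_x_cells") m <- Matrix::t(m)
  if (nrow(m) != nb)
    stop("dimension mismatch in the barcodes sidecar: matrix has ",
         nrow(m), " rows, sidecar ", nb, " entries")
  if (ncol(m) != np)
    stop("dimension mismatch in the peaks sidecar: matrix has ",
         ncol(m), " columns, sidecar ", np, " entries")
  count_matrix(m, kind = kind, cells = cell_table(barcodes), peaks = peaks)
}

read_sidecar_column <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  as.character(x[[1]])
}

read_peak_sidecar <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  if (ncol(x) >= 3 && is.numeric(x[[2]]) && is.numeric(x[[3]])) {
    peak_set(x[[1]], x[[2]], x[[3]])
  } else {
    parse_peak_strings(x[[1]])
  }
}

#' Write a MatrixMarket cell-by-peak dataset
#'
#' Inverse of [read_mtx_dataset]: writes `matrix.mtx`, `barcodes.tsv` and
#' `peaks.tsv` (colon-dash peak strings) into a directory.
#'
#' @param x A [count_matrix].
#' @param dir Output directory (created if missing).
#' @param transpose Write peaks-by-cells instead of cells-by-peaks.
#' @return Invisibly, the three file paths.
#' @export
write_mtx_dataset <- function(x, dir, transpose = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "peaks.tsv"))
  m <- x$values
  if (transpose) m <- Matrix::t(m)
  Matrix::writeMM(m, paths[1])
  writeLines(x$cells$barcode, paths[2])
  writeLines(x$peaks$peak_id, paths[3])
  invisible(paths)
}

#' Read a 10x-style fragment file
#'
#' Reads a tab-separated (optionally gzipped) fragment file with columns
#' chrom, start, end, barcode and optionally a support count. Coordinates
#' are passed through unchanged (0-based start, exclusive end; any Tn5
#' offset correction is assumed to have been applied upstream). Records
#' whose barcode is not in the whitelist are dropped; records with
#' `start >= end` are skipped with a warning and counted.
#'
#' @param fragments_path Path to `fragments.tsv` or `fragments.tsv.gz`.
#'   Lines starting with `#` are comments.
#' @param barcode_whitelist Optional character vector; `NULL` keeps all
#'   barcodes.
#' @return A data.frame with columns `chrom`, `start`, `end`, `barcode`,
#'   in file order, with attributes `n_input`, `n_filtered` (barcode not in
#'   whitelist) and `n_malformed` (skipped records).
#' @export
read_fragments <- function(fragments_path, barcode_whitelist = NULL) {
  if (!file.exists(fragments_path))
    stop("file not found: ", fragments_path)
  # decompress through a connection (gzfile reads plain files too) and drop
  # '#' comment lines before parsing, so they cannot confuse column inference
  con <- gzfile(fragments_path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    stop("fragment file has no data records")
  x <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                         data.table = FALSE,
                         colClasses = list(character = 1))
  if (ncol(x) < 4)
    stop("fragment file must have >= 4 tab-separated columns")
  out <- data.frame(chrom = as.character(x[[1]]),
                    start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]),
                    barcode = as.character(x[[4]]),
                    stringsAsFactors = FALSE)
  n_input <- nrow(out)
  malformed <- !is.na(out$start) & !is.na(out$end) & out$start >= out$end
  malformed <- malformed | is.na(out$start) | is.na(out$end)
  n_malformed <- sum(malformed)
  if (n_malformed > 0) {
    warning(n_malformed, " malformed fragment record(s) skipped ",
            "(start >= end)")
    out <- out[!malformed, , drop = FALSE]
  }
  n_filtered <- 0L
  if (!is.null(barcode_whitelist)) {
    keep <- out$barcode %in% barcode_whitelist
    n_filtered <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_input") <- n_input
  attr(out, "n_filtered") <- n_filtered
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Read peaks from a BED file
#'
#' BED3+ (0-based half-open), tab-separated, track/comment lines ignored.
#' @param path Path to the BED file.
#' @return A [peak_set].
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  x <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                         data.table = FALSE, fill = TRUE)
  if (ncol(x) < 3) stop("BED file must have >= 3 columns")
  peak_set(x[[1]], x[[2]], x[[3]])
}

#' Read a cell metadata TSV
#'
#' Expects a header with at least a `barcode` column; `batch` and
#' `cell_type` columns are used when present.
#' @param path Path to the TSV.
#' @return A [cell_table].
#' @export
read_cell_metadata <- function(path) {
  x <- data.table::fread(path, header = TRUE, sep = "\t",
                         data.table = FALSE)
  if (!"barcode" %in% names(x)) stop("metadata must have a 'barcode' column")
  cell_table(x$barcode,
             batch = if ("batch" %in% names(x)) x$batch else NULL,
             cell_type = if ("cell_type" %in% names(x)) x$cell_type else NULL,
             total_fragments = if ("total_fragments" %in% names(x))
               x$total_fragments else NULL)
}

#' Write / read a latent embedding as TSV
#'
#' The file has a `barcode` column followed by one numeric column per
#' latent dimension. A write/read round trip reproduces the matrix to
#' better than 1e-6.
#'
#' @param embedding Numeric matrix, cells in rows.
#' @param cell_table A [cell_table] with one row per embedding row.
#' @param path Output path.
#' @return `write_embedding`: invisibly, `path`. `read_embedding`: a list
#'   with `embedding` (numeric matrix, barcodes as rownames) and
#'   `barcode`.
#' @export
write_embedding <- function(embedding, cell_table, path) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != nrow(cell_table))
    stop("embedding rows (", nrow(embedding),
         ") do not match cell table (", nrow(cell_table), ")")
  d <- ncol(embedding)
  df <- data.frame(barcode = cell_table$barcode, stringsAsFactors = FALSE)
  if (d > 0 && nrow(embedding) > 0) {
    em <- as.data.frame(format(embedding, digits = 10, scientific = TRUE,
                               trim = TRUE))
    names(em) <- sprintf("latent_%d", seq_len(d))
    df <- cbind(df, em)
  } else if (d > 0) {
    for (j in seq_len(d)) df[[sprintf("latent_%d", j)]] <- numeric(0)
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  x <- data.table::fread(path, header = TRUE, sep = "\t",
                         data.table = FALSE)
  emb <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(emb) <- "double"
  rownames(emb) <- x[[1]]
  list(embedding = emb, barcode = as.character(x[[1]]))
}
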