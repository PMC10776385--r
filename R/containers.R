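#' Peak region set
#'
#' A set of genomic peak intervals in 0-based, half-open coordinates
#' (the dialect of 10x fragment files and BED). Peaks are the feature set of
#' the cell-by-peak count matrix.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, exclusive end; must satisfy `start < end`.
#' @param peak_id Optional identifiers; defaults to `"chrom:start-end"`.
#'
#' @return A `peak_set` object (a data.frame with columns `chrom`, `start`,
#'   `end`, `peak_id`).
#' @export
peak_set <- function(chrom, start, end, peak_id = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  if (any(is.na(start)) || any(is.na(end)))
    stop("peak coordinates contain NA")
  bad <- which(start >= end)
  if (length(bad))
    stop("peak start >= end at index ", bad[1])
  if (is.null(peak_id))
    peak_id <- sprintf("%s:%d-%d", chrom, start, end)
  if (anyDuplicated(peak_id))
    stop("peak_ids are not unique")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    peak_id = as.character(peak_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Parse peak identifier strings
#'
#' Accepts both the colon-dash dialect (`"chr1:100-500"`) and the
#' underscore dialect used by some GEO deposits (`"chr1_100_500"`);
#' identifiers are normalized internally to the colon-dash form.
#'
#' @param x Character vector of peak strings.
#' @return A [peak_set].
#' @export
parse_peak_strings <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  ok <- lengths(m) == 4L
  if (!all(ok)) {
    m2 <- regmatches(x[!ok], regexec("^(.+)_([0-9]+)_([0-9]+)$", x[!ok]))
    ok2 <- lengths(m2) == 4L
    if (!all(ok2))
      stop("unparseable peak string at line ", which(!ok)[which(!ok2)[1]],
           ": '", x[!ok][which(!ok2)[1]], "'")
    m[!ok] <- m2
  }
  m <- do.call(rbind, m)
  peak_set(m[, 2], as.integer(m[, 3]), as.integer(m[, 4]))
}

#' Convert a peak set to GRanges
#'
#' 0-based half-open intervals become 1-based closed `GRanges`.
#' @param peaks A [peak_set].
#' @return A `GRanges` object with a `peak_id` metadata column.
#' @export
peaks_to_granges <- function(peaks) {
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  S4Vectors::mcols(gr)$peak_id <- peaks$peak_id
  gr
}

#' Per-cell annotation table
#'
#' Holds barcode, batch label (the covariate `s_c` fed to the decoder),
#' optional cell-type label and the per-cell total fragment count used for
#' the depth offset.
#'
#' @param barcode Character vector of unique cell barcodes.
#' @param batch Batch labels (coerced to factor); defaults to one batch.
#' @param cell_type Optional cell-type labels.
#' @param total_fragments Optional non-negative integers; filled in from the
#'   count matrix when a [count_matrix] is built.
#' @return A `cell_table` object (a data.frame).
#' @export
cell_table <- function(barcode, batch = NULL, cell_type = NULL,
                       total_fragments = NULL) {
  barcode <- as.character(barcode)
  n <- length(barcode)
  if (anyDuplicated(barcode))
    stop("barcodes are not unique")
  if (is.null(batch)) batch <- rep("batch1", n)
  batch <- factor(batch)
  if (length(batch) != n) stop("batch length does not match barcodes")
  out <- data.frame(barcode = barcode, batch = batch,
                    stringsAsFactors = FALSE)
  if (!is.null(cell_type)) {
    if (length(cell_type) != n) stop("cell_type length does not match")
    out$cell_type <- factor(cell_type)
  }
  if (!is.null(total_fragments)) {
    if (length(total_fragments) != n) stop("total_fragments length mismatch")
    if (any(total_fragments < 0)) stop("total_fragments must be >= 0")
    out$total_fragments <- as.numeric(total_fragments)
  }
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Sparse cell-by-peak count matrix
#'
#' The central container: a sparse non-negative integer matrix of cells by
#' peaks, tagged with what its entries count (`reads` are deduplicated
#' fragment ends as produced by the standard 10x pipeline, `fragments` are
#' Tn5 fragments, `binary` is a 0/1 accessibility indicator).
#'
#' @param values Matrix-like (dense or `Matrix` sparse) of non-negative
#'   counts, cells in rows.
#' @param kind One of `"reads"`, `"fragments"`, `"binary"`.
#' @param cells Optional [cell_table] (row annotation); built from rownames
#'   or generated if absent.
#' @param peaks Optional [peak_set] (column annotation).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(values, kind = c("fragments", "reads", "binary"),
                         cells = NULL, peaks = NULL) {
  kind <- match.arg(kind)
  values <- methods::as(methods::as(methods::as(
    Matrix::Matrix(values, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  if (any(values@x < 0)) stop("count matrix entries must be >= 0")
  if (any(values@x != round(values@x))) stop("count matrix entries must be integers")
  if (kind == "binary" && any(values@x > 1))
    stop("kind = 'binary' requires entries in {0, 1}")
  n <- nrow(values); p <- ncol(values)
  if (is.null(cells)) {
    bc <- rownames(values)
    if (is.null(bc)) bc <- sprintf("cell%d", seq_len(n))
    cells <- cell_table(bc)
  }
  if (!inherits(cells, "cell_table")) stop("cells must be a cell_table")
  if (nrow(cells) != n) stop("cell_table length does not match matrix rows")
  if (is.null(peaks)) {
    pid <- colnames(values)
    if (!is.null(pid) && all(grepl("[:_]", pid))) {
      peaks <- parse_peak_strings(pid)
    } else {
      peaks <- peak_set(rep("chrU", p), seq_len(p) * 1000L,
                        seq_len(p) * 1000L + 500L)
    }
  }
  if (!inherits(peaks, "peak_set")) stop("peaks must be a peak_set")
  if (nrow(peaks) != p) stop("peak_set length does not match matrix columns")
  rownames(values) <- cells$barcode
  colnames(values) <- peaks$peak_id
  if (kind != "binary" || is.null(cells$total_fragments))
    cells$total_fragments <- Matrix::rowSums(values)
  structure(list(values = values, kind = kind, cells = cells, peaks = peaks),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d cells x %d peaks, %d nonzero (%.2f%%)\n",
              x$kind, nrow(x$values), ncol(x$values),
              Matrix::nnzero(x$values),
              100 * Matrix::nnzero(x$values) / prod(dim(x$values))))
  cat(sprintf("  batches: %s\n",
              paste(levels(x$cells$batch), collapse = ", ")))
  if (!is.null(x$cells$cell_type))
    cat(sprintf("  cell types: %s\n",
                paste(levels(x$cells$cell_type), collapse = ", ")))
  invisible(x)
}

#' Binarize a count matrix
#'
#' Thresholds counts at one or more (`y = 1` iff `x > 0`), the conventional
#' open/closed indicator.
#' @param x A [count_matrix].
#' @return A [count_matrix] with `kind = "binary"`.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  v <- x$values
  v@x <- as.numeric(v@x > 0)
  v <- Matrix::drop0(v)
  cells <- x$cells  # keep fragment totals from the source matrix
  out <- count_matrix(v, kind = "binary", cells = cells, peaks = x$peaks)
  out
}

# internal: coerce a count_matrix or plain matrix to base dense matrix
as_dense <- function(x) {
  if (inherits(x, "count_matrix")) x <- x$values
  as.matrix(x)
}
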