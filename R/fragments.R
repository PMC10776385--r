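#' Convert read counts to approximate fragment counts
#'
#' The standard 10x pipeline counts deduplicated fragment ends (reads), so
#' per-peak counts are predominantly even: both ends of a fragment usually
#' fall inside the peak, and odd counts arise only when one end lands
#' outside. Fragment counts are estimated by rounding every odd read count
#' up to the next even number and halving, i.e. each entry `r` becomes
#' `ceiling(r / 2)`. The sparsity pattern is unchanged. This is a
#' matrix-level approximation applied to the counts, not to alignments.
#'
#' @param read_matrix A [count_matrix] with `kind = "reads"`.
#' @return A [count_matrix] with `kind = "fragments"`.
#' @export
reads_to_fragments <- function(read_matrix) {
  stopifnot(inherits(read_matrix, "count_matrix"))
  if (read_matrix$kind != "reads")
    stop("reads_to_fragments expects kind = 'reads', got '",
         read_matrix$kind, "'")
  v <- read_matrix$values
  v@x <- ceiling(v@x / 2)
  cells <- read_matrix$cells
  cells$total_fragments <- NULL
  count_matrix(v, kind = "fragments", cells = cells,
               peaks = read_matrix$peaks)
}

#' Count fragments in peak regions
#'
#' Builds the cell-by-peak fragment count matrix from fragment records. A
#' fragment is counted in every peak it overlaps by at least 1 bp (so a
#' fragment spanning two peaks increments both), once per peak. Fragments
#' on chromosomes absent from the peak set are ignored (their number is
#' reported in the `n_off_peak_chrom` attribute).
#'
#' @param fragments A data.frame as returned by [read_fragments] (columns
#'   `chrom`, `start`, `end`, `barcode`; 0-based half-open).
#' @param peaks A [peak_set].
#' @param barcodes Character vector of unique barcodes defining the rows of
#'   the output; fragments with other barcodes are dropped.
#' @param batch Optional batch labels aligned with `barcodes`.
#' @return A [count_matrix] with `kind = "fragments"`.
#' @export
count_fragments_in_peaks <- function(fragments, peaks, barcodes,
                                     batch = NULL) {
  stopifnot(inherits(peaks, "peak_set"))
  if (nrow(peaks) == 0) stop("peak set is empty")
  if (anyDuplicated(barcodes)) stop("barcodes are not unique")
  cidx <- match(fragments$barcode, barcodes)
  keep <- !is.na(cidx)
  fragments <- fragments[keep, , drop = FALSE]
  cidx <- cidx[keep]
  off_chrom <- !(fragments$chrom %in% unique(peaks$chrom))
  n_off <- sum(off_chrom)
  fragments <- fragments[!off_chrom, , drop = FALSE]
  cidx <- cidx[!off_chrom]
  n <- length(barcodes); p <- nrow(peaks)
  if (nrow(fragments) == 0) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, p))
  } else {
    frag_gr <- GenomicRanges::GRanges(
      seqnames = fragments$chrom,
      ranges = IRanges::IRanges(start = fragments$start + 1L,
                                end = fragments$end))
    hits <- GenomicRanges::findOverlaps(frag_gr, peaks_to_granges(peaks),
                                        minoverlap = 1L)
    m <- Matrix::sparseMatrix(
      i = cidx[S4Vectors::queryHits(hits)],
      j = S4Vectors::subjectHits(hits),
      x = rep(1, length(hits)), dims = c(n, p))
  }
  out <- count_matrix(m, kind = "fragments",
                      cells = cell_table(barcodes, batch = batch),
                      peaks = peaks)
  attr(out, "n_off_peak_chrom") <- n_off
  out
}

#' Filter peaks by detection rate
#'
#' Keeps peaks detected (nonzero) in at least `min_cell_fraction` of the
#' cells; the boundary is inclusive, so with 100 cells and the default 1%
#' threshold a peak seen in exactly one cell is kept.
#'
#' @param matrix A [count_matrix].
#' @param min_cell_fraction Fraction in (0, 1], default 0.01.
#' @return A [count_matrix] restricted to the kept peaks, with a
#'   `kept_peaks` attribute giving the original column indices.
#' @export
filter_peaks <- function(matrix, min_cell_fraction = 0.01) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (min_cell_fraction <= 0 || min_cell_fraction > 1)
    stop("min_cell_fraction must be in (0, 1]")
  n <- nrow(matrix$values)
  detected <- unname(Matrix::colSums(matrix$values > 0))
  keep <- which(detected / n >= min_cell_fraction)
  if (length(keep) == 0)
    stop("all peaks removed at min_cell_fraction = ", min_cell_fraction,
         "; lower the threshold")
  cells <- matrix$cells
  cells$total_fragments <- NULL
  out <- count_matrix(matrix$values[, keep, drop = FALSE],
                      kind = matrix$kind, cells = cells,
                      peaks = {
                        ps <- matrix$peaks[keep, , drop = FALSE]
                        class(ps) <- c("peak_set", "data.frame")
                        ps
                      })
  attr(out, "kept_peaks") <- keep
  out
}

#' Per-peak mean and variance across cells
#'
#' The count distribution diagnostic that separates read from fragment
#' counting: fragment counts are approximately Poisson across cells of a
#' homogeneous population (variance equal to mean), whereas read counts —
#' roughly twice the fragments — have variance about twice the mean.
#' Computed on the sparse matrix without densifying; the variance is the
#' unbiased (n - 1) sample variance.
#'
#' @param matrix A [count_matrix] with at least 2 cells.
#' @return A data.frame with columns `peak_id`, `mean`, `variance` and
#'   `ratio` (variance / mean, `NA` where the mean is 0).
#' @export
mean_variance_profile <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  n <- nrow(matrix$values)
  if (n < 2) stop("variance undefined for a single cell")
  v <- matrix$values
  mu <- Matrix::colSums(v) / n
  ex2 <- Matrix::colSums(v^2) / n
  va <- (ex2 - mu^2) * n / (n - 1)
  va <- pmax(va, 0)
  data.frame(peak_id = matrix$peaks$peak_id, mean = mu, variance = va,
             ratio = ifelse(mu > 0, va / mu, NA_real_),
             stringsAsFactors = FALSE)
}

#' Count distribution summary with parity diagnostic
#'
#' Tabulates the entry counts of the matrix (counts above `max_count`
#' pooled into the last bin), the fraction of nonzero entries above the
#' standard binarization threshold of one, and the even/odd parity ratio:
#' (number of entries with even count >= 2) / (number with odd count).
#' Read-count matrices show a strong even excess (reads come in pairs);
#' fragment-count matrices do not.
#'
#' @param matrix A [count_matrix].
#' @param max_count Histogram upper bound, >= 2.
#' @return A list with `histogram` (named vector over 0..max_count, last
#'   bin pooled), `fraction_nonzero_gt1`, `even_odd_ratio` (may be `Inf`),
#'   and `degenerate` (`TRUE` for an all-zero matrix, in which case the
#'   fractions are reported as 0).
#' @export
count_distribution <- function(matrix, max_count = 10L) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (max_count < 2) stop("max_count must be >= 2")
  x <- matrix$values@x
  x <- x[x > 0]
  total <- prod(dim(matrix$values))
  hist <- integer(max_count + 1)
  names(hist) <- 0:max_count
  hist[1] <- total - length(x)
  if (length(x)) {
    xb <- pmin(x, max_count)
    tab <- table(factor(xb, levels = 1:max_count))
    hist[-1] <- as.integer(tab)
  }
  if (length(x) == 0) {
    return(list(histogram = hist, fraction_nonzero_gt1 = 0,
                even_odd_ratio = 0, degenerate = TRUE))
  }
  n_even <- sum(x %% 2 == 0)  # even counts are >= 2 by construction
  n_odd <- sum(x %% 2 == 1)
  list(histogram = hist,
       fraction_nonzero_gt1 = mean(x > 1),
       even_odd_ratio = if (n_odd == 0) Inf else n_even / n_odd,
       degenerate = FALSE)
}

#' Binomially downsample a count matrix
#'
#' Replaces each entry by a Binomial(count, fraction) draw, emulating a
#' shallower sequencing run; used to study how model performance depends
#' on depth.
#'
#' @param matrix A [count_matrix] (`reads` or `fragments`).
#' @param fraction Retention probability in (0, 1].
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A [count_matrix] of the same kind.
#' @export
downsample_counts <- function(matrix, fraction, seed = 1L) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  v <- matrix$values
  if (fraction < 1) {
    set.seed(as.integer(seed))
    v@x <- as.numeric(stats::rbinom(length(v@x), size = v@x,
                                    prob = fraction))
    v <- Matrix::drop0(v)
  }
  cells <- matrix$cells
  cells$total_fragments <- NULL
  count_matrix(v, kind = matrix$kind, cells = cells, peaks = matrix$peaks)
}
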