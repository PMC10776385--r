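#' Group peaks by quantiles of their above-threshold fraction
#'
#' Scores each peak by the fraction of cells whose count exceeds the
#' binarization threshold (strictly greater), then bins peaks by
#' quantiles of that score. Ties at a bin edge go to the lower bin.
#'
#' @param matrix A [count_matrix] (`fragments` or `reads`).
#' @param threshold Binarization threshold (default 1: a peak "exceeds"
#'   it in a cell when the count is > 1).
#' @param quantile_edges Strictly increasing probabilities in (0, 1)
#'   defining the bin boundaries (default quartiles).
#' @return A list with `score` (per peak), `group` (integer bin, 1 =
#'   lowest), `edges` (the score values at the quantile edges) and
#'   `peak_id`.
#' @export
peak_quantile_groups <- function(matrix, threshold = 1L,
                                 quantile_edges = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (matrix$kind == "binary")
    stop("quantile grouping needs counts, not a binarized matrix")
  if (any(diff(quantile_edges) <= 0) || any(quantile_edges <= 0) ||
      any(quantile_edges >= 1))
    stop("quantile_edges must be strictly increasing within (0, 1)")
  n <- nrow(matrix$values)
  score <- Matrix::colSums(matrix$values > threshold) / n
  edges <- stats::quantile(score, probs = quantile_edges, names = FALSE)
  if (length(unique(score)) == 1)
    warning("all peak scores identical: single group")
  # (lo, hi] bins: a score equal to an edge falls in the lower bin
  group <- findInterval(score, edges, left.open = TRUE,
                        rightmost.closed = FALSE) + 1L
  list(score = score, group = group, edges = edges,
       peak_id = matrix$peaks$peak_id)
}

#' Fisher enrichment of a peak group in an annotation set
#'
#' Tests whether peaks of a group overlap a set of annotation intervals
#' (any overlap of >= 1 bp) more often than the remaining peaks, with a
#' one-sided (enrichment) Fisher exact test. The odds ratio is the plain
#' cross-product ratio `(a d) / (b c)`; a zero cell yields `Inf` or 0
#' with a flag rather than a continuity correction. Annotations should be
#' pre-filtered to those overlapping at least one peak of the universe
#' (done here by construction of the 2x2 table).
#'
#' @param group_peaks [peak_set] of the group (must be a subset of
#'   `all_peaks`).
#' @param all_peaks [peak_set] universe.
#' @param annotation_intervals A [peak_set], `GRanges`, or BED path of
#'   annotation regions.
#' @param annotation_name Label carried into the result.
#' @return A data.frame row: `annotation_name`, `n_group`,
#'   `n_group_overlap`, `odds_ratio`, `or_degenerate` (zero-cell flag),
#'   `p_value`.
#' @export
fisher_enrichment <- function(group_peaks, all_peaks, annotation_intervals,
                              annotation_name = "annotation") {
  if (nrow(group_peaks) == 0) stop("empty peak group")
  if (!all(group_peaks$peak_id %in% all_peaks$peak_id))
    stop("group peaks must be a subset of the universe")
  ann_gr <- if (inherits(annotation_intervals, "GRanges"))
    annotation_intervals
  else if (inherits(annotation_intervals, "peak_set"))
    peaks_to_granges(annotation_intervals)
  else peaks_to_granges(read_bed_peaks(annotation_intervals))
  all_gr <- peaks_to_granges(all_peaks)
  overlaps <- GenomicRanges::countOverlaps(all_gr, ann_gr,
                                           minoverlap = 1L) > 0
  in_group <- all_peaks$peak_id %in% group_peaks$peak_id
  a <- sum(in_group & overlaps)
  b <- sum(in_group & !overlaps)
  c_ <- sum(!in_group & overlaps)
  d <- sum(!in_group & !overlaps)
  degenerate <- (b == 0 || c_ == 0 || a == 0 || d == 0)
  or <- if (b == 0 || c_ == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                          alternative = "greater")$p.value
  data.frame(annotation_name = annotation_name,
             n_group = sum(in_group), n_group_overlap = a,
             odds_ratio = or, or_degenerate = degenerate, p_value = p,
             stringsAsFactors = FALSE)
}

#' Enrichment of quantile groups against annotation sets
#'
#' Runs [fisher_enrichment] for every (quantile group, annotation) pair
#' and adjusts all p-values together with Benjamini-Hochberg.
#'
#' @param matrix A [count_matrix].
#' @param annotations Named list of annotation interval sets (each a
#'   [peak_set], `GRanges` or BED path).
#' @param threshold,quantile_edges Passed to [peak_quantile_groups].
#' @return A data.frame with one row per pair, including `group_id` and
#'   `q_value`.
#' @export
enrichment_by_quantile <- function(matrix, annotations, threshold = 1L,
                                   quantile_edges = c(0.25, 0.5, 0.75)) {
  groups <- peak_quantile_groups(matrix, threshold, quantile_edges)
  res <- list()
  for (g in sort(unique(groups$group))) {
    keep <- groups$group == g
    gp <- matrix$peaks[keep, , drop = FALSE]
    class(gp) <- c("peak_set", "data.frame")
    for (nm in names(annotations)) {
      row <- fisher_enrichment(gp, matrix$peaks, annotations[[nm]], nm)
      row$group_id <- g
      res[[length(res) + 1]] <- row
    }
  }
  out <- do.call(rbind, res)
  out$q_value <- benjamini_hochberg(out$p_value)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control:
#' `q_(i) = min_{j >= i} (m p_(j) / j)`, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Promoter accessibility vs gene expression correlation
#'
#' For each gene with a mapped promoter peak, computes the two-sided
#' Spearman correlation between the promoter fragment count and the
#' expression count across eligible cells. Eligible cells (i) have a
#' total fragment count inside the middle 0.25-0.75 quantile band
#' (inclusive on both ends), so the correlation is not driven by
#' sequencing depth, and (ii) have at least `min_promoter_count`
#' fragments in the promoter (default 1; set 2 to require a count
#' strictly above one). p-values are BH-adjusted across genes, and the
#' fraction of genes with a significant positive correlation is compared
#' against the nominal rate with a one-sided binomial test.
#'
#' @param fragment_matrix Cells x peaks [count_matrix] of fragment
#'   counts.
#' @param expression_matrix Cells x genes [count_matrix] (same cells, in
#'   the same order).
#' @param promoter_peak_map data.frame with columns `gene_id` and
#'   `peak_id` linking genes to their promoter peak (a promoter being the
#'   window from 1,000 bp upstream to 100 bp downstream of the TSS,
#'   resolved upstream of this function).
#' @param gene_ids Optional gene identifiers naming the expression
#'   columns; defaults to `promoter_map`-order columns.
#' @param min_promoter_count Minimum promoter fragment count for a cell
#'   to enter a gene's correlation (default 1).
#' @param alpha Significance level for the summary (default 0.05, also
#'   the nominal rate of the binomial test).
#' @return A list with `table` (per-gene `gene_id`, `spearman_rho`,
#'   `p_value`, `q_value`, `n_cells_used`), `skipped` (genes with < 3
#'   eligible cells), and `summary` (`n_genes`, `n_significant_positive`,
#'   `fraction_significant`, `fold_over_nominal`, `binomial_p`).
#' @export
promoter_expression_correlation <- function(fragment_matrix,
                                            expression_matrix,
                                            promoter_peak_map,
                                            gene_ids = NULL,
                                            min_promoter_count = 1L,
                                            alpha = 0.05) {
  stopifnot(inherits(fragment_matrix, "count_matrix"),
            inherits(expression_matrix, "count_matrix"))
  if (nrow(fragment_matrix$values) != nrow(expression_matrix$values))
    stop("fragment and expression matrices must share cells")
  tot <- Matrix::rowSums(fragment_matrix$values)
  band <- stats::quantile(tot, c(0.25, 0.75))
  in_band <- tot >= band[1] & tot <= band[2]
  if (is.null(gene_ids))
    gene_ids <- promoter_peak_map$gene_id
  expr_cols <- match(promoter_peak_map$gene_id, gene_ids)
  peak_cols <- match(promoter_peak_map$peak_id,
                     fragment_matrix$peaks$peak_id)
  if (any(is.na(peak_cols))) stop("promoter_peak_map names unknown peaks")
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(promoter_peak_map))) {
    g <- promoter_peak_map$gene_id[i]
    prom <- as.numeric(fragment_matrix$values[, peak_cols[i]])
    eligible <- in_band & prom >= min_promoter_count
    n_used <- sum(eligible)
    if (n_used < 3) {
      skipped[[length(skipped) + 1]] <- data.frame(
        gene_id = g, reason = sprintf("only %d eligible cells", n_used),
        stringsAsFactors = FALSE)
      next
    }
    e <- as.numeric(expression_matrix$values[eligible, expr_cols[i]])
    p <- prom[eligible]
    if (stats::sd(e) == 0 || stats::sd(p) == 0) {
      skipped[[length(skipped) + 1]] <- data.frame(
        gene_id = g, reason = "constant counts among eligible cells",
        stringsAsFactors = FALSE)
      next
    }
    ct <- suppressWarnings(stats::cor.test(p, e, method = "spearman",
                                           alternative = "two.sided",
                                           exact = FALSE))
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = g, spearman_rho = unname(ct$estimate),
      p_value = ct$p.value, n_cells_used = n_used,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), spearman_rho = numeric(0),
               p_value = numeric(0), n_cells_used = integer(0))
  tab$q_value <- benjamini_hochberg(tab$p_value)
  n_sig <- sum(tab$p_value < alpha & tab$spearman_rho > 0)
  m <- nrow(tab)
  summary <- list(
    n_genes = m, n_significant_positive = n_sig,
    fraction_significant = if (m) n_sig / m else NA_real_,
    fold_over_nominal = if (m) (n_sig / m) / alpha else NA_real_,
    binomial_p = if (m) stats::binom.test(n_sig, m, p = alpha,
                                          alternative = "greater")$p.value
    else NA_real_)
  list(table = tab,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
       summary = summary)
}
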