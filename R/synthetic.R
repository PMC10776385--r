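#' Simulate a multi-cell-type fragment count dataset
#'
#' Generates fragment counts with the statistical structure that the
#' Poisson model assumes: each cell type has an accessibility profile over
#' peaks (rows sum to 1), each cell has a lognormal sequencing depth, and
#' counts are Poisson with rate depth x profile. Batch effects
#' multiplicatively perturb the profile on a random peak subset (and the
#' profile is renormalized), which is the simplest mechanism that both the
#' batch-correction metrics can detect and a batch covariate in the
#' decoder can remove.
#'
#' Cell-type profiles are drawn from a symmetric Dirichlet whose
#' concentration is `1 / type_sharpness`: larger `type_sharpness` gives
#' sparser, better-separated profiles.
#'
#' @param n_cells,n_peaks,n_types,n_batches Dataset dimensions.
#' @param depth_meanlog,depth_sdlog Lognormal depth parameters. The
#'   defaults (`log(3000)`, 0.5) give a deep dataset relative to 1,000
#'   peaks; downsample with [downsample_counts] for sparse regimes.
#' @param type_sharpness Controls profile separation (Dirichlet
#'   concentration `1 / type_sharpness`).
#' @param batch_effect_size Batch effect magnitude in log2 units (the
#'   affected peaks are multiplied by `2^batch_effect_size`).
#' @param batch_peak_fraction Fraction of peaks affected per non-reference
#'   batch.
#' @param seed Integer seed; the whole draw is reproducible.
#' @return A list with `matrix` (a [count_matrix], `kind = "fragments"`,
#'   with `batch` and `cell_type` in its cell table) and `truth` (cell
#'   type, batch, per-type profiles `profiles`, per-cell depth `depth`,
#'   the affected `batch_peaks` and the multiplier).
#' @export
simulate_fragments <- function(n_cells = 2000, n_peaks = 1000,
                               n_types = 4, n_batches = 2,
                               depth_meanlog = log(3000),
                               depth_sdlog = 0.5,
                               type_sharpness = 2,
                               batch_effect_size = 1,
                               batch_peak_fraction = 0.1,
                               seed = 1L) {
  stopifnot(n_cells >= 1, n_peaks >= 1, n_types >= 1, n_batches >= 1)
  set.seed(as.integer(seed))
  alpha <- 1 / type_sharpness
  profiles <- matrix(stats::rgamma(n_types * n_peaks, shape = alpha),
                     n_types, n_peaks)
  profiles <- profiles / rowSums(profiles)
  cell_type <- sample.int(n_types, n_cells, replace = TRUE)
  batch <- sample.int(n_batches, n_cells, replace = TRUE)
  depth <- stats::rlnorm(n_cells, meanlog = depth_meanlog,
                         sdlog = depth_sdlog)
  batch_peaks <- vector("list", n_batches)
  batch_peaks[[1]] <- integer(0)  # batch 1 is the reference
  if (n_batches > 1) {
    n_aff <- max(1L, round(batch_peak_fraction * n_peaks))
    for (b in 2:n_batches)
      batch_peaks[[b]] <- sort(sample.int(n_peaks, n_aff))
  }
  mult <- 2^batch_effect_size
  # per (type, batch) adjusted + renormalized profile
  x <- matrix(0, n_cells, n_peaks)
  for (b in seq_len(n_batches)) {
    w_b <- profiles
    if (length(batch_peaks[[b]])) {
      w_b[, batch_peaks[[b]]] <- w_b[, batch_peaks[[b]]] * mult
      w_b <- w_b / rowSums(w_b)
    }
    for (t in seq_len(n_types)) {
      idx <- which(cell_type == t & batch == b)
      if (!length(idx)) next
      lam <- outer(depth[idx], w_b[t, ])
      x[idx, ] <- stats::rpois(length(lam), lam)
    }
  }
  cells <- cell_table(sprintf("cell%05d", seq_len(n_cells)),
                      batch = sprintf("batch%d", batch),
                      cell_type = sprintf("type%d", cell_type))
  cm <- count_matrix(x, kind = "fragments", cells = cells)
  truth <- list(cell_type = sprintf("type%d", cell_type),
                batch = sprintf("batch%d", batch),
                profiles = profiles, depth = depth,
                batch_peaks = batch_peaks, multiplier = mult)
  list(matrix = cm, truth = truth)
}

#' Turn a fragment matrix into a synthetic read matrix
#'
#' Emulates the paired-end counting artifact: each fragment contributes
#' two reads (both ends inside the peak) with probability `1 - end_loss_prob`,
#' and one read (one end outside) with probability `end_loss_prob`. At
#' `end_loss_prob = 0` the result is exactly twice the fragment matrix, so
#' counts are all even and the variance-to-mean ratio doubles.
#'
#' @param fragment_matrix A [count_matrix] with `kind = "fragments"`.
#' @param end_loss_prob Probability `q` in `[0, 0.5)` that a fragment loses
#'   one end.
#' @param seed Integer seed.
#' @return A [count_matrix] with `kind = "reads"`.
#' @export
fragments_to_reads <- function(fragment_matrix, end_loss_prob = 0,
                               seed = 1L) {
  stopifnot(inherits(fragment_matrix, "count_matrix"))
  if (fragment_matrix$kind != "fragments")
    stop("fragments_to_reads expects kind = 'fragments'")
  if (end_loss_prob < 0 || end_loss_prob >= 0.5)
    stop("end_loss_prob must be in [0, 0.5)")
  v <- fragment_matrix$values
  if (end_loss_prob == 0) {
    v@x <- 2 * v@x
  } else {
    set.seed(as.integer(seed))
    lost <- stats::rbinom(length(v@x), size = v@x, prob = end_loss_prob)
    v@x <- 2 * v@x - lost
  }
  cells <- fragment_matrix$cells
  cells$total_fragments <- NULL
  count_matrix(v, kind = "reads", cells = cells,
               peaks = fragment_matrix$peaks)
}

#' Plant promoter-expression correlation
#'
#' Builds a synthetic gene expression count matrix in which a chosen
#' fraction of genes has a target Spearman correlation between expression
#' and the fragment count of a promoter peak, via a Gaussian copula (the
#' copula correlation is `2 sin(pi * rho / 6)`, the standard conversion
#' from a target Spearman coefficient); the remaining genes are
#' independent Poisson counts. Gene `g` is mapped to peak `g` of the
#' fragment matrix.
#'
#' @param fragment_matrix A [count_matrix] providing promoter fragment
#'   counts.
#' @param n_genes Number of genes (at most the number of peaks).
#' @param frac_correlated Fraction of genes with planted correlation.
#' @param target_rho Target Spearman correlation for the planted genes.
#' @param mean_expression Poisson mean of the expression counts.
#' @param seed Integer seed.
#' @return A list with `expression` (cells x genes [count_matrix], kind
#'   `"fragments"` reused as a generic count tag), `promoter_map`
#'   (data.frame `gene_id`, `peak_id`), and `correlated_genes` (character
#'   vector).
#' @export
plant_expression <- function(fragment_matrix, n_genes = 100,
                             frac_correlated = 0.1, target_rho = 0.3,
                             mean_expression = 5, seed = 1L) {
  stopifnot(inherits(fragment_matrix, "count_matrix"))
  if (frac_correlated < 0 || frac_correlated > 1)
    stop("frac_correlated must be in [0, 1]")
  p <- ncol(fragment_matrix$values)
  if (n_genes > p) stop("n_genes exceeds the number of peaks")
  set.seed(as.integer(seed))
  n <- nrow(fragment_matrix$values)
  n_corr <- round(frac_correlated * n_genes)
  corr_genes <- if (n_corr > 0) sort(sample.int(n_genes, n_corr)) else integer(0)
  r <- 2 * sin(pi * target_rho / 6)
  expr <- matrix(0L, n, n_genes)
  for (g in seq_len(n_genes)) {
    if (g %in% corr_genes && abs(target_rho) > 0) {
      x <- as.numeric(fragment_matrix$values[, g])
      u <- (rank(x, ties.method = "random") - 0.5) / n
      z1 <- stats::qnorm(u)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
      expr[, g] <- stats::qpois(stats::pnorm(z2), mean_expression)
    } else {
      expr[, g] <- stats::rpois(n, mean_expression)
    }
  }
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  em <- count_matrix(expr, kind = "fragments",
                     cells = cell_table(fragment_matrix$cells$barcode,
                                        batch = fragment_matrix$cells$batch))
  # reuse peak slots as gene ids for printing purposes only
  list(expression = em,
       promoter_map = data.frame(
         gene_id = gene_ids,
         peak_id = fragment_matrix$peaks$peak_id[seq_len(n_genes)],
         stringsAsFactors = FALSE),
       correlated_genes = gene_ids[corr_genes])
}
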