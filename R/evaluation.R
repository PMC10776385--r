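#' Average precision
#'
#' Area under the precision-recall curve via the step-wise estimator
#' `sum_k (R_k - R_{k-1}) * P_k`, where thresholds step through blocks of
#' tied scores (so constant predictions score the positive prevalence).
#' Used to evaluate binarized reconstructions, which are highly
#' imbalanced.
#'
#' @param scores Numeric predictions (higher = more likely positive).
#' @param labels 0/1 (or logical) ground truth with at least one positive.
#' @return A scalar in (0, 1].
#' @export
average_precision <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(labels)
  if (n_pos == 0) stop("no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # end indices of blocks of tied scores
  block_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[block_end]
  n_seen <- block_end
  recall <- tp / n_pos
  precision <- tp / n_seen
  sum(diff(c(0, recall)) * precision)
}

# ---- kNN graph ------------------------------------------------------------

#' k-nearest-neighbor graph of an embedding
#'
#' Euclidean kNN, symmetrized by union, unweighted.
#' @param embedding Cells x d numeric matrix.
#' @param k Number of neighbors (default 15).
#' @return An `igraph` graph with one vertex per cell.
#' @export
knn_graph <- function(embedding, k = 15) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < k + 1) stop("need at least k + 1 cells")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Louvain clustering swept over resolutions
#'
#' Clusters the kNN graph of the embedding with Louvain at resolutions
#' 0.1 to 2.0 in steps of 0.1 (the convention for picking the clustering
#' that best matches annotated labels) and returns the clustering that
#' maximizes NMI against the provided labels.
#'
#' @param embedding Cells x d matrix.
#' @param labels Reference labels (cell types).
#' @param resolutions Resolution grid.
#' @param k_neighbors kNN parameter.
#' @param seed Seed making the (stochastic) Louvain runs reproducible.
#' @return A list with `membership` (best clustering), `resolution`,
#'   `nmi`, `sweep` (data.frame of resolution and NMI) and `clusterings`
#'   (all memberships, used by the isolated-label F1).
#' @export
louvain_sweep <- function(embedding, labels,
                          resolutions = seq(0.1, 2.0, by = 0.1),
                          k_neighbors = 15, seed = 0L) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  if (all(abs(sweep(embedding, 2, embedding[1, ], "-")) < 1e-12)) {
    warning("degenerate embedding (all rows equal): single cluster")
    memb <- rep(1L, nrow(embedding))
    return(list(membership = memb, resolution = NA_real_, nmi = 0,
                sweep = data.frame(resolution = NA_real_, nmi = 0),
                clusterings = list(memb)))
  }
  g <- knn_graph(embedding, k_neighbors)
  set.seed(as.integer(seed))
  memberships <- vector("list", length(resolutions))
  nmis <- numeric(length(resolutions))
  for (i in seq_along(resolutions)) {
    cl <- igraph::cluster_louvain(g, resolution = resolutions[i])
    memberships[[i]] <- igraph::membership(cl)
    nmis[i] <- nmi_score(memberships[[i]], labels)
  }
  best <- which.max(nmis)
  list(membership = as.integer(memberships[[best]]),
       resolution = resolutions[best], nmi = nmis[best],
       sweep = data.frame(resolution = resolutions, nmi = nmis),
       clusterings = memberships)
}

#' Normalized mutual information
#'
#' Arithmetic-mean normalization, `2 I(A;B) / (H(A) + H(B))`; a partition
#' with zero entropy (all items in one class) scores 0 by convention.
#'
#' @param clustering,labels Two partitions of the same items.
#' @return NMI in `[0, 1]`.
#' @export
nmi_score <- function(clustering, labels) {
  a <- as.integer(factor(clustering))
  b <- as.integer(factor(labels))
  if (length(a) != length(b)) stop("length mismatch")
  if (length(unique(a)) < 2 || length(unique(b)) < 2) return(0)
  igraph::compare(a, b, method = "nmi")
}

#' Adjusted Rand index
#'
#' Permutation-invariant clustering agreement, 1 for identical
#' partitions, approximately 0 for random ones. A degenerate comparison
#' (either partition with a single class) returns 0.
#'
#' @param clustering,labels Two partitions.
#' @param rescale Map from `[-1, 1]` to `[0, 1]` as `(ari + 1) / 2` (used
#'   when aggregating into an [integration_report]).
#' @return ARI (raw by default).
#' @export
ari_score <- function(clustering, labels, rescale = FALSE) {
  a <- as.integer(factor(clustering))
  b <- as.integer(factor(labels))
  if (length(a) != length(b)) stop("length mismatch")
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    ari <- 0
  else
    ari <- mclust::adjustedRandIndex(a, b)
  if (rescale) (ari + 1) / 2 else ari
}

#' Label (cell-type) silhouette width
#'
#' Mean silhouette width of cells grouped by label, rescaled from
#' `[-1, 1]` to `[0, 1]` via `(s + 1) / 2`; near 1 means labels form
#' tight, well-separated groups in the embedding.
#'
#' @param embedding Cells x d matrix.
#' @param labels Group labels; at least two distinct, each with >= 2
#'   cells.
#' @return A scalar in `[0, 1]`.
#' @export
label_silhouette <- function(embedding, labels) {
  f <- factor(labels)
  if (nlevels(f) < 2) stop("need at least two labels")
  if (any(table(f) < 2)) stop("every label needs >= 2 cells")
  sil <- cluster::silhouette(as.integer(f), stats::dist(as.matrix(embedding)))
  (mean(sil[, "sil_width"]) + 1) / 2
}

#' Isolated-label scores
#'
#' Isolated labels are the cell types present in the fewest batches —
#' typically rare populations whose recovery probes integration quality.
#' The F1 score is the best F1, over the swept clusterings and over their
#' clusters, of predicting the isolated label by cluster membership. The
#' silhouette score is the rescaled mean silhouette width of the isolated
#' label's cells in a binary (isolated vs rest) grouping. Ties for the
#' minimum batch count are averaged over all tied labels.
#'
#' @param embedding Cells x d matrix.
#' @param labels Cell-type labels.
#' @param batches Batch labels, aligned with `labels`.
#' @param clusterings Optional list of candidate memberships; defaults to
#'   a [louvain_sweep] on the embedding.
#' @param seed Seed for the default sweep.
#' @return A list with `f1`, `silhouette` and `isolated_labels`.
#' @export
isolated_label_scores <- function(embedding, labels, batches,
                                  clusterings = NULL, seed = 0L) {
  labels <- as.character(labels)
  batches <- as.character(batches)
  if (length(labels) != length(batches)) stop("labels/batches mismatch")
  n_batches_per_label <- tapply(batches, labels,
                                function(b) length(unique(b)))
  iso <- names(n_batches_per_label)[
    n_batches_per_label == min(n_batches_per_label)]
  if (is.null(clusterings))
    clusterings <- louvain_sweep(embedding, labels, seed = seed)$clusterings
  f1_one <- function(lab) {
    truth <- labels == lab
    best <- 0
    for (memb in clusterings) {
      for (cl in unique(memb)) {
        pred <- memb == cl
        tp <- sum(pred & truth)
        if (tp == 0) next
        prec <- tp / sum(pred); rec <- tp / sum(truth)
        best <- max(best, 2 * prec * rec / (prec + rec))
      }
    }
    best
  }
  sil_one <- function(lab) {
    grp <- factor(ifelse(labels == lab, lab, "rest"))
    if (nlevels(grp) < 2) return(NA_real_)
    sil <- cluster::silhouette(as.integer(grp),
                               stats::dist(as.matrix(embedding)))
    (mean(sil[labels == lab, "sil_width"]) + 1) / 2
  }
  list(f1 = mean(vapply(iso, f1_one, numeric(1))),
       silhouette = mean(vapply(iso, sil_one, numeric(1))),
       isolated_labels = iso)
}

#' Graph connectivity
#'
#' For each cell-type label, the fraction of that label's cells in the
#' largest connected component of the kNN graph restricted to the label;
#' averaged over labels. Strong batch effects split a label into
#' disconnected islands and lower the score.
#'
#' @param embedding Cells x d matrix.
#' @param labels Cell-type labels.
#' @param k_neighbors kNN parameter.
#' @return A scalar in `[0, 1]`.
#' @export
graph_connectivity <- function(embedding, labels, k_neighbors = 15) {
  g <- knn_graph(embedding, k_neighbors)
  labels <- as.character(labels)
  vals <- vapply(unique(labels), function(lab) {
    idx <- which(labels == lab)
    if (length(idx) == 1) return(1)
    sub <- igraph::induced_subgraph(g, idx)
    comp <- igraph::components(sub)
    max(comp$csize) / length(idx)
  }, numeric(1))
  mean(vals)
}

#' Batch silhouette width (batch mixing)
#'
#' Within each cell-type group, the silhouette of the batch labels is
#' computed and transformed per cell to `1 - |s|`, so perfectly mixed
#' batches score near 1; the per-group means are averaged. Groups
#' containing a single batch are skipped with a warning.
#'
#' @param embedding Cells x d matrix.
#' @param labels Cell-type labels defining the groups.
#' @param batches Batch labels; at least two overall.
#' @return A scalar in `[0, 1]`.
#' @export
batch_silhouette <- function(embedding, labels, batches) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  batches <- factor(batches)
  if (nlevels(batches) < 2) stop("need at least two batches")
  scores <- c()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    bf <- factor(as.character(batches[idx]))
    if (nlevels(bf) < 2 || length(idx) <= nlevels(bf)) {
      warning("group '", lab, "' has a single batch (or too few cells); ",
              "skipped")
      next
    }
    sil <- cluster::silhouette(as.integer(bf),
                               stats::dist(embedding[idx, , drop = FALSE]))
    scores <- c(scores, mean(1 - abs(sil[, "sil_width"])))
  }
  if (!length(scores)) stop("no group with more than one batch")
  mean(scores)
}

# variance-weighted R^2 of principal components regressed on batch
pcr_batch_variance <- function(embedding, batches) {
  embedding <- as.matrix(embedding)
  pc <- stats::prcomp(embedding, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > 1e-12)
  v <- pc$sdev[keep]^2
  bf <- factor(batches)
  r2 <- vapply(keep, function(j) {
    fit <- stats::lm(pc$x[, j] ~ bf)
    summary(fit)$r.squared
  }, numeric(1))
  sum(v / sum(v) * r2)
}

#' Principal component regression batch score
#'
#' The variance of an embedding's principal components explainable by the
#' batch variable, before vs after integration:
#' `(Var_before - Var_after) / Var_before`, clipped to `[0, 1]`. A value
#' near 1 means the integrated embedding removed the batch signal that
#' was present before.
#'
#' @param embedding_before,embedding_after Embeddings of the same cells
#'   (e.g. raw-count PCA and the VAE latent space).
#' @param batches Batch labels.
#' @return A scalar in `[0, 1]`.
#' @export
principal_component_regression <- function(embedding_before,
                                           embedding_after, batches) {
  if (nrow(as.matrix(embedding_before)) != nrow(as.matrix(embedding_after)))
    stop("embeddings must cover the same cells")
  vb <- pcr_batch_variance(embedding_before, batches)
  if (vb <= 0) stop("no batch variance in the 'before' embedding")
  va <- pcr_batch_variance(embedding_after, batches)
  min(max((vb - va) / vb, 0), 1)
}

#' Cell-type separation of a 1-D accessibility score
#'
#' How well a single peak's (normalized) accessibility separates a target
#' cell type from the rest: the silhouette width of the binary grouping
#' on the 1-D values, and the ROC AUC of the values as a score for target
#' membership (rank-based, ties averaged).
#'
#' @param values Numeric vector (one accessibility value per cell).
#' @param labels Cell-type labels.
#' @param target_label The cell type of interest.
#' @return A list with `silhouette` (in `[-1, 1]`), `roc_auc` (in
#'   `[0, 1]`) and `target_label`.
#' @export
celltype_separation <- function(values, labels, target_label) {
  values <- as.numeric(values)
  labels <- as.character(labels)
  if (length(values) != length(labels)) stop("length mismatch")
  is_target <- labels == target_label
  if (!any(is_target)) stop("target_label '", target_label, "' absent")
  if (all(is_target)) stop("all cells carry the target label")
  r <- rank(values)
  n1 <- sum(is_target); n0 <- sum(!is_target)
  auc <- (sum(r[is_target]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  sil <- cluster::silhouette(as.integer(factor(is_target)),
                             stats::dist(matrix(values, ncol = 1)))
  list(silhouette = mean(sil[, "sil_width"]), roc_auc = auc,
       target_label = target_label)
}

#' Integration report
#'
#' Computes the bioconservation metrics (NMI, ARI, label silhouette,
#' isolated-label F1 and silhouette) and batch-correction metrics (batch
#' silhouette, graph connectivity, and principal component regression
#' when a pre-integration embedding is supplied) of a latent embedding,
#' all mapped to `[0, 1]`, and aggregates them as the weighted mean of
#' the two category means.
#'
#' @param embedding Cells x d matrix (the integrated latent space).
#' @param labels Cell-type labels.
#' @param batches Batch labels.
#' @param embedding_before Optional pre-integration embedding for the PCR
#'   score.
#' @param k_neighbors kNN parameter for graph-based metrics.
#' @param seed Seed for the Louvain sweep.
#' @param bio_weight Weight of the bioconservation mean in the overall
#'   score (batch gets `1 - bio_weight`).
#' @return A list with `bioconservation`, `batch` (named score vectors),
#'   `ari_raw`, and the `bio_mean`, `batch_mean` and `overall` summaries.
#' @export
integration_report <- function(embedding, labels, batches,
                               embedding_before = NULL, k_neighbors = 15,
                               seed = 0L, bio_weight = 0.6) {
  sweep_res <- louvain_sweep(embedding, labels, k_neighbors = k_neighbors,
                             seed = seed)
  iso <- isolated_label_scores(embedding, labels, batches,
                               clusterings = sweep_res$clusterings)
  bio <- c(nmi = sweep_res$nmi,
           ari = ari_score(sweep_res$membership, labels, rescale = TRUE),
           label_silhouette = label_silhouette(embedding, labels),
           isolated_label_f1 = iso$f1,
           isolated_label_silhouette = iso$silhouette)
  batch <- c(batch_silhouette = batch_silhouette(embedding, labels, batches),
             graph_connectivity = graph_connectivity(embedding, labels,
                                                     k_neighbors))
  if (!is.null(embedding_before))
    batch <- c(batch, pcr = principal_component_regression(
      embedding_before, embedding, batches))
  stopifnot(all(bio >= 0 & bio <= 1), all(batch >= 0 & batch <= 1))
  list(bioconservation = bio, batch = batch,
       ari_raw = ari_score(sweep_res$membership, labels),
       bio_mean = mean(bio), batch_mean = mean(batch),
       overall = bio_weight * mean(bio) + (1 - bio_weight) * mean(batch))
}
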