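test_that("average precision matches the exhaustive PR-curve oracle on all small inputs", {
  # perfect ranking and constant predictions (tie handling)
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(rep(0.5, 8), c(1, 0, 0, 1, 0, 0, 0, 0)),
               0.25)
  # the worked 4-entry example
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
  # random small inputs, with and without ties, vs the oracle
  set.seed(17)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1
    expect_equal(average_precision(scores, labels),
                 ap_oracle(scores, labels), tolerance = 1e-12)
  }
  expect_error(average_precision(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("NMI and ARI identities, invariances and null behavior hold", {
  a <- rep(1:3, each = 10)
  expect_equal(nmi_score(a, a), 1)
  expect_equal(ari_score(a, a), 1)
  # relabeling leaves both invariant
  relab <- c(3, 1, 2)[a]
  expect_equal(ari_score(a, relab), 1)
  expect_equal(nmi_score(a, relab), 1)
  # degenerate single-class partitions are defined as 0
  expect_equal(nmi_score(rep(1, 30), a), 0)
  expect_equal(ari_score(rep(1, 30), a), 0)
  # random partitions: ARI near 0
  set.seed(23)
  aris <- replicate(20, ari_score(sample(1:4, 200, TRUE),
                                  sample(1:4, 200, TRUE)))
  expect_true(all(abs(aris) < 0.1))
  # rescaling maps [-1, 1] to [0, 1]
  expect_equal(ari_score(a, a, rescale = TRUE), 1)
})

test_that("label silhouette matches explicit arithmetic and calibrates on blobs", {
  # 4 hand-placed 1-D points: {0, 1} vs {10, 11}
  emb <- matrix(c(0, 1, 10, 11), ncol = 1)
  labs <- c("A", "A", "B", "B")
  s <- c((10.5 - 1) / 10.5, (9.5 - 1) / 9.5, (9.5 - 1) / 9.5,
         (10.5 - 1) / 10.5)
  expect_equal(label_silhouette(emb, labs), (mean(s) + 1) / 2,
               tolerance = 1e-12)
  # two tight distant blobs ~ 1; random labels on one blob ~ 0.5
  b <- make_blobs(n_per = 40, centers = rbind(c(0, 0), c(100, 0)),
                  sd = 0.5, seed = 2)
  expect_gt(label_silhouette(b$embedding, b$labels), 0.95)
  set.seed(3)
  one_blob <- matrix(rnorm(160), 80, 2)
  expect_equal(label_silhouette(one_blob, sample(c("x", "y"), 80, TRUE)),
               0.5, tolerance = 0.05)
  expect_error(label_silhouette(one_blob, rep("x", 80)), "two labels")
})

test_that("the Louvain sweep recovers well-separated blobs and handles degenerate input", {
  b <- make_blobs(n_per = 40, centers = diag(3) * 50, sd = 0.5, seed = 4)
  lv <- louvain_sweep(b$embedding, b$labels, seed = 1)
  expect_equal(lv$nmi, 1)
  expect_equal(ari_score(lv$membership, b$labels), 1)
  # deterministic given the seed
  lv2 <- louvain_sweep(b$embedding, b$labels, seed = 1)
  expect_identical(lv$membership, lv2$membership)
  # degenerate embedding: single cluster, NMI 0, warning
  expect_warning(
    lv0 <- louvain_sweep(matrix(1, 40, 2), rep(c("a", "b"), 20)),
    "degenerate")
  expect_equal(lv0$nmi, 0)
  expect_equal(length(unique(lv0$membership)), 1L)
})

test_that("graph connectivity is 1 for coherent labels and ~0.5 for a split label", {
  b <- make_blobs(n_per = 30, centers = diag(2) * 60, sd = 0.5, seed = 5)
  expect_equal(graph_connectivity(b$embedding, b$labels, k_neighbors = 10), 1)
  # one label split into two equal far-apart islands
  set.seed(6)
  emb <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 200), 30, 2),
               matrix(rnorm(60, 100), 30, 2))
  labs <- c(rep("split", 60), rep("solid", 30))
  gc <- graph_connectivity(emb, labs, k_neighbors = 5)
  expect_equal(gc, mean(c(0.5, 1)), tolerance = 0.05)
})

test_that("batch silhouette scores mixing high and separation low, averaging over groups", {
  set.seed(7)
  # mixed: batches drawn independently of position inside each type
  emb <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 50), 100, 2))
  types <- rep(c("t1", "t2"), each = 100)
  mixed_batches <- sample(c("b1", "b2"), 200, TRUE)
  expect_gt(batch_silhouette(emb, types, mixed_batches), 0.85)
  # separated: batch 2 shifted far away inside each type
  sep <- emb
  sep_batches <- rep(rep(c("b1", "b2"), each = 50), 2)
  sep[sep_batches == "b2", 1] <- sep[sep_batches == "b2", 1] + 25
  expect_lt(batch_silhouette(sep, types, sep_batches), 0.4)
  # report is the mean of per-group scores
  g1 <- batch_silhouette(emb[types == "t1", ], rep("t1", 100),
                         mixed_batches[types == "t1"])
  g2 <- batch_silhouette(emb[types == "t2", ], rep("t2", 100),
                         mixed_batches[types == "t2"])
  expect_equal(batch_silhouette(emb, types, mixed_batches),
               mean(c(g1, g2)), tolerance = 1e-12)
  # single-batch group skipped with warning
  expect_warning(batch_silhouette(emb, types,
                                  c(rep("b1", 100),
                                    sample(c("b1", "b2"), 100, TRUE))),
                 "skipped")
})

test_that("principal component regression scores 0 for identity and ~1 for full batch removal", {
  set.seed(8)
  n <- 200
  batches <- rep(c("b1", "b2"), each = n / 2)
  clean <- matrix(rnorm(n * 4), n, 4)
  shifted <- clean
  shifted[batches == "b2", 1] <- shifted[batches == "b2", 1] + 8
  expect_equal(principal_component_regression(shifted, shifted, batches), 0)
  expect_gt(principal_component_regression(shifted, clean, batches), 0.9)
  # with one PC and two batches, R^2 equals the squared correlation
  one_d <- matrix(rnorm(n) + 3 * (batches == "b2"), ncol = 1)
  r2 <- scatacounts:::pcr_batch_variance(one_d, batches)
  expect_equal(r2, cor(one_d[, 1], as.integer(factor(batches)))^2,
               tolerance = 1e-12)
})

test_that("isolated labels are found by minimum batch presence and scored by best-cluster F1", {
  # 12 hand-placed cells: label C only in batch 1; A and B in all 3 batches
  labs <- c("A", "A", "A", "A", "B", "B", "B", "B", "C", "C", "C", "C")
  batches <- c("x", "y", "z", "x", "x", "y", "z", "y", "x", "x", "x", "x")
  emb <- matrix(c(0, 0, 1, 1, 50, 50, 51, 51, 100, 100, 101, 101,
                  rep(0, 12)), ncol = 2)
  # clustering that puts one C cell with B: F1 of best cluster for C
  memb <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 3, 3, 3)
  res <- isolated_label_scores(emb, labs, batches, clusterings = list(memb))
  expect_identical(res$isolated_labels, "C")
  # cluster 3 has precision 1, recall 3/4 -> F1 = 6/7; cluster 2: 1/5, 1/4
  expect_equal(res$f1, 2 * (1 * 0.75) / (1 + 0.75))
  # a clustering isolating C perfectly gives F1 = 1
  res2 <- isolated_label_scores(emb, labs, batches,
                                clusterings = list(c(rep(1, 4), rep(2, 4),
                                                     rep(3, 4))))
  expect_equal(res2$f1, 1)
  expect_gt(res2$silhouette, 0.9)
})

test_that("cell-type separation AUC is exact for indicators, symmetric, and ~0.5 under the null", {
  labs <- rep(c("target", "rest"), each = 50)
  ind <- as.numeric(labs == "target")
  cs <- celltype_separation(ind, labs, "target")
  expect_equal(cs$roc_auc, 1)
  set.seed(9)
  vals <- rnorm(1000)
  labs2 <- sample(c("target", "rest"), 1000, TRUE)
  cs2 <- celltype_separation(vals, labs2, "target")
  expect_gt(cs2$roc_auc, 0.45); expect_lt(cs2$roc_auc, 0.55)
  # reversing the score maps AUC a -> 1 - a
  cs3 <- celltype_separation(-vals, labs2, "target")
  expect_equal(cs3$roc_auc, 1 - cs2$roc_auc, tolerance = 1e-12)
  expect_error(celltype_separation(vals, labs2, "absent"), "absent")
})

test_that("integration report aggregates scores in [0, 1] and responds to planted structure", {
  set.seed(10)
  b <- make_blobs(n_per = 50, centers = diag(3) * 40, sd = 1, seed = 11)
  batches <- sample(c("b1", "b2"), length(b$labels), TRUE)
  rep1 <- integration_report(b$embedding, b$labels, batches, seed = 1)
  expect_true(all(rep1$bioconservation >= 0 & rep1$bioconservation <= 1))
  expect_true(all(rep1$batch >= 0 & rep1$batch <= 1))
  expect_gt(rep1$bio_mean, 0.8)   # clean structure, mixed batches
  expect_gt(rep1$batch_mean, 0.8)
  expect_equal(rep1$overall, 0.6 * rep1$bio_mean + 0.4 * rep1$batch_mean)
})

test_that("a structured embedding beats random embeddings of equal dimension on NMI and ARI", {
  b <- make_blobs(n_per = 40, centers = diag(3) * 30, sd = 1, seed = 12)
  lv <- louvain_sweep(b$embedding, b$labels, seed = 1)
  real_nmi <- lv$nmi
  real_ari <- ari_score(lv$membership, b$labels)
  set.seed(13)
  null_scores <- t(replicate(20, {
    rnd <- matrix(rnorm(length(b$embedding)), nrow(b$embedding))
    l <- louvain_sweep(rnd, b$labels, resolutions = c(0.5, 1), seed = 1)
    c(l$nmi, ari_score(l$membership, b$labels))
  }))
  expect_true(all(real_nmi > null_scores[, 1]))
  expect_true(all(real_ari > null_scores[, 2]))
})
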