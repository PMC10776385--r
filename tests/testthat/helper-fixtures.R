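# Small programmatic fixtures shared across test files.

# random sparse non-negative integer count matrix
random_count_matrix <- function(n = 10, p = 8, lambda = 1,
                                kind = "fragments", seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p)
  count_matrix(m, kind = kind)
}

# a tiny fragment file on disk (optionally gzipped); returns the path
write_fragment_file <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".tsv.gz" else ".tsv")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  path
}

# embedding of well-separated Gaussian blobs with labels
make_blobs <- function(n_per = 30, centers = diag(3) * 20, sd = 0.5,
                       seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  emb <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per),
          2, centers[i, ], "+")))
  list(embedding = emb, labels = rep(sprintf("lab%d", seq_len(k)),
                                     each = n_per))
}

# a quickly trained small VAE (shared by several vae tests)
small_trained_vae <- local({
  cache <- new.env()
  function(likelihood = "poisson") {
    key <- likelihood
    if (is.null(cache[[key]])) {
      sim <- simulate_fragments(n_cells = 150, n_peaks = 60, n_types = 2,
                                n_batches = 2, depth_meanlog = log(200),
                                seed = 7)
      cfg <- vae_config(likelihood, n_latent = 4, max_epochs = 5,
                        patience = 5, seed = 2)
      cache[[key]] <- list(model = train_vae(sim$matrix, cfg), sim = sim)
    }
    cache[[key]]
  }
})

# brute-force PR-curve average precision: enumerate thresholds explicitly
ap_oracle <- function(scores, labels) {
  ts <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  ap <- 0
  for (t in ts) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / sum(labels == 1)
    ap <- ap + (rec - prev_r) * prec
    prev_r <- rec
  }
  ap
}
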