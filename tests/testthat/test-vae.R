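ns <- asNamespace("scatacounts")

test_that("the closed-form count-to-probability transform is exact and monotone", {
  expect_equal(poisson_rate_to_bernoulli(0), 0)
  expect_equal(poisson_rate_to_bernoulli(log(2)), 0.5)
  lam <- seq(0, 20, by = 0.5)
  th <- poisson_rate_to_bernoulli(lam)
  expect_true(all(diff(th) > 0))
  expect_true(all(th >= 0 & th < 1))
  expect_error(poisson_rate_to_bernoulli(-1), ">= 0")
})

test_that("encoder output is deterministic, finite, with strictly positive sigma", {
  fx <- small_trained_vae("poisson")
  X <- as.matrix(fx$sim$matrix$values)[1:5, ]
  enc1 <- encode_cells(fx$model, X)
  enc2 <- encode_cells(fx$model, X)
  expect_identical(enc1, enc2)
  expect_true(all(is.finite(enc1$mu)))
  expect_true(all(enc1$sigma > 0 & enc1$sigma < 100))
  # all-zero row still encodes to finite values
  enc0 <- encode_cells(fx$model, matrix(0, 1, ncol(X)))
  expect_true(all(is.finite(enc0$mu)) && all(enc0$sigma > 0))
  expect_error(encode_cells(fx$model, matrix(NaN, 1, ncol(X))),
               "non-finite")
})

test_that("Poisson decoder conserves each cell's total by the softmax construction", {
  fx <- small_trained_vae("poisson")
  set.seed(31)
  z <- matrix(rnorm(8 * 4), 8, 4)
  l_c <- log(c(10, 100, 55, 3000, 7, 12, 1, 250))
  lam <- decode_poisson(fx$model, z, rep(c(1L, 2L), 4), l_c)
  expect_true(all(lam >= 0))
  expect_lt(max(abs(rowSums(lam) - exp(l_c)) / exp(l_c)), 1e-4)
  expect_error(decode_poisson(fx$model, z, rep(9L, 8), l_c), "batch")
})

test_that("Binary decoder reduces to the cell's mean accessibility when decoder and bias are zeroed", {
  fx <- small_trained_vae("bernoulli")
  model <- fx$model
  model$params$out$W[] <- 0
  model$params$out$b[] <- 0
  model$params$r[] <- 0
  acc <- c(0.1, 0.37, 0.82)
  theta <- decode_binary(model, matrix(0, 3, 4), c(1L, 1L, 2L),
                         ns$logit(acc))
  for (i in 1:3)
    expect_equal(unname(theta[i, ]), rep(acc[i], ncol(theta)),
                 tolerance = 1e-6)
  # limits and range
  th_lo <- decode_binary(model, matrix(0, 1, 4), 1L, -30)
  expect_true(all(th_lo < 1e-12))
  fx2 <- small_trained_vae("bernoulli")
  th <- decode_binary(fx2$model, matrix(rnorm(4), 1), 1L, 0)
  expect_true(all(th > 0 & th < 1))
})

test_that("Poisson log-likelihood at x = 0 equals -lambda and the minibatch ELBO is the mean of singleton ELBOs", {
  fx <- small_trained_vae("poisson")
  model <- fx$model
  P <- model$n_peaks
  # x = 0 row with an explicit offset: reconstruction term is -sum(lambda)
  fw <- ns$vae_forward(matrix(0, 1, P), ns$one_hot_batch(1L, model$n_batch),
                       log(5), model$params, model$config)
  expect_equal(unname(fw$recon_ll), -5, tolerance = 1e-8)
  expect_true(all(fw$kl >= 0))
  # minibatch oracle equivalence (deterministic pass)
  X <- as.matrix(fx$sim$matrix$values)[1:6, ]
  bc <- as.integer(factor(fx$sim$matrix$cells$batch))[1:6]
  batch_loss <- elbo_loss(X, model, batch_code = bc)
  singles <- vapply(1:6, function(i)
    elbo_loss(X[i, , drop = FALSE], model, batch_code = bc[i]), numeric(1))
  expect_equal(batch_loss, mean(singles), tolerance = 1e-10)
})

test_that("analytic gradients match finite differences for both likelihoods", {
  set.seed(42)
  B <- 4; P <- 10; H <- 5; d <- 3; nb <- 2
  for (lik in c("poisson", "bernoulli")) {
    cfg <- vae_config(likelihood = lik, n_latent = d, n_hidden = H,
                      dropout_rate = 0, seed = 1)
    params <- ns$init_params(P, H, d, nb)
    X <- matrix(rpois(B * P, 2), B, P)
    if (lik == "bernoulli") X <- (X > 0) * 1
    X[, 1] <- pmax(X[, 1], 1)      # no zero rows
    if (lik == "bernoulli") X[, P] <- 0  # no all-one rows
    S <- ns$one_hot_batch(rep(c(1L, 2L), 2), nb)
    off <- ns$depth_offset(X, lik)
    eps <- matrix(rnorm(B * d), B, d)
    fw <- ns$vae_forward(X, S, off, params, cfg, training = TRUE, eps = eps)
    gr <- ns$vae_backward(fw, params, cfg)
    flat <- ns$flatten_params(params)
    gflat <- ns$flatten_params(gr)
    for (nm in names(flat)) {
      idx <- sample(length(flat[[nm]]), min(3, length(flat[[nm]])))
      for (i in idx) {
        h <- 1e-5
        up <- flat; up[[nm]][i] <- up[[nm]][i] + h
        dn <- flat; dn[[nm]][i] <- dn[[nm]][i] - h
        num <- (ns$vae_forward(X, S, off, ns$unflatten_into(params, up),
                               cfg, training = TRUE, eps = eps)$loss -
                ns$vae_forward(X, S, off, ns$unflatten_into(params, dn),
                               cfg, training = TRUE, eps = eps)$loss) / (2 * h)
        expect_equal(gflat[[nm]][i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training improves the validation loss, is seed-deterministic, and rejects read counts", {
  sim <- simulate_fragments(n_cells = 300, n_peaks = 120, n_types = 2,
                            n_batches = 1, depth_meanlog = log(300),
                            seed = 14)
  cfg <- vae_config("poisson", n_latent = 4, max_epochs = 30,
                    patience = 30, seed = 5)
  m1 <- train_vae(sim$matrix, cfg)
  expect_lt(min(m1$log$val_recon_loss), m1$log$val_recon_loss[1])
  m2 <- train_vae(sim$matrix, cfg)
  expect_identical(m1$log, m2$log)
  reads <- fragments_to_reads(sim$matrix, end_loss_prob = 0)
  expect_error(train_vae(reads, cfg), "fragment counts")
})

test_that("the latent embedding has the right shape and is row-permutation equivariant", {
  fx <- small_trained_vae("poisson")
  emb <- get_latent(fx$model, fx$sim$matrix)
  expect_identical(dim(emb), c(150L, 4L))
  perm <- sample(150)
  emb_p <- get_latent(fx$model,
                      scatacounts:::matrix_subset_rows(fx$sim$matrix, perm))
  expect_equal(unname(emb_p), unname(emb[perm, ]))
  # duplicate cells embed identically
  X <- as.matrix(fx$sim$matrix$values)
  emb_d <- encode_cells(fx$model, X[c(1L, 1L, 2L), ])$mu
  expect_equal(emb_d[1, ], emb_d[2, ])
})

test_that("normalized accessibility equalizes depth and sums to the median depth", {
  fx <- small_trained_vae("poisson")
  cm <- fx$sim$matrix
  na <- normalized_accessibility(fx$model, cm)
  med <- median(Matrix::rowSums(cm$values))
  expect_lt(max(abs(rowSums(na) - med) / med), 1e-4)
  expect_true(all(na >= 0))
  # two cells with identical z but different depth get identical rows
  X <- as.matrix(cm$values)
  X2 <- rbind(X[1, ], X[1, ] * 5)  # 5x depth, same profile
  z <- encode_cells(fx$model, X2)$mu
  lam <- decode_poisson(fx$model, z[c(1, 1), , drop = FALSE], c(1L, 1L),
                        rep(log(med), 2))
  expect_equal(lam[1, ], lam[2, ])
  # bernoulli variant stays in (0, 1)
  fxb <- small_trained_vae("bernoulli")
  nab <- normalized_accessibility(fxb$model, fxb$sim$matrix)
  expect_true(all(nab > 0 & nab < 1))
})

test_that("latent sweep returns the sole grid value on a singleton grid", {
  sim <- simulate_fragments(n_cells = 80, n_peaks = 40, n_types = 2,
                            n_batches = 1, depth_meanlog = log(100),
                            seed = 15)
  cfg <- vae_config("poisson", max_epochs = 2, patience = 2, seed = 1)
  sw <- sweep_latent_dims(sim$matrix, cfg, grid = 5L)
  expect_identical(sw$best_n_latent, 5L)
  expect_identical(names(sw$scores), "5")
})

test_that("cells with the same profile at 5x depth stay closer than other cell types in latent space", {
  fx <- small_trained_vae("poisson")
  sim <- fx$sim
  X <- as.matrix(sim$matrix$values)
  types <- sim$truth$cell_type
  i1 <- which(types == "type1")[1:20]
  emb_base <- encode_cells(fx$model, X[i1, ])$mu
  emb_deep <- encode_cells(fx$model, X[i1, ] * 5)$mu
  other <- encode_cells(fx$model, X[types == "type2", ][1:20, ])$mu
  d_same <- sqrt(rowSums((emb_base - emb_deep)^2))
  d_other <- apply(emb_base, 1, function(r)
    median(sqrt(colSums((t(other) - r)^2))))
  expect_lt(median(d_same), median(d_other))
})
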