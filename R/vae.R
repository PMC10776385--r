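#' VAE configuration
#'
#' Hyperparameters for [train_vae]. Defaults follow common practice for
#' accessibility VAEs: learning rate 1e-4, weight decay 1e-3, minibatch
#' size 128, hidden width equal to the square root of the number of peaks,
#' and early stopping on the validation reconstruction loss.
#'
#' @param likelihood `"poisson"` (fragment counts, softmax decoder with a
#'   log-depth offset) or `"bernoulli"` (binarized counts, sigmoid decoder
#'   with a logit-mean-accessibility offset).
#' @param n_latent Latent dimensionality.
#' @param n_hidden Hidden width; `NULL` means `round(sqrt(P))`.
#' @param dropout_rate Dropout probability in the encoder/decoder blocks.
#' @param learning_rate,weight_decay Adam learning rate and L2 weight
#'   decay (applied through the gradient, as in the usual Adam
#'   `weight_decay` argument).
#' @param minibatch_size Cells per gradient step.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param kl_weight Weight of the KL term (1 = plain ELBO, no annealing).
#' @param seed Integer seed controlling the split, initialization,
#'   dropout, minibatch order and the reparameterization noise.
#' @return A `vae_config` list.
#' @export
vae_config <- function(likelihood = c("poisson", "bernoulli"),
                       n_latent = 10L, n_hidden = NULL,
                       dropout_rate = 0.1, learning_rate = 1e-4,
                       weight_decay = 1e-3, minibatch_size = 128L,
                       max_epochs = 300L, patience = 20L,
                       kl_weight = 1, seed = 0L) {
  likelihood <- match.arg(likelihood)
  stopifnot(n_latent >= 1, dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, minibatch_size >= 1, max_epochs >= 1)
  structure(list(likelihood = likelihood, n_latent = as.integer(n_latent),
                 n_hidden = n_hidden, dropout_rate = dropout_rate,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 minibatch_size = as.integer(minibatch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), kl_weight = kl_weight,
                 seed = as.integer(seed)),
            class = "vae_config")
}

# ---- numerics -------------------------------------------------------------

lrelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p) - log1p(-p)

row_log_softmax <- function(eta) {
  m <- apply(eta, 1, max)
  s <- eta - m
  s - log(rowSums(exp(s)))
}

#' Poisson rate to Bernoulli probability
#'
#' Probability of observing at least one fragment under a Poisson rate:
#' `theta = 1 - exp(-lambda)`. Used to score quantitative models on the
#' binarized reconstruction task.
#'
#' @param lambda Non-negative rates.
#' @return Probabilities in `[0, 1)`.
#' @export
poisson_rate_to_bernoulli <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  -expm1(-lambda)
}

# ---- parameter initialization --------------------------------------------

init_linear <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
       b = stats::runif(n_out, -bound, bound))
}

init_block <- function(n_in, n_out) {
  lin <- init_linear(n_in, n_out)
  list(W = lin$W, b = lin$b, g = rep(1, n_out), beta = rep(0, n_out))
}

init_params <- function(P, H, d, n_batch) {
  p <- list()
  p$e1 <- init_block(P, H)
  p$e2 <- init_block(H, H)
  p$mu <- init_linear(H, d)
  p$ls <- init_linear(H, d)
  p$d1 <- init_block(d + n_batch, H)
  p$d2 <- init_block(H, H)
  p$out <- init_linear(H, P)
  p$r <- rep(0, P)
  p
}

# ---- block forward / backward --------------------------------------------
# block: affine -> dropout -> layer norm -> leaky ReLU

block_forward <- function(x, blk, dropout_rate, training) {
  a <- sweep(x %*% blk$W, 2, blk$b, "+")
  if (training && dropout_rate > 0) {
    mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout_rate) /
                     (1 - dropout_rate), nrow(a), ncol(a))
    dmat <- a * mask
  } else {
    mask <- NULL
    dmat <- a
  }
  mu <- rowMeans(dmat)
  ctr <- dmat - mu
  v <- rowMeans(ctr^2)
  inv <- 1 / sqrt(v + 1e-5)
  xhat <- ctr * inv
  pre <- sweep(sweep(xhat, 2, blk$g, "*"), 2, blk$beta, "+")
  h <- lrelu(pre)
  list(h = h, cache = list(x = x, mask = mask, xhat = xhat, inv = inv,
                           pre = pre))
}

block_backward <- function(dh, blk, cache, slope = 0.01) {
  dpre <- dh * ifelse(cache$pre > 0, 1, slope)
  dg <- colSums(dpre * cache$xhat)
  dbeta <- colSums(dpre)
  dxhat <- sweep(dpre, 2, blk$g, "*")
  # layer norm backward (per row, population variance)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  du <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  if (!is.null(cache$mask)) du <- du * cache$mask
  dW <- crossprod(cache$x, du)
  db <- colSums(du)
  dx <- du %*% t(blk$W)
  list(dx = dx, grads = list(W = dW, b = db, g = dg, beta = dbeta))
}

# ---- full forward / backward ---------------------------------------------

# X: dense minibatch (B x P of counts for poisson / 0-1 for bernoulli)
# S: one-hot batch matrix (B x n_batch); offset: per-cell depth offset
vae_forward <- function(X, S, offset, params, cfg, training = FALSE,
                        eps = NULL, kl_weight = 1) {
  f1 <- block_forward(X, params$e1, cfg$dropout_rate, training)
  f2 <- block_forward(f1$h, params$e2, cfg$dropout_rate, training)
  mu_z <- sweep(f2$h %*% params$mu$W, 2, params$mu$b, "+")
  logsig <- sweep(f2$h %*% params$ls$W, 2, params$ls$b, "+")
  logsig <- pmin(pmax(logsig, -10), 10)
  sig <- exp(logsig)
  if (training) {
    if (is.null(eps)) eps <- matrix(stats::rnorm(length(mu_z)),
                                    nrow(mu_z), ncol(mu_z))
    z <- mu_z + sig * eps
  } else {
    eps <- NULL
    z <- mu_z
  }
  u <- cbind(z, S)
  g1 <- block_forward(u, params$d1, cfg$dropout_rate, training)
  g2 <- block_forward(g1$h, params$d2, cfg$dropout_rate, training)
  rho <- sweep(g2$h %*% params$out$W, 2, params$out$b, "+")
  eta <- sweep(rho, 2, params$r, "+")
  B <- nrow(X)
  if (cfg$likelihood == "poisson") {
    ls_eta <- row_log_softmax(eta)
    loglam <- ls_eta + offset
    lam <- exp(loglam)
    recon_ll <- rowSums(X * loglam - lam - lgamma(X + 1))
    extra <- list(lambda = lam, log_softmax = ls_eta)
  } else {
    etap <- eta + offset
    recon_ll <- rowSums(X * etap - softplus(etap))
    extra <- list(theta = sigmoid(etap))
  }
  kl <- 0.5 * rowSums(mu_z^2 + sig^2 - 1 - 2 * logsig)
  loss <- mean(-recon_ll + kl_weight * kl)
  if (!all(is.finite(loss)))
    stop("non-finite loss (",
         if (!all(is.finite(recon_ll))) "reconstruction term"
         else "KL term", ")")
  list(loss = loss, recon_ll = recon_ll, kl = kl, mu = mu_z, sig = sig,
       logsig = logsig, z = z, eta = eta, extra = extra,
       cache = list(f1 = f1, f2 = f2, g1 = g1, g2 = g2, eps = eps,
                    X = X, S = S, offset = offset, h_enc = f2$h,
                    h_dec = g2$h, u = u))
}

vae_backward <- function(fw, params, cfg, kl_weight = 1) {
  ca <- fw$cache
  B <- nrow(ca$X)
  if (cfg$likelihood == "poisson") {
    # d(-ll)/d eta = rowTotal * softmax - x   (sum_p lambda is offset-const)
    sm <- exp(fw$extra$log_softmax)
    g_eta <- (rowSums(ca$X) * sm - ca$X) / B
  } else {
    g_eta <- (fw$extra$theta - ca$X) / B
  }
  grads <- list()
  grads$r <- colSums(g_eta)
  grads$out <- list(W = crossprod(ca$h_dec, g_eta), b = colSums(g_eta))
  dh2 <- g_eta %*% t(params$out$W)
  b2 <- block_backward(dh2, params$d2, ca$g2$cache)
  grads$d2 <- b2$grads
  b1 <- block_backward(b2$dx, params$d1, ca$g1$cache)
  grads$d1 <- b1$grads
  du <- b1$dx
  d_z <- du[, seq_len(cfg$n_latent), drop = FALSE]
  # KL gradients
  d_mu <- d_z + kl_weight * fw$mu / B
  d_logsig <- kl_weight * (fw$sig^2 - 1) / B
  if (!is.null(ca$eps)) d_logsig <- d_logsig + d_z * ca$eps * fw$sig
  # the clamp on logsig has zero gradient where it is active
  clipped <- fw$logsig <= -10 | fw$logsig >= 10
  if (any(clipped)) d_logsig[clipped] <- 0
  grads$mu <- list(W = crossprod(ca$h_enc, d_mu), b = colSums(d_mu))
  grads$ls <- list(W = crossprod(ca$h_enc, d_logsig), b = colSums(d_logsig))
  dh_enc <- d_mu %*% t(params$mu$W) + d_logsig %*% t(params$ls$W)
  e2 <- block_backward(dh_enc, params$e2, ca$f2$cache)
  grads$e2 <- e2$grads
  e1 <- block_backward(e2$dx, params$e1, ca$f1$cache)
  grads$e1 <- e1$grads
  grads
}

# ---- Adam -----------------------------------------------------------------

flatten_params <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      for (k in names(p[[nm]])) out[[paste0(nm, ".", k)]] <- p[[nm]][[k]]
    } else out[[nm]] <- p[[nm]]
  }
  out
}

unflatten_into <- function(p, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) p[[parts[1]]][[parts[2]]] <- flat[[nm]]
    else p[[nm]] <- flat[[nm]]
  }
  p
}

adam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(fp)) {
    g <- fg[[nm]] + weight_decay * fp[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    fp[[nm]] <- fp[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = unflatten_into(params, fp), state = state)
}

# ---- offsets and input preparation ---------------------------------------

depth_offset <- function(X_dense, likelihood) {
  if (likelihood == "poisson") {
    tot <- rowSums(X_dense)
    if (any(tot <= 0)) stop("cells with zero total count have no offset")
    log(tot)
  } else {
    frac <- rowMeans(X_dense)
    if (any(frac <= 0) || any(frac >= 1))
      stop("logit offset undefined for all-zero or all-one cells")
    logit(frac)
  }
}

one_hot_batch <- function(batch_codes, n_batch) {
  S <- matrix(0, length(batch_codes), n_batch)
  S[cbind(seq_along(batch_codes), batch_codes)] <- 1
  S
}

prepare_model_input <- function(matrix, likelihood) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (matrix$kind == "reads")
    stop("read counts are rejected: fragment counts, not read counts, ",
         "should be modeled; run reads_to_fragments() first")
  if (likelihood == "poisson") {
    if (matrix$kind != "fragments")
      stop("the poisson likelihood requires kind = 'fragments'")
    matrix
  } else {
    if (matrix$kind == "binary") matrix else binarize(matrix)
  }
}

# ---- training -------------------------------------------------------------

#' Train an accessibility VAE
#'
#' Fits a variational autoencoder to a cell-by-peak matrix. The generative
#' model draws a latent `z_c` from a diagonal Gaussian whose parameters
#' are encoded from the cell's count vector; a decoder maps `z_c`
#' concatenated with the one-hot batch label back to peak space, adds a
#' learned per-region bias `r_p`, and
#' \itemize{
#'   \item Poisson: applies a softmax so predicted per-peak weights sum to
#'     one, then scales by the observed total fragment count
#'     (`lambda = exp(l_c) * softmax(rho + r)`), so each cell's predicted
#'     total equals its observed total by construction;
#'   \item Bernoulli: adds the cell's logit mean accessibility and applies
#'     a sigmoid (`theta = sigmoid(rho + r + ltilde_c)`).
#' }
#' Both depth offsets are precomputed, not learned. The objective is the
#' negative ELBO; optimization is Adam with minibatches, early-stopped on
#' the validation reconstruction loss over a random 80/10/10
#' train/validation/test split. Cells with zero total count (no defined
#' offset) are dropped with a message.
#'
#' @param matrix A [count_matrix]; `fragments` for the Poisson likelihood,
#'   `binary` (or `fragments`, binarized internally) for the Bernoulli
#'   likelihood. Read-count matrices are rejected.
#' @param config A [vae_config].
#' @param verbose Print per-epoch losses.
#' @return An object of class `scatac_vae`: parameters, config, batch
#'   levels, the split indices (`train`, `validation`, `test`, relative to
#'   the retained cells, plus `kept_cells`), and a data.frame `log` of
#'   per-epoch train/validation losses.
#' @export
train_vae <- function(matrix, config = vae_config(), verbose = FALSE) {
  input <- prepare_model_input(matrix, config$likelihood)
  X <- as_dense(input$values)
  tot <- rowSums(X)
  keep <- which(tot > 0 & (config$likelihood == "poisson" |
                             rowMeans(X > 0) < 1))
  n_drop <- nrow(X) - length(keep)
  if (n_drop > 0)
    message(n_drop, " cell(s) without a defined depth offset dropped")
  X <- X[keep, , drop = FALSE]
  batch_f <- factor(input$cells$batch[keep])
  batch_codes <- as.integer(batch_f)
  n_batch <- nlevels(batch_f)
  N <- nrow(X); P <- ncol(X)
  if (N < 10) stop("need at least 10 usable cells for an 80/10/10 split")
  offset <- depth_offset(X, config$likelihood)
  H <- if (is.null(config$n_hidden)) max(8L, round(sqrt(P))) else
    as.integer(config$n_hidden)

  set.seed(config$seed)
  perm <- sample.int(N)
  n_train <- floor(0.8 * N)
  n_val <- floor(0.1 * N)
  split <- list(train = perm[seq_len(n_train)],
                validation = perm[n_train + seq_len(n_val)],
                test = perm[(n_train + n_val + 1):N],
                kept_cells = keep)
  params <- init_params(P, H, config$n_latent, n_batch)
  opt <- adam_init(params)
  Xtr <- X[split$train, , drop = FALSE]
  Str <- one_hot_batch(batch_codes[split$train], n_batch)
  otr <- offset[split$train]
  Xva <- X[split$validation, , drop = FALSE]
  Sva <- one_hot_batch(batch_codes[split$validation], n_batch)
  ova <- offset[split$validation]

  val_recon <- function() {
    fw <- vae_forward(Xva, Sva, ova, params, config, training = FALSE,
                      kl_weight = config$kl_weight)
    mean(-fw$recon_ll)
  }
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_recon_loss = numeric(0))
  mb <- config$minibatch_size
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nrow(Xtr))
    starts <- seq(1, length(ord), by = mb)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + mb - 1, length(ord))]
      fw <- vae_forward(Xtr[idx, , drop = FALSE],
                        Str[idx, , drop = FALSE], otr[idx],
                        params, config, training = TRUE,
                        kl_weight = config$kl_weight)
      gr <- vae_backward(fw, params, config, kl_weight = config$kl_weight)
      st <- adam_step(params, gr, opt, config$learning_rate,
                      config$weight_decay)
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + fw$loss * length(idx)
    }
    vl <- val_recon()
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = ep_loss / length(ord),
                                 val_recon_loss = vl))
    if (verbose)
      message(sprintf("epoch %d train %.3f val %.3f", epoch,
                      ep_loss / length(ord), vl))
    if (vl < best$loss) {
      best <- list(loss = vl, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best$params,
                 config = config,
                 n_hidden = H, n_peaks = P, n_batch = n_batch,
                 batch_levels = levels(batch_f),
                 peak_ids = input$peaks$peak_id,
                 split = split, log = log,
                 best_epoch = best$epoch,
                 n_dropped_cells = n_drop),
            class = "scatac_vae")
}

#' @export
print.scatac_vae <- function(x, ...) {
  cat(sprintf(
    "scatac_vae [%s]: %d peaks, %d latent, %d hidden, %d batch level(s)\n",
    x$config$likelihood, x$n_peaks, x$config$n_latent, x$n_hidden,
    x$n_batch))
  cat(sprintf("  best epoch %d, val recon loss %.4f\n", x$best_epoch,
              min(x$log$val_recon_loss)))
  invisible(x)
}

# dense model-ready rows for a fitted model
model_input_rows <- function(model, matrix) {
  input <- prepare_model_input(matrix, model$config$likelihood)
  if (ncol(input$values) != model$n_peaks)
    stop("matrix has ", ncol(input$values), " peaks but the model expects ",
         model$n_peaks)
  input
}

#' Encode cells into the posterior parameters
#'
#' Deterministic encoder pass (dropout off): returns the posterior mean
#' and standard deviation of the latent variable for each row.
#'
#' @param model A fitted `scatac_vae`.
#' @param x Numeric matrix of rows matching the model's peak dimension, or
#'   a [count_matrix].
#' @return A list with matrices `mu` and `sigma` (strictly positive).
#' @export
encode_cells <- function(model, x) {
  if (inherits(x, "count_matrix")) x <- as_dense(model_input_rows(model, x)$values)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite encoder input")
  if (ncol(x) != model$n_peaks) stop("input has wrong peak dimension")
  p <- model$params; cfg <- model$config
  f1 <- block_forward(x, p$e1, 0, FALSE)
  f2 <- block_forward(f1$h, p$e2, 0, FALSE)
  mu <- sweep(f2$h %*% p$mu$W, 2, p$mu$b, "+")
  logsig <- pmin(pmax(sweep(f2$h %*% p$ls$W, 2, p$ls$b, "+"), -10), 10)
  list(mu = mu, sigma = exp(logsig))
}

#' Latent embedding of a dataset
#'
#' Posterior means of all cells (the representation used by every
#' downstream metric). Deterministic and row-order equivariant.
#'
#' @param model A fitted `scatac_vae`.
#' @param matrix A [count_matrix] with the model's peak set.
#' @return A cells x n_latent numeric matrix with barcode rownames.
#' @export
get_latent <- function(model, matrix) {
  input <- model_input_rows(model, matrix)
  enc <- encode_cells(model, as_dense(input$values))
  emb <- enc$mu
  rownames(emb) <- input$cells$barcode
  emb
}

decoder_eta <- function(model, z, batch_code) {
  p <- model$params
  if (any(batch_code < 1 | batch_code > model$n_batch))
    stop("unknown batch code")
  S <- one_hot_batch(as.integer(batch_code), model$n_batch)
  u <- cbind(z, S)
  g1 <- block_forward(u, p$d1, 0, FALSE)
  g2 <- block_forward(g1$h, p$d2, 0, FALSE)
  rho <- sweep(g2$h %*% p$out$W, 2, p$out$b, "+")
  sweep(rho, 2, p$r, "+")
}

#' Decode Poisson rates
#'
#' `lambda = exp(l_c) * softmax(rho + r)`: by the softmax construction each
#' row of rates sums exactly to `exp(l_c)`, the cell's (observed or
#' chosen) total fragment count.
#'
#' @param model A fitted `scatac_vae` with the Poisson likelihood.
#' @param z Latent rows (cells x n_latent).
#' @param batch_code Integer batch codes (1-based into
#'   `model$batch_levels`).
#' @param l_c Per-cell log total fragment count.
#' @return A cells x peaks matrix of non-negative rates.
#' @export
decode_poisson <- function(model, z, batch_code, l_c) {
  if (model$config$likelihood != "poisson")
    stop("model does not have a poisson likelihood")
  if (!all(is.finite(l_c))) stop("l_c must be finite")
  eta <- decoder_eta(model, as.matrix(z), batch_code)
  exp(row_log_softmax(eta) + l_c)
}

#' Decode Bernoulli accessibility probabilities
#'
#' `theta = sigmoid(rho + r + ltilde_c)`. With a zeroed decoder and zero
#' region bias, `theta` equals the cell's mean accessibility (the
#' sigmoid/logit identity).
#'
#' @param model A fitted `scatac_vae` with the Bernoulli likelihood.
#' @param z Latent rows.
#' @param batch_code Integer batch codes.
#' @param l_tilde Per-cell logit mean accessibility.
#' @return A cells x peaks matrix of probabilities in (0, 1).
#' @export
decode_binary <- function(model, z, batch_code, l_tilde) {
  if (model$config$likelihood != "bernoulli")
    stop("model does not have a bernoulli likelihood")
  if (!all(is.finite(l_tilde))) stop("l_tilde must be finite")
  eta <- decoder_eta(model, as.matrix(z), batch_code)
  sigmoid(eta + l_tilde)
}

#' ELBO loss of a batch of cells
#'
#' Mean over cells of the negative ELBO (negative reconstruction
#' log-likelihood plus weighted KL to the standard normal prior). By
#' default the pass is deterministic (dropout off, `z` at the posterior
#' mean), so the minibatch value equals the mean of the per-cell values.
#'
#' @param x_batch Rows of counts (matrix) matching the model input space.
#' @param model A fitted (or freshly initialized) `scatac_vae`.
#' @param batch_code Integer batch codes, recycled if length 1.
#' @param offset Per-cell depth offsets.
#' @param sample Draw `z` stochastically instead of using the mean.
#' @return A finite scalar.
#' @export
elbo_loss <- function(x_batch, model, batch_code = 1L, offset = NULL,
                      sample = FALSE) {
  x_batch <- as.matrix(x_batch)
  if (is.null(offset))
    offset <- depth_offset(x_batch, model$config$likelihood)
  bc <- rep_len(as.integer(batch_code), nrow(x_batch))
  S <- one_hot_batch(bc, model$n_batch)
  fw <- vae_forward(x_batch, S, offset, model$params, model$config,
                    training = sample, kl_weight = model$config$kl_weight)
  fw$loss
}

#' Predicted probability of observing an open peak
#'
#' Reconstruction probabilities for the binarized matrix: the Bernoulli
#' model's `theta` directly, or the Poisson model's
#' `1 - exp(-lambda)` (probability of at least one fragment).
#'
#' @param model A fitted `scatac_vae`.
#' @param matrix A [count_matrix] over the model's peaks.
#' @param cells Optional integer subset of cells (rows).
#' @return A cells x peaks matrix of probabilities.
#' @export
predict_open_probability <- function(model, matrix, cells = NULL) {
  input <- model_input_rows(model, matrix)
  X <- as_dense(input$values)
  if (!is.null(cells)) X <- X[cells, , drop = FALSE]
  bc <- as.integer(factor(as.character(input$cells$batch),
                          levels = model$batch_levels))
  if (!is.null(cells)) bc <- bc[cells]
  if (any(is.na(bc))) stop("unknown batch label")
  offset <- depth_offset(X, model$config$likelihood)
  z <- encode_cells(model, X)$mu
  if (model$config$likelihood == "poisson") {
    poisson_rate_to_bernoulli(decode_poisson(model, z, bc, offset))
  } else {
    decode_binary(model, z, bc, offset)
  }
}

#' Depth-normalized accessibility
#'
#' Denoised accessibility at a common depth: the per-cell offset is
#' replaced by the same constant for every cell — the log median total
#' fragment count (Poisson) or the logit median per-cell mean
#' accessibility (Bernoulli) — so cells of different sequencing depth
#' become comparable. For the Poisson model every row of the full-peak
#' output sums to the median depth.
#'
#' @param model A fitted `scatac_vae`.
#' @param matrix A [count_matrix] over the model's peaks.
#' @param peak_subset Optional integer or character (peak id) subset of
#'   columns to return.
#' @return A cells x peaks (or subset) matrix.
#' @export
normalized_accessibility <- function(model, matrix, peak_subset = NULL) {
  input <- model_input_rows(model, matrix)
  X <- as_dense(input$values)
  bc <- as.integer(factor(as.character(input$cells$batch),
                          levels = model$batch_levels))
  if (any(is.na(bc))) stop("unknown batch label")
  if (model$config$likelihood == "poisson") {
    med <- stats::median(rowSums(X))
    if (med <= 0) stop("median total fragment count is zero")
    const <- log(med)
  } else {
    med <- stats::median(rowMeans(X))
    if (med <= 0 || med >= 1)
      stop("median mean accessibility is degenerate")
    const <- logit(med)
  }
  z <- encode_cells(model, X)$mu
  out <- if (model$config$likelihood == "poisson")
    decode_poisson(model, z, bc, const)
  else decode_binary(model, z, bc, const)
  colnames(out) <- model$peak_ids
  rownames(out) <- input$cells$barcode
  if (!is.null(peak_subset)) out <- out[, peak_subset, drop = FALSE]
  out
}

#' Select the latent dimensionality by validation reconstruction
#'
#' Trains one model per grid value and scores the binarized
#' reconstruction of the validation cells by average precision; returns
#' the grid value with the best score (ties go to the smallest).
#'
#' @param matrix A [count_matrix].
#' @param config A [vae_config] (its `n_latent` is overridden).
#' @param grid Candidate latent dimensionalities (default 10 to 100 in
#'   steps of 10).
#' @return A list with `best_n_latent`, `scores` (named by grid value) and
#'   `models`.
#' @export
sweep_latent_dims <- function(matrix, config = vae_config(),
                              grid = seq(10L, 100L, by = 10L)) {
  if (!length(grid)) stop("grid must be non-empty")
  scores <- numeric(length(grid))
  models <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- config
    cfg$n_latent <- as.integer(grid[i])
    m <- train_vae(matrix, cfg)
    input <- prepare_model_input(matrix, cfg$likelihood)
    y <- as_dense(binarize(input)$values)
    kept <- m$split$kept_cells
    vidx <- m$split$validation
    theta <- predict_open_probability(m, matrix_subset_rows(input, kept),
                                      cells = vidx)
    scores[i] <- average_precision(as.vector(theta),
                                   as.vector(y[kept, ][vidx, ]))
    models[[i]] <- m
  }
  names(scores) <- grid
  list(best_n_latent = grid[which.max(scores)], scores = scores,
       models = models)
}

# internal: subset rows of a count_matrix
matrix_subset_rows <- function(x, idx) {
  cells <- x$cells[idx, , drop = FALSE]
  cells$total_fragments <- NULL
  class(cells) <- c("cell_table", "data.frame")
  count_matrix(x$values[idx, , drop = FALSE], kind = x$kind,
               cells = cells, peaks = x$peaks)
}
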