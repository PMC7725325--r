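# Native implementation of the two-branch convolutional classifier.
#
# Both network inputs are one-hot, so the length-6 one-dimensional
# convolution factorizes exactly into six shifted embedding lookups:
# for a window starting at position p, conv(k, p) = sum_d E_d[code_{p+d-1}, k]
# where E_d is the d-th kernel slice indexed by symbol. This avoids
# materializing the dense one-hot matrices and their GEMM against mostly-zero
# inputs, which is what makes CPU training practical at package scale.
# Gradients scatter back into the slices with rowsum(). Index 0 (ambiguous
# symbol or padding) maps to a permanently zero first row.

.nn_he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# parameter initialization for a model config (called under the config seed)
.nn_init_params <- function(cfg) {
  Kt <- cfg$kernels_triplet; Kb <- cfg$kernels_base
  klen <- cfg$kernel_len; H <- cfg$hidden
  zero_top <- function(m) { m[1L, ] <- 0; m }
  params <- list(
    Et = lapply(seq_len(klen), function(d)
      zero_top(.nn_he_init(65L, Kt, fan_in = klen * 64L))),
    bt = numeric(Kt),
    Eb = lapply(seq_len(klen), function(d)
      zero_top(.nn_he_init(5L, Kb, fan_in = klen * 4L))),
    bb = numeric(Kb),
    bn1_gamma = rep(1, Kt + Kb), bn1_beta = numeric(Kt + Kb),
    W1 = .nn_he_init(Kt + Kb, H, fan_in = Kt + Kb), b1 = numeric(H),
    bn2_gamma = rep(1, H), bn2_beta = numeric(H),
    W2 = .nn_he_init(H, 1L, fan_in = H), b2 = 0
  )
  params
}

.nn_init_bn_state <- function(cfg) {
  d1 <- cfg$kernels_triplet + cfg$kernels_base
  list(bn1_mean = numeric(d1), bn1_var = rep(1, d1),
       bn2_mean = numeric(cfg$hidden), bn2_var = rep(1, cfg$hidden))
}

# forward pass of one convolution branch.
#   codes: B x T integer matrix (0 = ambiguous/pad), W: list of klen
#   embedding slices, b: bias, wts: B x P pooling-weight matrix.
# Returns pooled B x K features (+ cache for backward when training).
.nn_branch_forward <- function(codes, W, b, wts, training = FALSE) {
  klen <- length(W)
  B <- nrow(codes)
  P <- ncol(codes) - klen + 1L
  K <- ncol(W[[1L]])
  idx0 <- codes + 1L
  acc <- matrix(0, B * P, K)
  for (d in seq_len(klen)) {
    acc <- acc + W[[d]][as.vector(idx0[, d:(d + P - 1L), drop = FALSE]), ,
                        drop = FALSE]
  }
  acc <- sweep(acc, 2L, b, "+")
  relu_mask <- acc > 0
  acc[!relu_mask] <- 0
  wv <- as.vector(wts)
  pooled <- rowsum(acc * wv, group = rep(seq_len(B), times = P))
  if (!training) return(list(pooled = pooled))
  list(pooled = pooled,
       cache = list(idx0 = idx0, relu_mask = relu_mask, wv = wv,
                    B = B, P = P, klen = klen, K = K,
                    n_rows = nrow(W[[1L]])))
}

# backward pass of one branch; returns gradients for W (list) and b
.nn_branch_backward <- function(dpooled, cache) {
  B <- cache$B; P <- cache$P; klen <- cache$klen
  dZ <- dpooled[rep(seq_len(B), times = P), , drop = FALSE] * cache$wv
  dZ[!cache$relu_mask] <- 0
  db <- colSums(dZ)
  dW <- vector("list", klen)
  for (d in seq_len(klen)) {
    g <- rowsum(dZ, group = as.vector(cache$idx0[, d:(d + P - 1L),
                                                 drop = FALSE]))
    full <- matrix(0, cache$n_rows, cache$K)
    full[as.integer(rownames(g)), ] <- g
    full[1L, ] <- 0  # ambiguous/padding row stays zero
    dW[[d]] <- full
  }
  list(dW = dW, db = db)
}

.BN_EPS <- 1e-5

.nn_bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                           momentum = 0.9) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v[v < 0] <- 0
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv_sd <- 1 / sqrt(v + .BN_EPS)
  xhat <- sweep(sweep(x, 2L, mu, "-"), 2L, inv_sd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  new_run <- if (training) {
    list(mean = momentum * run_mean + (1 - momentum) * mu,
         var = momentum * run_var + (1 - momentum) * v)
  } else {
    list(mean = run_mean, var = run_var)
  }
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma),
       run = new_run)
}

.nn_bn_backward <- function(dy, cache) {
  B <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, cache$gamma, "*")
  mean_dxhat <- colMeans(dxhat)
  mean_dxhat_xhat <- colMeans(dxhat * cache$xhat)
  dx <- sweep(
    dxhat - matrix(mean_dxhat, B, length(mean_dxhat), byrow = TRUE) -
      cache$xhat * matrix(mean_dxhat_xhat, B, length(mean_dxhat_xhat),
                          byrow = TRUE),
    2L, cache$inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# full forward: returns sigmoid scores; when training, the caches needed for
# backprop and updated batch-norm running statistics
.nn_forward <- function(params, bn_state, batch, training = FALSE) {
  ft <- .nn_branch_forward(batch$tcodes, params$Et, params$bt, batch$wt,
                           training)
  fb <- .nn_branch_forward(batch$bcodes, params$Eb, params$bb, batch$wb,
                           training)
  x <- cbind(ft$pooled, fb$pooled)
  bn1 <- .nn_bn_forward(x, params$bn1_gamma, params$bn1_beta,
                        bn_state$bn1_mean, bn_state$bn1_var, training)
  h <- sweep(bn1$y %*% params$W1, 2L, params$b1, "+")
  hr_mask <- h > 0
  hr <- h * hr_mask
  bn2 <- .nn_bn_forward(hr, params$bn2_gamma, params$bn2_beta,
                        bn_state$bn2_mean, bn_state$bn2_var, training)
  logit <- drop(bn2$y %*% params$W2) + params$b2
  score <- stats::plogis(logit)
  out <- list(score = score)
  if (training) {
    out$cache <- list(ft = ft$cache, fb = fb$cache, bn1 = bn1$cache,
                      y1 = bn1$y, hr_mask = hr_mask, hr = hr,
                      bn2 = bn2$cache, y2 = bn2$y, logit = logit)
    out$bn_state <- list(bn1_mean = bn1$run$mean, bn1_var = bn1$run$var,
                         bn2_mean = bn2$run$mean, bn2_var = bn2$run$var)
  }
  out
}

# backward from binary cross-entropy; returns gradient list aligned with
# params
.nn_backward <- function(params, cache, score, y, Kt) {
  B <- length(y)
  dlogit <- (score - y) / B
  dW2 <- t(cache$y2) %*% matrix(dlogit, ncol = 1L)
  db2 <- sum(dlogit)
  dy2 <- matrix(dlogit, ncol = 1L) %*% t(params$W2)
  bn2 <- .nn_bn_backward(dy2, cache$bn2)
  dhr <- bn2$dx
  dh <- dhr * cache$hr_mask
  dW1 <- t(cache$y1) %*% dh
  db1 <- colSums(dh)
  dy1 <- dh %*% t(params$W1)
  bn1 <- .nn_bn_backward(dy1, cache$bn1)
  dx <- bn1$dx
  gt <- .nn_branch_backward(dx[, seq_len(Kt), drop = FALSE], cache$ft)
  gb <- .nn_branch_backward(dx[, -seq_len(Kt), drop = FALSE], cache$fb)
  list(Et = gt$dW, bt = gt$db, Eb = gb$dW, bb = gb$db,
       bn1_gamma = bn1$dgamma, bn1_beta = bn1$dbeta,
       W1 = dW1, b1 = db1,
       bn2_gamma = bn2$dgamma, bn2_beta = bn2$dbeta,
       W2 = dW2, b2 = db2)
}

# ---- Adam optimizer over the nested parameter list ----

.nn_adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

.nn_adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  params <- lapply(out, `[[`, "p")
  state$m <- lapply(out, `[[`, "m")
  state$v <- lapply(out, `[[`, "v")
  # keep the ambiguous/padding embedding rows pinned at zero
  params$Et <- lapply(params$Et, function(m) { m[1L, ] <- 0; m })
  params$Eb <- lapply(params$Eb, function(m) { m[1L, ] <- 0; m })
  list(params = params, state = state)
}

.nn_bce <- function(score, y, eps = 1e-12) {
  s <- pmin(pmax(score, eps), 1 - eps)
  -mean(y * log(s) + (1 - y) * log(1 - s))
}
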