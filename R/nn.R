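# Minimal dense/message-passing neural-network engine with manual
# backpropagation and an Adam optimizer. Kept deliberately small: only the
# layer types the autoencoders need (affine + tanh hidden layers, sigmoid
# heads, inverted dropout, two rounds of mean-aggregation message passing,
# Gaussian and exponential reparameterized latent heads).

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

dense_init <- function(fan_in, fan_out) {
  list(W = glorot(fan_in, fan_out), b = rep(0, fan_out))
}

affine <- function(x, layer) sweep(x %*% layer$W, 2, layer$b, "+")

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- parameter containers -------------------------------------------------

init_tabular_params <- function(d, h1, h2, L, variational, vae_prior) {
  params <- list(
    enc1 = dense_init(d, h1),
    enc2 = dense_init(h1, h2),
    lat  = dense_init(h2, L),
    dec1 = dense_init(L, h2),
    dec2 = dense_init(h2, h1),
    out  = dense_init(h1, d)
  )
  if (variational && vae_prior == "gaussian") {
    params$latv <- dense_init(h2, L)
  }
  params
}

init_mp_params <- function(channels, identity = FALSE) {
  if (identity) {
    # exact identity front end (requires identity activation): one pass-through
    # self-term per round, no neighbor term
    return(list(
      mp1 = list(ws = rep(1, channels), wn = rep(0, channels), b = rep(0, channels)),
      mp2 = list(ws = rep(1 / channels, channels), wn = rep(0, channels), b = 0)
    ))
  }
  lim1 <- sqrt(6 / (1 + channels))
  lim2 <- sqrt(6 / (channels + 1))
  list(
    mp1 = list(ws = runif(channels, -lim1, lim1),
               wn = runif(channels, -lim1, lim1),
               b = rep(0, channels)),
    mp2 = list(ws = runif(channels, -lim2, lim2),
               wn = runif(channels, -lim2, lim2),
               b = 0)
  )
}

# --- forward pass ---------------------------------------------------------

# Message-passing front end: x is B x N node-feature matrix (one feature per
# node), M the row-normalized adjacency. Two rounds: 1 -> C channels -> 1,
# tanh nonlinearity, mean aggregation over neighbors.
mp_forward <- function(x, params, M, activation = "tanh") {
  act <- if (activation == "identity") identity else tanh
  B <- nrow(x); N <- ncol(x); C <- length(params$mp1$ws)
  xm <- x %*% t(M)                              # neighbor means, B x N
  H1 <- array(0, c(B, N, C))
  for (c in seq_len(C)) {
    H1[, , c] <- act(x * params$mp1$ws[c] + xm * params$mp1$wn[c] + params$mp1$b[c])
  }
  agg1 <- array(0, c(B, N, C))
  pre2 <- matrix(params$mp2$b, B, N)
  for (c in seq_len(C)) {
    agg1[, , c] <- H1[, , c] %*% t(M)
    pre2 <- pre2 + H1[, , c] * params$mp2$ws[c] + agg1[, , c] * params$mp2$wn[c]
  }
  H2 <- act(pre2)
  list(H2 = H2, H1 = H1, agg1 = agg1, x = x, xm = xm, activation = activation)
}

mp_backward <- function(dH2, cache, params, M) {
  C <- length(params$mp1$ws)
  dpre2 <- if (cache$activation == "identity") dH2 else dH2 * (1 - cache$H2^2)
  g <- list(mp1 = list(ws = numeric(C), wn = numeric(C), b = numeric(C)),
            mp2 = list(ws = numeric(C), wn = numeric(C), b = 0))
  dpre2M <- dpre2 %*% M
  for (c in seq_len(C)) {
    g$mp2$ws[c] <- sum(dpre2 * cache$H1[, , c])
    g$mp2$wn[c] <- sum(dpre2 * cache$agg1[, , c])
    dH1c <- dpre2 * params$mp2$ws[c] + dpre2M * params$mp2$wn[c]
    dpre1c <- if (cache$activation == "identity") dH1c else dH1c * (1 - cache$H1[, , c]^2)
    g$mp1$ws[c] <- sum(dpre1c * cache$x)
    g$mp1$wn[c] <- sum(dpre1c * cache$xm)
    g$mp1$b[c] <- sum(dpre1c)
  }
  g$mp2$b <- sum(dpre2)
  g
}

# Full forward pass. `x_in` is the (already front-end-processed for graph
# models) input batch; `target` the clean reconstruction target. `noise`
# carries pre-drawn dropout masks and latent-sampling draws so the pass is a
# deterministic function of (params, noise); when `training` is FALSE no
# dropout is applied and the latent is the distribution mean.
ae_forward <- function(params, x_in, config, training = FALSE, noise = NULL) {
  p <- if (training) config$dropout_rate else 0
  variational <- "variational" %in% config$penalties
  keep <- 1 - p

  drop_mask <- function(nm, dims) {
    if (p <= 0) return(NULL)
    if (!is.null(noise[[nm]])) noise[[nm]] else
      matrix(rbinom(prod(dims), 1, keep), dims[1], dims[2])
  }
  apply_drop <- function(a, m) if (is.null(m)) a else a * m / keep

  a1 <- tanh(affine(x_in, params$enc1))
  m1 <- drop_mask("m1", dim(a1)); a1d <- apply_drop(a1, m1)
  a2 <- tanh(affine(a1d, params$enc2))
  m2 <- drop_mask("m2", dim(a2)); a2d <- apply_drop(a2, m2)

  mu <- log_var <- log_rate <- eps <- u <- NULL
  if (!variational) {
    zpre <- affine(a2d, params$lat)
    z <- sigmoid(zpre)
  } else if (config$vae_prior == "gaussian") {
    mu <- affine(a2d, params$lat)
    log_var <- affine(a2d, params$latv)
    if (training) {
      eps <- noise$eps %||% matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
      zpre <- mu + exp(log_var / 2) * eps
    } else {
      zpre <- mu
    }
    z <- sigmoid(zpre)
  } else {                                   # exponential prior
    log_rate <- affine(a2d, params$lat)
    rate <- exp(log_rate)
    if (training) {
      u <- noise$u %||% matrix(runif(length(rate)), nrow(rate), ncol(rate))
      zpre <- -log1p(-u) / rate
    } else {
      zpre <- 1 / rate                       # mean of Exp(rate)
    }
    z <- sigmoid(zpre)
  }

  d1 <- tanh(affine(z, params$dec1))
  m3 <- drop_mask("m3", dim(d1)); d1d <- apply_drop(d1, m3)
  d2 <- tanh(affine(d1d, params$dec2))
  m4 <- drop_mask("m4", dim(d2)); d2d <- apply_drop(d2, m4)
  xhat <- sigmoid(affine(d2d, params$out))

  list(xhat = xhat, latent = z, zpre = zpre,
       mu = mu, log_var = log_var, log_rate = log_rate,
       cache = list(x_in = x_in, a1 = a1, a1d = a1d, a2 = a2, a2d = a2d,
                    d1 = d1, d1d = d1d, d2 = d2, d2d = d2d,
                    m1 = m1, m2 = m2, m3 = m3, m4 = m4,
                    eps = eps, u = u, keep = keep))
}

# Loss of one forward pass against the clean target. Reconstruction MSE is
# summed over features and averaged over the batch; penalties follow the
# configuration.
ae_loss_from_output <- function(out, target, config) {
  B <- nrow(target)
  recon <- sum((out$xhat - target)^2) / B
  loss <- recon
  if ("sparse" %in% config$penalties) {
    rho_hat <- colMeans(out$latent)
    loss <- loss + config$sparse_weight *
      kl_sparsity_penalty(rho_hat, config$sparse_target)
  }
  if ("variational" %in% config$penalties) {
    if (config$vae_prior == "gaussian") {
      kl <- 0.5 * sum(out$mu^2 + exp(out$log_var) - out$log_var - 1) / B
    } else {
      kl <- sum(out$log_rate + exp(-out$log_rate) - 1) / B
    }
    loss <- loss + kl
  }
  loss
}

ae_backward <- function(params, out, target, config) {
  cache <- out$cache
  B <- nrow(target)
  keep <- cache$keep
  variational <- "variational" %in% config$penalties
  undrop <- function(d, m) if (is.null(m)) d else d * m / keep

  g <- list()

  dxhat <- 2 * (out$xhat - target) / B
  dpre_out <- dxhat * out$xhat * (1 - out$xhat)
  g$out <- list(W = t(cache$d2d) %*% dpre_out, b = colSums(dpre_out))
  dd2d <- dpre_out %*% t(params$out$W)
  dd2 <- undrop(dd2d, cache$m4)
  dpre_d2 <- dd2 * (1 - cache$d2^2)
  g$dec2 <- list(W = t(cache$d1d) %*% dpre_d2, b = colSums(dpre_d2))
  dd1d <- dpre_d2 %*% t(params$dec2$W)
  dd1 <- undrop(dd1d, cache$m3)
  dpre_d1 <- dd1 * (1 - cache$d1^2)
  g$dec1 <- list(W = t(out$latent) %*% dpre_d1, b = colSums(dpre_d1))

  dz <- dpre_d1 %*% t(params$dec1$W)
  if ("sparse" %in% config$penalties) {
    rho <- config$sparse_target
    rho_hat <- colMeans(out$latent)
    inside <- rho_hat > 1e-6 & rho_hat < 1 - 1e-6
    rh <- pmin(pmax(rho_hat, 1e-6), 1 - 1e-6)
    dkl <- ifelse(inside, -rho / rh + (1 - rho) / (1 - rh), 0)
    dz <- dz + matrix(config$sparse_weight * dkl / nrow(out$latent),
                      nrow(out$latent), ncol(out$latent), byrow = TRUE)
  }
  dzpre <- dz * out$latent * (1 - out$latent)

  if (!variational) {
    g$lat <- list(W = t(cache$a2d) %*% dzpre, b = colSums(dzpre))
    da2d <- dzpre %*% t(params$lat$W)
  } else if (config$vae_prior == "gaussian") {
    dmu <- dzpre + out$mu / B
    dlogvar <- if (!is.null(cache$eps)) {
      dzpre * 0.5 * exp(out$log_var / 2) * cache$eps +
        0.5 * (exp(out$log_var) - 1) / B
    } else {
      0.5 * (exp(out$log_var) - 1) / B
    }
    g$lat <- list(W = t(cache$a2d) %*% dmu, b = colSums(dmu))
    g$latv <- list(W = t(cache$a2d) %*% dlogvar, b = colSums(dlogvar))
    da2d <- dmu %*% t(params$lat$W) + dlogvar %*% t(params$latv$W)
  } else {
    # zpre = -log(1-u)/rate (training) or 1/rate (eval); both give
    # dzpre/dlog_rate = -zpre. KL term adds (1 - exp(-log_rate))/B.
    dlograte <- dzpre * (-out$zpre) + (1 - exp(-out$log_rate)) / B
    g$lat <- list(W = t(cache$a2d) %*% dlograte, b = colSums(dlograte))
    da2d <- dlograte %*% t(params$lat$W)
  }

  da2 <- undrop(da2d, cache$m2)
  dpre_a2 <- da2 * (1 - cache$a2^2)
  g$enc2 <- list(W = t(cache$a1d) %*% dpre_a2, b = colSums(dpre_a2))
  da1d <- dpre_a2 %*% t(params$enc2$W)
  da1 <- undrop(da1d, cache$m1)
  dpre_a1 <- da1 * (1 - cache$a1^2)
  g$enc1 <- list(W = t(cache$x_in) %*% dpre_a1, b = colSums(dpre_a1))
  dx_in <- dpre_a1 %*% t(params$enc1$W)

  list(grads = g, dx_in = dx_in)
}

# --- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), walk)
      return(list(p = purrr::map(out, "p"), m = purrr::map(out, "m"),
                  v = purrr::map(out, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}
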