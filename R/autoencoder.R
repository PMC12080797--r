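#' Configure an autoencoder
#'
#' Collects the architecture and training hyperparameters of the tabular and
#' graph autoencoders. Defaults follow the study protocol: batches of 16
#' samples, 100 epochs, learning rate 1e-4 halved every 25 epochs, additive
#' Gaussian input noise with sd 0.001 (0.1% of the normalized data range) for
#' the denoising variant, a Bernoulli-KL sparsity penalty with weight 0.1 and
#' target activation 0.001, and dropout of 20% (tabular) or 10% (graph).
#'
#' @param input_dim Width `d` of the input (genes, or graph nodes).
#' @param latent_dim Width `L` of the latent representation (default 64; 16
#'   and 128 are the other protocol values). Must satisfy `L < d`.
#' @param penalties Character subset of `c("denoising", "sparse",
#'   "variational")`. Combining `sparse` and `variational` is refused unless
#'   `allow_all_penalties = TRUE` (only sparse + denoising is combined in the
#'   protocol).
#' @param noise_sigma Denoising corruption sd on the `[0, 1]` data.
#' @param sparse_weight Weight of the KL sparsity penalty.
#' @param sparse_target Target mean activation `rho` of each latent unit.
#' @param vae_prior `"gaussian"` (standard normal) or `"exponential"`
#'   (unit-rate) latent prior for the variational variant.
#' @param dropout_rate Dropout probability on hidden layers; `NULL` picks the
#'   architecture default (0.2 tabular, 0.1 graph).
#' @param hidden_widths Optional integer vector of the two hidden widths;
#'   `NULL` interpolates geometrically between `input_dim` and `latent_dim`.
#' @param batch_size,epochs,learning_rate,lr_decay_factor,lr_decay_every
#'   Optimization schedule.
#' @param mp_channels Channels of the first message-passing round (graph
#'   architecture only).
#' @param mp_activation `"tanh"` (default) or `"identity"` for the
#'   message-passing nonlinearity.
#' @param freeze_front If `TRUE`, the message-passing front end is not
#'   updated during training (used for tabular/graph parity checks).
#' @param allow_all_penalties Permit sparse + variational together.
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and corruption.
#'
#' @return An object of class `ae_config`.
#' @export
ae_config <- function(input_dim,
                      latent_dim = 64L,
                      penalties = character(),
                      noise_sigma = 0.001,
                      sparse_weight = 0.1,
                      sparse_target = 0.001,
                      vae_prior = c("gaussian", "exponential"),
                      dropout_rate = NULL,
                      hidden_widths = NULL,
                      batch_size = 16L,
                      epochs = 100L,
                      learning_rate = 1e-4,
                      lr_decay_factor = 0.5,
                      lr_decay_every = 25L,
                      mp_channels = 4L,
                      mp_activation = c("tanh", "identity"),
                      freeze_front = FALSE,
                      allow_all_penalties = FALSE,
                      seed = 1L) {
  if (length(penalties) > 0L) {
    penalties <- match.arg(penalties, c("denoising", "sparse", "variational"),
                           several.ok = TRUE)
  }
  if (all(c("sparse", "variational") %in% penalties) && !allow_all_penalties) {
    abort("sparse and variational penalties are not combined; set allow_all_penalties = TRUE to override")
  }
  if (latent_dim >= input_dim) abort("latent_dim must be smaller than input_dim")
  if (noise_sigma < 0) abort("noise_sigma must be non-negative")
  if (sparse_target <= 0 || sparse_target >= 1) abort("sparse_target must lie in (0, 1)")
  if (!is.null(dropout_rate) && (dropout_rate < 0 || dropout_rate >= 1)) {
    abort("dropout_rate must lie in [0, 1)")
  }
  structure(list(
    input_dim = as.integer(input_dim), latent_dim = as.integer(latent_dim),
    penalties = penalties, noise_sigma = noise_sigma,
    sparse_weight = sparse_weight, sparse_target = sparse_target,
    vae_prior = match.arg(vae_prior), dropout_rate = dropout_rate,
    hidden_widths = hidden_widths, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), learning_rate = learning_rate,
    lr_decay_factor = lr_decay_factor, lr_decay_every = as.integer(lr_decay_every),
    mp_channels = as.integer(mp_channels),
    mp_activation = match.arg(mp_activation),
    freeze_front = freeze_front, seed = as.integer(seed)
  ), class = "ae_config")
}

# Wide hidden layers (3/4 and 3/8 of the input width): the bottleneck is the
# latent layer, and generous hidden capacity eases optimization on small
# cohorts.
default_hidden_widths <- function(d, L) {
  h1 <- max(min(round(0.75 * d), d), L + 1L)
  h2 <- max(min(round(0.375 * d), h1), L)
  c(h1, h2)
}

#' Build a tabular autoencoder
#'
#' Encoder: input-normalization layer (fixed to training-set mean/sd at
#' training time) -> two affine + tanh hidden layers with dropout -> affine +
#' sigmoid latent head (or distribution heads for the variational variant).
#' Decoder mirrors the hidden widths and ends in a sigmoid, since the
#' reconstruction targets live in `[0, 1]`. Initialization is deterministic
#' per seed.
#'
#' @param config An [ae_config()].
#' @return An object of class `ae_model`.
#' @export
build_tabular_autoencoder <- function(config) {
  stopifnot(inherits(config, "ae_config"))
  d <- config$input_dim
  L <- config$latent_dim
  hw <- config$hidden_widths %||% default_hidden_widths(d, L)
  variational <- "variational" %in% config$penalties
  params <- with_seed(derive_seed(config$seed, "init-tabular"), {
    init_tabular_params(d, hw[1], hw[2], L, variational, config$vae_prior)
  })
  if (is.null(config$dropout_rate)) config$dropout_rate <- 0.2
  structure(list(
    arch = "tabular", config = config, params = params,
    hidden_widths = hw,
    norm = list(center = rep(0, d), scale = rep(1, d)),
    trained = FALSE
  ), class = "ae_model")
}

#' Build a graph autoencoder
#'
#' Prepends a two-round message-passing front end to the tabular architecture:
#' each round applies an affine transform to the node's own feature and to the
#' mean of its neighbors' features, adds them, and applies the nonlinearity
#' (1 -> `mp_channels` -> 1 channels). The resulting per-node embeddings are
#' flattened per patient and compressed by the tabular body. The training
#' objective reconstructs the node features only — never the adjacency.
#'
#' @param config An [ae_config()]; `input_dim` is overridden by the node
#'   count of `topology`.
#' @param topology A pruned, undirected `igraph` graph.
#' @return An object of class `ae_model`.
#' @export
build_graph_autoencoder <- function(config, topology) {
  stopifnot(inherits(config, "ae_config"))
  N <- igraph::vcount(topology)
  if (N < 2L) abort("topology must have at least two nodes")
  config$input_dim <- N
  if (config$latent_dim >= N) abort("latent_dim must be smaller than the node count")
  if (is.null(config$dropout_rate)) config$dropout_rate <- 0.1
  A <- igraph::as_adjacency_matrix(topology, sparse = FALSE)
  deg <- rowSums(A)
  M <- A / ifelse(deg == 0, 1, deg)             # mean aggregation
  hw <- config$hidden_widths %||% default_hidden_widths(N, config$latent_dim)
  variational <- "variational" %in% config$penalties
  identity_front <- config$mp_activation == "identity"
  params <- with_seed(derive_seed(config$seed, "init-tabular"), {
    p <- init_tabular_params(N, hw[1], hw[2], config$latent_dim,
                             variational, config$vae_prior)
    c(p, init_mp_params(config$mp_channels, identity = identity_front))
  })
  structure(list(
    arch = "graph", config = config, params = params,
    hidden_widths = hw, M = M,
    node_names = igraph::V(topology)$name,
    norm = list(center = rep(0, N), scale = rep(1, N)),
    trained = FALSE
  ), class = "ae_model")
}

#' Corrupt a batch with additive Gaussian noise
#'
#' Denoising corruption: `x_tilde = x + noise_sigma * eps` with standard
#' normal `eps` per entry. The reconstruction target remains the clean `x`.
#'
#' @param x Numeric matrix (batch).
#' @param noise_sigma Noise standard deviation (>= 0).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The corrupted matrix.
#' @export
corrupt_input <- function(x, noise_sigma, seed = NULL) {
  if (noise_sigma < 0) abort("noise_sigma must be non-negative")
  if (noise_sigma == 0) return(x)
  add <- function() x + matrix(rnorm(length(x), sd = noise_sigma), nrow(x), ncol(x))
  if (is.null(seed)) add() else with_seed(seed, add())
}

#' Bernoulli KL sparsity penalty
#'
#' Sum over latent units of the KL divergence between a Bernoulli with the
#' desired activation probability `rho` and one with the observed mean
#' activation `rho_hat` (clamped to `[1e-6, 1 - 1e-6]`):
#' `sum_j rho*log(rho/rho_hat_j) + (1-rho)*log((1-rho)/(1-rho_hat_j))`.
#' Non-negative; zero iff every `rho_hat_j` equals `rho`.
#'
#' @param rho_hat Vector of observed mean activations (one per latent unit).
#' @param rho Target activation probability in (0, 1).
#' @return A non-negative scalar.
#' @export
kl_sparsity_penalty <- function(rho_hat, rho) {
  if (rho <= 0 || rho >= 1) abort("rho must lie in (0, 1)")
  rh <- pmin(pmax(rho_hat, 1e-6), 1 - 1e-6)
  sum(rho * log(rho / rh) + (1 - rho) * log((1 - rho) / (1 - rh)))
}

#' Variational KL penalty against the latent prior
#'
#' For the Gaussian prior, the closed-form KL of `N(mu, sigma^2)` against the
#' standard normal, summed over units:
#' `0.5 * sum(mu^2 + sigma^2 - log(sigma^2) - 1)`. For the exponential prior,
#' the KL of `Exp(rate)` against the unit-rate exponential:
#' `sum(log(rate) + 1/rate - 1)` with `rate = exp(log_rate)`. Both are
#' non-negative and vanish only at the prior.
#'
#' @param dist A list with `mu` and `log_var` (Gaussian) or `log_rate`
#'   (exponential); vectors or matrices (summed over everything, so pass one
#'   sample's encoding for the per-sample penalty).
#' @param prior `"gaussian"` or `"exponential"`.
#' @return A non-negative scalar.
#' @export
variational_kl_penalty <- function(dist, prior = c("gaussian", "exponential")) {
  prior <- match.arg(prior)
  if (prior == "gaussian") {
    if (!all(is.finite(dist$mu)) || !all(is.finite(dist$log_var))) {
      abort("non-finite encoded distribution")
    }
    0.5 * sum(dist$mu^2 + exp(dist$log_var) - dist$log_var - 1)
  } else {
    if (!all(is.finite(dist$log_rate))) abort("non-finite encoded distribution")
    sum(dist$log_rate + exp(-dist$log_rate) - 1)
  }
}

#' Total training loss of an autoencoder forward pass
#'
#' Reconstruction mean squared error (summed over features, averaged over the
#' batch) plus the configured penalties: `sparse_weight` times the Bernoulli
#' KL sparsity penalty on the batch mean activation, and the variational KL
#' (averaged over the batch). The denoising variant alters the input, not the
#' loss.
#'
#' @param x Clean target batch (matrix).
#' @param output A forward-pass output list with `xhat`, `latent`, and for
#'   variational models `mu`/`log_var` or `log_rate`.
#' @param config The [ae_config()].
#' @return The scalar loss.
#' @export
ae_total_loss <- function(x, output, config) {
  ae_loss_from_output(output, x, config)
}

as_input_matrix <- function(data) {
  if (is.data.frame(data)) expr_to_matrix(data) else as.matrix(data)
}

ae_standardize <- function(model, x) {
  sweep(sweep(x, 2, model$norm$center, "-"), 2, model$norm$scale, "/")
}

# One deterministic (evaluation-mode) forward pass through front end + body.
ae_eval_forward <- function(model, x) {
  x_in <- ae_standardize(model, x)
  front <- NULL
  if (model$arch == "graph") {
    front <- mp_forward(x_in, model$params, model$M, model$config$mp_activation)
    x_in <- front$H2
  }
  out <- ae_forward(model$params, x_in, model$config, training = FALSE)
  out$front <- front
  out
}

#' Train an autoencoder
#'
#' Minibatch Adam with the configured schedule (learning rate halved every
#' `lr_decay_every` epochs). The input-normalization layer is fixed to the
#' training set's per-feature mean and (population) standard deviation, and
#' the decoder's output bias is initialized at the logit of the per-feature
#' training mean so optimization starts from the width-0 baseline. The
#' denoising variant corrupts each training batch freshly; the loss target is
#' always the clean batch. Validation loss is tracked every epoch with a
#' deterministic forward pass (no dropout; variational encoders use the
#' distribution mean) and the parameters of the best-validation epoch are
#' returned. Fully seeded: identical calls give identical results.
#'
#' @param model An [build_tabular_autoencoder()] / [build_graph_autoencoder()]
#'   model.
#' @param train,val Training and validation data: normalized expression
#'   tibbles (`patient_id` + features) or plain matrices, disjoint.
#'
#' @return A list with `model` (trained, parameters of the best-validation
#'   epoch) and `log` (tibble with `epoch`, `train_loss`, `val_loss`, `lr`;
#'   attribute `best_epoch`).
#' @export
train_autoencoder <- function(model, train, val) {
  stopifnot(inherits(model, "ae_model"))
  config <- model$config
  x_train <- as_input_matrix(train)
  x_val <- as_input_matrix(val)
  if (nrow(x_train) == 0L || nrow(x_val) == 0L) abort("empty train or validation split")
  if (ncol(x_train) != config$input_dim) abort("training data width does not match input_dim")

  center <- colMeans(x_train)
  scale <- sqrt(colMeans(sweep(x_train, 2, center)^2))   # population sd
  scale[scale == 0] <- 1
  model$norm <- list(center = center, scale = scale)
  mbar <- pmin(pmax(center, 1e-3), 1 - 1e-3)
  model$params$out$b <- qlogis(mbar)

  denoising <- "denoising" %in% config$penalties
  n <- nrow(x_train)
  bs <- min(config$batch_size, n)
  params <- model$params
  opt <- adam_init(params)
  log <- vector("list", config$epochs)
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L

  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        config$lr_decay_factor^((epoch - 1) %/% config$lr_decay_every)
      idx <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1, n, by = bs)) {
        rows <- idx[start:min(start + bs - 1, n)]
        if (length(rows) < 2L) next                     # skip singleton tail
        xb <- x_train[rows, , drop = FALSE]
        xin <- if (denoising) corrupt_input(xb, config$noise_sigma) else xb
        x_in <- sweep(sweep(xin, 2, center, "-"), 2, scale, "/")
        front <- NULL
        if (model$arch == "graph") {
          front <- mp_forward(x_in, params, model$M, config$mp_activation)
          x_in <- front$H2
        }
        out <- ae_forward(params, x_in, config, training = TRUE)
        batch_losses <- c(batch_losses, ae_loss_from_output(out, xb, config))
        bk <- ae_backward(params, out, xb, config)
        grads <- bk$grads
        if (model$arch == "graph") {
          if (config$freeze_front) {
            grads$mp1 <- list(ws = params$mp1$ws * 0, wn = params$mp1$wn * 0,
                              b = params$mp1$b * 0)
            grads$mp2 <- list(ws = params$mp2$ws * 0, wn = params$mp2$wn * 0,
                              b = 0)
          } else {
            mg <- mp_backward(bk$dx_in, front, params, model$M)
            grads$mp1 <- mg$mp1
            grads$mp2 <- mg$mp2
          }
        }
        grads <- grads[names(params)]
        step <- adam_step(params, grads, opt, lr)
        params <- step$params
        opt$m <- step$state$m; opt$v <- step$state$v; opt$t <- step$state$t
      }
      model$params <- params
      val_out <- ae_eval_forward(model, x_val)
      val_loss <- ae_loss_from_output(val_out, x_val, config)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
      }
      log[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(batch_losses),
        val_loss = val_loss, lr = lr
      )
    }
  })

  model$params <- best_params
  model$trained <- TRUE
  log <- dplyr::bind_rows(log)
  attr(log, "best_epoch") <- best_epoch
  class(log) <- c("ae_training_log", class(log))
  list(model = model, log = log)
}

#' Encode a cohort into latent features (+ histology)
#'
#' Deterministic inference pass: no dropout, no sampling (variational encoders
#' return the latent distribution mean, squashed by the sigmoid). The latent
#' columns lie in (0, 1); when a normalized histology table is supplied its
#' features are appended.
#'
#' @param model A trained [ae_model][build_tabular_autoencoder()].
#' @param data Normalized expression tibble or matrix (width `input_dim`).
#' @param hist Optional normalized histology tibble, row-aligned with `data`.
#'
#' @return A tibble `patient_id` + `latent_1..latent_L` (+ histology
#'   columns), with attribute `latent_cols` naming the latent columns.
#' @export
encode_cohort <- function(model, data, hist = NULL) {
  if (!model$trained) warn("encoding with an untrained model")
  x <- as_input_matrix(data)
  if (ncol(x) != model$config$input_dim) abort("data width does not match the model input")
  out <- ae_eval_forward(model, x)
  z <- out$latent
  colnames(z) <- paste0("latent_", seq_len(ncol(z)))
  ids <- if (is.data.frame(data)) data$patient_id else rownames(x) %||% as.character(seq_len(nrow(x)))
  res <- tibble::as_tibble(z) |> dplyr::mutate(patient_id = ids, .before = 1L)
  if (!is.null(hist)) {
    if (!identical(ids, hist$patient_id)) abort("histology rows are not aligned with the data")
    res <- dplyr::bind_cols(res, hist[setdiff(names(hist), "patient_id")])
  }
  attr(res, "latent_cols") <- colnames(z)
  res
}

#' Mean reconstruction error of a model on clean data
#'
#' Mean squared error summed over features and averaged over patients, on
#' clean (uncorrupted) inputs, using the deterministic forward pass.
#'
#' @param model A trained autoencoder.
#' @param data Normalized expression tibble or matrix.
#' @return A scalar.
#' @export
reconstruction_error <- function(model, data) {
  x <- as_input_matrix(data)
  out <- ae_eval_forward(model, x)
  sum((out$xhat - x)^2) / nrow(x)
}
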