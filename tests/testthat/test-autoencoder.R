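test_that("configuration enforces the architecture invariants", {
  expect_error(ae_config(input_dim = 10, latent_dim = 10), "smaller")
  expect_error(ae_config(input_dim = 10, latent_dim = 2,
                         penalties = c("sparse", "variational")),
               "allow_all_penalties")
  expect_silent(ae_config(input_dim = 10, latent_dim = 2,
                          penalties = c("sparse", "denoising")))
  expect_error(ae_config(input_dim = 10, latent_dim = 2, sparse_target = 0),
               "sparse_target")
})

test_that("tabular build is deterministic per seed and encodes into (0,1)", {
  cfg <- ae_config(input_dim = 100, latent_dim = 16, seed = 5)
  m1 <- build_tabular_autoencoder(cfg)
  m2 <- build_tabular_autoencoder(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_tabular_autoencoder(ae_config(input_dim = 100, latent_dim = 16, seed = 6))
  expect_false(identical(m1$params, m3$params))

  x <- matrix(runif(5 * 100), 5, 100)
  out <- survae:::ae_eval_forward(m1, x)
  expect_equal(dim(out$latent), c(5, 16))
  expect_true(all(out$latent > 0 & out$latent < 1))
  z0 <- survae:::ae_eval_forward(m1, matrix(0, 2, 100))
  expect_true(all(is.finite(z0$xhat)))
  expect_equal(ncol(z0$xhat), 100)
})

test_that("denoising corruption has the stated moments and zero noise is identity", {
  x <- matrix(0.5, 200, 500)
  expect_identical(corrupt_input(x, 0), x)
  noisy <- corrupt_input(x, 0.01, seed = 42)
  d <- noisy - x
  expect_lt(abs(mean(d)), 3 * 0.01 / sqrt(length(d)))
  expect_lt(abs(sd(d) - 0.01) / 0.01, 0.05)
})

test_that("penalty formulas match their closed-form values", {
  expect_equal(kl_sparsity_penalty(rep(0.001, 4), 0.001), 0)
  expect_equal(kl_sparsity_penalty(0.5, 0.001),
               0.001 * log(0.001 / 0.5) + 0.999 * log(0.999 / 0.5),
               tolerance = 1e-10)
  # strictly increasing away from rho on either side
  expect_gt(kl_sparsity_penalty(0.3, 0.1), kl_sparsity_penalty(0.2, 0.1))
  expect_gt(kl_sparsity_penalty(0.01, 0.1), kl_sparsity_penalty(0.05, 0.1))
  expect_error(kl_sparsity_penalty(0.5, 1.5), "rho")

  expect_equal(variational_kl_penalty(list(mu = rep(0, 3), log_var = rep(0, 3)),
                                      "gaussian"), 0)
  expect_equal(variational_kl_penalty(list(mu = 1, log_var = 0), "gaussian"), 0.5)
  expect_equal(variational_kl_penalty(list(log_rate = 0), "exponential"), 0)
  expect_gt(variational_kl_penalty(list(log_rate = 1), "exponential"), 0)
  expect_error(variational_kl_penalty(list(mu = NaN, log_var = 0), "gaussian"),
               "finite")
})

test_that("total loss decomposes as reconstruction plus configured penalties", {
  cfg <- ae_config(input_dim = 4, latent_dim = 2)
  x <- matrix(runif(12), 3, 4)
  perfect <- list(xhat = x, latent = matrix(0.5, 3, 2))
  expect_equal(ae_total_loss(x, perfect, cfg), 0)
  offset <- list(xhat = x + 1, latent = matrix(0.5, 3, 2))
  expect_equal(ae_total_loss(x, offset, cfg), 4)       # d features, +1 each
  cfg_sp <- ae_config(input_dim = 4, latent_dim = 2, penalties = "sparse",
                      sparse_target = 0.5)
  expect_equal(ae_total_loss(x, perfect, cfg_sp), 0)   # rho_hat == rho
})

test_that("analytic gradients match finite differences on a d=6, L=2 toy", {
  x <- survae:::with_seed(8, matrix(runif(24), 4, 6))
  noise <- survae:::with_seed(9, list(eps = matrix(rnorm(8), 4, 2),
                                      u = matrix(runif(8), 4, 2)))
  for (case in list(list(p = character(), prior = "gaussian"),
                    list(p = "sparse", prior = "gaussian"),
                    list(p = "variational", prior = "gaussian"),
                    list(p = "variational", prior = "exponential"))) {
    cfg <- ae_config(input_dim = 6, latent_dim = 2, penalties = case$p,
                     vae_prior = case$prior, dropout_rate = 0,
                     hidden_widths = c(5, 4), seed = 3)
    model <- build_tabular_autoencoder(cfg)
    loss_of <- function(p) {
      survae:::ae_loss_from_output(
        survae:::ae_forward(p, x, cfg, training = TRUE, noise = noise), x, cfg)
    }
    out <- survae:::ae_forward(model$params, x, cfg, training = TRUE, noise = noise)
    grads <- survae:::ae_backward(model$params, out, x, cfg)$grads
    for (nm in names(model$params)) {
      for (part in names(model$params[[nm]])) {
        p0 <- model$params
        num <- vapply(seq_along(p0[[nm]][[part]]), function(i) {
          h <- 1e-6
          pp <- p0; pp[[nm]][[part]][i] <- pp[[nm]][[part]][i] + h
          pm <- p0; pm[[nm]][[part]][i] <- pm[[nm]][[part]][i] - h
          (loss_of(pp) - loss_of(pm)) / (2 * h)
        }, numeric(1))
        rel <- max(abs(num - as.numeric(grads[[nm]][[part]])) / pmax(abs(num), 1e-4))
        expect_lt(rel, 1e-4)
      }
    }
  }
})

test_that("training is seeded, schedule-driven, and a zero learning rate is inert", {
  x <- expr_tbl(survae:::with_seed(4, matrix(runif(40 * 12), 40, 12)))
  cfg0 <- ae_config(input_dim = 12, latent_dim = 3, learning_rate = 0,
                    dropout_rate = 0, epochs = 3, seed = 7)
  m0 <- build_tabular_autoencoder(cfg0)
  tr0 <- train_autoencoder(m0, x[1:32, ], x[33:40, ])
  expect_equal(tr0$model$params$enc1$W, m0$params$enc1$W, ignore_attr = TRUE)
  expect_equal(length(unique(round(tr0$log$val_loss, 12))), 1)  # flat curve

  cfg <- ae_config(input_dim = 12, latent_dim = 3, learning_rate = 3e-3,
                   epochs = 60, lr_decay_every = 25, seed = 7)
  tra <- train_autoencoder(build_tabular_autoencoder(cfg), x[1:32, ], x[33:40, ])
  trb <- train_autoencoder(build_tabular_autoencoder(cfg), x[1:32, ], x[33:40, ])
  expect_identical(tra$log, trb$log)
  expect_equal(unique(tra$log$lr), 3e-3 * c(1, 0.5, 0.25))
  expect_lt(tra$log$train_loss[60], tra$log$train_loss[1])
  expect_error(train_autoencoder(build_tabular_autoencoder(cfg), x[0, ], x), "empty")
})

test_that("a two-feature linear relation is learned and encoding is deterministic", {
  x1 <- survae:::with_seed(12, runif(60))
  x <- expr_tbl(cbind(x1, x1), genes = c("a", "b"))
  cfg <- ae_config(input_dim = 2, latent_dim = 1, hidden_widths = c(4, 3),
                   learning_rate = 3e-3, epochs = 100, seed = 2)
  tr <- train_autoencoder(build_tabular_autoencoder(cfg), x[1:50, ], x[51:60, ])
  expect_lt(tr$log$train_loss[100], tr$log$train_loss[1])

  hist <- tibble::tibble(patient_id = x$patient_id[51:60],
                         h1 = runif(10), h2 = runif(10))
  enc <- encode_cohort(tr$model, x[51:60, ], hist)
  expect_equal(ncol(enc), 4)                            # id + 1 latent + 2 histology
  expect_identical(attr(enc, "latent_cols"), "latent_1")
  expect_true(all(enc$latent_1 > 0 & enc$latent_1 < 1))
  expect_identical(enc, encode_cohort(tr$model, x[51:60, ], hist))

  err <- reconstruction_error(tr$model, x[51:60, ])
  perm <- sample(10)
  expect_equal(reconstruction_error(tr$model, x[51:60, ][perm, ]), err)
})

test_that("the sparse penalty pulls mean latent activation toward its target", {
  x <- expr_tbl(survae:::with_seed(5, matrix(runif(50 * 15), 50, 15)))
  act_of <- function(penalties) {
    cfg <- ae_config(input_dim = 15, latent_dim = 4, penalties = penalties,
                     learning_rate = 3e-3, epochs = 80, seed = 11)
    tr <- train_autoencoder(build_tabular_autoencoder(cfg), x[1:40, ], x[41:50, ])
    mean(survae:::ae_eval_forward(tr$model, survae:::expr_to_matrix(x))$latent)
  }
  rho <- 0.001
  expect_lt(abs(act_of("sparse") - rho), abs(act_of(character()) - rho))
})

test_that("denoising training reconstructs clean inputs at least as well as plain", {
  wins <- vapply(1:10, function(s) {
    sp <- cohort_spec(n_patients = 60, n_genes = 24, n_latent_true = 2,
                      beta_true = c(1, -1), noise_sd = 0.3,
                      frac_uninformative = 0, seed = 200 + s)
    x <- normalize_expression(simulate_expression(sp)$expression)$expression
    err_of <- function(penalties) {
      cfg <- ae_config(input_dim = 24, latent_dim = 4, penalties = penalties,
                       noise_sigma = 0.001, learning_rate = 3e-3,
                       epochs = 60, seed = 300 + s)
      tr <- train_autoencoder(build_tabular_autoencoder(cfg), x[1:48, ], x[49:60, ])
      reconstruction_error(tr$model, x[49:60, ])
    }
    err_of("denoising") <= err_of(character())
  }, logical(1))
  expect_gte(sum(wins), 7)
})

test_that("an L=4 autoencoder beats the width-0 baseline on 4-factor data", {
  sp <- cohort_spec(n_patients = 150, n_genes = 40, n_latent_true = 4,
                    beta_true = c(1, -1, 0.5, 0), frac_uninformative = 0,
                    seed = 31)
  x <- normalize_expression(simulate_expression(sp)$expression)$expression
  cfg <- ae_config(input_dim = 40, latent_dim = 4, learning_rate = 3e-3,
                   epochs = 150, lr_decay_every = 40, seed = 31)
  tr <- train_autoencoder(build_tabular_autoencoder(cfg), x[1:120, ], x[121:150, ])
  te <- x[121:150, ]
  err <- reconstruction_error(tr$model, te)
  m <- survae:::expr_to_matrix(te)
  baseline <- sum(sweep(m, 2, colMeans(survae:::expr_to_matrix(x[1:120, ])))^2) / nrow(m)
  expect_lt(err, baseline)
})
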