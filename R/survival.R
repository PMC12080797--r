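#' Standardize covariate columns
#'
#' Centers and scales every covariate to zero mean and unit variance using the
#' population standard deviation (divide by `n`). When `fit_stats` (training
#' statistics) is supplied, it is applied unchanged to new data. Constant
#' columns map to zero with a warning.
#'
#' @param X Covariate tibble (`patient_id` + numeric columns) or matrix.
#' @param fit_stats Optional list with `center` and `scale` from a previous
#'   call (returned in the `stats` attribute).
#'
#' @return The standardized tibble/matrix with a `stats` attribute; the
#'   `latent_cols` attribute of the input, if any, is preserved.
#' @export
standardize_features <- function(X, fit_stats = NULL) {
  latent_cols <- attr(X, "latent_cols")
  is_df <- is.data.frame(X)
  m <- as_input_matrix(X)
  if (is.null(fit_stats)) {
    if (nrow(m) < 2L) abort("need at least two rows to fit standardization statistics")
    center <- colMeans(m)
    scale <- sqrt(colMeans(sweep(m, 2, center)^2))
    if (any(scale == 0)) {
      warn(paste0("constant column(s) standardized to 0: ",
                  paste(colnames(m)[scale == 0], collapse = ", ")))
    }
    fit_stats <- list(center = center, scale = ifelse(scale == 0, 1, scale))
  }
  out_m <- sweep(sweep(m, 2, fit_stats$center, "-"), 2, fit_stats$scale, "/")
  out <- if (is_df) {
    res <- X
    res[colnames(m)] <- as.data.frame(out_m)
    res
  } else {
    out_m
  }
  attr(out, "stats") <- fit_stats
  attr(out, "latent_cols") <- latent_cols
  out
}

# Factory for the negative mean partial log-likelihood with Breslow tie
# handling (tied events share the risk-set denominator) and its gradient.
# Sorting and tie bookkeeping are done once; the returned closure evaluates
# both at a coefficient vector. Risk sets are {j : time_j >= time_i}.
make_neg_partial_loglik <- function(X, time, event) {
  n <- length(time)
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]; ev <- event[ord]
  Xs <- X[ord, , drop = FALSE]
  runs <- rle(ts)
  last <- rep(cumsum(runs$lengths), runs$lengths)   # last index of each tie group
  ev_idx <- which(ev == 1)
  if (length(ev_idx) == 0L) abort("no observed events; cannot evaluate the partial likelihood")
  r <- last[ev_idx]
  function(beta) {
    eta <- as.numeric(Xs %*% beta)
    emax <- max(eta)
    w <- exp(eta - emax)
    cw <- cumsum(w)
    cwx <- apply(Xs * w, 2, cumsum)
    if (is.null(dim(cwx))) cwx <- matrix(cwx, ncol = ncol(Xs))
    value <- -(sum(eta[ev_idx]) - sum(log(cw[r]) + emax)) / n
    grad_mat <- Xs[ev_idx, , drop = FALSE] - cwx[r, , drop = FALSE] / cw[r]
    grad <- -colSums(grad_mat) / n
    list(value = value, grad = grad)
  }
}

neg_partial_loglik <- function(beta, X, time, event) {
  make_neg_partial_loglik(X, time, event)(beta)
}

#' Elastic-net penalized Cox objective
#'
#' The negative mean partial log-likelihood (Breslow handling of tied event
#' times: tied events share the risk-set denominator) plus the elastic-net
#' penalty `lambda * (alpha * sum(|beta|) + (1 - alpha)/2 * sum(beta^2))`.
#'
#' @param beta Coefficient vector.
#' @param X Covariate matrix or tibble (standardized), `n x P`.
#' @param labels Survival-label tibble (`time`, `event`; `event = 1` means
#'   the event was observed).
#' @param lambda Penalty strength (>= 0).
#' @param alpha Elastic-net mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#' @return The scalar objective value.
#' @export
cox_penalized_objective <- function(beta, X, labels, lambda = 0, alpha = 0.5) {
  m <- as_input_matrix(X)
  pl <- neg_partial_loglik(beta, m, labels$time, labels$event)
  pl$value + lambda * (alpha * sum(abs(beta)) + 0.5 * (1 - alpha) * sum(beta^2))
}

#' Fit an elastic-net penalized Cox proportional-hazards model
#'
#' Minimizes [cox_penalized_objective()] by proximal gradient descent (FISTA
#' with backtracking line search and adaptive restart): the partial likelihood
#' and the ridge part form the smooth term, the lasso part is handled by
#' soft-thresholding. Deterministic given its inputs.
#'
#' @param X Standardized covariate tibble (`patient_id` + columns) or matrix.
#' @param labels Survival labels aligned with `X`.
#' @param lambda Penalty strength.
#' @param alpha Elastic-net mixing (default 0.5, balancing l1 and l2).
#' @param init Optional warm-start coefficient vector.
#' @param max_iter,tol Convergence controls (max iterations; threshold on the
#'   largest coefficient change per iteration).
#'
#' @return An object of class `cox_fit`: coefficients `beta`, the
#'   hyperparameters, the standardization `stats` carried by `X` (if any),
#'   the latent-column names, and the training labels (needed by the Breslow
#'   baseline and IPCW weights).
#' @export
fit_cox_elastic_net <- function(X, labels, lambda = 0, alpha = 0.5,
                                init = NULL, max_iter = 5000L, tol = 1e-6) {
  m <- as_input_matrix(X)
  if (nrow(m) != nrow(labels)) abort("X and labels have different numbers of rows")
  if (sum(labels$event) == 0L) abort("no observed events in the training labels")
  time <- labels$time; event <- labels$event
  P <- ncol(m)
  l1 <- lambda * alpha
  l2 <- lambda * (1 - alpha)
  npll <- make_neg_partial_loglik(m, time, event)

  smooth_f <- function(b) {
    pl <- npll(b)
    list(value = pl$value + 0.5 * l2 * sum(b^2), grad = pl$grad + l2 * b)
  }
  objective <- function(b) smooth_f(b)$value + l1 * sum(abs(b))

  beta <- init %||% rep(0, P)
  y <- beta
  t_acc <- 1
  s <- 1                                   # step size, adapted by backtracking
  f_y <- smooth_f(y)
  obj_old <- objective(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    repeat {
      cand <- soft_threshold(y - s * f_y$grad, s * l1)
      diff <- cand - y
      f_cand <- smooth_f(cand)$value
      if (f_cand <= f_y$value + sum(f_y$grad * diff) + sum(diff^2) / (2 * s) + 1e-12) break
      s <- s / 2
      if (s < 1e-14) abort("line search failed; objective may be unbounded")
    }
    beta_new <- cand
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- beta_new + ((t_acc - 1) / t_new) * (beta_new - beta)
    obj_new <- objective(beta_new)
    if (obj_new > obj_old) {               # adaptive restart
      y <- beta_new
      t_new <- 1
    }
    delta <- max(abs(beta_new - beta))
    obj_delta <- abs(obj_new - obj_old)
    beta <- beta_new
    t_acc <- t_new
    obj_old <- min(obj_old, obj_new)
    f_y <- smooth_f(y)
    s <- min(s * 2, 1)
    if (it > 1L && (delta < tol || obj_delta < 1e-12 * max(1, abs(obj_old)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(paste0("Cox elastic net did not converge in ", max_iter,
                 " iterations (last coefficient change ", signif(delta, 3), ")"))
  }
  structure(list(
    beta = setNames(as.numeric(beta), colnames(m)),
    lambda = lambda, alpha = alpha,
    stats = attr(X, "stats"),
    latent_cols = attr(X, "latent_cols"),
    train_labels = labels[c("time", "event")],
    n = nrow(m), iterations = it
  ), class = "cox_fit")
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' `H0(t) = sum over distinct event times t_k <= t of d_k / sum_{j in R(t_k)}
#' exp(X_j beta)`, with `d_k` the number of events at `t_k` and `R(t_k)` the
#' at-risk set `{j : time_j >= t_k}`. With `beta = 0` this reduces to the
#' Nelson-Aalen estimator.
#'
#' @param fit A [cox_fit][fit_cox_elastic_net()].
#' @param X Training covariates (standardized, as used for the fit).
#' @param labels Training survival labels.
#'
#' @return An object of class `breslow_baseline`: a tibble with `time`
#'   (distinct event times, increasing) and `cumhaz` (non-decreasing).
#' @export
breslow_baseline <- function(fit, X, labels) {
  m <- as_input_matrix(X)
  eta <- as.numeric(m %*% fit$beta)
  w <- exp(eta)
  etimes <- sort(unique(labels$time[labels$event == 1]))
  jump <- vapply(etimes, function(tk) {
    d <- sum(labels$time == tk & labels$event == 1)
    d / sum(w[labels$time >= tk])
  }, numeric(1))
  structure(
    tibble::tibble(time = etimes, cumhaz = cumsum(jump)),
    class = c("breslow_baseline", class(tibble::tibble()))
  )
}

#' Predict a patient's survival curve
#'
#' `S(t | x) = exp(-H0(t) * exp(x . beta))`: a non-increasing step function
#' with `S(0) = 1`, stepping at the baseline's event times.
#'
#' @param fit A [cox_fit][fit_cox_elastic_net()].
#' @param baseline A [breslow_baseline()].
#' @param x One patient's covariate row (standardized with the fit's
#'   statistics): numeric vector, one-row matrix, or one-row tibble.
#'
#' @return An object of class `survival_curve`: tibble with `time` (starting
#'   at 0) and `surv`.
#' @export
predict_survival_curve <- function(fit, baseline, x) {
  if (is.data.frame(x)) x <- as_input_matrix(x)
  risk <- exp(sum(as.numeric(x) * fit$beta))
  structure(
    tibble::tibble(
      time = c(0, baseline$time),
      surv = exp(-c(0, baseline$cumhaz) * risk)
    ),
    class = c("survival_curve", class(tibble::tibble()))
  )
}

#' Predict progression-free survival as the area under the survival curve
#'
#' Exact rectangle sum of the right-continuous step function on
#' `[0, horizon]`; beyond its last step the curve is held constant at its last
#' value.
#'
#' @param curve A [survival_curve][predict_survival_curve()].
#' @param horizon Upper integration limit (> 0), in the labels' time unit.
#' @return The predicted PFS (same unit as `horizon`).
#' @export
predict_pfs <- function(curve, horizon) {
  if (horizon <= 0) abort("horizon must be positive")
  t <- c(curve$time, Inf)
  s <- curve$surv
  area <- 0
  for (k in seq_along(s)) {
    lo <- min(t[k], horizon)
    hi <- min(t[k + 1], horizon)
    area <- area + s[k] * (hi - lo)
  }
  area
}

# Kaplan-Meier estimate of the censoring survival function G(t) from training
# labels (censoring is the "event"); returns a right-continuous step function.
censoring_survfit <- function(labels) {
  sf <- survival::survfit(survival::Surv(labels$time, 1 - labels$event) ~ 1)
  stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
}

#' IPCW concordance index (Uno's estimator)
#'
#' Inverse-probability-of-censoring-weighted concordance: over comparable
#' pairs `(i, j)` with `event_i = 1`, `time_i < time_j` and `time_i <= tau`,
#' each pair is weighted by `G(time_i)^-2`, where `G` is the Kaplan-Meier
#' estimate of the censoring survival function on the *training* labels. A
#' pair is concordant when the earlier-event patient has the higher risk
#' score; ties in risk count one half. Without censoring all weights are
#' equal and the estimator reduces to Harrell's C.
#'
#' @param train_labels Training labels used to estimate `G`.
#' @param risk Risk scores (`X . beta`) of the evaluated patients.
#' @param labels Labels of the evaluated patients, aligned with `risk`.
#' @param tau Truncation time; defaults to the largest evaluated time below
#'   the training follow-up maximum.
#' @return Concordance in `[0, 1]`.
#' @export
ipcw_concordance <- function(train_labels, risk, labels, tau = NULL) {
  if (length(risk) != nrow(labels)) abort("risk and labels lengths differ")
  G <- censoring_survfit(train_labels)
  if (is.null(tau)) {
    below <- labels$time[labels$time < max(train_labels$time)]
    tau <- if (length(below) > 0) max(below) else max(labels$time)
  }
  y <- labels$time; ev <- labels$event
  num <- 0; den <- 0
  for (i in which(ev == 1 & y <= tau)) {
    g <- G(y[i])
    if (g <= 0) next
    w <- 1 / g^2
    later <- which(y > y[i])
    if (length(later) == 0L) next
    conc <- sum((risk[i] > risk[later]) + 0.5 * (risk[i] == risk[later]))
    num <- num + w * conc
    den <- den + w * length(later)
  }
  if (den == 0) abort("no comparable pairs for the concordance index")
  num / den
}

#' Mean time-dependent cumulative/dynamic AUC
#'
#' At each grid time `t`, cases are evaluated patients with an observed event
#' by `t` (weighted by `1/G(time_i)`, with `G` the censoring survival function
#' estimated on the training labels) and controls are patients still at risk
#' beyond `t`. The AUC at `t` is the weighted probability that a case
#' outranks a control (risk ties count one half); grid times with no cases or
#' no controls are dropped with a warning. Returns the unweighted mean over
#' the remaining grid.
#'
#' @param train_labels Training labels used to estimate `G`.
#' @param risk Risk scores of the evaluated patients.
#' @param labels Labels of the evaluated patients.
#' @param time_grid Evaluation times; defaults to the inner deciles of the
#'   evaluated event times, truncated strictly below the training follow-up
#'   maximum.
#' @return A list with `mean_auc` and a tibble `by_time` (`time`, `auc`).
#' @export
mean_time_dependent_auc <- function(train_labels, risk, labels, time_grid = NULL) {
  G <- censoring_survfit(train_labels)
  y <- labels$time; ev <- labels$event
  if (is.null(time_grid)) {
    emax <- max(train_labels$time)
    et <- y[ev == 1 & y < emax]
    if (length(et) < 2L) abort("too few observed events to build a time grid")
    qs <- quantile(et, probs = seq(0.1, 0.9, by = 0.1), names = FALSE, type = 7)
    time_grid <- sort(unique(qs))
  }
  aucs <- vapply(time_grid, function(t) {
    cases <- which(y <= t & ev == 1)
    controls <- which(y > t)
    if (length(cases) == 0L || length(controls) == 0L) return(NA_real_)
    wts <- 1 / pmax(vapply(y[cases], G, numeric(1)), 1e-12)
    num <- 0
    for (k in seq_along(cases)) {
      i <- cases[k]
      num <- num + wts[k] * sum((risk[i] > risk[controls]) +
                                  0.5 * (risk[i] == risk[controls]))
    }
    num / (sum(wts) * length(controls))
  }, numeric(1))
  if (anyNA(aucs)) {
    warn("dropping time-grid points with no cases or no controls")
  }
  keep <- !is.na(aucs)
  if (!any(keep)) abort("no usable time-grid points for the time-dependent AUC")
  list(
    mean_auc = mean(aucs[keep]),
    by_time = tibble::tibble(time = time_grid[keep], auc = aucs[keep])
  )
}

#' Default regularization grid
#'
#' Fifty penalty strengths spanning `[1e-4, 1e-2]` in equal steps (step
#' ~2e-4).
#'
#' @return Numeric vector of length 50.
#' @export
lambda_grid <- function() seq(1e-4, 1e-2, length.out = 50)

#' Grid search for the Cox penalty strength
#'
#' Fits the elastic-net Cox model at every grid value on the supplied data
#' (training + validation combined, per protocol), scores each fit by the
#' IPCW concordance on the same data, and returns the best penalty. Ties are
#' broken toward the larger penalty (favoring sparsity). Fits are
#' warm-started along the grid.
#'
#' @param X Standardized covariates (train + validation).
#' @param labels Aligned survival labels.
#' @param grid Penalty values (default [lambda_grid()]).
#' @param alpha Elastic-net mixing.
#' @return A list with `best_lambda`, `best_fit`, and `table` (tibble:
#'   `lambda`, `concordance`, `n_nonzero`).
#' @export
lambda_grid_search <- function(X, labels, grid = lambda_grid(), alpha = 0.5) {
  if (length(grid) == 0L) abort("empty penalty grid")
  grid <- sort(grid)
  m <- as_input_matrix(X)
  fits <- vector("list", length(grid))
  scores <- numeric(length(grid))
  nnz <- integer(length(grid))
  warm <- NULL
  for (k in seq_along(grid)) {
    fit <- fit_cox_elastic_net(X, labels, lambda = grid[k], alpha = alpha,
                               init = warm)
    warm <- fit$beta
    risk <- as.numeric(m %*% fit$beta)
    scores[k] <- ipcw_concordance(labels, risk, labels)
    nnz[k] <- sum(fit$beta != 0)
    fits[[k]] <- fit
  }
  best <- max(which(scores == max(scores)))       # ties -> larger lambda
  list(
    best_lambda = grid[best],
    best_fit = fits[[best]],
    table = tibble::tibble(lambda = grid, concordance = scores, n_nonzero = nnz)
  )
}

#' PFS prediction error metrics
#'
#' `pfs_mse()` is the mean squared difference between predicted and actual
#' PFS; `overestimation_rate()` is the percentage of patients whose predicted
#' PFS strictly exceeds the actual value (0% = never overestimates).
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @return A scalar (mean squared error, or a percentage in `[0, 100]`).
#' @export
pfs_mse <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual)) {
    abort("predicted and actual must be non-empty and of equal length")
  }
  mean((predicted - actual)^2)
}

#' @rdname pfs_mse
#' @export
overestimation_rate <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual)) {
    abort("predicted and actual must be non-empty and of equal length")
  }
  100 * mean(predicted > actual)
}

#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta),
    estimate = as.numeric(x$beta),
    hazard_ratio = exp(as.numeric(x$beta))
  )
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, alpha = x$alpha,
    n = x$n, n_events = sum(x$train_labels$event),
    n_nonzero = sum(x$beta != 0), iterations = x$iterations
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Elastic-net Cox proportional-hazards fit\n")
  cat(sprintf("  %d covariates (%d nonzero), lambda = %.4g, alpha = %.2f\n",
              length(x$beta), sum(x$beta != 0), x$lambda, x$alpha))
  cat(sprintf("  n = %d patients, %d events\n", x$n, sum(x$train_labels$event)))
  invisible(x)
}
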