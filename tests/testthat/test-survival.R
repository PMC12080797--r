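test_that("standardization uses population sd and training statistics", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  s <- standardize_features(m)
  expect_equal(as.numeric(s), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(as.numeric(s)[1], -1.2247, tolerance = 1e-4)
  # idempotent when reusing fitted stats on already-standardized data
  s2 <- standardize_features(s, fit_stats = list(center = c(a = 0), scale = c(a = 1)))
  expect_equal(as.numeric(s2), as.numeric(s))
  expect_warning(standardize_features(matrix(3, 3, 1, dimnames = list(NULL, "c"))),
                 "constant")
})

test_that("the penalized objective evaluates the partial likelihood by hand", {
  labels <- toy_labels(c(1, 2, 3))
  X <- matrix(c(1, 0, 0), 3, 1, dimnames = list(NULL, "x"))
  # beta = 0: risk sets of sizes 3, 2, 1
  expect_equal(cox_penalized_objective(0, X, labels, 0, 0.5),
               (log(3) + log(2) + log(1)) / 3)
  expect_equal(cox_penalized_objective(0, X, labels, 0, 0.5), 0.5973, tolerance = 1e-4)
  # lambda = 0 equals the unpenalized value at any beta
  b <- 0.7
  pen <- cox_penalized_objective(b, X, labels, 0.3, 0.5) -
    cox_penalized_objective(b, X, labels, 0, 0.5)
  expect_equal(pen, 0.3 * (0.5 * abs(b) + 0.25 * b^2))
  # tied event times share the risk-set denominator (Breslow)
  lt <- toy_labels(c(1, 1, 2))
  Xt <- matrix(0, 3, 1, dimnames = list(NULL, "x"))
  expect_equal(cox_penalized_objective(0, Xt, lt, 0, 0.5),
               (log(3) + log(3) + log(1)) / 3)
  expect_error(cox_penalized_objective(0, X, toy_labels(1:3, c(0, 0, 0)), 0, 0.5),
               "no observed events")
})

test_that("the elastic-net Cox fit matches a brute-force minimizer at lambda 0", {
  dat <- simulate_cox_data(50, c(1, -0.5, 0.5, 0, 0), censor_frac = 0.3, seed = 7)
  xs <- standardize_features(dat$x)
  fit <- fit_cox_elastic_net(xs, dat$labels, lambda = 0)
  oracle <- optim(rep(0, 5),
                  function(b) cox_penalized_objective(b, xs, dat$labels, 0, 0.5),
                  method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(max(abs(fit$beta - oracle$par)), 1e-3)
})

test_that("penalty-dominated and collinear fits behave as elastic net should", {
  dat <- simulate_cox_data(60, c(1, -1), censor_frac = 0.2, seed = 3)
  xs <- standardize_features(dat$x)
  big <- fit_cox_elastic_net(xs, dat$labels, lambda = 1e3)
  expect_equal(unname(big$beta), c(0, 0))
  dup <- cbind(dat$x, x3 = dat$x[, 1])
  fitd <- fit_cox_elastic_net(standardize_features(dup), dat$labels, lambda = 0.01)
  expect_true(all(is.finite(fitd$beta)))
})

test_that("the fit agrees with glmnet's Cox elastic net", {
  dat <- simulate_cox_data(80, c(1, -0.5, 0), censor_frac = 0.3, seed = 9)
  xs <- standardize_features(dat$x)
  lam <- 0.01
  fit <- fit_cox_elastic_net(xs, dat$labels, lambda = lam, alpha = 0.5)
  gfit <- glmnet::glmnet(
    as.matrix(xs), survival::Surv(dat$labels$time, dat$labels$event),
    family = "cox", alpha = 0.5, lambda = lam,
    standardize = FALSE, thresh = 1e-14
  )
  expect_equal(unname(fit$beta), as.numeric(gfit$beta), tolerance = 5e-3)
})

test_that("Breslow baseline reduces to Nelson-Aalen at beta 0 and handles censoring", {
  labels <- toy_labels(c(1, 2, 3))
  X <- matrix(0, 3, 1, dimnames = list(NULL, "x"))
  bb <- breslow_baseline(null_cox_fit("x", labels), X, labels)
  expect_equal(bb$cumhaz, c(1 / 3, 1 / 3 + 1 / 2, 1 / 3 + 1 / 2 + 1))
  # censored patient at time 2: in risk sets for t <= 2, no jump of its own
  lc <- toy_labels(c(1, 2, 3), c(1, 0, 1))
  bc <- breslow_baseline(null_cox_fit("x", lc), X, lc)
  expect_equal(bc$time, c(1, 3))
  expect_equal(bc$cumhaz, c(1 / 3, 1 / 3 + 1))
  expect_true(all(diff(bb$cumhaz) >= 0))
})

test_that("survival curves follow S(t|x) = S0(t)^exp(x.beta) with curve invariants", {
  dat <- simulate_cox_data(40, c(1, -1), censor_frac = 0.3, seed = 5)
  xs <- standardize_features(dat$x)
  fit <- fit_cox_elastic_net(xs, dat$labels, lambda = 1e-3)
  base <- breslow_baseline(fit, xs, dat$labels)
  m <- as.matrix(xs)
  for (i in c(1, 7, 20)) {
    cv <- predict_survival_curve(fit, base, m[i, ])
    expect_equal(cv$surv[1], 1)
    expect_true(all(diff(cv$surv) <= 1e-12))
    expect_true(all(cv$surv >= 0 & cv$surv <= 1))
  }
  # x.beta = 0 reproduces the baseline survival exactly
  x0 <- rep(0, 2)
  cv0 <- predict_survival_curve(fit, base, x0)
  expect_equal(cv0$surv[-1], exp(-base$cumhaz))
  # larger risk means a pointwise lower curve
  risks <- as.numeric(m %*% fit$beta)
  hi <- predict_survival_curve(fit, base, m[which.max(risks), ])
  lo <- predict_survival_curve(fit, base, m[which.min(risks), ])
  expect_true(all(hi$surv <= lo$surv + 1e-12))
})

test_that("PFS is the exact area under the step curve", {
  flat <- structure(tibble::tibble(time = 0, surv = 1),
                    class = c("survival_curve", class(tibble::tibble())))
  expect_equal(predict_pfs(flat, 7), 7)
  toy <- structure(tibble::tibble(time = c(0, 1), surv = c(1, 0.5)),
                   class = c("survival_curve", class(tibble::tibble())))
  expect_equal(predict_pfs(toy, 2), 1.5)
  half <- toy; half$surv <- half$surv / 2
  expect_equal(predict_pfs(half, 2), 0.75)             # linearity
  expect_error(predict_pfs(toy, 0), "positive")
})

test_that("IPCW concordance reduces to Harrell's C without censoring", {
  n <- 50
  dat <- simulate_cox_data(n, c(1.5), censor_frac = 0, seed = 13)
  risk <- survae:::with_seed(14, rnorm(n))
  # brute-force Harrell oracle
  num <- den <- 0
  y <- dat$labels$time
  for (i in 1:n) for (j in 1:n) {
    if (y[i] < y[j]) {
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
      den <- den + 1
    }
  }
  expect_equal(ipcw_concordance(dat$labels, risk, dat$labels, tau = max(y)),
               num / den)
  # perfectly reverse-ordered risk
  expect_equal(ipcw_concordance(dat$labels, -y, dat$labels, tau = max(y)), 1)
  # constant risk: all ties
  expect_equal(ipcw_concordance(dat$labels, rep(0, n), dat$labels, tau = max(y)), 0.5)
})

test_that("time-dependent AUC is 1 under perfect separation and 0.5 under the null", {
  dat <- simulate_cox_data(100, c(2), censor_frac = 0.2, seed = 21)
  expect_equal(mean_time_dependent_auc(dat$labels, -dat$labels$time,
                                       dat$labels)$mean_auc, 1)
  null <- simulate_cox_data(500, c(0), censor_frac = 0.3, seed = 22)
  rnd <- survae:::with_seed(23, rnorm(500))
  expect_lt(abs(mean_time_dependent_auc(null$labels, rnd, null$labels)$mean_auc - 0.5),
            0.05)
  # a single grid time reduces to the two-sample AUC at that time
  one <- mean_time_dependent_auc(dat$labels, -dat$labels$time, dat$labels,
                                 time_grid = median(dat$labels$time))
  expect_equal(one$mean_auc, one$by_time$auc[1])
})

test_that("the default penalty grid spans [1e-4, 1e-2] with 50 values", {
  g <- lambda_grid()
  expect_length(g, 50)
  expect_equal(g[1], 1e-4)
  expect_equal(g[50], 1e-2)
  expect_lt(max(abs(diff(g) - 2e-4)), 1e-5)
})

test_that("grid search scores by IPCW concordance and breaks ties upward", {
  dat <- simulate_cox_data(60, c(1, -0.5), censor_frac = 0.3, seed = 17)
  xs <- standardize_features(dat$x)
  single <- lambda_grid_search(xs, dat$labels, grid = 5e-3)
  expect_equal(single$best_lambda, 5e-3)
  # two tiny penalties give identical risk ORDERING, hence identical scores
  two <- lambda_grid_search(xs, dat$labels, grid = c(1e-6, 2e-6))
  expect_equal(two$table$concordance[1], two$table$concordance[2])
  expect_equal(two$best_lambda, 2e-6)
  full <- lambda_grid_search(xs, dat$labels)
  expect_equal(nrow(full$table), 50)
  expect_true(full$best_lambda %in% full$table$lambda)
})

test_that("PFS error metrics follow their definitions", {
  expect_equal(pfs_mse(c(1, 2), c(1, 2)), 0)
  expect_equal(overestimation_rate(c(1, 2), c(1, 2)), 0)
  expect_equal(overestimation_rate(c(5, 1), c(4, 2)), 50)
  expect_equal(pfs_mse(c(2, 3), c(1, 2)), 1)
  expect_equal(overestimation_rate(c(2, 3), c(1, 2)), 100)
  expect_error(pfs_mse(numeric(), numeric()), "non-empty")
})

test_that("tidy and glance expose the fit as tibbles", {
  dat <- simulate_cox_data(40, c(1, 0), censor_frac = 0.2, seed = 19)
  fit <- fit_cox_elastic_net(standardize_features(dat$x), dat$labels, lambda = 1e-3)
  td <- tidy(fit)
  expect_identical(names(td), c("term", "estimate", "hazard_ratio"))
  expect_equal(td$hazard_ratio, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$lambda, 1e-3)
  expect_equal(gl$n, 40)
})
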