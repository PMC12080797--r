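# Stratified fold assignment: within each event stratum patients are
# shuffled and dealt round-robin, so each fold's event fraction is within one
# patient of the global fraction.
stratified_folds <- function(event, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(event))
    for (lev in unique(event)) {
      idx <- sample(which(event == lev))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# PCA reducer: rank-L truncated SVD fitted on the training rows of the
# normalized expression; latent scores are min-max rescaled to [0, 1] with
# training statistics (clipped on new data) before histology concatenation.
fit_pca_reducer <- function(x_train, latent_dim) {
  if (latent_dim > min(dim(x_train))) {
    abort("latent_dim exceeds the rank of the training data")
  }
  center <- colMeans(x_train)
  sv <- svd(sweep(x_train, 2, center), nu = 0, nv = latent_dim)
  v <- sv$v
  scores <- sweep(x_train, 2, center) %*% v
  list(center = center, v = v,
       score_min = apply(scores, 2, min), score_max = apply(scores, 2, max))
}

pca_encode <- function(red, x) {
  scores <- sweep(x, 2, red$center) %*% red$v
  rng <- red$score_max - red$score_min
  rng[rng == 0] <- 1
  z <- sweep(sweep(scores, 2, red$score_min), 2, rng, "/")
  pmin(pmax(z, 0), 1)
}

pca_reconstruction_error <- function(red, x) {
  scores <- sweep(x, 2, red$center) %*% red$v
  xhat <- sweep(scores %*% t(red$v), 2, red$center, "+")
  sum((xhat - x)^2) / nrow(x)
}

#' Cross-validated survival-prediction pipeline
#'
#' Runs the full protocol: stratified K-fold split on the event indicator;
#' within each training fold an 85/15 train/validation split; preprocessing
#' statistics (low-expression filter, global expression maximum, histology
#' min-max) fitted on the training split only; dimensionality reduction
#' (autoencoder trained on the training split with validation-based
#' checkpointing, or a PCA baseline); latent features concatenated with
#' histology, standardized, and fed to the elastic-net Cox model with the
#' penalty chosen by IPCW-concordance grid search on train + validation
#' combined; Breslow baseline and per-patient survival curves on the held-out
#' fold; PFS predicted as the area under each curve up to the training
#' follow-up maximum. Reports reconstruction error, PFS mean squared error,
#' mean time-dependent AUC, overestimation percentage and IPCW concordance
#' per fold. Fully seeded and repeatable.
#'
#' @param expression Raw expression tibble (`patient_id` + genes).
#' @param histology Histology tibble aligned with `expression`.
#' @param labels Survival labels in months (converted to trimesters
#'   internally unless `convert_to_trimesters = FALSE`).
#' @param n_folds Number of outer folds (default 10; the protocol also used
#'   a stratified K = 7).
#' @param reducer `"autoencoder"` or `"pca"`.
#' @param latent_dim Latent width fed to the Cox model.
#' @param penalties Autoencoder penalties (see [ae_config()]).
#' @param ae_options Named list of extra [ae_config()] arguments.
#' @param alpha Elastic-net mixing.
#' @param grid Penalty grid (default [lambda_grid()]).
#' @param val_frac Fraction of the training fold held out for validation.
#' @param convert_to_trimesters Convert month labels to trimesters first.
#' @param attribution If `TRUE`, attribute each fold's top latent features to
#'   genes by mutual information and aggregate gene frequencies.
#' @param k_features,k_genes Attribution sizes (top features, genes each).
#' @param seed Root seed; all stage seeds are derived substreams.
#'
#' @return An object of class `cv_report`: `folds` (per-fold metric tibble),
#'   `summary` (mean and sd per metric), `reducer`, and when requested
#'   `attribution` (per-fold tibbles) and `gene_frequency`.
#' @export
run_cross_validation <- function(expression, histology, labels,
                                 n_folds = 10L,
                                 reducer = c("autoencoder", "pca"),
                                 latent_dim = 64L,
                                 penalties = character(),
                                 ae_options = list(),
                                 alpha = 0.5,
                                 grid = lambda_grid(),
                                 val_frac = 0.15,
                                 convert_to_trimesters = TRUE,
                                 attribution = FALSE,
                                 k_features = 5L, k_genes = 5L,
                                 seed = 1L) {
  reducer <- match.arg(reducer)
  assert_aligned(expression, histology, "histology")
  assert_aligned(expression, labels, "labels")
  if (n_folds < 2L) abort("n_folds must be >= 2")
  if (convert_to_trimesters) labels <- convert_pfs_to_trimesters(labels)

  fold <- stratified_folds(labels$event, n_folds, derive_seed(seed, "folds"))
  fold_rows <- vector("list", n_folds)
  attr_reports <- vector("list", n_folds)

  for (f in seq_len(n_folds)) {
    test_idx <- which(fold == f)
    tv_idx <- which(fold != f)
    if (sum(labels$event[test_idx]) == 0L || sum(labels$event[tv_idx]) == 0L) {
      abort(paste0("fold ", f, " has no observed events"))
    }
    # inner 85/15 split, stratified on the event indicator
    inner <- stratified_folds(labels$event[tv_idx],
                              n_folds = max(2L, round(1 / val_frac)),
                              seed = derive_seed(seed, paste0("inner-", f)))
    val_idx <- tv_idx[inner == 1L]
    train_idx <- setdiff(tv_idx, val_idx)

    # preprocessing statistics from the training split only
    filt <- filter_low_expression(expression[train_idx, ])
    keep_genes <- setdiff(names(filt$expression), "patient_id")
    expr_kept <- expression[c("patient_id", keep_genes)]
    norm <- normalize_expression(expr_kept[train_idx, ])
    expr_norm <- normalize_expression(expr_kept, max_value = norm$max_value)$expression
    hstats <- normalize_histology(histology[train_idx, ])$stats
    hist_norm <- normalize_histology(histology, fit_stats = hstats)$histology

    x_train <- expr_norm[train_idx, ]
    x_val <- expr_norm[val_idx, ]
    x_tv <- expr_norm[tv_idx, ]
    x_test <- expr_norm[test_idx, ]

    if (reducer == "autoencoder") {
      cfg_args <- c(list(
        input_dim = length(keep_genes), latent_dim = latent_dim,
        penalties = penalties, seed = derive_seed(seed, paste0("ae-", f))
      ), ae_options)
      config <- do.call(ae_config, cfg_args)
      model <- build_tabular_autoencoder(config)
      trained <- train_autoencoder(model, x_train, x_val)
      model <- trained$model
      recon <- reconstruction_error(model, x_test)
      lat_tv <- encode_cohort(model, x_tv, hist_norm[tv_idx, ])
      lat_test <- encode_cohort(model, x_test, hist_norm[test_idx, ])
    } else {
      red <- fit_pca_reducer(expr_to_matrix(x_train), latent_dim)
      recon <- pca_reconstruction_error(red, expr_to_matrix(x_test))
      wrap <- function(rows) {
        z <- pca_encode(red, expr_to_matrix(expr_norm[rows, ]))
        colnames(z) <- paste0("latent_", seq_len(ncol(z)))
        out <- tibble::as_tibble(z) |>
          dplyr::mutate(patient_id = expr_norm$patient_id[rows], .before = 1L)
        out <- dplyr::bind_cols(out, hist_norm[rows, setdiff(names(hist_norm), "patient_id")])
        attr(out, "latent_cols") <- colnames(z)
        out
      }
      lat_tv <- wrap(tv_idx)
      lat_test <- wrap(test_idx)
    }

    lab_tv <- labels[tv_idx, ]
    lab_test <- labels[test_idx, ]
    lat_tv_std <- standardize_features(lat_tv)
    lat_test_std <- standardize_features(lat_test, fit_stats = attr(lat_tv_std, "stats"))

    search <- lambda_grid_search(lat_tv_std, lab_tv, grid = grid, alpha = alpha)
    fit <- search$best_fit
    base <- breslow_baseline(fit, lat_tv_std, lab_tv)

    test_m <- as_input_matrix(lat_test_std)
    risk <- as.numeric(test_m %*% fit$beta)
    horizon <- max(lab_tv$time)
    pfs_pred <- vapply(seq_len(nrow(test_m)), function(i) {
      predict_pfs(predict_survival_curve(fit, base, test_m[i, ]), horizon)
    }, numeric(1))

    auc <- mean_time_dependent_auc(lab_tv, risk, lab_test)
    fold_rows[[f]] <- tibble::tibble(
      fold = f,
      reconstruction = recon,
      pfs_mse = pfs_mse(pfs_pred, lab_test$time),
      mean_auc = auc$mean_auc,
      overestimation_pct = overestimation_rate(pfs_pred, lab_test$time),
      ipcw_concordance = ipcw_concordance(lab_tv, risk, lab_test),
      best_lambda = search$best_lambda,
      n_test = length(test_idx)
    )

    if (attribution) {
      attr_reports[[f]] <- attribute_latent_features(
        fit, lat_tv, expr_norm[tv_idx, ],
        k_features = k_features, k_genes = k_genes
      )
    }
  }

  folds <- dplyr::bind_rows(fold_rows)
  metrics <- c("reconstruction", "pfs_mse", "mean_auc",
               "overestimation_pct", "ipcw_concordance")
  summary <- tidyr::pivot_longer(folds[metrics], dplyr::everything(),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value)) |>
    dplyr::arrange(match(.data$metric, metrics))

  structure(list(
    folds = folds, summary = summary, reducer = reducer,
    latent_dim = latent_dim, penalties = penalties, n_folds = n_folds,
    seed = seed,
    attribution = if (attribution) attr_reports else NULL,
    gene_frequency = if (attribution) gene_frequency_across_folds(attr_reports) else NULL
  ), class = "cv_report")
}

#' PCA baseline pipeline
#'
#' The pipeline of [run_cross_validation()] with the autoencoder replaced by
#' a rank-`latent_dim` truncated singular-value projection (fitted on the
#' training split, applied to validation/test), the linear yardstick against
#' which the nonlinear compression is judged.
#'
#' @inheritParams run_cross_validation
#' @param ... Passed on to [run_cross_validation()].
#' @return A `cv_report`.
#' @export
pca_baseline <- function(expression, histology, labels, ...) {
  run_cross_validation(expression, histology, labels, reducer = "pca", ...)
}

#' Compare pipeline configurations by one-way ANOVA
#'
#' Tests whether a per-fold metric differs across configurations, as in the
#' protocol's penalty and architecture comparisons (significance level 0.05).
#'
#' @param reports Named list of `cv_report` objects with equal fold counts.
#' @param metric Metric column to compare (e.g. `"mean_auc"`).
#' @param sig_level Significance threshold for flagging pairs.
#' @return A list with `f_statistic`, `p_value`, `table` (per-configuration
#'   mean and sd) and `pairs` (Tukey HSD pairwise comparisons flagged at
#'   `sig_level`).
#' @export
compare_configurations <- function(reports, metric, sig_level = 0.05) {
  if (length(reports) < 2L) abort("need at least two reports to compare")
  if (is.null(names(reports))) names(reports) <- paste0("config_", seq_along(reports))
  kfolds <- vapply(reports, function(r) nrow(r$folds), integer(1))
  if (length(unique(kfolds)) != 1L) abort("reports have different fold counts")
  df <- purrr::imap_dfr(reports, function(r, nm) {
    tibble::tibble(configuration = nm, value = r$folds[[metric]])
  })
  if (all(tapply(df$value, df$configuration, var) == 0)) {
    abort("zero within-group variance; ANOVA is undefined")
  }
  df$configuration <- factor(df$configuration)
  fit <- aov(value ~ configuration, data = df)
  tab <- anova(fit)
  tk <- stats::TukeyHSD(fit)$configuration
  pairs <- tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < sig_level
  )
  list(
    f_statistic = tab[["F value"]][1],
    p_value = tab[["Pr(>F)"]][1],
    table = df |>
      dplyr::group_by(.data$configuration) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value)),
    pairs = pairs
  )
}

#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @export
glance.cv_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(
    tibble::tibble(reducer = x$reducer, latent_dim = x$latent_dim,
                   n_folds = x$n_folds),
    wide
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validated survival pipeline (%s, L = %d, %d folds)\n",
              x$reducer, x$latent_dim, x$n_folds))
  if (length(x$penalties) > 0) {
    cat("  penalties:", paste(x$penalties, collapse = " + "), "\n")
  }
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s %8.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
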