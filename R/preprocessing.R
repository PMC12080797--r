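#' Filter genes with low, patient-specific expression
#'
#' Removes every gene whose per-cohort median expression is below
#' `median_max` AND whose upper quartile (Q3, type-7 linear interpolation) is
#' below `q3_max`. The conjunction targets genes expressed appreciably in only
#' a small subset of patients; a gene failing only one of the two conditions
#' is kept. Retained columns keep their original order and values.
#'
#' @param expr Expression tibble (`patient_id` + one numeric column per gene).
#' @param median_max,q3_max Filter thresholds; defaults 2 and 4.
#'
#' @return A list with `expression` (filtered tibble) and `removed`
#'   (character vector of removed gene symbols, in original column order).
#' @export
filter_low_expression <- function(expr, median_max = 2, q3_max = 4) {
  x <- expr_to_matrix(expr)
  if (nrow(x) == 0L || ncol(x) == 0L) abort("expression matrix is empty")
  med <- apply(x, 2, median)
  q3 <- apply(x, 2, quantile, probs = 0.75, names = FALSE, type = 7)
  drop <- med < median_max & q3 < q3_max
  list(
    expression = expr[c("patient_id", colnames(x)[!drop])],
    removed = colnames(x)[drop]
  )
}

#' Keep only disease-associated genes
#'
#' Intersects the expression matrix's genes with those associated to any of
#' the queried disease identifiers in a gene-disease association table.
#' Column order is preserved.
#'
#' @param expr Expression tibble.
#' @param gda Gene-disease association tibble (`gene_symbol`, `disease_id`).
#' @param disease_ids Character vector of disease identifiers to query.
#'
#' @return The expression tibble restricted to associated genes.
#' @export
select_disease_genes <- function(expr, gda,
                                 disease_ids = unique(gda$disease_id)) {
  if (length(disease_ids) == 0L) abort("disease_ids must be non-empty")
  assoc <- unique(gda$gene_symbol[gda$disease_id %in% disease_ids])
  genes <- setdiff(names(expr), "patient_id")
  keep <- genes[genes %in% assoc]
  if (length(keep) == 0L) {
    abort("no expression gene is associated with the queried diseases")
  }
  expr[c("patient_id", keep)]
}

#' Normalize expression by the global maximum
#'
#' Divides every entry by a single global maximum so all values land in
#' `[0, 1]` while all pairwise ratios are preserved. When `max_value` is
#' supplied (the maximum fitted on a training fold) it is reused, so
#' validation/test data are scaled consistently; values may then exceed 1.
#'
#' @param expr Expression tibble.
#' @param max_value Optional training-fold maximum to reuse.
#'
#' @return A list with `expression` (normalized tibble) and `max_value` (the
#'   divisor used, for the inverse transform).
#' @export
normalize_expression <- function(expr, max_value = NULL) {
  x <- expr_to_matrix(expr)
  if (is.null(max_value)) {
    max_value <- max(x)
    if (max_value <= 0) abort("cannot normalize an all-zero expression matrix")
  }
  list(
    expression = matrix_to_expr(x / max_value, expr$patient_id),
    max_value = max_value
  )
}

#' Min-max normalize histology covariates
#'
#' Scales each histology feature to `[0, 1]` by its (training) minimum and
#' maximum. When `fit_stats` is supplied, those statistics are applied and the
#' result is clipped to `[0, 1]`; a constant feature maps to 0 with a warning.
#'
#' @param hist Histology tibble (`patient_id` + numeric features).
#' @param fit_stats Optional list with `min` and `max` named vectors from a
#'   previous call.
#'
#' @return A list with `histology` (normalized tibble) and `stats` (list of
#'   per-feature `min` and `max`).
#' @export
normalize_histology <- function(hist, fit_stats = NULL) {
  if (nrow(hist) < 1L) abort("histology table must have at least one row")
  feats <- setdiff(names(hist), "patient_id")
  m <- as.matrix(hist[feats])
  if (is.null(fit_stats)) {
    fit_stats <- list(min = apply(m, 2, min), max = apply(m, 2, max))
  }
  rng <- fit_stats$max - fit_stats$min
  if (any(rng == 0)) {
    warn(paste0("constant histology feature(s) mapped to 0: ",
                paste(feats[rng == 0], collapse = ", ")))
  }
  scaled <- sweep(m, 2, fit_stats$min, "-")
  scaled <- sweep(scaled, 2, ifelse(rng == 0, 1, rng), "/")
  scaled[, rng == 0] <- 0
  scaled <- pmin(pmax(scaled, 0), 1)
  out <- hist
  out[feats] <- as.data.frame(scaled)
  list(histology = out, stats = fit_stats)
}

#' Convert progression-free survival from months to trimesters
#'
#' Divides the observed times by 3 and updates the label unit; event
#' indicators are untouched. Refuses to convert labels already expressed in
#' trimesters.
#'
#' @param labels Survival-label tibble with a `unit` attribute of
#'   `"months"`.
#'
#' @return The converted labels, with `unit` attribute `"trimesters"`.
#' @export
convert_pfs_to_trimesters <- function(labels) {
  unit <- attr(labels, "unit") %||% "months"
  if (!identical(unit, "months")) {
    abort("labels are not in months; refusing to convert twice")
  }
  out <- labels
  out$time <- labels$time / 3
  attr(out, "unit") <- "trimesters"
  out
}
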