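#' Latent features with the largest Cox coefficients
#'
#' Returns the indices (into the latent columns) of the `k` latent features
#' with the largest absolute Cox coefficients. Histology columns are
#' excluded; ties are broken toward the lower index.
#'
#' @param fit A [cox_fit][fit_cox_elastic_net()] whose covariates include
#'   latent columns (recorded in its `latent_cols`).
#' @param k Number of features to return (default 5).
#' @return Integer vector of latent feature indices (1-based, within the
#'   latent columns).
#' @export
top_latent_features <- function(fit, k = 5L) {
  latent_cols <- fit$latent_cols %||% names(fit$beta)
  beta <- fit$beta[names(fit$beta) %in% latent_cols]
  if (k > length(beta)) abort("k exceeds the number of latent features")
  if (all(beta == 0)) abort("all latent coefficients are zero; nothing to interpret")
  ord <- order(-abs(beta), seq_along(beta))
  ord[seq_len(k)]
}

#' Normalized mutual information between two continuous vectors
#'
#' Both vectors are discretized by equal-frequency binning into `bins` bins
#' (rank-based, so the value is invariant to monotone transforms); the
#' plug-in mutual information of the joint histogram is normalized by
#' `sqrt(H(A) * H(B))`, giving a value in `[0, 1]`: 0 for independence, 1 for
#' a deterministic monotone relationship. Returns 0 (with a warning) when
#' either vector is constant.
#'
#' @param a,b Equal-length numeric vectors (length >= `2 * bins`).
#' @param bins Number of equal-frequency bins (default 8).
#' @return Normalized mutual information in `[0, 1]`.
#' @export
mutual_information <- function(a, b, bins = 8L) {
  if (length(a) != length(b)) abort("a and b must have equal length")
  if (length(a) < 2L * bins) abort("need at least 2 * bins observations")
  if (length(unique(a)) == 1L || length(unique(b)) == 1L) {
    warn("constant vector: mutual information is 0")
    return(0)
  }
  n <- length(a)
  bin_of <- function(x) {
    ceiling(rank(x, ties.method = "first") * bins / n)
  }
  ba <- bin_of(a)
  bb <- bin_of(b)
  joint <- table(ba, bb) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0) return(0)
  min(max(mi / sqrt(ha * hb), 0), 1)
}

#' Genes most informative about one latent feature
#'
#' Ranks genes by the normalized mutual information between the latent
#' feature's values and each gene's (preprocessed) expression, returning the
#' top `k`. Ties are broken by original gene order.
#'
#' @param latent_col Numeric vector: one latent feature across patients.
#' @param expr Expression tibble aligned with `latent_col`.
#' @param k Number of genes (default 5).
#' @param bins Bins passed to [mutual_information()].
#' @return A tibble with `gene`, `mi`, sorted by decreasing `mi`.
#' @export
top_genes_for_feature <- function(latent_col, expr, k = 5L, bins = 8L) {
  x <- expr_to_matrix(expr)
  if (nrow(x) != length(latent_col)) abort("latent_col and expr are not aligned")
  if (k > ncol(x)) {
    warn("fewer genes than k; returning all")
    k <- ncol(x)
  }
  mi <- vapply(seq_len(ncol(x)), function(j) {
    mutual_information(latent_col, x[, j], bins = bins)
  }, numeric(1))
  ord <- order(-mi, seq_along(mi))[seq_len(k)]
  tibble::tibble(gene = colnames(x)[ord], mi = mi[ord])
}

#' Attribute a fitted model's top latent features to genes
#'
#' For one fold: find the `k_features` latent features with the largest
#' absolute Cox coefficients, then for each the `k_genes` genes with the
#' highest normalized mutual information against the preprocessed expression
#' used for training.
#'
#' @param fit A [cox_fit][fit_cox_elastic_net()].
#' @param latent Latent-feature tibble (as returned by [encode_cohort()]).
#' @param expr Preprocessed expression tibble aligned with `latent`.
#' @param k_features,k_genes Numbers of features and genes (default 5 each).
#' @param bins Bins for [mutual_information()].
#' @return A tibble with `feature` (latent column name), `coefficient`,
#'   `gene`, `mi`.
#' @export
attribute_latent_features <- function(fit, latent, expr,
                                      k_features = 5L, k_genes = 5L, bins = 8L) {
  assert_aligned(latent, expr, "expression")
  latent_cols <- fit$latent_cols %||% setdiff(names(latent), "patient_id")
  k_features <- min(k_features, length(latent_cols))
  idx <- top_latent_features(fit, k_features)
  purrr::map_dfr(idx, function(i) {
    col <- latent_cols[i]
    top <- top_genes_for_feature(latent[[col]], expr, k = k_genes, bins = bins)
    tibble::tibble(
      feature = col,
      coefficient = unname(fit$beta[col]),
      gene = top$gene,
      mi = top$mi
    )
  })
}

#' Aggregate gene attribution frequencies across folds
#'
#' Counts how many (fold x top-feature) slots each gene occupies across the
#' per-fold attribution reports — a gene occupies a slot when it is among
#' that feature's top genes in that fold, so counts are bounded by
#' folds x k_features. This is the cross-validated summary used to surface
#' the genes most represented in the survival-relevant latent features.
#'
#' @param per_fold_reports List of tibbles from
#'   [attribute_latent_features()], one per fold.
#' @return A tibble with `gene` and `count`, sorted by decreasing count then
#'   gene symbol.
#' @export
gene_frequency_across_folds <- function(per_fold_reports) {
  if (length(per_fold_reports) == 0L) abort("need at least one fold report")
  purrr::imap_dfr(per_fold_reports, function(r, f) {
    dplyr::mutate(r, fold = f)
  }) |>
    dplyr::distinct(.data$fold, .data$feature, .data$gene) |>
    dplyr::count(.data$gene, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$gene)
}
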