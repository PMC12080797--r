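#' Specify a synthetic patient cohort
#'
#' Bundles the generative parameters of the synthetic-cohort model: expression
#' of `n_genes` genes in `n_patients` patients is driven by `n_latent_true`
#' independent standard-normal latent factors through gene-specific softplus
#' response curves, a fraction `frac_uninformative` of genes carries no signal
#' (low exponential expression, designed to fall under the low-expression
#' filter), two histology covariates track the first latent factor, and
#' progression times follow a Weibull proportional-hazards model with
#' log-hazard coefficients `beta_true` on the latent factors plus independent
#' uniform censoring calibrated to `censor_rate_target`.
#'
#' @param n_patients,n_genes Cohort dimensions (positive integers).
#' @param n_latent_true Number of generative latent factors.
#' @param noise_sd Standard deviation of additive Gaussian observation noise
#'   on expression (truncated at zero to keep expression non-negative).
#' @param censor_rate_target Desired fraction of censored patients in
#'   `[0, 1]`.
#' @param beta_true Log-hazard-ratio effect of each latent factor (length
#'   `n_latent_true`).
#' @param baseline_scale,baseline_shape Weibull baseline-hazard parameters
#'   (months).
#' @param frac_uninformative Fraction of genes generated without any latent
#'   signal, with median expression below 2 and upper quartile below 4.
#' @param seed Integer seed; identical specs generate identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 400L,
                        n_genes = 300L,
                        n_latent_true = 4L,
                        noise_sd = 0.05,
                        censor_rate_target = 0.45,
                        beta_true = c(1, -1, 0.5, 0)[seq_len(n_latent_true)],
                        baseline_scale = 12,
                        baseline_shape = 1.5,
                        frac_uninformative = 0.3,
                        seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
    n_latent_true = as.integer(n_latent_true), noise_sd = noise_sd,
    censor_rate_target = censor_rate_target, beta_true = as.numeric(beta_true),
    baseline_scale = baseline_scale, baseline_shape = baseline_shape,
    frac_uninformative = frac_uninformative, seed = as.integer(seed)
  )
  if (spec$n_patients < 1L || spec$n_genes < 1L || spec$n_latent_true < 1L) {
    abort("n_patients, n_genes and n_latent_true must all be >= 1")
  }
  if (spec$n_latent_true > spec$n_genes) {
    abort("n_latent_true must not exceed n_genes")
  }
  if (length(spec$beta_true) != spec$n_latent_true) {
    abort("beta_true must have length n_latent_true")
  }
  if (spec$censor_rate_target < 0 || spec$censor_rate_target > 1) {
    abort("censor_rate_target must lie in [0, 1]")
  }
  if (spec$noise_sd < 0) abort("noise_sd must be non-negative")
  if (spec$frac_uninformative < 0 || spec$frac_uninformative > 1) {
    abort("frac_uninformative must lie in [0, 1]")
  }
  if (spec$baseline_scale <= 0 || spec$baseline_shape <= 0) {
    abort("baseline_scale and baseline_shape must be positive")
  }
  structure(spec, class = "cohort_spec")
}

#' Generate synthetic expression, histology and ground truth
#'
#' Informative genes are partitioned into one block per latent factor; a gene
#' in block `k` responds to a linear mix of the factors dominated by its
#' block's factor, `s * softplus(a * z_k + c . z + b)`, with gene-specific
#' dominant slope `a` (random sign, magnitude in `[1, 2]`), cross-loadings
#' `c` on the other factors uniform in `[-0.6, 0.6]`, offset `b` in
#' `[0, 0.5]` and scale `s` in `[4, 6]`, plus Gaussian noise truncated at
#' zero. The `[0, 0.5]` offsets keep the median of every informative gene
#' safely above the low-expression filter threshold while the softplus kink
#' stays inside the sampled factor range, so the gene map is genuinely
#' nonlinear and not absorbed by a low-rank linear projection. Uninformative
#' genes are i.i.d. exponential with rate 1 (median ~0.69, upper quartile
#' ~1.39), so the median < 2 and Q3 < 4 filter removes them with margin. Two
#' histology covariates are logistic transforms of the first latent factor
#' plus noise, hence already in `[0, 1]`.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A list with elements `expression` (tibble: `patient_id` + one
#'   column per gene), `histology` (tibble: `patient_id`,
#'   `tumor_cell_content`, `immune_cells_per_area`), and `truth` (list with
#'   `latent_factors` matrix, `beta_true`, `gene_loading_map` — gene symbols
#'   per factor — and `uninformative_genes`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$seed, "expression"), {
    n <- spec$n_patients
    d <- spec$n_genes
    k <- spec$n_latent_true
    genes <- sprintf("G%04d", seq_len(d))
    patients <- sprintf("P%04d", seq_len(n))

    z <- matrix(rnorm(n * k), n, k,
                dimnames = list(patients, paste0("factor_", seq_len(k))))

    n_uninf <- round(spec$frac_uninformative * d)
    n_inf <- d - n_uninf
    if (n_inf < k) abort("too few informative genes to cover every latent factor")

    # contiguous blocks: genes 1..n_inf informative, remainder uninformative
    block <- sort(rep(seq_len(k), length.out = n_inf))
    x <- matrix(0, n, d, dimnames = list(patients, genes))
    slope <- sample(c(-1, 1), n_inf, replace = TRUE) * runif(n_inf, 1, 2)
    offset <- runif(n_inf, 0, 0.5)
    scale <- runif(n_inf, 4, 6)
    for (g in seq_len(n_inf)) {
      cross <- runif(k, -0.6, 0.6)
      cross[block[g]] <- 0
      x[, g] <- scale[g] *
        softplus(slope[g] * z[, block[g]] + as.numeric(z %*% cross) + offset[g])
    }
    if (n_uninf > 0) {
      x[, n_inf + seq_len(n_uninf)] <- matrix(rexp(n * n_uninf, rate = 1), n, n_uninf)
    }
    if (spec$noise_sd > 0) {
      x <- pmax(x + matrix(rnorm(n * d, sd = spec$noise_sd), n, d), 0)
    }

    hist <- tibble::tibble(
      patient_id = patients,
      tumor_cell_content = plogis(z[, 1] + rnorm(n, sd = 0.3)),
      immune_cells_per_area = plogis(0.8 * z[, 1] + rnorm(n, sd = 0.3))
    )

    loading <- split(genes[seq_len(n_inf)], block)
    names(loading) <- paste0("factor_", seq_len(k))

    list(
      expression = matrix_to_expr(x, patients),
      histology = hist,
      truth = list(
        latent_factors = z,
        beta_true = spec$beta_true,
        gene_loading_map = loading,
        uninformative_genes = if (n_uninf > 0) genes[n_inf + seq_len(n_uninf)] else character()
      )
    )
  })
}

#' Generate right-censored survival labels from cohort ground truth
#'
#' Event times follow a Weibull proportional-hazards model: the cumulative
#' baseline hazard is `H0(t) = (t / baseline_scale)^baseline_shape` and each
#' patient's hazard is multiplied by `exp(z %*% beta_true)`, so times are
#' drawn by inverse-transform sampling. Censoring times are uniform on
#' `[0, c_max]`, independent of the covariates (as required by inverse
#' probability of censoring weighting), with `c_max` solved by bisection so
#' the expected censored fraction matches `censor_rate_target`.
#'
#' @param truth Ground-truth list from [simulate_expression()].
#' @param spec The matching [cohort_spec()].
#'
#' @return A survival-label tibble (`patient_id`, `time`, `event`) with a
#'   `unit` attribute of `"months"`; `event = 1` means progression was
#'   observed at `time`, `event = 0` means follow-up was censored.
#' @export
simulate_survival <- function(truth, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  z <- truth$latent_factors
  if (ncol(z) != length(truth$beta_true)) {
    abort("latent_factors and beta_true dimensions do not conform")
  }
  with_seed(derive_seed(spec$seed, "survival"), {
    n <- nrow(z)
    lp <- as.numeric(z %*% truth$beta_true)
    e <- rexp(n)
    t_event <- spec$baseline_scale * (e * exp(-lp))^(1 / spec$baseline_shape)

    if (spec$censor_rate_target <= 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      # expected censored fraction when C ~ U(0, c): mean(min(T/c, 1))
      frac <- function(c) mean(pmin(t_event / c, 1))
      lo <- min(t_event) * 1e-6
      hi <- max(t_event) * 1e6
      for (i in seq_len(200)) {
        mid <- sqrt(lo * hi)
        if (frac(mid) > spec$censor_rate_target) lo <- mid else hi <- mid
      }
      c_max <- sqrt(lo * hi)
      cens <- runif(n, 0, c_max)
      time <- pmin(t_event, cens)
      event <- as.integer(t_event <= cens)
    }

    labels <- tibble::tibble(
      patient_id = rownames(z) %||% sprintf("P%04d", seq_len(n)),
      time = time,
      event = event
    )
    attr(labels, "unit") <- "months"
    labels
  })
}

#' Generate a synthetic tissue interactome by preferential attachment
#'
#' Starts from `m_attach` isolated nodes; every subsequent node attaches to
#' `m_attach` distinct existing nodes chosen with probability proportional to
#' degree + 1. The result is an undirected, connected, scale-free-like graph
#' with exactly `(n_genes - m_attach) * m_attach` edges, no self-loops and no
#' multi-edges, labeled with a single tissue. Node identifiers follow the
#' numeric-ID convention of [simulate_id_map()] (gene `i` has ID `1000 + i`).
#'
#' @param n_genes Number of nodes (one per gene).
#' @param m_attach Edges added per new node; must be `< n_genes`.
#' @param seed Integer seed.
#' @param tissue Tissue label attached to every edge.
#'
#' @return An edge-list tibble with columns `node_a`, `node_b`, `tissue`.
#' @export
simulate_interactome <- function(n_genes, m_attach = 2L, seed = 1L, tissue = "kidney") {
  n_genes <- as.integer(n_genes)
  m_attach <- as.integer(m_attach)
  if (m_attach >= n_genes) abort("m_attach must be smaller than n_genes")
  if (m_attach < 1L) abort("m_attach must be >= 1")
  with_seed(derive_seed(seed, "interactome"), {
    deg <- integer(n_genes)
    from <- integer(0)
    to <- integer(0)
    for (i in seq(m_attach + 1L, n_genes)) {
      cand <- seq_len(i - 1L)
      targets <- if (length(cand) == m_attach) {
        cand
      } else {
        sample(cand, m_attach, prob = deg[cand] + 1)
      }
      from <- c(from, rep.int(i, m_attach))
      to <- c(to, targets)
      deg[i] <- deg[i] + m_attach
      deg[targets] <- deg[targets] + 1L
    }
    tibble::tibble(
      node_a = 1000L + to,
      node_b = 1000L + from,
      tissue = tissue
    )
  })
}

#' Generate a synthetic gene-disease association table
#'
#' @param genes Character vector of unique gene symbols.
#' @param frac_associated Fraction of genes associated with at least one
#'   disease; `ceiling(frac_associated * length(genes))` genes are selected.
#' @param seed Integer seed.
#' @param disease_ids Disease identifiers (CUIs) to distribute genes over.
#'
#' @return A tibble with columns `gene_symbol`, `disease_id` (no duplicate
#'   pairs).
#' @export
simulate_gda_table <- function(genes, frac_associated = 0.5, seed = 1L,
                               disease_ids = c("C0007134", "C0279702",
                                               "C2608055", "C2931352")) {
  if (anyDuplicated(genes)) abort("gene symbols must be unique")
  if (frac_associated < 0 || frac_associated > 1) {
    abort("frac_associated must lie in [0, 1]")
  }
  n_assoc <- ceiling(frac_associated * length(genes))
  with_seed(derive_seed(seed, "gda"), {
    chosen <- sort(sample(seq_along(genes), n_assoc))
    tibble::tibble(
      gene_symbol = genes[chosen],
      disease_id = sample(disease_ids, n_assoc, replace = TRUE)
    )
  })
}

#' Generate a symbol-to-numeric gene ID map
#'
#' A bijection between gene symbols and synthetic numeric IDs (`1000 + i` for
#' the i-th gene), mirroring the symbol/Entrez dual representation of public
#' interactomes.
#'
#' @param genes Character vector of unique gene symbols.
#' @return A tibble with columns `symbol`, `entrez_id`.
#' @export
simulate_id_map <- function(genes) {
  if (anyDuplicated(genes)) abort("gene symbols must be unique")
  tibble::tibble(symbol = genes, entrez_id = 1000L + seq_along(genes))
}

#' Generate a complete synthetic study (cohort + resources)
#'
#' Convenience wrapper running [simulate_expression()], [simulate_survival()],
#' [simulate_interactome()], [simulate_gda_table()] and [simulate_id_map()]
#' with a shared spec.
#'
#' @param spec A [cohort_spec()].
#' @param frac_associated Fraction of genes in the gene-disease table.
#' @param m_attach Preferential-attachment parameter of the interactome.
#'
#' @return A list with `expression`, `histology`, `labels`, `truth`, `edges`,
#'   `gda`, `id_map`.
#' @export
simulate_cohort <- function(spec, frac_associated = 0.5, m_attach = 2L) {
  expr <- simulate_expression(spec)
  labels <- simulate_survival(expr$truth, spec)
  genes <- setdiff(names(expr$expression), "patient_id")
  list(
    expression = expr$expression,
    histology = expr$histology,
    labels = labels,
    truth = expr$truth,
    edges = simulate_interactome(spec$n_genes, m_attach = m_attach, seed = spec$seed),
    gda = simulate_gda_table(genes, frac_associated = frac_associated, seed = spec$seed),
    id_map = simulate_id_map(genes)
  )
}
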