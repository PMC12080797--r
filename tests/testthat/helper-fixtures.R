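# Shared fixture builders. Everything is generated in code; no files.

# A small all-events label set with distinct times.
toy_labels <- function(times = c(1, 2, 3), events = rep(1L, length(times))) {
  labels <- tibble::tibble(
    patient_id = sprintf("P%02d", seq_along(times)),
    time = times, event = as.integer(events)
  )
  attr(labels, "unit") <- "months"
  labels
}

# Expression tibble from a plain matrix.
expr_tbl <- function(m, genes = sprintf("G%03d", seq_len(ncol(m)))) {
  colnames(m) <- genes
  tibble::as_tibble(m) |>
    dplyr::mutate(patient_id = sprintf("P%03d", seq_len(nrow(m))), .before = 1)
}

# A zero-coefficient cox_fit over the given column names (for Breslow toys).
null_cox_fit <- function(cols, labels) {
  structure(list(
    beta = stats::setNames(rep(0, length(cols)), cols),
    lambda = 0, alpha = 0.5, stats = NULL, latent_cols = cols,
    train_labels = labels[c("time", "event")], n = nrow(labels), iterations = 0L
  ), class = "cox_fit")
}

# Survival data with a known linear predictor on supplied covariates.
simulate_cox_data <- function(n, beta, censor_frac = 0.3, seed = 1,
                              shape = 1.5, scale = 10) {
  survae:::with_seed(seed, {
    p <- length(beta)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
    lp <- as.numeric(x %*% beta)
    t_event <- scale * (rexp(n) * exp(-lp))^(1 / shape)
    if (censor_frac <= 0) {
      time <- t_event; event <- rep(1L, n)
    } else {
      cmax <- as.numeric(quantile(t_event, 1 - censor_frac)) * 2
      cens <- runif(n, 0, cmax)
      time <- pmin(t_event, cens); event <- as.integer(t_event <= cens)
    }
    list(x = x, labels = tibble::tibble(time = time, event = event))
  })
}

# Independent brute-force shortest-path reachability: nodes within depth k of
# any seed, via boolean powers of (A + I). Independent of igraph's BFS.
reach_within <- function(g, seeds, depth) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  diag(a) <- TRUE
  nodes <- igraph::V(g)$name
  reach <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
  diag(reach) <- TRUE
  cur <- diag(length(nodes)) > 0
  for (i in seq_len(depth)) {
    cur <- (cur %*% a) > 0
    reach <- reach | cur
  }
  seeds <- intersect(as.character(seeds), nodes)
  sort(nodes[colSums(reach[seeds, , drop = FALSE]) > 0])
}

# Desk-scale training options shared by the heavier end-to-end checks.
desk_ae_options <- function() {
  list(learning_rate = 3e-3, epochs = 300, lr_decay_every = 75)
}
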