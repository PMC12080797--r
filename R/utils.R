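# Internal helpers shared across modules.

# Derive a reproducible 31-bit sub-seed from a root seed and a stream name,
# so independent stages (splits, initialization, noise, generators) never
# share a random stream.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(seed) %% 2147483629 + h * 7919) %% 2147483629 + 1)
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Convert a patient-by-gene expression tibble (patient_id + gene columns)
# to a plain numeric matrix with patient ids as rownames.
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "patient_id" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "patient_id")])
  storage.mode(m) <- "double"
  rownames(m) <- expr$patient_id
  m
}

matrix_to_expr <- function(m, patient_ids = rownames(m)) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(patient_id = patient_ids, .before = 1L)
}

assert_aligned <- function(expr, other, what = "table") {
  if (!identical(expr$patient_id, other$patient_id)) {
    abort(paste0("patient_id of ", what, " is not aligned with the expression matrix"))
  }
  invisible(TRUE)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}
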