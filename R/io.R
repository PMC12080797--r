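# Plain-text readers and writers for the pipeline's tabular formats:
# expression and histology as TSV (patients as rows), survival labels as CSV,
# interactome edge lists / gene-disease tables / ID maps as TSV.

#' Write a synthetic study to disk
#'
#' Writes `expression.tsv`, `histology.tsv` (patients as rows),
#' `labels.csv` (`patient_id`, `pfs_months`, `censor` — the event-status
#' indicator, 1 when progression was observed), `edges.tsv`
#' (`node_a`, `node_b`, `tissue`), `gda.tsv` and `id_map.tsv`.
#'
#' @param cohort A list as returned by [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$histology, file.path(dir, "histology.tsv"))
  readr::write_csv(
    tibble::tibble(patient_id = cohort$labels$patient_id,
                   pfs_months = cohort$labels$time,
                   censor = cohort$labels$event),
    file.path(dir, "labels.csv")
  )
  readr::write_tsv(cohort$edges, file.path(dir, "edges.tsv"))
  readr::write_tsv(cohort$gda, file.path(dir, "gda.tsv"))
  readr::write_tsv(cohort$id_map, file.path(dir, "id_map.tsv"))
  invisible(dir)
}

#' Read pipeline input files
#'
#' `read_expression_tsv()` and `read_histology_tsv()` read patients-as-rows
#' TSV tables; `read_survival_labels_csv()` reads `patient_id`, `pfs_months`,
#' `censor` (1 = event observed) and returns a label tibble in months;
#' `read_edge_list_tsv()`, `read_gda_tsv()` and `read_id_map_tsv()` read the
#' interactome resources.
#'
#' @param path File path.
#' @return A tibble of the corresponding shape.
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_expression_tsv
#' @export
read_histology_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_expression_tsv
#' @export
read_survival_labels_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  labels <- tibble::tibble(
    patient_id = df$patient_id,
    time = df$pfs_months,
    event = as.integer(df$censor)
  )
  attr(labels, "unit") <- "months"
  labels
}

#' @rdname read_expression_tsv
#' @export
read_edge_list_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_names = c("node_a", "node_b", "tissue"), skip = 1)
}

#' @rdname read_expression_tsv
#' @export
read_gda_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_expression_tsv
#' @export
read_id_map_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
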