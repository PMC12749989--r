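## Per-monomer label tables ----------------------------------------------
##
## One row per extracted monomer: (particle_id, copy_index, state_label)
## with an optional numeric score. This is the tabular hand-off from 3D
## classification (or from assign_state) into the census.

#' Validate a per-monomer label table
#'
#' Checks the label-table contract: `copy_index` in 0..2, `state_label` in
#' the fixed vocabulary (see [state_labels()]), and `(particle_id,
#' copy_index)` unique.
#'
#' @param labels Data frame with columns `particle_id`, `copy_index`,
#'   `state_label` (and optionally `score`).
#' @return The validated tibble (invisibly classed `label_tbl`).
#' @export
validate_labels <- function(labels) {
  labels <- as_tibble(labels)
  need <- c("particle_id", "copy_index", "state_label")
  miss <- setdiff(need, names(labels))
  if (length(miss))
    abort(paste0("label table missing column(s): ", paste(miss, collapse = ", ")),
          class = "rnd_label_error")
  labels$particle_id <- as.character(labels$particle_id)
  labels$copy_index <- as.integer(labels$copy_index)
  bad <- !labels$copy_index %in% 0:2
  if (any(bad))
    abort(paste0("copy_index outside 0-2 in ", sum(bad), " row(s)"),
          class = "rnd_label_error")
  bad_lab <- setdiff(unique(labels$state_label), LABEL_LEVELS)
  if (length(bad_lab))
    abort(paste0("unknown state label(s): ", paste(bad_lab, collapse = ", "),
                 "; allowed: ", paste(LABEL_LEVELS, collapse = ", ")),
          class = "rnd_label_error")
  key <- paste(labels$particle_id, labels$copy_index)
  if (anyDuplicated(key))
    abort(paste0("duplicate (particle_id, copy_index): ",
                 key[duplicated(key)][1]),
          class = "rnd_label_duplicate")
  class(labels) <- unique(c("label_tbl", class(labels)))
  labels
}

#' Read a label table from TSV
#'
#' Expects a header with columns `particle_id`, `copy_index`, `state_label`
#' and optionally `score`. `O*` is spelled with a literal asterisk.
#'
#' @param path TSV file path.
#' @return A validated label tibble.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "rnd_io_error")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           particle_id = readr::col_character(),
                           copy_index = readr::col_integer(),
                           state_label = readr::col_character(),
                           .default = readr::col_double()))
  validate_labels(tab)
}

#' Write a label table to TSV
#'
#' Inverse of [read_label_table()]; write-then-read is the identity.
#'
#' @param labels Label table.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_label_table <- function(labels, path) {
  labels <- validate_labels(labels)
  readr::write_tsv(labels, path, progress = FALSE)
  invisible(path)
}
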