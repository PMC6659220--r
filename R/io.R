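#' Read a binary response matrix from CSV
#'
#' Expects a header row, a first column `student_id`, and one 0/1 column per
#' item. Any non-binary cell or duplicated student/item identifier is an
#' error naming the offending location.
#'
#' @param path Path to a comma-delimited UTF-8 file.
#' @return Integer 0/1 matrix with student/item dimnames.
#' @export
read_responses <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "student_id") {
    rlang::abort("first column must be `student_id`.")
  }
  ids <- as.character(df$student_id)
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicated student_id: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  items <- names(df)[-1]
  if (anyDuplicated(items)) rlang::abort("duplicated item columns.")
  mat <- as.matrix(df[-1])
  bad <- which(!(mat %in% c(0, 1)) | is.na(mat))
  if (length(bad)) {
    r <- ((bad[1] - 1) %% nrow(mat)) + 1
    c_ <- ((bad[1] - 1) %/% nrow(mat)) + 1
    rlang::abort(sprintf(
      "non-binary response at student `%s`, item `%s` (value `%s`).",
      ids[r], items[c_], as.character(mat[bad[1]])))
  }
  storage.mode(mat) <- "integer"
  dimnames(mat) <- list(ids, items)
  mat
}

#' Read item metadata and align exposure flags to a response matrix
#'
#' The file must contain columns `item_id` and `exposed` (0/1); a numeric
#' `difficulty` column is optional. Flags are matched to the response-matrix
#' item columns by `item_id`; an item missing from the metadata is an error
#' listing the offenders, extra metadata rows are dropped with a warning.
#'
#' @param path Path to a comma-delimited file.
#' @param item_ids Character vector of response-matrix column names to align
#'   to (e.g. `colnames(read_responses(...))`). If `NULL`, rows are returned
#'   in file order.
#' @return A tibble with columns `item_id`, `exposed` and, when present,
#'   `difficulty`, ordered to match `item_ids`.
#' @export
read_item_metadata <- function(path, item_ids = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("item_id", "exposed") %in% names(df))) {
    rlang::abort("item metadata needs columns `item_id` and `exposed`.")
  }
  if (!all(df$exposed %in% c(0, 1))) {
    rlang::abort("`exposed` must be 0/1.")
  }
  df$item_id <- as.character(df$item_id)
  if (anyDuplicated(df$item_id)) rlang::abort("duplicated item_id in metadata.")
  if (!is.null(item_ids)) {
    missing <- setdiff(item_ids, df$item_id)
    if (length(missing)) {
      rlang::abort(sprintf("metadata missing item(s): %s",
                           paste(missing, collapse = ", ")))
    }
    extra <- setdiff(df$item_id, item_ids)
    if (length(extra)) {
      warning(sprintf("ignoring %d metadata row(s) not in the response matrix: %s",
                      length(extra), paste(extra, collapse = ", ")))
    }
    df <- df[match(item_ids, df$item_id), ]
  }
  keep <- intersect(c("item_id", "exposed", "difficulty"), names(df))
  tibble::as_tibble(df[keep])
}

#' Write a simulated examination to CSV files
#'
#' Writes three files into `dir`: `<prefix>_responses.csv` (student_id +
#' one column per item), `<prefix>_items.csv` (item_id, difficulty, exposed)
#' and `<prefix>_cohort.csv` (student_id, theta_true, theta_cheat, gain,
#' is_cheater). Reading the responses back with [read_responses()] restores
#' the matrix bit-identically.
#'
#' @param exam An `exam_sim` from [simulate_exam()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"exam"`).
#' @return Invisibly, the three paths.
#' @export
write_exam <- function(exam, dir, prefix = "exam") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("responses", "items", "cohort"),
                                 ".csv"))
  resp <- tibble::as_tibble(exam$responses, rownames = "student_id")
  readr::write_csv(resp, paths[1])
  readr::write_csv(exam$items, paths[2])
  readr::write_csv(exam$cohort, paths[3])
  invisible(stats::setNames(paths, c("responses", "items", "cohort")))
}
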