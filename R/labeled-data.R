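#' Labeled expression tables
#'
#' Throughout rceife a two-class dataset is an ordinary tibble in "samples in
#' rows" layout: a `sample_id` character column, a `label` factor with levels
#' `pos` and `neg`, and one numeric column per feature. Every user-facing
#' function takes such a tibble first and returns a tibble, so calls chain
#' with the pipe. `as_labeled_data()` coerces and validates a data frame into
#' this layout; `feature_ids()` and `feature_matrix()` are the accessors the
#' rest of the package is built on.
#'
#' @param data A data frame with `sample_id`, `label` and numeric feature
#'   columns.
#' @name labeled-data
NULL

label_levels <- c("pos", "neg")

#' @describeIn labeled-data Validate and coerce to the canonical layout.
#'   Fails with an informative error on duplicate ids, non-binary labels,
#'   missing values or non-numeric feature columns.
#' @export
as_labeled_data <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("sample_id", "label") %in% names(data))) {
    abort("`data` must have `sample_id` and `label` columns.", class = "rceife_format_error")
  }
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) {
    abort("duplicate sample ids.", class = "rceife_id_error")
  }
  lab <- as.character(data$label)
  if (!all(lab %in% label_levels)) {
    abort("labels must be 'pos' or 'neg'; use `read_labeled_matrix()` to map raw labels.",
          class = "rceife_label_error")
  }
  data$label <- factor(lab, levels = label_levels)
  feats <- setdiff(names(data), c("sample_id", "label"))
  if (anyDuplicated(feats)) abort("duplicate feature ids.", class = "rceife_id_error")
  numeric_ok <- vapply(unclass(data)[feats], is.numeric, logical(1))
  if (!all(numeric_ok)) {
    abort(paste0("feature column '", feats[which(!numeric_ok)[1L]], "' is not numeric."),
          class = "rceife_parse_error")
  }
  if (length(feats) && anyNA(data[feats])) {
    bad <- which(is.na(as.matrix(data[feats])), arr.ind = TRUE)
    cells <- paste0(data$sample_id[bad[, 1]], "/", feats[bad[, 2]])
    abort(paste0("missing values in cells: ", paste(head(cells, 5), collapse = ", "),
                 if (nrow(bad) > 5) " ..."), class = "rceife_parse_error")
  }
  dplyr::relocate(data, "sample_id", "label")
}

#' @describeIn labeled-data Character vector of feature column names, in
#'   column order.
#' @export
feature_ids <- function(data) {
  setdiff(names(data), c("sample_id", "label"))
}

#' @describeIn labeled-data The numeric samples-by-features matrix, with
#'   sample ids as row names.
#' @export
feature_matrix <- function(data) {
  feats <- feature_ids(data)
  m <- as.matrix(data[feats])
  rownames(m) <- data$sample_id
  m
}

# both classes present, used as a guard before any supervised step
check_two_class <- function(data, call_name) {
  counts <- table(data$label)
  if (any(counts == 0)) {
    abort(paste0(call_name, ": both classes must be present."), class = "rceife_label_error")
  }
  invisible(counts)
}

restrict_features <- function(data, features) {
  unknown <- setdiff(features, feature_ids(data))
  if (length(unknown)) {
    abort(paste0("unknown feature ids: ", paste(head(unknown, 5), collapse = ", ")),
          class = "rceife_id_error")
  }
  data[c("sample_id", "label", features)]
}
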