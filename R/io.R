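#' Read a labeled expression matrix from delimited text
#'
#' Reads the kind of two-class table exported from expression, methylation or
#' abundance studies: a header row, one sample-id column, one label column,
#' and numeric feature columns. The delimiter is auto-detected between comma
#' and tab from the header line unless given. Matrices stored features-in-rows
#' (common for array exports) are transposed on load; in that layout the label
#' "column" is the row whose id equals `label_column`.
#'
#' @param path Path to a CSV/TSV file.
#' @param label_column Name of the label column (or label row when
#'   `orientation = "features_in_rows"`).
#' @param positive_label The raw label value mapped to `pos`; the single other
#'   value becomes `neg`. More than two distinct values is an error.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @param delim Field delimiter; `NULL` auto-detects `,` vs tab.
#' @param sample_column Name of the id column; default the first column.
#' @return A labeled tibble (see [as_labeled_data()]).
#' @export
read_labeled_matrix <- function(path, label_column = "label", positive_label = "pos",
                                orientation = c("samples_in_rows", "features_in_rows"),
                                delim = NULL, sample_column = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "rceife_io_error")
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (orientation == "features_in_rows") {
    ids <- raw[[1L]]
    if (anyDuplicated(ids)) abort("duplicate row ids.", class = "rceife_id_error")
    vals <- t(as.matrix(raw[-1L]))
    colnames(vals) <- ids
    raw <- tibble::as_tibble(vals, rownames = names(raw)[1L])
  }
  if (is.null(sample_column)) sample_column <- names(raw)[1L]
  if (!label_column %in% names(raw)) {
    abort(paste0("label column '", label_column, "' not found."), class = "rceife_format_error")
  }
  if (nrow(raw) < 2L) abort("need at least 2 samples.", class = "rceife_format_error")
  lab_raw <- raw[[label_column]]
  lev <- unique(lab_raw)
  if (length(lev) != 2L || !positive_label %in% lev) {
    abort(paste0("labels must take exactly two values including '", positive_label,
                 "'; found: ", paste(lev, collapse = ", ")), class = "rceife_label_error")
  }
  feats <- setdiff(names(raw), c(sample_column, label_column))
  if (!length(feats)) abort("no feature columns.", class = "rceife_format_error")
  out <- tibble::tibble(
    sample_id = as.character(raw[[sample_column]]),
    label = ifelse(lab_raw == positive_label, "pos", "neg")
  )
  for (f in feats) {
    v <- suppressWarnings(as.numeric(raw[[f]]))
    bad <- which(is.na(v) & !is.na(raw[[f]]))
    if (length(bad)) {
      abort(paste0("non-numeric value in column '", f, "', row ", bad[1L],
                   " ('", raw[[f]][bad[1L]], "')"), class = "rceife_parse_error")
    }
    out[[f]] <- v
  }
  as_labeled_data(out)
}

#' Write a labeled matrix back to CSV
#'
#' Inverse of [read_labeled_matrix()] for the samples-in-rows layout; values
#' round-trip at full double precision.
#'
#' @param data A labeled tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(data, path) {
  data <- as_labeled_data(data)
  out <- data
  out$label <- as.character(out$label)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write aggregate results to a directory
#'
#' Emits the three artifacts of a repeated run: `metrics.csv` (level, metric,
#' mean, std, n_defined), `ranking.csv` (rank, feature_id, survival_score)
#' and `manifest.txt`, a key-value echo of the configuration and seeds.
#'
#' @param aggregate An `rceife_agg` object from [rce_ife_repeat()].
#' @param out_dir Output directory; created if absent.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_results <- function(aggregate, out_dir) {
  stopifnot(inherits(aggregate, "rceife_agg"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", out_dir), class = "rceife_io_error")
  }
  if (file.access(out_dir, 2L) != 0L) {
    abort(paste0("directory not writable: ", out_dir), class = "rceife_io_error")
  }
  paths <- c(
    metrics = file.path(out_dir, "metrics.csv"),
    ranking = file.path(out_dir, "ranking.csv"),
    manifest = file.path(out_dir, "manifest.txt")
  )
  readr::write_csv(aggregate$per_level_stats, paths[["metrics"]], progress = FALSE)
  ranking <- dplyr::mutate(aggregate$ranking, rank = dplyr::row_number(), .before = 1L)
  readr::write_csv(ranking, paths[["ranking"]], progress = FALSE)
  cfg <- aggregate$config
  cfg$n_repeats <- aggregate$n_repeats
  lines <- purrr::imap_chr(cfg, function(v, k) {
    paste0(k, ": ", paste(format(v, digits = 15), collapse = " "))
  })
  writeLines(lines, paths[["manifest"]])
  invisible(paths)
}
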