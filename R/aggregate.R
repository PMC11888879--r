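#' Repeat the full run and aggregate
#'
#' Executes [rce_ife()] `n_repeats` times, each repetition with its own
#' derived seed (fresh undersampling and outer split every time), then
#' averages every metric per level over the repetitions where it is defined
#' and builds the survival-ranked feature list. Repeating smooths the
#' variance of the single small held-out test set — the protocol behind
#' reported mean-and-sd tables.
#'
#' @param data A labeled tibble.
#' @param n_repeats Number of repetitions (the reference protocol uses 100).
#' @param master_seed Master seed; repetition `r` runs with
#'   `derive_seed(master_seed, r)`.
#' @inheritParams rce_ife
#' @return An object of class `rceife_agg`: `per_level_stats` (tibble:
#'   `level`, `metric`, `mean`, `std`, `n_defined`), `ranking` (tibble:
#'   `feature_id`, `survival_score`, sorted score-descending with id
#'   ascending on ties), `per_run_metrics` (tibble with `repetition` +
#'   per-level metric rows), `runs` (list of `rceife_run`), `n_repeats`,
#'   `config` and `master_seed`.
#' @export
rce_ife_repeat <- function(data, n_repeats = 10L, master_seed = 1L,
                           config = NULL, ...) {
  if (n_repeats < 1L) abort("n_repeats must be >= 1.", class = "rceife_parameter_error")
  if (is.null(config)) config <- rce_ife_config(...)
  data <- as_labeled_data(data)
  runs <- purrr::map(seq_len(n_repeats), function(r) {
    tryCatch(
      rce_ife(data, config = config, seed = derive_seed(master_seed, r)),
      error = function(e) {
        abort(paste0("repetition ", r, " (seed ", derive_seed(master_seed, r),
                     ") failed: ", conditionMessage(e)), parent = e)
      }
    )
  })
  per_run <- purrr::imap_dfr(runs, function(run, r) {
    dplyr::mutate(run$per_level, repetition = r, .before = 1L)
  })
  metric_cols <- setdiff(names(per_run), c("repetition", "level", "n_clusters"))
  per_level_stats <- per_run |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$level, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      std = if (sum(!is.na(.data$value)) > 1L) sd(.data$value, na.rm = TRUE) else 0,
      n_defined = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$level), .data$metric)

  structure(
    list(per_level_stats = per_level_stats,
         ranking = feature_survival_ranking(runs),
         per_run_metrics = per_run,
         runs = runs,
         n_repeats = n_repeats,
         config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
         master_seed = master_seed),
    class = "rceife_agg"
  )
}

#' Survival-ranked feature list
#'
#' A feature's survival score is the number of elimination levels it
#' persisted through, summed over runs; features screened out before the
#' first level score 0. The ranking orders features by score descending,
#' ties by feature id ascending — the interpretable output of the engine, a
#' ranked candidate-biomarker list.
#'
#' @param runs A list of `rceife_run` objects (>= 1).
#' @return A tibble with `feature_id` and `survival_score`.
#' @export
feature_survival_ranking <- function(runs) {
  if (!length(runs)) abort("need at least one run.", class = "rceife_parameter_error")
  purrr::map_dfr(runs, "survival_count") |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(survival_score = sum(.data$n_levels), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$survival_score), .data$feature_id)
}

#' Top-k overlap between rankings
#'
#' Consistency analysis across independent rankings: for the top-`k` feature
#' sets of each ranking, the number common to all, every pairwise
#' intersection size, and the count unique to each ranking — the Venn-region
#' counts used to show run-to-run stability of selected features.
#'
#' @param rankings A list of >= 2 ranking tibbles (as from
#'   [feature_survival_ranking()]) or character vectors of ordered ids.
#' @param k Top-list size; must not exceed any ranking's length.
#' @return A tibble with columns `region` (`"common_to_all"`,
#'   `"pair_<i>_<j>"`, `"unique_<i>"`) and `count`.
#' @export
#' @examples
#' r <- list(letters[1:5], letters[c(1:4, 6)], letters[1:5])
#' topk_overlap(r, k = 5)
topk_overlap <- function(rankings, k) {
  if (length(rankings) < 2L) abort("need >= 2 rankings.", class = "rceife_parameter_error")
  if (k < 1L) abort("k must be >= 1.", class = "rceife_parameter_error")
  tops <- purrr::map(rankings, function(r) {
    ids <- if (is.data.frame(r)) r$feature_id else as.character(r)
    if (length(ids) < k) abort("k exceeds a ranking's length.", class = "rceife_parameter_error")
    ids[seq_len(k)]
  })
  n <- length(tops)
  common <- Reduce(intersect, tops)
  rows <- list(tibble::tibble(region = "common_to_all", count = length(common)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        region = paste0("pair_", i, "_", j),
        count = length(intersect(tops[[i]], tops[[j]]))
      )
    }
  }
  for (i in seq_len(n)) {
    others <- unique(unlist(tops[-i]))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      region = paste0("unique_", i),
      count = length(setdiff(tops[[i]], others))
    )
  }
  dplyr::bind_rows(rows)
}

#' @export
print.rceife_agg <- function(x, ...) {
  cat("RCE-IFE aggregate over", x$n_repeats, "repetitions\n")
  final <- min(x$per_level_stats$level)
  cat("final level", final, "summary:\n")
  print(dplyr::filter(x$per_level_stats, .data$level == final))
  invisible(x)
}
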