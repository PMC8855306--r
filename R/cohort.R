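#' Construct a cohort of panic-attack recordings
#'
#' A cohort bundles the long-format sample table (one row per measurement)
#' with per-attack categorical metadata. This is the container consumed by
#' [qc_filter()], [profile_cohort()] and the summary functions, and the
#' schema used for on-disk interchange ([read_cohort()] / [write_cohort()]).
#'
#' @param samples A data frame with columns `user_id`, `attack_index`,
#'   `channel` (`"hr"` or `"anxiety"`), `t_seconds`, `value`. Timestamps
#'   must be strictly increasing within each recording and channel; HR
#'   values must be positive; anxiety ratings must lie in 0--10.
#' @param meta A data frame with one row per recording: `user_id`,
#'   `attack_index`, the five lifestyle ordinals (1--5 or NA) and a
#'   `trigger` label from [pa_triggers()] (or NA if none was reported).
#' @param config Optionally, the [generator_config()] that produced the
#'   cohort (absent for ingested real data).
#'
#' @return An object of class `"pa_cohort"`: a list with elements
#'   `samples` (tibble), `meta` (tibble) and `config`.
#' @export
as_pa_cohort <- function(samples, meta = NULL, config = NULL) {
  samples <- tibble::as_tibble(samples)
  required <- c("user_id", "attack_index", "channel", "t_seconds", "value")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("`samples` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (is.null(meta)) {
    meta <- dplyr::distinct(samples, .data$user_id, .data$attack_index)
    meta[pa_lifestyle_factors] <- NA_integer_
    meta$trigger <- NA_character_
  }
  meta <- tibble::as_tibble(meta)
  cohort <- structure(list(samples = samples, meta = meta, config = config),
                      class = "pa_cohort")
  validate_cohort(cohort)
}

#' Validate a cohort against the recording schema
#'
#' Checks channel labels, strict within-channel timestamp monotonicity,
#' value ranges (HR > 0, anxiety in 0--10), lifestyle ordinals in 1--5,
#' trigger vocabulary membership, and uniqueness of (user, attack) pairs in
#' the metadata. Errors name the offending recording.
#'
#' @param cohort A `"pa_cohort"`.
#' @return The cohort, invisibly usable in a pipe (returned visibly).
#' @export
validate_cohort <- function(cohort) {
  s <- cohort$samples
  bad_chan <- setdiff(unique(s$channel), c("hr", "anxiety"))
  if (length(bad_chan) > 0) {
    abort(paste0("Unknown channel label(s): ",
                 paste(bad_chan, collapse = ", "), "."))
  }
  mono <- s |>
    dplyr::group_by(.data$user_id, .data$attack_index, .data$channel) |>
    dplyr::summarise(ok = all(diff(.data$t_seconds) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(mono) > 0) {
    abort(sprintf(
      "Timestamps not strictly increasing for user_id=%s attack_index=%s channel=%s.",
      mono$user_id[1], mono$attack_index[1], mono$channel[1]))
  }
  hr <- dplyr::filter(s, .data$channel == "hr", .data$value <= 0)
  if (nrow(hr) > 0) {
    abort(sprintf("Non-positive HR value for user_id=%s attack_index=%s.",
                  hr$user_id[1], hr$attack_index[1]))
  }
  anx <- dplyr::filter(s, .data$channel == "anxiety",
                       .data$value < 0 | .data$value > 10)
  if (nrow(anx) > 0) {
    abort(sprintf("Anxiety rating outside [0, 10] for user_id=%s attack_index=%s.",
                  anx$user_id[1], anx$attack_index[1]))
  }
  m <- cohort$meta
  if (anyDuplicated(m[c("user_id", "attack_index")]) > 0) {
    abort("Duplicate (user_id, attack_index) pairs in cohort metadata.")
  }
  for (f in intersect(pa_lifestyle_factors, names(m))) {
    v <- m[[f]]
    if (any(!is.na(v) & (v < 1 | v > 5 | v != round(v)))) {
      abort(sprintf("Lifestyle factor `%s` must be an ordinal in 1..5.", f))
    }
  }
  if ("trigger" %in% names(m)) {
    bad_tr <- setdiff(stats::na.omit(unique(m$trigger)), pa_trigger_levels)
    if (length(bad_tr) > 0) {
      abort(paste0("Trigger label(s) outside the app vocabulary: ",
                   paste(bad_tr, collapse = ", "), "."))
    }
  }
  cohort
}

#' @export
print.pa_cohort <- function(x, ...) {
  n_rec <- nrow(x$meta)
  n_hr <- sum(x$samples$channel == "hr")
  n_anx <- sum(x$samples$channel == "anxiety")
  cat(sprintf("<pa_cohort> %d recording(s): %d HR samples, %d anxiety ratings\n",
              n_rec, n_hr, n_anx))
  if (!is.null(x$config)) {
    cat(sprintf("  generated synthetically (seed %d)\n", x$config$seed))
  }
  invisible(x)
}

#' Number of recordings in a cohort
#' @param cohort A `"pa_cohort"`.
#' @return Integer count of (user, attack) recordings.
#' @export
n_recordings <- function(cohort) nrow(cohort$meta)

#' Per-recording HR series as a nested tibble
#'
#' Convenience accessor used by peak detection and alignment: one row per
#' recording with the channel's samples nested as a `t_seconds`/`value`
#' tibble in a list column.
#'
#' @param cohort A `"pa_cohort"`.
#' @param channel `"hr"` or `"anxiety"`.
#' @return A tibble with columns `user_id`, `attack_index`, `samples`.
#' @export
cohort_series <- function(cohort, channel = c("hr", "anxiety")) {
  channel <- match.arg(channel)
  cohort$samples |>
    dplyr::filter(.data$channel == !!channel) |>
    dplyr::select("user_id", "attack_index", "t_seconds", "value") |>
    tidyr::nest(samples = c("t_seconds", "value"))
}

#' Restrict a cohort to a set of recordings
#'
#' @param cohort A `"pa_cohort"`.
#' @param keys A data frame with columns `user_id` and `attack_index`.
#' @return A `"pa_cohort"` containing only the matching recordings.
#' @export
subset_cohort <- function(cohort, keys) {
  keys <- dplyr::distinct(tibble::as_tibble(keys), .data$user_id,
                          .data$attack_index)
  as_pa_cohort(
    dplyr::semi_join(cohort$samples, keys, by = c("user_id", "attack_index")),
    dplyr::semi_join(cohort$meta, keys, by = c("user_id", "attack_index")),
    config = cohort$config
  )
}

#' Write / read a cohort in the on-disk interchange format
#'
#' `write_cohort()` writes `samples.csv` (long format, header
#' `user_id,attack_index,channel,t_seconds,value`), `meta.json` (one record
#' per attack with lifestyle ordinals and trigger) and, when present,
#' `config.json`. `read_cohort()` reads the same layout back and validates
#' it against the schema, erroring with the offending `user_id` /
#' `attack_index` on malformed input.
#'
#' @param cohort A `"pa_cohort"`.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   validated `"pa_cohort"`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$samples, file.path(dir, "samples.csv"))
  jsonlite::write_json(cohort$meta, file.path(dir, "meta.json"),
                       dataframe = "rows", na = "null", digits = NA)
  if (!is.null(cohort$config)) {
    jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  samples <- readr::read_csv(
    file.path(dir, "samples.csv"),
    col_types = readr::cols(
      user_id = readr::col_character(),
      attack_index = readr::col_integer(),
      channel = readr::col_character(),
      t_seconds = readr::col_double(),
      value = readr::col_double()
    )
  )
  meta_path <- file.path(dir, "meta.json")
  meta <- if (file.exists(meta_path)) {
    tibble::as_tibble(jsonlite::fromJSON(meta_path))
  } else {
    NULL
  }
  if (!is.null(meta) && "user_id" %in% names(meta)) {
    meta$user_id <- as.character(meta$user_id)
  }
  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path)) {
    cfg <- jsonlite::fromJSON(cfg_path)
    cfg$lifestyle_means <- unlist(cfg$lifestyle_means)
    cfg$trigger_weights <- unlist(cfg$trigger_weights)
    structure(cfg, class = "pa_config")
  } else {
    NULL
  }
  as_pa_cohort(samples, meta, config = config)
}
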