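#' Read a clonotype count table
#'
#' Reads per-clone read counts for one repertoire sample from a tab-separated
#' file. Two dialects are supported:
#'
#' * `"airr"` — an AIRR Rearrangement style TSV. The clone identifier is taken
#'   from `junction_aa` (the CDR3 amino-acid sequence), the read count from
#'   `duplicate_count` (defaulting to 1 when the column is absent), and the
#'   functionality flag from `productive`.
#' * `"simple"` — a minimal two-column table `clone_id<TAB>count` with a header
#'   row. Records are assumed productive.
#'
#' Rows with a missing clone identifier or a missing/non-positive count are
#' dropped with a warning.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect `"airr"`, `"simple"`, or `"auto"` (default) which picks
#'   `"airr"` when a `junction_aa` column is present.
#' @param sample_id Sample identifier attached to every record; defaults to the
#'   file name without extension.
#' @return A tibble of clonotype records with columns `sample_id`, `clone_id`,
#'   `count` (integer reads) and `productive` (logical).
#' @seealso [filter_clonotypes()], [clonal_frequencies()]
#' @export
read_clonotype_table <- function(path, dialect = c("auto", "airr", "simple"),
                                 sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(tbl) == 0) abort(paste0("Empty clonotype table: ", path))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[A-Za-z]+$", "", basename(path))
  }
  if (dialect == "auto") {
    dialect <- if ("junction_aa" %in% names(tbl)) "airr" else "simple"
  }

  if (dialect == "airr") {
    if (!"junction_aa" %in% names(tbl)) {
      abort("AIRR dialect requires a `junction_aa` column.")
    }
    count <- if ("duplicate_count" %in% names(tbl)) {
      suppressWarnings(as.integer(tbl$duplicate_count))
    } else {
      rep(1L, nrow(tbl))
    }
    productive <- if ("productive" %in% names(tbl)) {
      tolower(tbl$productive) %in% c("t", "true", "1", "yes", "productive")
    } else {
      rep(TRUE, nrow(tbl))
    }
    out <- tibble::tibble(
      sample_id = sample_id,
      clone_id = tbl$junction_aa,
      count = count,
      productive = productive
    )
  } else {
    missing_cols <- setdiff(c("clone_id", "count"), names(tbl))
    if (length(missing_cols) > 0) {
      abort(paste0("Simple dialect requires column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    out <- tibble::tibble(
      sample_id = sample_id,
      clone_id = tbl$clone_id,
      count = suppressWarnings(as.integer(tbl$count)),
      productive = TRUE
    )
  }

  bad <- is.na(out$clone_id) | out$clone_id == "" | is.na(out$count) |
    out$count < 1
  if (any(bad)) {
    warn(paste0(sum(bad), " row(s) lacking a clone identifier or a positive ",
                "count were dropped from ", basename(path), "."))
    out <- out[!bad, ]
  }
  if (nrow(out) == 0) abort(paste0("No usable records in ", path))
  out
}

#' Read a sample metadata table
#'
#' @param path Tab-separated file with columns `sample_id` and `status_label`
#'   (further columns are kept as covariates).
#' @return A tibble with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(c("sample_id", "status_label"), names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("Metadata requires column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tbl$sample_id)) abort("Duplicated sample_id in metadata.")
  tbl
}

#' Apply clonotype preprocessing filters
#'
#' Retains clonotype records that (i) are productive, (ii) carry a CDR3 of at
#' least `min_cdr3_length` amino acids, and (iii) — after aggregating read
#' counts over exact (100 % identity) clone_id matches within each sample —
#' reach a minimum aggregated abundance. The abundance filter deliberately
#' runs after aggregation so that it applies to clones, not to individual
#' table rows.
#'
#' @param records A tibble of clonotype records as returned by
#'   [read_clonotype_table()].
#' @param min_cdr3_length Minimal clone identifier length in amino acids
#'   (default 4).
#' @param min_abundance Minimal aggregated per-clone read count (default 2).
#' @param require_productive Drop non-productive records first (default TRUE).
#' @return A filtered, aggregated tibble with columns `sample_id`, `clone_id`,
#'   `count`. Filtering is idempotent.
#' @export
filter_clonotypes <- function(records, min_cdr3_length = 4,
                              min_abundance = 2, require_productive = TRUE) {
  if (nrow(records) == 0) abort("`records` is empty.")
  if (!"productive" %in% names(records)) records$productive <- TRUE
  if (!"sample_id" %in% names(records)) records$sample_id <- "sample"

  out <- records
  if (require_productive) out <- dplyr::filter(out, .data$productive)
  out <- dplyr::filter(out, nchar(.data$clone_id) >= min_cdr3_length)
  out <- out |>
    dplyr::group_by(.data$sample_id, .data$clone_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$count >= min_abundance)
  if (nrow(out) == 0) {
    abort("All records were removed by the preprocessing filters.")
  }
  dplyr::arrange(out, .data$sample_id, dplyr::desc(.data$count),
                 .data$clone_id)
}

#' Clonal frequency distribution from clonotype counts
#'
#' Normalizes per-clone read counts into clonal frequencies
#' f_i = count_i / total reads, per sample. The clonal frequency distribution
#' is the object every downstream computation (diversity profiles,
#' intersection analysis, clustering, classification) consumes.
#'
#' @param records Tibble with columns `clone_id` and `count` (and optionally
#'   `sample_id`). Counts for duplicated clone ids within a sample are summed.
#' @return A tibble with columns `sample_id`, `clone_id`, `count`, `frequency`
#'   sorted by descending frequency within sample; frequencies sum to 1 per
#'   sample.
#' @examples
#' tbl <- tibble::tibble(clone_id = c("A", "B"), count = c(2L, 2L))
#' clonal_frequencies(tbl)$frequency # 0.5 0.5
#' @export
clonal_frequencies <- function(records) {
  if (nrow(records) == 0) abort("`records` is empty.")
  if (!"sample_id" %in% names(records)) records$sample_id <- "sample"
  out <- records |>
    dplyr::group_by(.data$sample_id, .data$clone_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(frequency = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$frequency),
                   .data$clone_id)
  if (any(!is.finite(out$frequency)) || any(out$frequency <= 0)) {
    abort("Counts must be positive with a positive per-sample total.")
  }
  out
}

# Coerce a frequency input (numeric vector, or a tibble with a `frequency`
# or `count` column describing a single sample) to a validated frequency
# vector summing to 1.
as_frequency_vector <- function(f, tol = 1e-9) {
  if (is.data.frame(f)) {
    if ("sample_id" %in% names(f) && dplyr::n_distinct(f$sample_id) > 1) {
      abort("Expected a single-sample distribution; got several sample_id values.")
    }
    if ("frequency" %in% names(f)) {
      f <- f$frequency
    } else if ("count" %in% names(f)) {
      f <- f$count / sum(f$count)
    } else {
      abort("Data frame input needs a `frequency` or `count` column.")
    }
  }
  f <- as.numeric(f)
  if (length(f) == 0 || anyNA(f) || any(f <= 0)) {
    abort("Clonal frequencies must be positive and non-missing.")
  }
  if (abs(sum(f) - 1) > max(tol, 1e-6)) {
    abort("Clonal frequencies must sum to 1.")
  }
  f
}

#' Write and read diversity/evenness profile tables
#'
#' Profiles are stored as plain CSV with columns
#' `sample_id, alpha, diversity, evenness`.
#'
#' @param profiles A profile tibble as returned by [repertoire_profiles()].
#' @param path CSV file path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   returns the profile tibble.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_csv(profiles, path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    sample_id = "c", .default = "d"), progress = FALSE)
  new_profile_tbl(tbl)
}
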