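#' Read a chromosome measurement table
#'
#' One row per chromosome per homolog per metaphase cell, lengths in
#' micrometres. Tab- or comma-separated is detected from the file extension
#' (`.csv` means comma, anything else tab); decimal points only.
#'
#' Required columns: `cell_id`, `pair_id`, `homolog_id`, `short_um`,
#' `long_um`. Optional: `sat_um` (satellite length, default 0) and `sat_arm`
#' (`"short"`, `"long"` or `"none"`). Arms are oriented on read so that the
#' short arm is the shorter one (satellite included when
#' `config$satellite_in_length`).
#'
#' @param path Path to a TSV/CSV file.
#' @param config A [karyo_config()] (orientation convention).
#' @param orient Orient arms after validation (default `TRUE`).
#' @return A tibble of validated measurement records.
#' @seealso [orient_measurements()], [summarize_pairs()]
#' @export
read_measurements <- function(path, config = karyo_config(), orient = TRUE) {
  config <- as_karyo_config(config)
  df <- read_delim_auto(path)
  required <- c("cell_id", "pair_id", "homolog_id", "short_um", "long_um")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("Measurement file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "karyo_schema_error")
  }
  if (!"sat_um" %in% names(df)) df$sat_um <- 0
  if (!"sat_arm" %in% names(df)) df$sat_arm <- "none"
  df$sat_um[is.na(df$sat_um)] <- 0
  df$sat_arm[is.na(df$sat_arm)] <- "none"
  records <- tibble(
    cell_id = as.character(df$cell_id),
    pair_id = as.integer(df$pair_id),
    homolog_id = as.integer(df$homolog_id),
    short_um = as.numeric(df$short_um),
    long_um = as.numeric(df$long_um),
    sat_um = as.numeric(df$sat_um),
    sat_arm = as.character(df$sat_arm)
  )
  validate_measurements(records)
  if (orient) records <- orient_measurements(records, config) else records
}

#' Validate measurement records
#'
#' Checks positivity of arm lengths, satellite consistency (`sat_um > 0` iff
#' `sat_arm != "none"`), uniqueness of `(cell_id, pair_id, homolog_id)` and
#' that every pair observed in a cell has an even number of homologs.
#'
#' @param records Measurement tibble (see [read_measurements()]).
#' @return The records, invisibly, if valid; otherwise an error.
#' @export
validate_measurements <- function(records) {
  stopifnot(is.data.frame(records))
  bad <- which(!is.finite(records$short_um) | records$short_um <= 0 |
                 !is.finite(records$long_um) | records$long_um <= 0)
  if (length(bad) > 0) {
    abort(paste0("Non-positive or missing arm length at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "karyo_validation_error")
  }
  if (any(!is.finite(records$sat_um) | records$sat_um < 0)) {
    abort("sat_um must be finite and >= 0.", class = "karyo_validation_error")
  }
  if (!all(records$sat_arm %in% c("short", "long", "none"))) {
    abort("sat_arm must be one of 'short', 'long', 'none'.",
          class = "karyo_validation_error")
  }
  inconsistent <- which((records$sat_um > 0) != (records$sat_arm != "none"))
  if (length(inconsistent) > 0) {
    abort(paste0("sat_um > 0 iff sat_arm != 'none' violated at row(s): ",
                 paste(head(inconsistent, 5), collapse = ", ")),
          class = "karyo_validation_error")
  }
  if (!all(records$homolog_id %in% c(1L, 2L))) {
    abort("homolog_id must be 1 or 2.", class = "karyo_validation_error")
  }
  key <- paste(records$cell_id, records$pair_id, records$homolog_id)
  if (anyDuplicated(key) > 0) {
    abort("(cell_id, pair_id, homolog_id) must be unique within a dataset.",
          class = "karyo_validation_error")
  }
  counts <- table(paste(records$cell_id, records$pair_id))
  odd <- names(counts)[counts %% 2 == 1]
  if (length(odd) > 0) {
    abort(paste0("Odd homolog count for (cell, pair): ",
                 paste(head(odd, 5), collapse = "; ")),
          class = "karyo_pairing_error")
  }
  invisible(records)
}

#' Orient arms so the short arm is the shorter one
#'
#' Arms are compared by effective length: the measured arm plus its satellite
#' when `config$satellite_in_length` is `TRUE`. When the raw short arm is the
#' longer one, `short_um`/`long_um` are swapped and `sat_arm` follows its arm.
#' Orienting twice equals orienting once.
#'
#' @inheritParams read_measurements
#' @param records Measurement tibble.
#' @return The oriented tibble (row order preserved).
#' @export
orient_measurements <- function(records, config = karyo_config()) {
  config <- as_karyo_config(config)
  with_sat <- config$satellite_in_length
  eff_short <- records$short_um +
    if (with_sat) ifelse(records$sat_arm == "short", records$sat_um, 0) else 0
  eff_long <- records$long_um +
    if (with_sat) ifelse(records$sat_arm == "long", records$sat_um, 0) else 0
  swap <- eff_short > eff_long
  if (any(swap)) {
    s <- records$short_um[swap]
    records$short_um[swap] <- records$long_um[swap]
    records$long_um[swap] <- s
    sa <- records$sat_arm[swap]
    records$sat_arm[swap] <- ifelse(sa == "short", "long",
                                    ifelse(sa == "long", "short", "none"))
  }
  records
}

MARKER_TYPES <- c("CPD", "DAPI", "5S", "45S")
ARM_LEVELS <- c("short", "long", "centromere-spanning")

#' Read a marker table (fluorochrome bands and rDNA sites)
#'
#' One row per band or rDNA site on one arm of a chromosome pair. Extents are
#' fractions of the arm length with origin 0 at the centromere, increasing
#' toward the telomere (both arms independently span 0 to 1).
#'
#' Required columns: `pair_id`, `arm` (`"short"`, `"long"` or
#' `"centromere-spanning"`), `marker_type` (`"CPD"`, `"DAPI"`, `"5S"`,
#' `"45S"`), `start_frac`, `end_frac`.
#'
#' @param path Path to a TSV/CSV file.
#' @return A tibble of validated marker sites (derived fields such as `di`
#'   are added later by [annotate_markers()]).
#' @export
read_markers <- function(path) {
  df <- read_delim_auto(path)
  required <- c("pair_id", "arm", "marker_type", "start_frac", "end_frac")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("Marker file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "karyo_schema_error")
  }
  sites <- tibble(
    pair_id = as.integer(df$pair_id),
    arm = as.character(df$arm),
    marker_type = as.character(df$marker_type),
    start_frac = as.numeric(df$start_frac),
    end_frac = as.numeric(df$end_frac)
  )
  validate_markers(sites)
  sites
}

#' Validate marker sites
#'
#' @param sites Marker tibble (see [read_markers()]).
#' @return The sites, invisibly, if valid.
#' @export
validate_markers <- function(sites) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0) return(invisible(sites))
  if (!all(sites$marker_type %in% MARKER_TYPES)) {
    bad <- setdiff(unique(sites$marker_type), MARKER_TYPES)
    abort(paste0("Unknown marker_type: ", paste(bad, collapse = ", "),
                 " (allowed: ", paste(MARKER_TYPES, collapse = ", "), ")"),
          class = "karyo_schema_error")
  }
  if (!all(sites$arm %in% ARM_LEVELS)) {
    abort(paste0("arm must be one of: ", paste(ARM_LEVELS, collapse = ", ")),
          class = "karyo_schema_error")
  }
  bad <- which(!(sites$start_frac >= 0 & sites$start_frac < sites$end_frac &
                   sites$end_frac <= 1))
  if (length(bad) > 0) {
    abort(paste0("Need 0 <= start_frac < end_frac <= 1; violated at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "karyo_validation_error")
  }
  invisible(sites)
}

#' Write measurement / marker tables
#'
#' Inverse of [read_measurements()] / [read_markers()]; tab- or
#' comma-separated by extension.
#'
#' @param records,sites Tibbles as produced by the readers or by
#'   [generate_dataset()].
#' @param path Output path (`.csv` for comma, anything else tab).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  validate_measurements(records)
  write_delim_auto(records, path)
}

#' @rdname write_measurements
#' @export
write_markers <- function(sites, path) {
  validate_markers(sites)
  write_delim_auto(sites, path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "karyo_io_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # everything as character: type conversion is explicit in the readers
  # (guessing would turn labels like "45S" into numbers)
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}

write_delim_auto <- function(df, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}
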