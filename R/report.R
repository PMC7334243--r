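#' Run the full karyotype analysis pipeline
#'
#' Measurement table to complete report: pair morphometrics and complement
#' summary ([summarize_pairs()], [karyotype_summary()]), marker annotation on
#' the renumbered pairs ([annotate_markers()]), band amounts, rDNA locus
#' counts, colocalization, and an idiogram specification. Marker `pair_id`s
#' refer to the *input* pair numbering and are remapped to the decreasing-RL
#' numbering of the summary.
#'
#' @param measurements Measurement tibble or path ([read_measurements()]).
#' @param markers Optional marker tibble or path ([read_markers()]).
#' @param species Species label.
#' @param config A [karyo_config()].
#' @return A list of class `karyo_report`: `species`, `summary`
#'   (`karyo_summary`), `pairs`, `markers` (annotated), `band_totals`,
#'   `cpd_including_rdna_percent`, `locus_counts`, `colocalization`,
#'   `idiogram`, `config`.
#' @export
analyze_karyotype <- function(measurements, markers = NULL,
                              species = "unknown", config = karyo_config()) {
  config <- as_karyo_config(config)
  if (is.character(measurements)) {
    measurements <- read_measurements(measurements, config)
  }
  if (is.character(markers)) markers <- read_markers(markers)
  if (is.null(markers)) {
    markers <- tibble(pair_id = integer(), arm = character(),
                      marker_type = character(), start_frac = numeric(),
                      end_frac = numeric())
  }
  validate_markers(markers)

  pairs <- summarize_pairs(measurements, config)
  summary <- karyotype_summary(measurements, species, config)

  # remap marker pair ids from input numbering to decreasing-RL numbering
  if (nrow(markers) > 0) {
    unknown <- setdiff(unique(markers$pair_id), pairs$source_pair_id)
    if (length(unknown) > 0) {
      abort(paste0("Marker site(s) reference unknown input pair_id: ",
                   paste(unknown, collapse = ", ")),
            class = "karyo_linkage_error")
    }
    markers$pair_id <- pairs$pair_id[match(markers$pair_id,
                                           pairs$source_pair_id)]
    markers <- arrange(markers, .data$pair_id, .data$arm, .data$marker_type,
                       .data$start_frac)
  }
  annotated <- annotate_markers(markers, pairs, summary$tcl_um, config)
  amounts <- band_amounts(markers, pairs, summary$tcl_um, config)
  structure(
    list(species = species,
         summary = summary,
         pairs = pairs,
         markers = annotated,
         band_totals = amounts$totals,
         cpd_including_rdna_percent = amounts$cpd_including_rdna_percent,
         locus_counts = locus_counts(markers),
         colocalization = colocalization_report(markers),
         idiogram = build_idiogram(pairs, markers, species),
         config = unclass(config)),
    class = "karyo_report")
}

#' @export
print.karyo_report <- function(x, ...) {
  print(x$summary)
  cat("  rDNA loci: ", x$locus_counts$n_5S, "x 5S, ",
      x$locus_counts$n_45S, "x 45S\n", sep = "")
  bt <- x$band_totals
  cat("  Band amounts (% TCL, non-rDNA):",
      paste(sprintf("%s %.2f", bt$marker_type, bt$amount_percent),
            collapse = ", "), "\n")
  invisible(x)
}

summary_fields <- function() {
  c("species", "two_n", "n_pairs", "kf", "tcl_um", "tcl_se_um", "c_um",
    "rrl_min", "rrl_max", "ci_mean", "ci_sd", "a1", "a2", "ask_percent",
    "cv_cl", "cv_ci", "ai", "stebbins")
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (full precision, machine readable: summary, per-pair
#' table, annotated marker table, band totals, locus counts, effective
#' configuration), `karyotype_table.tsv` (one-row complement summary in the
#' layout of a comparative karyotype table, rounded to `config$digits`),
#' `marker_table.tsv` (pair, arm, type, position class, di, size as percent
#' of karyotype length), and `idiogram.svg`.
#'
#' @param report A `karyo_report` from [analyze_karyotype()].
#' @param dir Output directory (created if needed).
#' @param render Also render the idiogram SVG.
#' @param style [idiogram_style()] used for the SVG.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, render = TRUE,
                         style = idiogram_style()) {
  stopifnot(inherits(report, "karyo_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dg <- report$config$digits
  rnd <- function(x) round(x, dg)

  json_path <- file.path(dir, "report.json")
  payload <- list(
    summary = unclass(report$summary),
    pairs = report$pairs,
    markers = report$markers,
    band_totals = report$band_totals,
    cpd_including_rdna_percent = report$cpd_including_rdna_percent,
    locus_counts = report$locus_counts,
    colocalization = report$colocalization,
    config = report$config
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")

  s <- report$summary
  kt <- tibble(
    species = s$species, two_n = s$two_n, kf = s$kf,
    tcl_um = rnd(s$tcl_um), tcl_se_um = rnd(s$tcl_se_um), c_um = rnd(s$c_um),
    rrl = paste0(rnd(s$rrl_min), "-", rnd(s$rrl_max)),
    ci_mean = rnd(s$ci_mean), ci_sd = rnd(s$ci_sd),
    a1 = rnd(s$a1), a2 = rnd(s$a2), ask_percent = rnd(s$ask_percent),
    ai = rnd(s$ai), stebbins = s$stebbins)
  kt_path <- file.path(dir, "karyotype_table.tsv")
  readr::write_tsv(kt, kt_path)

  mk <- report$markers
  mt_path <- file.path(dir, "marker_table.tsv")
  if (nrow(mk) > 0) {
    mt <- tibble(pair_id = mk$pair_id, arm = mk$arm,
                 marker_type = mk$marker_type,
                 position_class = mk$position_class,
                 di = rnd(mk$di), size_percent_tcl = rnd(mk$size_percent_tcl))
  } else {
    mt <- tibble(pair_id = integer(), arm = character(),
                 marker_type = character(), position_class = character(),
                 di = numeric(), size_percent_tcl = numeric())
  }
  readr::write_tsv(mt, mt_path)

  files <- c(report = json_path, karyotype_table = kt_path,
             marker_table = mt_path)
  if (render) {
    svg_path <- file.path(dir, "idiogram.svg")
    render_svg(report$idiogram, svg_path, style)
    files <- c(files, idiogram = svg_path)
  }
  invisible(files)
}

#' Read back a report.json
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return A list with `summary`, `pairs`, `markers`, `band_totals`,
#'   `locus_counts`, `colocalization`, `config` as tibbles/lists.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pairs <- as_tibble(x$pairs)
  x$markers <- as_tibble(x$markers)
  x$band_totals <- as_tibble(x$band_totals)
  x$colocalization <- as_tibble(x$colocalization)
  x
}

#' Comparative multi-species karyotype table
#'
#' One row per species with the complement-level parameters, plus
#' cross-species ratios as attributes: `tcl_ratio_max_min` (longest / shortest
#' karyotype) and the pairwise TCL ratio matrix `tcl_ratio`.
#'
#' @param reports A list of `karyo_report` objects (or of `karyo_summary`),
#'   or a summary tibble with the columns of [reference_karyotypes()].
#' @return A tibble (class `karyo_comparison`) with attributes
#'   `tcl_ratio_max_min` and `tcl_ratio`.
#' @export
compare_karyotypes <- function(reports) {
  if (is.data.frame(reports)) {
    tab <- as_tibble(reports)
  } else {
    rows <- lapply(reports, function(r) {
      s <- if (inherits(r, "karyo_report")) r$summary else r
      stopifnot(inherits(s, "karyo_summary"))
      as_tibble(unclass(s)[summary_fields()])
    })
    tab <- bind_rows(rows)
  }
  if (nrow(tab) < 2) {
    abort("Need at least 2 reports to compare.", class = "karyo_domain_error")
  }
  if (anyDuplicated(tab$species) > 0) {
    abort("Duplicate species names in comparison.",
          class = "karyo_naming_error")
  }
  ratio <- outer(tab$tcl_um, tab$tcl_um, "/")
  dimnames(ratio) <- list(tab$species, tab$species)
  structure(tab,
            tcl_ratio_max_min = max(tab$tcl_um) / min(tab$tcl_um),
            tcl_ratio = ratio,
            class = c("karyo_comparison", class(tab)))
}

#' Cross-species TCL ratio from a comparison
#'
#' @param comparison A `karyo_comparison` from [compare_karyotypes()].
#' @param a,b Species names (numerator, denominator).
#' @return The ratio of the two TCLs.
#' @export
tcl_ratio <- function(comparison, a, b) {
  m <- attr(comparison, "tcl_ratio")
  if (!(a %in% rownames(m)) || !(b %in% colnames(m))) {
    abort("Species not found in comparison.", class = "karyo_naming_error")
  }
  m[a, b]
}
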