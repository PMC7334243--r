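#' Analysis configuration
#'
#' Collects every numeric convention the pipeline relies on so a run can be
#' reproduced from its echoed configuration. Defaults are the conventional
#' values used throughout plant karyotype work.
#'
#' @param levan_breaks Upper arm-ratio bounds of the Levan morphology classes
#'   `m`, `sm`, `st` (class `t` is everything above the last break). Intervals
#'   are half-open on the left, so an arm ratio exactly on a break falls in the
#'   lower class; `M` is reserved for an arm ratio of exactly 1.
#' @param stebbins_ar Arm-ratio threshold of the Stebbins intrachromosomal
#'   classes: a chromosome "exceeds" it only when AR is strictly greater.
#' @param pcen_max_di Largest `di` (percent distance from the centromere, of
#'   the arm length) still called pericentromeric; larger non-terminal sites
#'   are interstitial.
#' @param ter_min_end Smallest `end_frac` at which a site counts as terminal;
#'   slightly below 1 to absorb measurement noise at the telomere.
#' @param satellite_in_length Include satellite length in the carrying arm for
#'   arm ratio, centromeric index and all length statistics (the satellite is
#'   still flagged separately for the karyotype formula and the idiogram).
#' @param rdna_overlap_min Minimum fraction of a heterochromatin band covered
#'   by an rDNA site for the band to count as an rDNA band (and be excluded
#'   from the headline non-rDNA band amount).
#' @param digits Decimal places used in the human-readable report tables.
#'
#' @return A list of class `karyo_config`.
#' @export
#' @examples
#' cfg <- karyo_config(pcen_max_di = 25)
#' cfg$pcen_max_di
karyo_config <- function(levan_breaks = c(m = 1.70, sm = 3.00, st = 7.00),
                         stebbins_ar = 2.0,
                         pcen_max_di = 28,
                         ter_min_end = 0.98,
                         satellite_in_length = TRUE,
                         rdna_overlap_min = 0.5,
                         digits = 2) {
  stopifnot(length(levan_breaks) == 3, all(diff(c(1, levan_breaks)) > 0),
            stebbins_ar >= 1, pcen_max_di >= 0, pcen_max_di <= 100,
            ter_min_end > 0, ter_min_end <= 1,
            is.logical(satellite_in_length),
            rdna_overlap_min >= 0, rdna_overlap_min <= 1)
  structure(
    list(levan_breaks = unname(levan_breaks),
         stebbins_ar = stebbins_ar,
         pcen_max_di = pcen_max_di,
         ter_min_end = ter_min_end,
         satellite_in_length = satellite_in_length,
         rdna_overlap_min = rdna_overlap_min,
         digits = digits),
    class = "karyo_config"
  )
}

#' @export
print.karyo_config <- function(x, ...) {
  cat("<karyo_config>\n")
  cat("  Levan breaks (m|sm|st):", paste(x$levan_breaks, collapse = ", "), "\n")
  cat("  Stebbins AR threshold: ", x$stebbins_ar, "\n")
  cat("  PCEN max di:           ", x$pcen_max_di, "\n")
  cat("  TER min end_frac:      ", x$ter_min_end, "\n")
  cat("  satellite in length:   ", x$satellite_in_length, "\n")
  cat("  rDNA band overlap min: ", x$rdna_overlap_min, "\n")
  invisible(x)
}

as_karyo_config <- function(config) {
  if (inherits(config, "karyo_config")) return(config)
  if (is.null(config)) return(karyo_config())
  if (is.list(config)) return(do.call(karyo_config, config))
  abort("`config` must be a karyo_config or a list of karyo_config arguments.")
}
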