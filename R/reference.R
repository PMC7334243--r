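#' Published karyotype parameters of five wild Vigna species
#'
#' Reference complement-level karyotype parameters (all species 2n = 2x =
#' 22, 11 pairs, measured over five metaphase plates) as published: karyotype
#' formula, TCL with its standard error, mean chromosome length `C`, the
#' relative-length range, mean centromeric index with the dispersion of the
#' per-pair values, the asymmetry indices A1, A2, AsK% and AI, and the
#' Stebbins category. Used to parameterize [builtin_templates()] and as the
#' worked-example input for recomputing derived quantities (e.g. `C = TCL /
#' n_pairs`, AI from A2 and the centromeric-index dispersion, cross-species
#' TCL ratios).
#'
#' The `ci_sd` column is the dispersion printed next to the mean centromeric
#' index, read as the standard deviation of the 11 per-pair values: under
#' that reading `AI = (100 A2)(100 ci_sd/ci_mean)/100` reproduces the
#' published AI for V. vexillata and V. caracalla to two decimals (the other
#' three species differ by at most 0.03 purely from the two-decimal rounding
#' of the published A2).
#'
#' @return A tibble with one row per species: `species`, `two_n`, `n_pairs`,
#'   `kf`, `tcl_um`, `tcl_se_um`, `c_um`, `rrl_min`, `rrl_max`, `ci_mean`,
#'   `ci_sd`, `a1`, `a2`, `ask_percent`, `ai`, `stebbins`.
#' @export
#' @examples
#' ref <- reference_karyotypes()
#' round(ref$tcl_um / ref$n_pairs, 2)  # recomputes the published C column
reference_karyotypes <- function() {
  tibble(
    species = c("V. luteola", "V. vexillata", "V. minima", "V. trilobata",
                "V. caracalla"),
    two_n = 22L,
    n_pairs = 11L,
    kf = c("11m", "11m", "11m", "9m + 2sm", "10m (1SAT) + 1sm"),
    tcl_um = c(33.81, 25.67, 38.29, 36.56, 46.62),
    tcl_se_um = c(1.56, 2.02, 1.04, 2.73, 1.71),
    c_um = c(3.07, 2.33, 3.48, 3.32, 4.24),
    rrl_min = c(6.88, 6.99, 7.37, 7.20, 5.61),
    rrl_max = c(12.40, 12.66, 12.14, 13.48, 12.80),
    ci_mean = c(44.35, 43.24, 44.55, 42.15, 44.37),
    ci_sd = c(2.45, 3.45, 2.03, 3.87, 3.13),
    a1 = c(0.20, 0.23, 0.19, 0.27, 0.20),
    a2 = c(0.21, 0.19, 0.14, 0.19, 0.20),
    ask_percent = c(55.97, 57.01, 55.53, 58.00, 55.39),
    ai = c(1.15, 1.52, 0.66, 1.76, 1.41),
    stebbins = c("1A", "1A", "1A", "1A", "1B")
  )
}
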