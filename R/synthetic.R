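#' Construct and validate a synthetic species template
#'
#' A template holds everything needed to generate measurement and marker
#' tables for one species: the relative-length profile (percent of the
#' haploid complement per pair, decreasing, summing to 100), the arm-ratio
#' profile, a target karyotype length, an optional satellite, the marker
#' layout, and the noise model (multiplicative lognormal per homolog arm per
#' cell with coefficient of variation `noise_cv`, plus a lognormal cell-level
#' condensation factor with coefficient of variation `condensation_cv`).
#'
#' @param name Species label.
#' @param target_tcl_um Haploid complement length to emulate, micrometres.
#' @param rl_profile Numeric vector, one value per pair, non-increasing,
#'   summing to 100.
#' @param ar_profile Arm ratios per pair, all >= 1.
#' @param satellite Optional list `(pair, arm, frac)`: satellite as a
#'   fraction of its (effective) arm length.
#' @param markers Marker tibble or data.frame (see [read_markers()]).
#' @param noise_cv Homolog-arm measurement noise, percent CV.
#' @param condensation_cv Cell-to-cell condensation spread, percent CV.
#' @param n_cells Number of metaphase cells to simulate.
#' @param seed Default RNG seed used by [generate_dataset()].
#' @return A list of class `species_template`.
#' @export
species_template <- function(name, target_tcl_um, rl_profile, ar_profile,
                             satellite = NULL, markers = NULL,
                             noise_cv = 5, condensation_cv = 5,
                             n_cells = 5, seed = 1L) {
  n <- length(rl_profile)
  if (length(ar_profile) != n) {
    abort("rl_profile and ar_profile must have the same length.",
          class = "karyo_template_error")
  }
  if (abs(sum(rl_profile) - 100) > 1e-6) {
    abort("rl_profile must sum to 100.", class = "karyo_template_error")
  }
  if (any(diff(rl_profile) > 1e-9)) {
    abort("rl_profile must be non-increasing.", class = "karyo_template_error")
  }
  if (any(ar_profile < 1)) {
    abort("ar_profile entries must be >= 1.", class = "karyo_template_error")
  }
  if (!is.null(satellite)) {
    stopifnot(satellite$pair %in% seq_len(n),
              satellite$arm %in% c("short", "long"),
              satellite$frac > 0, satellite$frac < 1)
  }
  if (is.null(markers)) {
    markers <- tibble(pair_id = integer(), arm = character(),
                      marker_type = character(), start_frac = numeric(),
                      end_frac = numeric())
  } else {
    markers <- as_tibble(markers)
    validate_markers(markers)
    if (any(!markers$pair_id %in% seq_len(n))) {
      abort("Template markers reference pairs outside 1..n_pairs.",
            class = "karyo_template_error")
    }
  }
  structure(list(name = name, n_pairs = n, target_tcl_um = target_tcl_um,
                 rl_profile = rl_profile, ar_profile = ar_profile,
                 satellite = satellite, markers = markers,
                 noise_cv = noise_cv, condensation_cv = condensation_cv,
                 n_cells = n_cells, seed = as.integer(seed)),
            class = "species_template")
}

#' @export
print.species_template <- function(x, ...) {
  cat("<species_template> ", x$name, ": ", x$n_pairs, " pairs, target TCL ",
      x$target_tcl_um, " um, ", nrow(x$markers), " marker sites, noise_cv ",
      x$noise_cv, "%\n", sep = "")
  invisible(x)
}

#' Relative-length profile between two printed endpoints
#'
#' Builds a decreasing profile of `n` relative lengths with exact largest and
#' smallest values that sums to 100. Interior values interpolate
#' geometrically between the endpoints on a power-warped index
#' (`rl_i = rl_max * (rl_min/rl_max)^(((i-1)/(n-1))^g)`); the warp exponent
#' `g` is solved numerically so the profile sums to 100. Useful when only the
#' extremes of a published relative-length range are known.
#'
#' @param rl_max,rl_min Largest and smallest relative length (percent).
#' @param n Number of pairs.
#' @return Numeric vector of length `n`, non-increasing, summing to 100.
#' @export
#' @examples
#' p <- rl_profile_between(12.40, 6.88, 11)
#' c(sum(p), p[1], p[11])
rl_profile_between <- function(rl_max, rl_min, n) {
  stopifnot(rl_max >= rl_min, rl_min > 0, n >= 2)
  lo <- rl_max + (n - 1) * rl_min
  hi <- (n - 1) * rl_max + rl_min
  if (100 < lo - 1e-9 || 100 > hi + 1e-9) {
    abort("No decreasing profile with these endpoints can sum to 100.",
          class = "karyo_template_error")
  }
  t <- (seq_len(n) - 1) / (n - 1)
  ratio <- rl_min / rl_max
  prof <- function(g) rl_max * ratio^(t^g)
  f <- function(g) sum(prof(g)) - 100
  g <- uniroot(f, lower = 0.01, upper = 60, tol = 1e-12)$root
  prof(g)
}

#' The pairs a template implies at zero noise
#'
#' Expected per-pair morphometrics of a template's noiseless dataset:
#' the values [summarize_pairs()] recovers exactly when `noise_cv = 0`.
#'
#' @param template A [species_template()].
#' @return A pair summary tibble (same columns as [summarize_pairs()]).
#' @export
template_pairs <- function(template) {
  stopifnot(inherits(template, "species_template"))
  L <- template$rl_profile / 100 * template$target_tcl_um
  b <- L / (1 + template$ar_profile)
  B <- L - b
  sat_pair <- if (is.null(template$satellite)) NA_integer_ else template$satellite$pair
  tibble(
    pair_id = seq_len(template$n_pairs),
    source_pair_id = seq_len(template$n_pairs),
    b = b, B = B, L = L,
    ar = template$ar_profile,
    ci = 100 * b / L,
    rl = template$rl_profile,
    levan_class = classify_levan(template$ar_profile),
    has_satellite = seq_len(template$n_pairs) %in% sat_pair,
    sat_arm = ifelse(seq_len(template$n_pairs) %in% sat_pair,
                     template$satellite$arm, NA_character_),
    sat_frac = ifelse(seq_len(template$n_pairs) %in% sat_pair,
                      if (is.null(template$satellite)) NA_real_ else template$satellite$frac,
                      NA_real_)
  )
}

lnorm_factors <- function(n, cv_percent) {
  if (cv_percent <= 0) return(rep(1, n))
  s <- sqrt(log(1 + (cv_percent / 100)^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate a synthetic measurement + marker dataset
#'
#' Emulates measuring `n_cells` metaphase plates of one diploid complement.
#' For each cell a lognormal condensation factor scales every chromosome;
#' pair lengths come from `rl_profile * target_tcl_um`, arms are split by
#' `ar_profile`, and each homolog arm is perturbed by independent
#' multiplicative lognormal noise with CV `noise_cv` percent. The satellite,
#' when present, is carved out of its (noisy) arm at the template fraction.
#' Markers are fractional layouts and are emitted unchanged. Fully
#' reproducible from the seed.
#'
#' @param template A [species_template()].
#' @param seed RNG seed; defaults to the template's own.
#' @return A list with `measurements` (record tibble) and `markers`.
#' @export
generate_dataset <- function(template, seed = NULL) {
  stopifnot(inherits(template, "species_template"))
  if (is.null(seed)) seed <- template$seed
  set.seed(as.integer(seed))
  n <- template$n_pairs
  L <- template$rl_profile / 100 * template$target_tcl_um
  b <- L / (1 + template$ar_profile)   # effective short arm, satellite included
  B <- L - b
  sat <- template$satellite
  rows <- vector("list", template$n_cells)
  for (c in seq_len(template$n_cells)) {
    f_c <- lnorm_factors(1, template$condensation_cv)
    m_s <- lnorm_factors(2 * n, template$noise_cv)
    m_l <- lnorm_factors(2 * n, template$noise_cv)
    k <- 0
    cell <- vector("list", 2 * n)
    for (p in seq_len(n)) {
      for (h in 1:2) {
        k <- k + 1
        s_eff <- b[p] * f_c * m_s[k]
        l_eff <- B[p] * f_c * m_l[k]
        sat_um <- 0; sat_arm <- "none"
        if (!is.null(sat) && sat$pair == p) {
          sat_arm <- sat$arm
          if (sat$arm == "short") {
            sat_um <- sat$frac * s_eff; s_eff <- s_eff - sat_um
          } else {
            sat_um <- sat$frac * l_eff; l_eff <- l_eff - sat_um
          }
        }
        cell[[k]] <- tibble(cell_id = sprintf("cell%02d", c),
                            pair_id = p, homolog_id = h,
                            short_um = s_eff, long_um = l_eff,
                            sat_um = sat_um, sat_arm = sat_arm)
      }
    }
    rows[[c]] <- bind_rows(cell)
  }
  measurements <- bind_rows(rows)
  validate_measurements(measurements)
  list(measurements = measurements, markers = template$markers)
}

peri_bands <- function(type, pairs, arms, width) {
  grid <- expand.grid(pair_id = pairs, arm = arms,
                      stringsAsFactors = FALSE)
  tibble(pair_id = as.integer(grid$pair_id), arm = grid$arm,
         marker_type = type, start_frac = 0, end_frac = width)
}

site_row <- function(pair, arm, type, start, end) {
  tibble(pair_id = as.integer(pair), arm = arm, marker_type = type,
         start_frac = start, end_frac = end)
}

# Interstitial / pericentromeric rDNA sites are placed so their centers sit at
# the published di percent; terminal sites start at their published di.
int_site <- function(pair, arm, type, di, halfwidth = 0.05) {
  site_row(pair, arm, type, di / 100 - halfwidth, di / 100 + halfwidth)
}
ter_site <- function(pair, arm, type, di) {
  site_row(pair, arm, type, di / 100, 1)
}

#' Built-in species templates
#'
#' Templates for the five wild Vigna species of the reference karyotype table
#' (see [reference_karyotypes()]), all 2n = 22 over 5 metaphase cells with 5%
#' measurement noise. Karyotype formula, relative-length extremes, satellite,
#' rDNA locus layout (counts, arms, published di values) and band presence
#' patterns follow the published karyotypes; the full per-pair arm-ratio and
#' relative-length profiles are not published, so interior values are
#' interpolated ([rl_profile_between()]) and arm ratios chosen within the
#' published class and mean-CI constraints. Band extents approximate the
#' published band amounts.
#'
#' @return A named list of five [species_template()] objects.
#' @export
#' @examples
#' tpl <- builtin_templates()$V_luteola
#' tpl$n_pairs
builtin_templates <- function() {
  t_lut <- species_template(
    name = "V. luteola", target_tcl_um = 33.81,
    rl_profile = rl_profile_between(12.40, 6.88, 11),
    ar_profile = seq(1.10, 1.45, length.out = 11),
    markers = bind_rows(
      peri_bands("CPD", 1:11, c("short", "long"), 0.31) |>
        filter(!(.data$pair_id == 3 & .data$arm == "short")),
      site_row(3, "short", "CPD", 0, 1),          # rDNA-CPD over the 45S arm
      site_row(3, "short", "45S", 0, 1),
      int_site(11, "short", "5S", 16.55)
    ),
    seed = 101L)

  t_vex <- species_template(
    name = "V. vexillata", target_tcl_um = 25.67,
    rl_profile = rl_profile_between(12.66, 6.99, 11),
    ar_profile = seq(1.10, 1.52, length.out = 11),
    markers = bind_rows(
      ter_site(2, "short", "45S", 20.53),
      ter_site(2, "short", "CPD", 20.53),
      ter_site(3, "short", "45S", 16.73),
      ter_site(3, "short", "CPD", 16.73),
      int_site(8, "long", "5S", 52.29)
    ),
    seed = 102L)

  t_min <- species_template(
    name = "V. minima", target_tcl_um = 38.29,
    rl_profile = rl_profile_between(12.14, 7.37, 11),
    ar_profile = seq(1.08, 1.42, length.out = 11),
    markers = bind_rows(
      ter_site(2, "long", "45S", 58.64), ter_site(2, "long", "CPD", 58.64),
      ter_site(4, "long", "45S", 59.42), ter_site(4, "long", "CPD", 59.42),
      ter_site(6, "short", "45S", 38.91), ter_site(6, "short", "CPD", 38.91),
      ter_site(7, "short", "45S", 50.74), ter_site(7, "short", "CPD", 50.74),
      ter_site(9, "short", "45S", 67.94), ter_site(9, "short", "CPD", 67.94),
      int_site(2, "short", "5S", 30.86),
      int_site(2, "short", "CPD", 30.86)          # 5S sites carry CPD bands
    ),
    seed = 103L)

  ar_tri <- seq(1.10, 1.50, length.out = 11)
  ar_tri[c(2, 7)] <- c(1.85, 1.95)                # the two sm pairs
  t_tri <- species_template(
    name = "V. trilobata", target_tcl_um = 36.56,
    rl_profile = rl_profile_between(13.48, 7.20, 11),
    ar_profile = ar_tri,
    markers = bind_rows(
      peri_bands("CPD", 1:11, c("short", "long"), 0.21) |>
        filter(!(.data$pair_id == 7 & .data$arm == "short")),
      int_site(6, "short", "45S", 25.05, halfwidth = 0.03),
      int_site(6, "short", "CPD", 25.05, halfwidth = 0.03),
      site_row(7, "short", "45S", 0, 1),
      site_row(7, "short", "CPD", 0, 1),
      int_site(4, "long", "5S", 14.95)
    ),
    seed = 104L)

  ar_car <- seq(1.08, 1.45, length.out = 11)
  ar_car[3] <- 1.85                               # the sm pair
  t_car <- species_template(
    name = "V. caracalla", target_tcl_um = 46.62,
    rl_profile = rl_profile_between(12.80, 5.61, 11),
    ar_profile = ar_car,
    satellite = list(pair = 1, arm = "short", frac = 0.2),
    markers = bind_rows(
      peri_bands("CPD", 1:11, c("short", "long"), 0.19) |>
        filter(!(.data$pair_id == 1 & .data$arm == "short")),
      site_row(1, "short", "45S", 0, 0.8),        # whole arm except satellite
      site_row(1, "short", "CPD", 0, 0.8),
      site_row(4, "short", "CPD", 0.46, 0.64),    # interstitial CPD bands
      site_row(4, "long", "CPD", 0.46, 0.64),
      site_row(5, "long", "CPD", 0.46, 0.64),
      int_site(2, "long", "5S", 34.32),
      int_site(5, "short", "5S", 56.70),
      peri_bands("DAPI", c(2, 3, 4, 5), "short", 0.22),
      peri_bands("DAPI", c(4, 5, 6, 8), "long", 0.22)
    ),
    seed = 105L)

  list(V_luteola = t_lut, V_vexillata = t_vex, V_minima = t_min,
       V_trilobata = t_tri, V_caracalla = t_car)
}

#' Write / read a template as YAML
#'
#' @param template A [species_template()].
#' @param path YAML file path.
#' @return `path` (writer, invisibly) or the template (reader).
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "species_template"))
  x <- unclass(template)
  x$markers <- lapply(seq_len(nrow(template$markers)), function(i)
    as.list(template$markers[i, ]))
  x$n_pairs <- NULL
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  x <- yaml::read_yaml(path)
  markers <- if (length(x$markers) > 0) {
    bind_rows(lapply(x$markers, as_tibble))
  } else NULL
  species_template(
    name = x$name, target_tcl_um = x$target_tcl_um,
    rl_profile = as.numeric(unlist(x$rl_profile)),
    ar_profile = as.numeric(unlist(x$ar_profile)),
    satellite = x$satellite, markers = markers,
    noise_cv = x$noise_cv, condensation_cv = x$condensation_cv,
    n_cells = x$n_cells, seed = x$seed)
}
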