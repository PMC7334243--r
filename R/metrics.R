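#' Levan morphology class from the arm ratio
#'
#' Classifies chromosomes by arm ratio (AR = long arm / short arm):
#' `M` at AR exactly 1 (median point), `m` for 1 < AR <= 1.70, `sm` for
#' 1.70 < AR <= 3.00, `st` for 3.00 < AR <= 7.00 and `t` above 7.00.
#' Intervals are half-open on the left so two-decimal ARs classify
#' deterministically.
#'
#' @param ar Numeric vector of arm ratios, all >= 1 (orient records first).
#' @param config A [karyo_config()] (class boundaries).
#' @return Character vector of classes among `M, m, sm, st, t`.
#' @export
#' @examples
#' classify_levan(c(1, 1.5, 2.5, 5, 8))
classify_levan <- function(ar, config = karyo_config()) {
  config <- as_karyo_config(config)
  if (any(!is.finite(ar) | ar < 1)) {
    abort("Arm ratios must be finite and >= 1 (orient measurements first).",
          class = "karyo_domain_error")
  }
  br <- config$levan_breaks
  cls <- ifelse(ar == 1, "M",
         ifelse(ar <= br[1], "m",
         ifelse(ar <= br[2], "sm",
         ifelse(ar <= br[3], "st", "t"))))
  cls
}

effective_arms <- function(records, config) {
  with_sat <- config$satellite_in_length
  sat_s <- ifelse(records$sat_arm == "short", records$sat_um, 0)
  sat_l <- ifelse(records$sat_arm == "long", records$sat_um, 0)
  tibble(
    cell_id = records$cell_id,
    pair_id = records$pair_id,
    short = records$short_um + if (with_sat) sat_s else 0,
    long = records$long_um + if (with_sat) sat_l else 0,
    sat_um = records$sat_um,
    sat_arm = records$sat_arm
  )
}

#' Per-pair morphometrics
#'
#' Averages homolog measurements over cells into one summary row per
#' chromosome pair: mean short-arm (`b`) and long-arm (`B`) lengths, total
#' length `L`, arm ratio `AR = B/b`, centromeric index
#' `CI = 100 b / (b + B)`, relative length `RL` (computed per cell as percent
#' of that cell's haploid complement length, then averaged across cells, so
#' condensation differences between cells cancel), Levan class, and satellite
#' annotation. Pairs are sorted by decreasing RL and renumbered 1..n
#' (ties broken by the lower input `pair_id`); the input id is kept in
#' `source_pair_id`.
#'
#' @param records Oriented measurement tibble ([read_measurements()] or
#'   [generate_dataset()]).
#' @param config A [karyo_config()].
#' @return A tibble with one row per pair: `pair_id`, `source_pair_id`, `b`,
#'   `B`, `L`, `ar`, `ci`, `rl`, `levan_class`, `has_satellite`, `sat_arm`,
#'   `sat_frac`.
#' @export
summarize_pairs <- function(records, config = karyo_config()) {
  config <- as_karyo_config(config)
  validate_measurements(records)
  records <- orient_measurements(records, config)
  arms <- effective_arms(records, config)

  per_pair <- arms |>
    group_by(pair_id = .data$pair_id) |>
    summarise(b = mean(.data$short), B = mean(.data$long),
              has_satellite = any(.data$sat_um > 0),
              sat_mean = mean(.data$sat_um),
              .groups = "drop")

  # RL per cell (percent of that cell's haploid complement), then averaged.
  cell_pair <- arms |>
    group_by(cell_id = .data$cell_id, pair_id = .data$pair_id) |>
    summarise(len = mean(.data$short + .data$long), .groups = "drop")
  n_pairs <- length(unique(cell_pair$pair_id))
  per_cell_n <- table(cell_pair$cell_id)
  if (any(per_cell_n != n_pairs)) {
    warn("Not every cell contains every pair; RL is averaged over the cells where a pair was measured.")
  }
  rl <- cell_pair |>
    group_by(cell_id = .data$cell_id) |>
    mutate(rl_cell = 100 * .data$len / sum(.data$len)) |>
    ungroup() |>
    group_by(pair_id = .data$pair_id) |>
    summarise(rl = mean(.data$rl_cell), .groups = "drop")

  sat_lookup <- vapply(split(records$sat_arm[records$sat_um > 0],
                             records$pair_id[records$sat_um > 0]),
                       function(x) names(sort(table(x), decreasing = TRUE))[1],
                       character(1))

  out <- left_join(per_pair, rl, by = "pair_id") |>
    mutate(L = .data$b + .data$B,
           ar = .data$B / .data$b,
           ci = 100 * .data$b / (.data$b + .data$B),
           levan_class = classify_levan(.data$ar, config),
           sat_arm0 = unname(sat_lookup[as.character(.data$pair_id)]),
           sat_arm = ifelse(.data$has_satellite, .data$sat_arm0, NA_character_),
           sat_frac = ifelse(.data$has_satellite,
                             .data$sat_mean /
                               ifelse(.data$sat_arm0 == "short", .data$b, .data$B),
                             NA_real_)) |>
    arrange(desc(.data$rl), .data$pair_id) |>
    mutate(source_pair_id = .data$pair_id, pair_id = row_number()) |>
    select("pair_id", "source_pair_id", "b", "B", "L", "ar", "ci", "rl",
           "levan_class", "has_satellite", "sat_arm", "sat_frac")
  out
}

#' Karyotype formula string
#'
#' Haploid formula: counts per Levan class in the order `m`, `sm`, `st`, `t`
#' (`M` chromosomes are counted with `m`), zero-count classes omitted,
#' components joined by `" + "`. Satellited pairs add a `"(kSAT)"` token after
#' the count of the class containing them, e.g. `"10m (1SAT) + 1sm"`.
#'
#' @param pairs Pair summary tibble from [summarize_pairs()].
#' @return A single string.
#' @export
karyotype_formula <- function(pairs) {
  cls <- ifelse(pairs$levan_class == "M", "m", pairs$levan_class)
  order_cls <- c("m", "sm", "st", "t")
  parts <- character(0)
  for (k in order_cls) {
    nk <- sum(cls == k)
    if (nk == 0) next
    term <- paste0(nk, k)
    n_sat <- sum(pairs$has_satellite & cls == k)
    if (n_sat > 0) term <- paste0(term, " (", n_sat, "SAT)")
    parts <- c(parts, term)
  }
  paste(parts, collapse = " + ")
}

#' Karyotype length statistics
#'
#' Total length of the haploid complement (TCL) from per-cell haploid totals:
#' in each cell the haploid total is the sum over pairs of the mean homolog
#' length; TCL is the mean of those totals over cells and its standard error
#' is the sample SD over cells divided by sqrt(number of cells). `C` is the
#' mean chromosome length, TCL / number of pairs.
#'
#' @inheritParams summarize_pairs
#' @return A list with `tcl_um`, `tcl_se_um`, `c_um`, `n_cells`, `n_pairs`.
#' @export
karyotype_length <- function(records, config = karyo_config()) {
  config <- as_karyo_config(config)
  records <- orient_measurements(records, config)
  arms <- effective_arms(records, config)
  totals <- arms |>
    group_by(cell_id = .data$cell_id, pair_id = .data$pair_id) |>
    summarise(len = mean(.data$short + .data$long), .groups = "drop") |>
    group_by(cell_id = .data$cell_id) |>
    summarise(total = sum(.data$len), .groups = "drop")
  n_cells <- nrow(totals)
  n_pairs <- length(unique(records$pair_id))
  tcl <- mean(totals$total)
  if (n_cells < 2) {
    warn("Only one cell: TCL standard error reported as 0.")
    se <- 0
  } else {
    se <- sd(totals$total) / sqrt(n_cells)
  }
  list(tcl_um = tcl, tcl_se_um = se, c_um = tcl / n_pairs,
       n_cells = n_cells, n_pairs = n_pairs)
}

#' Karyotype asymmetry suite
#'
#' Computes, over the per-pair values of a complement:
#' * mean centromeric index and its sample SD (`ci_mean`, `ci_sd`);
#' * Romero Zarco's intrachromosomal index `A1 = 1 - mean(b_i / B_i)`;
#' * Romero Zarco's interchromosomal index `A2 = sd(L_i) / mean(L_i)`
#'   (the coefficient of variation of chromosome length);
#' * Arano's `AsK% = 100 * sum(B_i) / sum(b_i + B_i)` (long-arm share of the
#'   complement length);
#' * the coefficients of variation `CVcl = 100 * A2` and
#'   `CVci = 100 * ci_sd / ci_mean`;
#' * Paszko's asymmetry index `AI = CVcl * CVci / 100`.
#'
#' Sample (n-1) standard deviations are used throughout.
#'
#' @param pairs Pair summary tibble from [summarize_pairs()].
#' @return A list with `ci_mean`, `ci_sd`, `a1`, `a2`, `ask_percent`,
#'   `cv_cl`, `cv_ci`, `ai`.
#' @export
asymmetry_suite <- function(pairs) {
  if (nrow(pairs) < 2) {
    abort("Dispersion statistics need at least 2 pairs.",
          class = "karyo_domain_error")
  }
  ci_mean <- mean(pairs$ci)
  ci_sd <- sd(pairs$ci)
  a2 <- sd(pairs$L) / mean(pairs$L)
  cv_cl <- 100 * a2
  cv_ci <- 100 * ci_sd / ci_mean
  list(
    ci_mean = ci_mean,
    ci_sd = ci_sd,
    a1 = 1 - mean(pairs$b / pairs$B),
    a2 = a2,
    ask_percent = 100 * sum(pairs$B) / sum(pairs$b + pairs$B),
    cv_cl = cv_cl,
    cv_ci = cv_ci,
    ai = paszko_ai(cv_cl, cv_ci)
  )
}

#' Paszko asymmetry index from its two coefficients of variation
#'
#' `AI = CVcl * CVci / 100`, where `CVcl` is the coefficient of variation of
#' chromosome length (100 times the interchromosomal index A2) and `CVci` the
#' coefficient of variation of the centromeric index, both in percent. Useful
#' on its own to recompute AI from published summary rows (A2 plus the mean
#' and SD of the centromeric index) without the raw measurements.
#'
#' @param cv_cl,cv_ci Coefficients of variation in percent.
#' @return The asymmetry index (dimensionless).
#' @export
#' @examples
#' # from a published summary row: A2 = 0.19, CI = 43.24 +/- 3.45
#' paszko_ai(100 * 0.19, 100 * 3.45 / 43.24)
paszko_ai <- function(cv_cl, cv_ci) {
  stopifnot(is.numeric(cv_cl), is.numeric(cv_ci))
  cv_cl * cv_ci / 100
}

#' Stebbins symmetry category
#'
#' Two-way classification of karyotype asymmetry. The digit encodes the
#' proportion `p` of chromosomes whose arm ratio exceeds the threshold
#' (default 2.0; exactly 2.0 counts as not exceeding): `1` if `p = 0`, `2` if
#' `0 < p <= 0.5`, `3` if `0.5 < p < 1`, `4` if `p = 1`. The letter encodes
#' the ratio of the largest to the smallest chromosome (relative lengths;
#' absolute lengths give the same ratio): `A` below 2, `B` from 2 to 4
#' inclusive, `C` above 4.
#'
#' @param pairs Pair summary tibble from [summarize_pairs()].
#' @param config A [karyo_config()] (arm-ratio threshold).
#' @return A string such as `"1A"`.
#' @export
stebbins_category <- function(pairs, config = karyo_config()) {
  config <- as_karyo_config(config)
  p <- mean(pairs$ar > config$stebbins_ar)
  digit <- if (p == 0) "1" else if (p <= 0.5) "2" else if (p < 1) "3" else "4"
  r <- max(pairs$rl) / min(pairs$rl)
  letter <- if (r < 2) "A" else if (r <= 4) "B" else "C"
  paste0(digit, letter)
}

#' Complement-level karyotype summary
#'
#' Runs the full morphometric pipeline on a measurement table and returns the
#' complement-level statistics: karyotype formula, TCL and its SE, mean
#' chromosome length, relative-length range, the asymmetry suite and the
#' Stebbins category.
#'
#' @inheritParams summarize_pairs
#' @param species Species (or sample) label carried into reports.
#' @return A list of class `karyo_summary` with fields `species`, `two_n`,
#'   `n_pairs`, `kf`, `tcl_um`, `tcl_se_um`, `c_um`, `rrl_min`, `rrl_max`,
#'   `ci_mean`, `ci_sd`, `a1`, `a2`, `ask_percent`, `cv_cl`, `cv_ci`, `ai`,
#'   `stebbins`.
#' @export
karyotype_summary <- function(records, species = "unknown",
                              config = karyo_config()) {
  config <- as_karyo_config(config)
  pairs <- summarize_pairs(records, config)
  len <- karyotype_length(records, config)
  asym <- asymmetry_suite(pairs)
  out <- c(
    list(species = species,
         two_n = 2L * nrow(pairs),
         n_pairs = nrow(pairs),
         kf = karyotype_formula(pairs)),
    len[c("tcl_um", "tcl_se_um", "c_um")],
    list(rrl_min = min(pairs$rl), rrl_max = max(pairs$rl)),
    asym,
    list(stebbins = stebbins_category(pairs, config))
  )
  structure(out, class = "karyo_summary")
}

#' @export
print.karyo_summary <- function(x, digits = 2, ...) {
  f <- function(v) formatC(v, format = "f", digits = digits)
  cat("<karyo_summary> ", x$species, " (2n = ", x$two_n, ")\n", sep = "")
  cat("  KF:       ", x$kf, "\n")
  cat("  TCL:      ", f(x$tcl_um), "+/-", f(x$tcl_se_um), "um;  C:",
      f(x$c_um), "um\n")
  cat("  RRL:      ", f(x$rrl_min), "-", f(x$rrl_max), "\n")
  cat("  CI:       ", f(x$ci_mean), "+/-", f(x$ci_sd), "\n")
  cat("  A1:", f(x$a1), " A2:", f(x$a2), " AsK%:", f(x$ask_percent),
      " AI:", f(x$ai), "\n")
  cat("  Stebbins: ", x$stebbins, "\n")
  invisible(x)
}
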