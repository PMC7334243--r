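# Independent brute-force oracles: each asymmetry statistic recomputed in one
# line straight from the raw per-pair arm lengths.
oracle_ci <- function(b, B) 100 * b / (b + B)
oracle_a1 <- function(b, B) 1 - sum(b / B) / length(b)
oracle_a2 <- function(b, B) { L <- b + B; sd(L) / mean(L) }
oracle_ask <- function(b, B) 100 * sum(B) / (sum(b) + sum(B))
oracle_ai <- function(b, B) {
  L <- b + B; ci <- oracle_ci(b, B)
  (100 * sd(L) / mean(L)) * (100 * sd(ci) / mean(ci)) / 100
}

# Hand-coded Stebbins reference table: digit from the proportion of
# chromosomes with AR above 2, letter from the largest/smallest length ratio.
oracle_stebbins <- function(ar, rl) {
  p <- mean(ar > 2)
  digit <- if (p == 0) "1" else if (p <= 0.5) "2" else if (p < 1) "3" else "4"
  r <- max(rl) / min(rl)
  letter <- if (r < 2) "A" else if (r <= 4) "B" else "C"
  paste0(digit, letter)
}

# A pair-summary tibble straight from arm lengths (container only; the
# statistics under test are computed by the package, not here).
pairs_from_arms <- function(b, B) {
  L <- b + B
  ord <- order(-L, seq_along(L))
  b <- b[ord]; B <- B[ord]; L <- L[ord]
  tibble::tibble(
    pair_id = seq_along(b), source_pair_id = ord,
    b = b, B = B, L = L, ar = B / b, ci = 100 * b / L,
    rl = 100 * L / sum(L),
    levan_class = karyostat::classify_levan(B / b),
    has_satellite = FALSE, sat_arm = NA_character_, sat_frac = NA_real_)
}

# Exact (noise-free) measurement records for given per-pair arms.
records_from_arms <- function(b, B, n_cells = 2) {
  grid <- expand.grid(cell = seq_len(n_cells), pair = seq_along(b),
                      homolog = 1:2)
  tibble::tibble(
    cell_id = paste0("c", grid$cell),
    pair_id = as.integer(grid$pair),
    homolog_id = as.integer(grid$homolog),
    short_um = b[grid$pair], long_um = B[grid$pair],
    sat_um = 0, sat_arm = "none")
}

random_arms <- function(n_pairs) {
  b <- runif(n_pairs, 0.5, 3)
  B <- b * runif(n_pairs, 1, 4)
  list(b = b, B = B)
}

# All 5S/45S rows of the published marker table that print a position class
# and a di value, in template pair numbering (frozen from the source table).
published_rdna_rows <- function() {
  tibble::tribble(
    ~species,       ~pair_id, ~arm,    ~marker_type, ~class, ~di,
    "V_luteola",    11L,      "short", "5S",         "PCEN", 16.55,
    "V_vexillata",   8L,      "long",  "5S",         "INT",  52.29,
    "V_vexillata",   2L,      "short", "45S",        "TER",  20.53,
    "V_vexillata",   3L,      "short", "45S",        "TER",  16.73,
    "V_minima",      2L,      "short", "5S",         "INT",  30.86,
    "V_minima",      2L,      "long",  "45S",        "TER",  58.64,
    "V_minima",      4L,      "long",  "45S",        "TER",  59.42,
    "V_minima",      6L,      "short", "45S",        "TER",  38.91,
    "V_minima",      7L,      "short", "45S",        "TER",  50.74,
    "V_minima",      9L,      "short", "45S",        "TER",  67.94,
    "V_trilobata",   4L,      "long",  "5S",         "PCEN", 14.95,
    "V_trilobata",   6L,      "short", "45S",        "PCEN", 25.05,
    "V_caracalla",   2L,      "long",  "5S",         "INT",  34.32,
    "V_caracalla",   5L,      "short", "5S",         "INT",  56.70)
}
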