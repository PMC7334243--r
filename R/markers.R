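#' Percent distance from the centromere (di)
#'
#' For each marker site, `di = 100 * d / a` where `a` is the length of the
#' site's arm and `d` is measured from the centromere to the *starting point*
#' of a terminal site (one whose `end_frac` reaches the telomere within the
#' TER tolerance) or to the *center* of a non-terminal site. Because extents
#' are stored as fractions of the arm, `di` is invariant under uniform
#' scaling of arm length. Centromere-spanning sites have no `di` (`NA`).
#'
#' @param sites Marker tibble ([read_markers()]); `pair_id` must match
#'   `pairs$pair_id`.
#' @param pairs Pair summary tibble ([summarize_pairs()]).
#' @param config A [karyo_config()] (TER tolerance).
#' @return `sites` with added columns `a_um` (arm length), `d_um`, `di`.
#' @export
compute_di <- function(sites, pairs, config = karyo_config()) {
  config <- as_karyo_config(config)
  validate_markers(sites)
  link_sites(sites, pairs)
  idx <- match(sites$pair_id, pairs$pair_id)
  a_um <- ifelse(sites$arm == "short", pairs$b[idx],
          ifelse(sites$arm == "long", pairs$B[idx], NA_real_))
  terminal <- sites$arm != "centromere-spanning" &
    sites$end_frac >= config$ter_min_end
  d_frac <- ifelse(sites$arm == "centromere-spanning", NA_real_,
            ifelse(terminal, sites$start_frac,
                   (sites$start_frac + sites$end_frac) / 2))
  sites$a_um <- a_um
  sites$d_um <- d_frac * a_um
  sites$di <- 100 * d_frac
  sites
}

#' Marker position class (CEN / PCEN / INT / TER)
#'
#' Centromere-spanning sites are `CEN`; sites reaching the telomere
#' (`end_frac >= ter_min_end`) are `TER`; of the rest, those with
#' `di <= pcen_max_di` are pericentromeric (`PCEN`) and the others
#' interstitial (`INT`).
#'
#' @param sites Marker tibble with `di` computed ([compute_di()]).
#' @param config A [karyo_config()].
#' @return `sites` with an added `position_class` column.
#' @export
classify_position <- function(sites, config = karyo_config()) {
  config <- as_karyo_config(config)
  if (!"di" %in% names(sites)) {
    abort("Run compute_di() before classify_position().",
          class = "karyo_domain_error")
  }
  # epsilon so a di sitting exactly on the cutoff is not pushed to INT by
  # floating-point midpoint arithmetic
  sites$position_class <- ifelse(sites$arm == "centromere-spanning", "CEN",
    ifelse(sites$end_frac >= config$ter_min_end, "TER",
    ifelse(sites$di <= config$pcen_max_di + 1e-9, "PCEN", "INT")))
  sites
}

link_sites <- function(sites, pairs) {
  unknown <- setdiff(unique(sites$pair_id), pairs$pair_id)
  if (length(unknown) > 0) {
    abort(paste0("Marker site(s) reference unknown pair_id: ",
                 paste(unknown, collapse = ", ")),
          class = "karyo_linkage_error")
  }
  invisible(sites)
}

site_size_um <- function(sites, pairs) {
  idx <- match(sites$pair_id, pairs$pair_id)
  a_um <- ifelse(sites$arm == "short", pairs$b[idx],
          ifelse(sites$arm == "long", pairs$B[idx],
                 pairs$b[idx] + pairs$B[idx]))
  (sites$end_frac - sites$start_frac) * a_um
}

#' Band amounts as percent of karyotype length
#'
#' Physical band sizes are computed on one homolog per pair (haploid
#' accounting) as `(end_frac - start_frac) * arm length` and expressed as
#' percent of the karyotype length (TCL). For CPD the headline total excludes
#' rDNA-CPD bands: CPD bands of which at least `rdna_overlap_min` (default
#' half) is covered by a 5S or 45S site on the same pair and arm; the
#' including-rDNA total is reported alongside.
#'
#' @param sites Marker tibble.
#' @param pairs Pair summary tibble ([summarize_pairs()]).
#' @param tcl_um Total length of the haploid complement in micrometres.
#' @param config A [karyo_config()].
#' @return A list with `totals` (tibble: `marker_type`, `amount_percent`,
#'   CPD excluding rDNA bands), `cpd_including_rdna_percent`, and `per_site`
#'   (sites with `size_um`, `size_percent_tcl`, `is_rdna_band`).
#' @export
band_amounts <- function(sites, pairs, tcl_um, config = karyo_config()) {
  config <- as_karyo_config(config)
  validate_markers(sites)
  empty <- tibble(marker_type = c("CPD", "DAPI"), amount_percent = c(0, 0))
  if (nrow(sites) == 0) {
    return(list(totals = empty, cpd_including_rdna_percent = 0,
                per_site = sites))
  }
  link_sites(sites, pairs)
  sites$size_um <- site_size_um(sites, pairs)
  sites$size_percent_tcl <- 100 * sites$size_um / tcl_um

  rdna <- sites[sites$marker_type %in% c("5S", "45S"), , drop = FALSE]
  is_rdna_band <- rep(FALSE, nrow(sites))
  band_idx <- which(sites$marker_type %in% c("CPD", "DAPI"))
  for (i in band_idx) {
    same <- rdna$pair_id == sites$pair_id[i] & rdna$arm == sites$arm[i]
    if (!any(same)) next
    ov <- pmax(0, pmin(rdna$end_frac[same], sites$end_frac[i]) -
                  pmax(rdna$start_frac[same], sites$start_frac[i]))
    covered <- sum(ov) / (sites$end_frac[i] - sites$start_frac[i])
    is_rdna_band[i] <- covered >= config$rdna_overlap_min
  }
  sites$is_rdna_band <- is_rdna_band

  tot <- function(type, excl_rdna) {
    keep <- sites$marker_type == type & (!excl_rdna | !sites$is_rdna_band)
    sum(sites$size_percent_tcl[keep])
  }
  totals <- tibble(marker_type = c("CPD", "DAPI"),
                   amount_percent = c(tot("CPD", TRUE), tot("DAPI", TRUE)))
  list(totals = totals,
       cpd_including_rdna_percent = tot("CPD", FALSE),
       per_site = sites)
}

#' Count chromosome pairs bearing each rDNA type
#'
#' @param sites Marker tibble.
#' @return A list with `n_5S`, `n_45S` (number of distinct pairs carrying
#'   each type) and `syntenic_pairs` (pairs carrying both).
#' @export
locus_counts <- function(sites) {
  pairs_of <- function(type) {
    sort(unique(sites$pair_id[sites$marker_type == type]))
  }
  p5 <- pairs_of("5S")
  p45 <- pairs_of("45S")
  list(n_5S = length(p5), n_45S = length(p45),
       pairs_5S = p5, pairs_45S = p45,
       syntenic_pairs = intersect(p5, p45))
}

#' Overlaps between rDNA sites and heterochromatin bands
#'
#' For each 5S/45S site, lists the CPD/DAPI bands on the same pair and arm
#' whose fractional intervals intersect it, with the intersection expressed
#' as a fraction of the rDNA site's interval.
#'
#' @param sites Marker tibble.
#' @return A tibble with one row per (rDNA site, overlapping band):
#'   `pair_id`, `arm`, `rdna_type`, `band_type`, `overlap_frac`.
#' @export
colocalization_report <- function(sites) {
  validate_markers(sites)
  out <- tibble(pair_id = integer(), arm = character(),
                rdna_type = character(), band_type = character(),
                overlap_frac = numeric())
  if (nrow(sites) == 0) return(out)
  rdna <- sites[sites$marker_type %in% c("5S", "45S"), , drop = FALSE]
  bands <- sites[sites$marker_type %in% c("CPD", "DAPI"), , drop = FALSE]
  if (nrow(rdna) == 0 || nrow(bands) == 0) return(out)
  rows <- list()
  for (i in seq_len(nrow(rdna))) {
    same <- which(bands$pair_id == rdna$pair_id[i] & bands$arm == rdna$arm[i])
    for (j in same) {
      ov <- min(rdna$end_frac[i], bands$end_frac[j]) -
        max(rdna$start_frac[i], bands$start_frac[j])
      if (ov <= 0) next
      rows[[length(rows) + 1]] <- tibble(
        pair_id = rdna$pair_id[i], arm = rdna$arm[i],
        rdna_type = rdna$marker_type[i], band_type = bands$marker_type[j],
        overlap_frac = ov / (rdna$end_frac[i] - rdna$start_frac[i]))
    }
  }
  if (length(rows) == 0) out else bind_rows(rows)
}

#' Fully annotate a marker table
#'
#' Convenience wrapper: [compute_di()], [classify_position()] and per-site
#' sizes from [band_amounts()] in one call.
#'
#' @inheritParams band_amounts
#' @return The annotated marker tibble with `a_um`, `d_um`, `di`,
#'   `position_class`, `size_um`, `size_percent_tcl`, `is_rdna_band`.
#' @export
annotate_markers <- function(sites, pairs, tcl_um, config = karyo_config()) {
  config <- as_karyo_config(config)
  if (nrow(sites) == 0) return(sites)
  sites <- compute_di(sites, pairs, config)
  sites <- classify_position(sites, config)
  amounts <- band_amounts(sites, pairs, tcl_um, config)
  amounts$per_site
}
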