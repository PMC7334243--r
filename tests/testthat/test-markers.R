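mk_pairs <- function(n = 2, b = rep(2, n), B = rep(2, n)) pairs_from_arms(b, B)

site <- function(pair, arm, type, s, e) {
  tibble::tibble(pair_id = as.integer(pair), arm = arm, marker_type = type,
                 start_frac = s, end_frac = e)
}

test_that("di: centromeric limit, terminal start rule, interstitial midpoint", {
  pairs <- mk_pairs()
  # site starting at the centromere, non-terminal: center rule
  s <- compute_di(site(1, "short", "CPD", 0, 0.1), pairs)
  expect_equal(s$di, 5)
  # terminal site: distance to the starting point
  s <- compute_di(site(1, "short", "45S", 0.6794, 1), pairs)
  expect_equal(s$di, 67.94)
  # interstitial: midpoint
  s <- compute_di(site(1, "long", "5S", 0.25, 0.35), pairs)
  expect_equal(s$di, 30)
  # invariant under uniform scaling of arm length
  pairs2 <- mk_pairs(b = rep(7, 2), B = rep(9, 2))
  s2 <- compute_di(site(1, "long", "5S", 0.25, 0.35), pairs2)
  expect_equal(s2$di, 30)
  # unknown pair -> linkage error
  expect_error(compute_di(site(9, "short", "5S", 0.1, 0.2), pairs),
               class = "karyo_linkage_error")
})

test_that("position classes follow TER/PCEN/INT/CEN rules", {
  pairs <- mk_pairs()
  cls <- function(s) classify_position(compute_di(s, pairs))$position_class
  expect_equal(cls(site(1, "short", "CPD", 0, 0.05)), "PCEN")   # di 2.5
  expect_equal(cls(site(1, "short", "45S", 0.95, 1)), "TER")
  expect_equal(cls(site(1, "long", "5S", 0.4729, 0.5729)), "INT")  # di 52.29
  expect_equal(cls(site(1, "short", "45S", 0.2053, 1)), "TER")  # TER beats PCEN
  s <- classify_position(compute_di(
    site(1, "centromere-spanning", "CPD", 0, 0.1), pairs))
  expect_equal(s$position_class, "CEN")
  expect_true(is.na(s$di))
  # threshold: di exactly at the PCEN cutoff stays PCEN, just above is INT
  expect_equal(cls(site(1, "short", "5S", 0.23, 0.33)), "PCEN")  # di 28
  expect_equal(cls(site(1, "short", "5S", 0.24, 0.34)), "INT")   # di 29
})

test_that("band amounts: identities, haploid accounting, rDNA exclusion", {
  pairs <- mk_pairs(n = 5, b = rep(2, 5), B = rep(2, 5))  # TCL 20 um
  tcl <- sum(pairs$L)

  # no bands
  ba <- band_amounts(site(1, "short", "CPD", 0, 1)[0, ], pairs, tcl)
  expect_equal(ba$totals$amount_percent, c(0, 0))

  # a band covering an entire arm that is 10% of TCL
  ba <- band_amounts(site(1, "short", "CPD", 0, 1), pairs, tcl)
  expect_equal(ba$totals$amount_percent[ba$totals$marker_type == "CPD"], 10)

  # two bands 0-0.1 on 2 um arms, TCL 20 -> 2%
  ba <- band_amounts(dplyr::bind_rows(site(1, "short", "CPD", 0, 0.1),
                                      site(2, "short", "CPD", 0, 0.1)),
                     pairs, tcl)
  expect_equal(ba$totals$amount_percent[1], 2, tolerance = 1e-12)
  # per-site sizes sum to the per-type total exactly
  expect_equal(sum(ba$per_site$size_percent_tcl), 2, tolerance = 1e-12)

  # CPD coextensive with a 45S site is excluded from the headline total
  ba <- band_amounts(dplyr::bind_rows(site(1, "short", "CPD", 0, 1),
                                      site(1, "short", "45S", 0, 1),
                                      site(2, "long", "CPD", 0, 0.2)),
                     pairs, tcl)
  expect_equal(ba$totals$amount_percent[1], 2, tolerance = 1e-12)
  expect_equal(ba$cpd_including_rdna_percent, 12, tolerance = 1e-12)
})

test_that("locus counts and syntenic pairs", {
  expect_equal(locus_counts(site(1, "short", "5S", 0, 0.1)[0, ])$n_45S, 0)
  tpl <- builtin_templates()
  lc <- locus_counts(tpl$V_minima$markers)
  expect_equal(lc$n_45S, 5)
  expect_equal(lc$syntenic_pairs, 2L)  # pair 2 carries both 5S and 45S
  expect_equal(locus_counts(tpl$V_caracalla$markers)$n_5S, 2)
  expect_equal(locus_counts(tpl$V_luteola$markers)$n_45S, 1)
})

test_that("colocalization reports interval overlaps on the same arm", {
  full <- dplyr::bind_rows(site(1, "short", "45S", 0, 1),
                           site(1, "short", "CPD", 0, 1))
  co <- colocalization_report(full)
  expect_equal(co$overlap_frac, 1)

  partial <- dplyr::bind_rows(site(1, "short", "5S", 0.10, 0.20),
                              site(1, "short", "CPD", 0, 0.15))
  co <- colocalization_report(partial)
  expect_equal(co$overlap_frac, 0.5, tolerance = 1e-12)

  different_arms <- dplyr::bind_rows(site(1, "short", "5S", 0.1, 0.2),
                                     site(1, "long", "CPD", 0, 1))
  expect_equal(nrow(colocalization_report(different_arms)), 0)
})

test_that("published marker fixture: every printed (class, di) pair reproduced", {
  tpl <- builtin_templates()
  expected <- published_rdna_rows()
  for (sp in unique(expected$species)) {
    pairs <- template_pairs(tpl[[sp]])
    ann <- classify_position(compute_di(tpl[[sp]]$markers, pairs))
    exp_sp <- expected[expected$species == sp, ]
    for (i in seq_len(nrow(exp_sp))) {
      row <- ann[ann$pair_id == exp_sp$pair_id[i] & ann$arm == exp_sp$arm[i] &
                   ann$marker_type == exp_sp$marker_type[i], ]
      expect_equal(nrow(row), 1, info = paste(sp, i))
      expect_equal(row$position_class, exp_sp$class[i], info = paste(sp, i))
      expect_equal(round(row$di, 2), exp_sp$di[i], info = paste(sp, i))
    }
  }
})
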