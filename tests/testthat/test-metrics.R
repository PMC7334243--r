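test_that("pair summaries: means, ratios, scale invariance, renumbering", {
  # metacentric identity
  rec <- records_from_arms(b = 1, B = 1)
  p <- summarize_pairs(rec)
  expect_equal(p$ar, 1)
  expect_equal(p$ci, 50)
  expect_equal(p$levan_class, "M")

  # direct arithmetic: b = 1, B = 3
  p <- summarize_pairs(records_from_arms(b = 1, B = 3))
  expect_equal(p$ar, 3)
  expect_equal(p$ci, 25)
  expect_equal(p$levan_class, "sm")  # 3.00 falls in sm (left-open intervals)

  # cell-level condensation doubling leaves RL, AR, CI untouched
  rec <- records_from_arms(b = c(1, 2), B = c(2, 3), n_cells = 1)
  rec2 <- rec
  rec2$cell_id <- "c2"
  rec2$short_um <- 2 * rec2$short_um
  rec2$long_um <- 2 * rec2$long_um
  p1 <- summarize_pairs(rec)
  p2 <- summarize_pairs(dplyr::bind_rows(rec, rec2))
  expect_equal(p2$rl, p1$rl, tolerance = 1e-12)
  expect_equal(p2$ar, p1$ar, tolerance = 1e-12)
  expect_equal(p2$ci, p1$ci, tolerance = 1e-12)

  # renumbering: decreasing RL, source id retained, ties by lower input id
  p <- summarize_pairs(records_from_arms(b = c(1, 2, 1.5), B = c(1, 2, 2)))
  expect_equal(p$source_pair_id, c(2L, 3L, 1L))
  expect_true(all(diff(p$rl) <= 1e-12))
  expect_equal(sum(p$rl), 100, tolerance = 1e-9)
})

test_that("Levan classification covers all classes and boundaries", {
  expect_equal(classify_levan(c(1, 1.5, 2.5, 5, 8)),
               c("M", "m", "sm", "st", "t"))
  # boundaries belong to the lower class
  expect_equal(classify_levan(c(1.70, 3.00, 7.00)), c("m", "sm", "st"))
  expect_equal(classify_levan(1 + 1e-12), "m")
  expect_error(classify_levan(0.9), class = "karyo_domain_error")
})

test_that("karyotype formula matches the published rendering conventions", {
  mk <- function(classes, sat = rep(FALSE, length(classes))) {
    tibble::tibble(levan_class = classes, has_satellite = sat)
  }
  expect_equal(karyotype_formula(mk(rep("m", 11))), "11m")
  expect_equal(karyotype_formula(mk(c(rep("m", 9), "sm", "sm"))), "9m + 2sm")
  expect_equal(
    karyotype_formula(mk(c(rep("m", 10), "sm"),
                         sat = c(TRUE, rep(FALSE, 10)))),
    "10m (1SAT) + 1sm")
  # M merged into m; class order m, sm, st, t; zero classes dropped
  expect_equal(karyotype_formula(mk(c("M", "m", "t", "st"))), "2m + 1st + 1t")
})

test_that("karyotype length: TCL over cells, SE, C", {
  b <- c(1, 1.5); B <- c(2, 2.5)
  rec <- records_from_arms(b, B, n_cells = 1)
  rec2 <- rec; rec2$cell_id <- "c2"
  rec2$short_um <- rec2$short_um * 1.2; rec2$long_um <- rec2$long_um * 1.2
  len <- karyotype_length(dplyr::bind_rows(rec, rec2))
  totals <- c(sum(b + B), 1.2 * sum(b + B))
  expect_equal(len$tcl_um, mean(totals), tolerance = 1e-12)
  expect_equal(len$tcl_se_um, sd(totals) / sqrt(2), tolerance = 1e-12)
  expect_equal(len$c_um, mean(totals) / 2, tolerance = 1e-12)

  # single cell: SE degenerates to 0 with a warning
  expect_warning(len1 <- karyotype_length(rec), "one cell")
  expect_equal(len1$tcl_se_um, 0)
})

test_that("asymmetry suite: symmetry limit and direct sums", {
  # uniform metacentric karyotype
  p <- pairs_from_arms(b = rep(2, 4), B = rep(2, 4))
  a <- asymmetry_suite(p)
  expect_equal(a$a1, 0)
  expect_equal(a$a2, 0)
  expect_equal(a$ask_percent, 50)
  expect_equal(a$ai, 0)

  # two pairs with b/B of 0.5 and 1.0
  p <- pairs_from_arms(b = c(1, 2), B = c(2, 2))
  expect_equal(asymmetry_suite(p)$a1, 0.25, tolerance = 1e-12)

  expect_error(asymmetry_suite(pairs_from_arms(1, 2)),
               class = "karyo_domain_error")
})

test_that("AI recomputes published values from summary components", {
  ref <- reference_karyotypes()
  ai <- paszko_ai(100 * ref$a2, 100 * ref$ci_sd / ref$ci_mean)
  vex <- which(ref$species == "V. vexillata")
  car <- which(ref$species == "V. caracalla")
  expect_equal(round(ai[vex], 2), 1.52)
  expect_equal(round(ai[car], 2), 1.41)
  # remaining species reproduce within the rounding slack of two-decimal A2
  expect_true(all(abs(round(ai, 2) - ref$ai) <= 0.03))
})

test_that("Stebbins category: published inputs and the 12-cell truth table", {
  mk <- function(ar, rl) tibble::tibble(ar = ar, rl = rl)
  # all-identical metacentric complement
  expect_equal(stebbins_category(mk(rep(1, 4), rep(25, 4))), "1A")

  # full truth table against the hand-coded reference
  ar_sets <- list(rep(1.5, 4), c(2.5, 1.5, 1.5, 1.5), c(2.5, 2.5, 2.5, 1.5),
                  rep(2.5, 4))
  rl_sets <- list(c(30, 28, 22, 20), c(42, 26, 18, 14), c(50, 25, 15, 10))
  for (ar in ar_sets) {
    for (rl in rl_sets) {
      expect_equal(stebbins_category(mk(ar, rl)), oracle_stebbins(ar, rl))
    }
  }
  # threshold AR exactly 2 counts as not exceeding
  expect_equal(stebbins_category(mk(rep(2, 4), c(30, 28, 22, 20))), "1A")
})
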