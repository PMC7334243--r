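test_that("rl_profile_between hits endpoints exactly and sums to 100", {
  for (ends in list(c(12.40, 6.88), c(12.80, 5.61), c(13.48, 7.20))) {
    p <- rl_profile_between(ends[1], ends[2], 11)
    expect_equal(p[1], ends[1], tolerance = 1e-9)
    expect_equal(p[11], ends[2], tolerance = 1e-9)
    expect_equal(sum(p), 100, tolerance = 1e-9)
    expect_true(all(diff(p) <= 0))
  }
  expect_error(rl_profile_between(10, 9.9, 3), class = "karyo_template_error")
})

test_that("template validation catches malformed profiles", {
  expect_error(species_template("x", 30, c(60, 50), c(1.2, 1.2)),
               class = "karyo_template_error")   # sums to 110
  expect_error(species_template("x", 30, c(40, 60), c(1.2, 1.2)),
               class = "karyo_template_error")   # increasing
  expect_error(species_template("x", 30, c(60, 40), c(0.9, 1.2)),
               class = "karyo_template_error")   # AR < 1
})

test_that("generation is reproducible from the seed", {
  tpl <- builtin_templates()$V_vexillata
  d1 <- generate_dataset(tpl, seed = 42)
  d2 <- generate_dataset(tpl, seed = 42)
  expect_identical(d1, d2)
  d3 <- generate_dataset(tpl, seed = 43)
  expect_false(identical(d1$measurements, d3$measurements))
})

test_that("noiseless generation recovers the template's implied values", {
  for (tpl in builtin_templates()) {
    tpl$noise_cv <- 0
    ds <- generate_dataset(tpl)
    pairs <- summarize_pairs(ds$measurements)
    implied <- template_pairs(tpl)
    expect_equal(pairs$rl, implied$rl, tolerance = 1e-9)
    expect_equal(pairs$ar, implied$ar, tolerance = 1e-9)
    expect_equal(pairs$ci, implied$ci, tolerance = 1e-9)
    expect_equal(pairs$levan_class, implied$levan_class)
    expect_equal(pairs$has_satellite, implied$has_satellite)
    expect_equal(karyotype_formula(pairs), karyotype_formula(implied))
  }
})

test_that("doubling target TCL doubles TCL and leaves indices unchanged", {
  tpl <- builtin_templates()$V_minima
  tpl$noise_cv <- 0
  tpl2 <- tpl
  tpl2$target_tcl_um <- 2 * tpl$target_tcl_um
  s1 <- karyotype_summary(generate_dataset(tpl, seed = 7)$measurements)
  s2 <- karyotype_summary(generate_dataset(tpl2, seed = 7)$measurements)
  expect_equal(s2$tcl_um, 2 * s1$tcl_um, tolerance = 1e-9)
  for (f in c("a1", "a2", "ask_percent", "ai", "ci_mean", "rrl_min",
              "rrl_max")) {
    expect_equal(s2[[f]], s1[[f]], tolerance = 1e-9)
  }
})

test_that("noise CV of generated per-pair lengths converges to noise_cv", {
  tpl <- builtin_templates()$V_luteola
  tpl$condensation_cv <- 0
  tpl$noise_cv <- 5
  set.seed(11)
  cvs <- replicate(60, {
    m <- generate_dataset(tpl, seed = sample.int(1e6, 1))$measurements
    len <- m$short_um + m$long_um + m$sat_um
    rel <- len / ave(len, m$pair_id)           # within-pair relative lengths
    sd(rel)
  })
  # total length = short + long, each with 5% CV: expected CV ~ 5/sqrt(2) %
  # weighted by arm shares; accept a generous Monte-Carlo band around it
  expect_gt(mean(cvs), 0.025)
  expect_lt(mean(cvs), 0.05)
})

test_that("templates survive a YAML round-trip", {
  tpl <- builtin_templates()$V_caracalla
  path <- withr::local_tempfile(fileext = ".yaml")
  write_template(tpl, path)
  back <- read_template(path)
  expect_equal(back$rl_profile, tpl$rl_profile, tolerance = 1e-9)
  expect_equal(back$ar_profile, tpl$ar_profile, tolerance = 1e-9)
  expect_equal(as.data.frame(back$markers), as.data.frame(tpl$markers))
  expect_equal(back$satellite, tpl$satellite)
  expect_identical(generate_dataset(back, seed = 5),
                   generate_dataset(tpl, seed = 5))
})
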