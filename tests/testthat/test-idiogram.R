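test_that("idiogram geometry: heights track RL, centromere at CI", {
  pairs <- pairs_from_arms(b = c(2, 1.5), B = c(2, 2.5))
  idg <- build_idiogram(pairs, species = "test")
  g <- idg$pairs
  expect_equal(g$height / g$height[1], pairs$rl / pairs$rl[1],
               tolerance = 1e-6)
  expect_equal(g$short_h + g$long_h, g$height, tolerance = 1e-12)
  expect_equal(g$short_h / g$height * 100, pairs$ci, tolerance = 1e-6)

  # uniform two-pair karyotype: equal heights, centromere at mid-height
  pairs <- pairs_from_arms(b = c(2, 2), B = c(2, 2))
  g <- build_idiogram(pairs)$pairs
  expect_equal(g$height[1], g$height[2])
  expect_equal(g$short_h, g$long_h)

  # marker rectangles carry their fractional extents exactly
  sites <- tibble::tibble(pair_id = 1L, arm = "short", marker_type = "45S",
                          start_frac = 0.2053, end_frac = 1)
  idg <- build_idiogram(pairs, sites)
  expect_equal(idg$markers$start_frac, 0.2053, tolerance = 1e-6)
  expect_equal(idg$markers$end_frac, 1, tolerance = 1e-6)

  # linkage and ordering contracts
  bad <- sites; bad$pair_id <- 9L
  expect_error(build_idiogram(pairs, bad), class = "karyo_linkage_error")
  increasing <- pairs_from_arms(b = c(1, 2), B = c(1, 2))
  increasing$pair_id <- rev(increasing$pair_id)   # heights increase left->right
  expect_error(build_idiogram(increasing), class = "karyo_domain_error")
})

test_that("satellited glyph keeps its height and carries the 45S block", {
  tpl <- builtin_templates()$V_caracalla
  idg <- build_idiogram(template_pairs(tpl), tpl$markers, species = tpl$name)
  g1 <- idg$pairs[1, ]
  expect_true(g1$has_satellite)
  expect_equal(g1$sat_arm, "short")
  m1 <- idg$markers[idg$markers$pair_id == 1 &
                      idg$markers$marker_type == "45S", ]
  expect_equal(nrow(m1), 1)
  expect_equal(c(m1$start_frac, m1$end_frac), c(0, 0.8))
})

test_that("SVG rendering is well formed, deterministic, and complete", {
  tpl <- builtin_templates()$V_luteola
  idg <- build_idiogram(template_pairs(tpl), tpl$markers, species = tpl$name)
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_svg(idg, f1)
  render_svg(idg, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  doc <- xml2::read_xml(f1)  # parses => well-formed XML
  svg_txt <- readLines(f1)
  expect_equal(sum(grepl('<g id="pair-', svg_txt)), 11)

  # empty karyotype still renders a valid document with the axis
  empty <- build_idiogram(pairs_from_arms(numeric(0), numeric(0)))
  f3 <- withr::local_tempfile(fileext = ".svg")
  render_svg(empty, f3)
  expect_silent(xml2::read_xml(f3))
  expect_true(any(grepl('id="axis"', readLines(f3))))
})

test_that("rendered SVG matches the golden file byte for byte", {
  tpl <- builtin_templates()$V_caracalla
  idg <- build_idiogram(template_pairs(tpl), tpl$markers, species = tpl$name)
  f <- withr::local_tempfile(fileext = ".svg")
  render_svg(idg, f)
  golden <- test_path("golden-idiogram-caracalla.svg")
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(golden, "raw", file.size(golden)))
})
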