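#' Build an idiogram drawing specification
#'
#' Abstract geometry for a relative-length-scaled idiogram: one glyph per
#' chromosome pair, ordered 1..n left to right (pairs are already numbered in
#' decreasing relative length), glyph height proportional to RL, short arm
#' drawn above the centromeric constriction (placed at the CI fraction of the
#' glyph), satellite as a distal block on its arm separated by a secondary
#' constriction gap, and one rectangle per marker at its fractional extent.
#'
#' @param pairs Pair summary tibble from [summarize_pairs()].
#' @param sites Optional marker tibble; `pair_id` must reference `pairs`.
#' @param species Label drawn as the panel title.
#' @param short_arm_up Draw the short arm above the centromere (the usual
#'   convention); set `FALSE` to flip.
#' @return A list of class `karyo_idiogram` with `pairs` (glyph geometry:
#'   `pair_id`, `height` = RL, `short_h`, `long_h`, satellite fields) and
#'   `markers` (per-rectangle geometry in arm fractions).
#' @export
build_idiogram <- function(pairs, sites = NULL, species = "",
                           short_arm_up = TRUE) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 0)
  pairs <- arrange(pairs, .data$pair_id)
  if (nrow(pairs) > 1 && any(diff(pairs$rl) > 1e-9)) {
    abort("Pair heights must be non-increasing: renumber with summarize_pairs().",
          class = "karyo_domain_error")
  }
  glyphs <- tibble(
    pair_id = pairs$pair_id,
    height = pairs$rl,
    ci = pairs$ci,
    short_h = pairs$rl * pairs$ci / 100,
    long_h = pairs$rl * (1 - pairs$ci / 100),
    levan_class = pairs$levan_class,
    has_satellite = pairs$has_satellite,
    sat_arm = pairs$sat_arm,
    sat_frac = pairs$sat_frac
  )
  markers <- tibble(pair_id = integer(), arm = character(),
                    marker_type = character(), start_frac = numeric(),
                    end_frac = numeric())
  if (!is.null(sites) && nrow(sites) > 0) {
    link_sites(sites, pairs)
    markers <- tibble(pair_id = sites$pair_id, arm = sites$arm,
                      marker_type = sites$marker_type,
                      start_frac = sites$start_frac,
                      end_frac = sites$end_frac)
  }
  structure(list(species = species, pairs = glyphs, markers = markers,
                 short_arm_up = isTRUE(short_arm_up)),
            class = "karyo_idiogram")
}

#' Idiogram SVG style
#'
#' @param px_per_rl Vertical pixels per RL percent.
#' @param glyph_w,gap Glyph width and horizontal gap between pairs (px).
#' @param sat_gap_px Visual gap of the secondary constriction (px).
#' @param colors Named fill colors per marker type.
#' @param outline,background Stroke and page colors.
#' @return A list of style settings for [render_svg()].
#' @export
idiogram_style <- function(px_per_rl = 28, glyph_w = 22, gap = 16,
                           sat_gap_px = 4,
                           colors = c(CPD = "#d7191c", DAPI = "#2c7bb6",
                                      `5S` = "#e66101", `45S` = "#1a9641"),
                           outline = "#333333", background = "#ffffff") {
  list(px_per_rl = px_per_rl, glyph_w = glyph_w, gap = gap,
       sat_gap_px = sat_gap_px, colors = colors, outline = outline,
       background = background)
}

fmt_px <- function(x) sprintf("%.4f", x)

svg_rect <- function(x, y, w, h, fill, stroke, rx = 2, extra = "") {
  sprintf('<rect x="%s" y="%s" width="%s" height="%s" rx="%s" fill="%s" stroke="%s" stroke-width="1"%s/>',
          fmt_px(x), fmt_px(y), fmt_px(w), fmt_px(h), fmt_px(rx), fill,
          stroke, extra)
}

#' Render an idiogram specification to SVG
#'
#' Writes a well-formed SVG 1.1 document. Output is byte-deterministic for a
#' fixed specification and style (numbers are printed with fixed precision),
#' so renders can be compared against golden files. Each pair is wrapped in a
#' `<g id="pair-k">` group; the left ordinate axis is in RL percent.
#'
#' @param idiogram A `karyo_idiogram` from [build_idiogram()].
#' @param path Output file path.
#' @param style A style list from [idiogram_style()].
#' @return `path`, invisibly.
#' @export
render_svg <- function(idiogram, path, style = idiogram_style()) {
  stopifnot(inherits(idiogram, "karyo_idiogram"))
  g <- idiogram$pairs
  st <- style
  n <- nrow(g)
  axis_max <- if (n > 0) ceiling(max(g$height)) else 10
  margin_l <- 46
  margin_t <- 30
  margin_b <- 24
  plot_h <- axis_max * st$px_per_rl
  width <- margin_l + max(1, n) * (st$glyph_w + st$gap) + st$gap
  height <- margin_t + plot_h + margin_b +
    if (any(g$has_satellite)) st$sat_gap_px else 0

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_px(width), fmt_px(height), fmt_px(width), fmt_px(height)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="%s"/>',
            fmt_px(width), fmt_px(height), st$background),
    sprintf('<text x="%s" y="18" font-family="sans-serif" font-size="13" font-style="italic">%s</text>',
            fmt_px(margin_l), xml_escape(idiogram$species))
  )

  # ordinate axis (RL percent), ticks every 2 units, 0 at the baseline
  baseline <- margin_t + plot_h
  out <- c(out, '<g id="axis">',
           sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
                   fmt_px(margin_l - 8), fmt_px(margin_t), fmt_px(margin_l - 8),
                   fmt_px(baseline), st$outline))
  for (tick in seq(0, axis_max, by = 2)) {
    y <- baseline - tick * st$px_per_rl
    out <- c(out,
             sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
                     fmt_px(margin_l - 12), fmt_px(y), fmt_px(margin_l - 8),
                     fmt_px(y), st$outline),
             sprintf('<text x="%s" y="%s" font-family="sans-serif" font-size="9" text-anchor="end">%d</text>',
                     fmt_px(margin_l - 15), fmt_px(y + 3), tick))
  }
  out <- c(out,
           sprintf('<text x="12" y="%s" font-family="sans-serif" font-size="10" transform="rotate(-90 12 %s)" text-anchor="middle">RL (%%)</text>',
                   fmt_px(margin_t + plot_h / 2), fmt_px(margin_t + plot_h / 2)),
           '</g>')

  up <- idiogram$short_arm_up
  for (i in seq_len(n)) {
    x <- margin_l + (i - 1) * (st$glyph_w + st$gap) + st$gap
    h_top <- (if (up) g$short_h[i] else g$long_h[i]) * st$px_per_rl
    h_bot <- (if (up) g$long_h[i] else g$short_h[i]) * st$px_per_rl
    y_cen <- baseline - h_bot          # centromere y; glyph spans cen +/- arms
    grp <- sprintf('<g id="pair-%d">', g$pair_id[i])
    body <- character(0)

    top_arm <- if (up) "short" else "long"
    sat_here <- isTRUE(g$has_satellite[i]) && !is.na(g$sat_arm[i])
    sat_top <- sat_here && g$sat_arm[i] == top_arm
    sat_bot <- sat_here && !sat_top
    sat_h_top <- if (sat_top) g$sat_frac[i] * h_top else 0
    sat_h_bot <- if (sat_bot) g$sat_frac[i] * h_bot else 0

    # top arm body (satellite, if any, split off with a constriction gap)
    body <- c(body, svg_rect(x, y_cen - (h_top - sat_h_top),
                             st$glyph_w, h_top - sat_h_top,
                             "#f2f2f2", st$outline))
    if (sat_top) {
      body <- c(body, svg_rect(x, y_cen - h_top - st$sat_gap_px,
                               st$glyph_w, sat_h_top, "#f2f2f2", st$outline))
    }
    body <- c(body, svg_rect(x, y_cen, st$glyph_w, h_bot - sat_h_bot,
                             "#f2f2f2", st$outline))
    if (sat_bot) {
      body <- c(body, svg_rect(x, y_cen + h_bot - sat_h_bot + st$sat_gap_px,
                               st$glyph_w, sat_h_bot, "#f2f2f2", st$outline))
    }
    # centromeric constriction
    body <- c(body,
              sprintf('<ellipse cx="%s" cy="%s" rx="%s" ry="3" fill="%s"/>',
                      fmt_px(x + st$glyph_w / 2), fmt_px(y_cen),
                      fmt_px(st$glyph_w / 2), st$outline))

    mk <- idiogram$markers[idiogram$markers$pair_id == g$pair_id[i], ,
                           drop = FALSE]
    if (nrow(mk) > 0) {
      for (j in seq_len(nrow(mk))) {
        col <- st$colors[[mk$marker_type[j]]]
        if (is.null(col)) col <- "#999999"
        arm_up <- mk$arm[j] == top_arm
        arm_px <- if (arm_up) h_top else h_bot
        gap_off <- if (arm_up && sat_top) st$sat_gap_px
                   else if (!arm_up && sat_bot) st$sat_gap_px else 0
        sat_split <- if (arm_up) h_top - sat_h_top else h_bot - sat_h_bot
        seg <- function(s, e) {   # draw [s, e] (arm fractions) on this arm
          a <- s * arm_px; b <- e * arm_px
          off_a <- if (gap_off > 0 && a >= sat_split - 1e-9) gap_off else 0
          off_b <- if (gap_off > 0 && b > sat_split + 1e-9) gap_off else 0
          if (arm_up) {
            svg_rect(x + 1, y_cen - b - off_b, st$glyph_w - 2,
                     (b + off_b) - (a + off_a), col, col, rx = 1)
          } else {
            svg_rect(x + 1, y_cen + a + off_a, st$glyph_w - 2,
                     (b + off_b) - (a + off_a), col, col, rx = 1)
          }
        }
        if (mk$arm[j] == "centromere-spanning") {
          ext <- (mk$end_frac[j] - mk$start_frac[j]) / 2
          body <- c(body,
                    svg_rect(x + 1, y_cen - ext * h_top, st$glyph_w - 2,
                             ext * (h_top + h_bot), col, col, rx = 1))
        } else {
          body <- c(body, seg(mk$start_frac[j], mk$end_frac[j]))
        }
      }
    }
    body <- c(body,
              sprintf('<text x="%s" y="%s" font-family="sans-serif" font-size="10" text-anchor="middle">%d</text>',
                      fmt_px(x + st$glyph_w / 2), fmt_px(baseline + 16),
                      g$pair_id[i]))
    out <- c(out, grp, body, '</g>')
  }
  out <- c(out, '</svg>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
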