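#' Render the atlas on a spiral timeline (SVG)
#'
#' Draws an Archimedean spiral on the days-before-death axis — death at the
#' center, one revolution per `days_per_rev` days — with the equal-window
#' baseline as a green polyline (boundary ticks every `B` days) and the
#' irregular time-lapse segments as a radially offset red polyline with
#' boundary markers and day-range labels. Output is plain SVG text and is
#' byte-identical for identical inputs.
#'
#' @param atlas a `copd_atlas`, a `copd_segments`, or a segment data frame
#'   (`start_days`, `end_days`).
#' @param baseline equal-window baseline segments
#'   ([equal_window_baseline()]).
#' @param path output `.svg` path.
#' @param days_per_rev days per spiral revolution (default 360, roughly one
#'   year per turn).
#' @param size canvas size in pixels.
#' @return `path`, invisibly.
#' @export
render_spiral <- function(atlas, baseline, path, days_per_rev = 360,
                          size = 760) {
  seg <- atlas_segment_frame(atlas)
  if (!nrow(seg)) stop_cfg("no segments to render")
  base <- if (inherits(baseline, "copd_segments")) baseline$segments else baseline
  max_days <- max(seg$start_days, base$start_days)
  cx <- size / 2; cy <- size / 2
  r0 <- 18
  turns <- max(1, max_days / days_per_rev)
  gap <- (size / 2 - r0 - 70) / turns
  pt <- function(d, off = 0) {
    theta <- 2 * pi * d / days_per_rev
    r <- r0 + gap * d / days_per_rev + off
    c(cx + r * sin(theta), cy - r * cos(theta))
  }
  poly <- function(days, off, colour, width) {
    pts <- vapply(days, pt, numeric(2), off = off)
    sprintf('<polyline fill="none" stroke="%s" stroke-width="%.1f" points="%s"/>',
            colour, width,
            paste(sprintf("%.2f,%.2f", pts[1, ], pts[2, ]), collapse = " "))
  }
  circle <- function(d, off, r, colour) {
    p <- pt(d, off)
    sprintf('<circle cx="%.2f" cy="%.2f" r="%.1f" fill="%s"/>', p[1], p[2], r, colour)
  }
  label <- function(d, off, text) {
    p <- pt(d, off)
    sprintf('<text x="%.2f" y="%.2f" font-size="11" font-family="sans-serif" fill="#333">%s</text>',
            p[1] + 4, p[2] - 4, text)
  }
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            size, size, size, size),
    sprintf('<rect width="%d" height="%d" fill="white"/>', size, size),
    sprintf('<circle cx="%.1f" cy="%.1f" r="3" fill="black"/>', cx, cy),
    sprintf('<text x="%.1f" y="%.1f" font-size="12" font-family="sans-serif">death</text>',
            cx + 6, cy + 4),
    # green: equal-window baseline
    poly(seq(0, max(base$start_days), by = 1), 0, "#2e8b57", 1.6),
    vapply(base$start_days, circle, character(1), off = 0, r = 2.5,
           colour = "#2e8b57"),
    # red: irregular time-lapse segments, radially offset for visibility
    poly(seq(0, max(seg$start_days), by = 1), 9, "#c0392b", 2.2),
    vapply(unique(c(seg$end_days, seg$start_days)), circle, character(1),
           off = 9, r = 3.5, colour = "#c0392b"),
    vapply(seq_len(nrow(seg)), function(i) {
      mid <- (seg$start_days[i] + seg$end_days[i]) / 2
      label(mid, 22, sprintf("[%d-%d]", seg$end_days[i], seg$start_days[i]))
    }, character(1)),
    sprintf('<text x="12" y="%d" font-size="12" font-family="sans-serif" fill="#2e8b57">green: equal %d-day windows</text>',
            size - 28, base$start_days[1] - base$end_days[1]),
    sprintf('<text x="12" y="%d" font-size="12" font-family="sans-serif" fill="#c0392b">red: irregular time-lapse segments</text>',
            size - 12),
    '</svg>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unlist(out), con, useBytes = TRUE)
  invisible(path)
}

atlas_segment_frame <- function(x) {
  if (inherits(x, "copd_atlas"))
    data.frame(start_days = vapply(x$segments, `[[`, numeric(1), "start_days"),
               end_days = vapply(x$segments, `[[`, numeric(1), "end_days"))
  else if (inherits(x, "copd_segments")) x$segments
  else as.data.frame(x)
}
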