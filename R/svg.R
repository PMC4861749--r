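# Minimal deterministic SVG emission for bar and line charts.  Geometry
# constants are fixed so repeated runs are byte-identical and elements are
# countable by an XML parser.

.svg_w <- 640; .svg_h <- 400; .svg_margin <- 50

.svg_num <- function(x) sprintf("%.3f", x)

svg_open <- function(width = .svg_w, height = .svg_h) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                   'width="%d" height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height))
}

svg_axes <- function(width = .svg_w, height = .svg_h, m = .svg_margin) {
  c(sprintf('<line class="axis" x1="%d" y1="%d" x2="%d" y2="%d" stroke="black"/>',
            m, height - m, width - m, height - m),
    sprintf('<line class="axis" x1="%d" y1="%d" x2="%d" y2="%d" stroke="black"/>',
            m, m, m, height - m))
}

#' Render a series chart as SVG
#'
#' Deterministic scalable-vector-graphics output: a \code{bar} chart
#' emits one \code{<rect class="bar">} per value, a \code{line} chart a
#' single \code{<polyline class="line">} with one circle marker per
#' point.  Fixed margins and number formatting make repeated runs
#' byte-identical.
#'
#' @param table data.frame with columns \code{x} (numeric or label) and
#'   \code{y} (numeric); \code{NA} rows are skipped.
#' @param kind \code{"bar"} or \code{"line"}.
#' @param path output path (\code{.svg}).
#' @param title chart title (optional).
#' @return \code{path}, invisibly.
#' @export
render_series_chart <- function(table, kind = c("bar", "line"), path,
                                title = "") {
  kind <- match.arg(kind)
  w <- .svg_w; h <- .svg_h; m <- .svg_margin
  body <- svg_axes()
  tab <- table[!is.na(table$y), , drop = FALSE]
  n <- nrow(tab)
  if (n > 0) {
    ymax <- max(tab$y, 0); ymin <- min(tab$y, 0)
    span <- if (ymax > ymin) ymax - ymin else 1
    sy <- function(v) (h - m) - (v - ymin) / span * (h - 2 * m)
    if (kind == "bar") {
      slot <- (w - 2 * m) / n
      bw <- slot * 0.8
      for (i in seq_len(n)) {
        x0 <- m + (i - 1) * slot + slot * 0.1
        y1 <- sy(tab$y[i]); y0 <- sy(0)
        body <- c(body, sprintf(
          '<rect class="bar" x="%s" y="%s" width="%s" height="%s" fill="steelblue"/>',
          .svg_num(x0), .svg_num(min(y0, y1)), .svg_num(bw),
          .svg_num(abs(y0 - y1))))
      }
    } else {
      xs <- as.numeric(tab$x)
      xmin <- min(xs); xmax <- max(xs)
      xspan <- if (xmax > xmin) xmax - xmin else 1
      sx <- function(v) m + (v - xmin) / xspan * (w - 2 * m)
      pts <- paste(sprintf("%s,%s", .svg_num(sx(xs)), .svg_num(sy(tab$y))),
                   collapse = " ")
      body <- c(body, sprintf(
        '<polyline class="line" points="%s" fill="none" stroke="steelblue"/>',
        pts))
      body <- c(body, sprintf(
        '<circle class="point" cx="%s" cy="%s" r="3" fill="steelblue"/>',
        .svg_num(sx(xs)), .svg_num(sy(tab$y))))
    }
    body <- c(body,
              sprintf('<text class="ylab" x="%d" y="%d">%s</text>',
                      5, m, .svg_num(ymax)),
              sprintf('<text class="ylab" x="%d" y="%d">%s</text>',
                      5, h - m, .svg_num(ymin)))
  }
  if (nzchar(title))
    body <- c(body, sprintf('<text class="title" x="%d" y="%d">%s</text>',
                            m, m - 20, title))
  writeLines(c(svg_open(), body, "</svg>"), path)
  invisible(path)
}
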