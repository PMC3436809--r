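# Minimal deterministic drawing canvas with two backends: an SVG text
# writer (byte-stable for identical input) and the grDevices png device.
# Coordinates are pixels, origin top-left, y growing downward.

newCanvas <- function(width, height) {
  env <- new.env(parent = emptyenv())
  env$width <- width
  env$height <- height
  env$ops <- list()
  class(env) <- "eqtlnetCanvas"
  env
}

addOp <- function(canvas, op) {
  canvas$ops[[length(canvas$ops) + 1L]] <- op
  invisible(canvas)
}

cvRect <- function(canvas, x, y, w, h, fill = "#000000", stroke = "none",
                   class = NULL) {
  addOp(canvas, list(type = "rect", x = x, y = y, w = w, h = h, fill = fill,
                     stroke = stroke, class = class))
}

cvCircle <- function(canvas, cx, cy, r, fill = "#000000", stroke = "none") {
  addOp(canvas, list(type = "circle", cx = cx, cy = cy, r = r, fill = fill,
                     stroke = stroke))
}

cvLine <- function(canvas, x1, y1, x2, y2, stroke = "#000000", width = 1) {
  addOp(canvas, list(type = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                     stroke = stroke, width = width))
}

# quadratic bezier (for curved multi-edges)
cvCurve <- function(canvas, x1, y1, cx, cy, x2, y2, stroke = "#000000",
                    width = 1) {
  addOp(canvas, list(type = "curve", x1 = x1, y1 = y1, cx = cx, cy = cy,
                     x2 = x2, y2 = y2, stroke = stroke, width = width))
}

cvText <- function(canvas, x, y, text, size = 10, anchor = "middle",
                   fill = "#000000") {
  addOp(canvas, list(type = "text", x = x, y = y, text = text, size = size,
                     anchor = anchor, fill = fill))
}

px <- function(x) sprintf("%.2f", x)

svgEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

canvasToSvg <- function(canvas) {
  head <- sprintf(paste0(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\" ",
    "viewBox=\"0 0 %d %d\">"),
    canvas$width, canvas$height, canvas$width, canvas$height)
  body <- vapply(canvas$ops, function(op) {
    switch(op$type,
      rect = sprintf(
        "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" stroke=\"%s\"/>",
        px(op$x), px(op$y), px(op$w), px(op$h), op$fill, op$stroke),
      circle = sprintf(
        "<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" stroke=\"%s\"/>",
        px(op$cx), px(op$cy), px(op$r), op$fill, op$stroke),
      line = sprintf(
        "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>",
        px(op$x1), px(op$y1), px(op$x2), px(op$y2), op$stroke, px(op$width)),
      curve = sprintf(
        "<path d=\"M %s %s Q %s %s %s %s\" fill=\"none\" stroke=\"%s\" stroke-width=\"%s\"/>",
        px(op$x1), px(op$y1), px(op$cx), px(op$cy), px(op$x2), px(op$y2),
        op$stroke, px(op$width)),
      text = sprintf(
        "<text x=\"%s\" y=\"%s\" font-size=\"%s\" text-anchor=\"%s\" fill=\"%s\" font-family=\"sans-serif\">%s</text>",
        px(op$x), px(op$y), px(op$size), op$anchor, op$fill,
        svgEscape(op$text)))
  }, "")
  c(head, body, "</svg>")
}

canvasRenderPng <- function(canvas, path) {
  grDevices::png(path, width = canvas$width, height = canvas$height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, canvas$width),
                        ylim = c(canvas$height, 0))
  noneToNA <- function(x) if (identical(x, "none")) NA else x
  for (op in canvas$ops) {
    switch(op$type,
      rect = graphics::rect(op$x, op$y + op$h, op$x + op$w, op$y,
                            col = noneToNA(op$fill),
                            border = noneToNA(op$stroke)),
      circle = graphics::symbols(op$cx, op$cy, circles = op$r,
                                 inches = FALSE, add = TRUE,
                                 bg = noneToNA(op$fill),
                                 fg = noneToNA(op$stroke) %||% "black"),
      line = graphics::segments(op$x1, op$y1, op$x2, op$y2,
                                col = op$stroke, lwd = op$width),
      curve = {
        t <- seq(0, 1, length.out = 30L)
        bx <- (1 - t)^2 * op$x1 + 2 * (1 - t) * t * op$cx + t^2 * op$x2
        by <- (1 - t)^2 * op$y1 + 2 * (1 - t) * t * op$cy + t^2 * op$y2
        graphics::lines(bx, by, col = op$stroke, lwd = op$width)
      },
      text = graphics::text(op$x, op$y, op$text,
                            adj = switch(op$anchor, middle = 0.5,
                                         start = 0, end = 1),
                            cex = op$size / 12, col = op$fill))
  }
  invisible(path)
}

renderCanvas <- function(canvas, path, format = c("svg", "png")) {
  format <- match.arg(format)
  if (format == "svg") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(canvasToSvg(canvas), con, sep = "\n")
  } else {
    canvasRenderPng(canvas, path)
  }
  invisible(path)
}

formatFromPath <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("svg", "png")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("svg", "png")) ext else "svg"
}
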