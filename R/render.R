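#' Render a 2DE pattern as an SVG bubble map
#'
#' Draws one circle per virtual spot at (pI-window midpoint, Mw), sized by
#' emPAI.  By default circle AREA is proportional to emPAI, the perceptually
#' honest encoding; \code{sizeMode = "radius"} makes the radius proportional
#' instead.  The Mw axis is log10-scaled.  Output is deterministic: rendering
#' the same pattern twice yields byte-identical files.
#'
#' @param pattern a non-empty \linkS4class{Pattern2DE}.
#' @param file output path; when \code{NULL} the SVG text is returned only.
#' @param sizeMode \code{"area"} (default) or \code{"radius"}.
#' @param width,height canvas size in pixels.
#' @param maxRadius radius in pixels of the most abundant spot.
#' @return invisibly, the SVG document as a character vector of lines.
#' @export
renderPattern <- function(pattern, file = NULL,
                          sizeMode = c("area", "radius"),
                          width = 640, height = 420, maxRadius = 18) {
  sizeMode <- match.arg(sizeMode)
  sp <- pattern@spots
  if (!nrow(sp)) stop("cannot render an empty pattern")
  mar <- c(left = 60, right = 15, top = 15, bottom = 45)
  pw <- width - mar["left"] - mar["right"]
  ph <- height - mar["top"] - mar["bottom"]
  piMid <- (sp$pi_low + sp$pi_high) / 2
  xr <- range(c(sp$pi_low, sp$pi_high))
  lmw <- log10(sp$mw)
  yr <- range(lmw) + c(-1, 1) * max(0.05 * diff(range(lmw)), 0.1)
  xmap <- function(p) mar["left"] + (p - xr[1]) / diff(xr) * pw
  ymap <- function(l) mar["top"] + (yr[2] - l) / diff(yr) * ph
  rel <- sp$empai / max(sp$empai)
  r <- maxRadius * if (sizeMode == "area") sqrt(rel) else rel
  fmt <- function(x) sprintf("%.3f", x)
  out <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white"/>',
            width, height))
  ## axes
  x0 <- mar["left"]; y0 <- mar["top"] + ph
  out <- c(out,
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
            fmt(x0), fmt(y0), fmt(x0 + pw), fmt(y0)),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
            fmt(x0), fmt(mar["top"]), fmt(x0), fmt(y0)))
  for (t in seq(ceiling(xr[1]), floor(xr[2]))) {
    out <- c(out,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
              fmt(xmap(t)), fmt(y0), fmt(xmap(t)), fmt(y0 + 5)),
      sprintf('<text x="%s" y="%s" font-size="11" text-anchor="middle">%d</text>',
              fmt(xmap(t)), fmt(y0 + 18), t))
  }
  yticks <- if (ceiling(yr[1] * 2) <= floor(yr[2] * 2))
    seq(ceiling(yr[1] * 2) / 2, floor(yr[2] * 2) / 2, by = 0.5)
  else round(mean(yr) * 100) / 100       # degenerate span: one mid tick
  for (t in yticks) {
    out <- c(out,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
              fmt(x0 - 5), fmt(ymap(t)), fmt(x0), fmt(ymap(t))),
      sprintf(paste0('<text x="%s" y="%s" font-size="11" ',
                     'text-anchor="end">%.0f</text>'),
              fmt(x0 - 8), fmt(ymap(t) + 4), 10^t))
  }
  out <- c(out,
    sprintf(paste0('<text x="%s" y="%s" font-size="12" ',
                   'text-anchor="middle">pI (pH)</text>'),
            fmt(x0 + pw / 2), fmt(y0 + 35)),
    sprintf(paste0('<text x="%s" y="%s" font-size="12" text-anchor="middle" ',
                   'transform="rotate(-90 %s %s)">Mw (Da)</text>'),
            fmt(15), fmt(mar["top"] + ph / 2), fmt(15),
            fmt(mar["top"] + ph / 2)))
  ## spots, in stable order
  ord <- order(sp$accession, sp$row, sp$col)
  out <- c(out, sprintf(
    paste0('<circle cx="%s" cy="%s" r="%s" fill="steelblue" ',
           'fill-opacity="0.6" stroke="navy"><title>%s s%d emPAI=%.4f',
           '</title></circle>'),
    fmt(xmap(piMid[ord])), fmt(ymap(lmw[ord])), fmt(r[ord]),
    sp$accession[ord], sp$col[ord], sp$empai[ord]))
  out <- c(out, "</svg>")
  out <- unname(out)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
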