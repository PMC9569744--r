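#' Calibrate the pI axis of an IPG strip
#'
#' Builds a monotone piecewise-linear map between physical position along the
#' strip (cm) and pH from anchor points.  For a linear gradient two anchors
#' suffice; a nonlinear gradient (e.g. pH 3-11 NL) is approximated by more
#' anchors, ideally the manufacturer's gradient curve.
#'
#' @param anchors data.frame with columns \code{position} (cm, strictly
#'   increasing) and \code{pH} (strictly increasing).
#' @return a \linkS4class{PiAxis}.
#' @examples
#' ax <- piAxis(data.frame(position = c(0, 18), pH = c(3, 11)))
#' positionToPH(ax, 9)   # 7
#' @export
piAxis <- function(anchors) {
  if (!all(c("position", "pH") %in% names(anchors)))
    stop("anchors must have columns 'position' and 'pH'")
  anchors <- anchors[order(anchors$position), c("position", "pH")]
  new("PiAxis", anchors = anchors,
      mode = if (nrow(anchors) == 2L) "linear" else "piecewise_linear")
}

#' Default anchor table for a nonlinear pH 3-11 gradient
#'
#' A documented 5-point piecewise-linear approximation of an 18 cm
#' "3-11 NL" immobilized pH gradient: steep below pH 5 and above pH 8,
#' shallow in the middle.  It is an approximation for testing and teaching;
#' supply the manufacturer's gradient curve for accurate work.
#'
#' @param length strip length in cm (default 18).
#' @return anchor data.frame suitable for \code{\link{piAxis}}.
#' @export
nl311Anchors <- function(length = 18) {
  data.frame(position = c(0, 0.25, 0.5, 0.75, 1) * length,
             pH = c(3, 4.8, 6.0, 7.6, 11))
}

#' Convert between strip position and pH
#'
#' Piecewise-linear interpolation on the axis anchors.  Queries outside the
#' anchored range are an error (extrapolation is forbidden); the boundaries
#' themselves are included.
#'
#' @param axis a \linkS4class{PiAxis}.
#' @param position position(s) in cm.
#' @param pH pH value(s).
#' @return the interpolated pH (or position) values.
#' @export
positionToPH <- function(axis, position) {
  a <- axis@anchors
  if (any(position < min(a$position) | position > max(a$position)))
    stop(sprintf("position outside calibrated range [%g, %g] cm",
                 min(a$position), max(a$position)))
  stats::approx(a$position, a$pH, xout = position, ties = "ordered")$y
}

#' @rdname positionToPH
#' @export
phToPosition <- function(axis, pH) {
  a <- axis@anchors
  if (any(pH < min(a$pH) | pH > max(a$pH)))
    stop(sprintf("pH outside calibrated range [%g, %g]",
                 min(a$pH), max(a$pH)))
  stats::approx(a$pH, a$position, xout = pH, ties = "ordered")$y
}

#' Calibrate the Mw axis of an SDS-PAGE gel
#'
#' Least-squares fit of log10(Mw) against relative migration for a marker
#' ladder.  The fitted slope must be negative (larger proteins migrate less).
#'
#' @param markers data.frame with columns \code{migration} (fraction of the
#'   separation distance in [0, 1]) and \code{mw} (Da); at least two markers
#'   with distinct migrations.
#' @param gelPercent \% acrylamide, recorded as metadata.
#' @return an \linkS4class{MwAxis}.
#' @examples
#' ax <- mwAxis(data.frame(migration = c(0.2, 0.8), mw = c(1e5, 1e4)))
#' migrationToMw(ax, 0.5)   # 31623, the geometric mean
#' @export
mwAxis <- function(markers, gelPercent = 14) {
  if (!all(c("migration", "mw") %in% names(markers)))
    stop("markers must have columns 'migration' and 'mw'")
  if (nrow(markers) < 2L) stop("at least 2 markers required")
  if (anyDuplicated(markers$migration))
    stop("duplicate migration values in marker table")
  fit <- stats::lm(log10(mw) ~ migration, data = markers)
  co <- stats::coef(fit)
  new("MwAxis", markers = markers[order(markers$migration), ],
      slope = unname(co[2]), intercept = unname(co[1]),
      gelPercent = gelPercent)
}

#' Convert between gel migration and molecular mass
#'
#' @param axis an \linkS4class{MwAxis}.
#' @param migration relative migration value(s).
#' @param mw molecular mass value(s) in Da.
#' @return the converted values.
#' @export
migrationToMw <- function(axis, migration)
  10^(axis@intercept + axis@slope * migration)

#' @rdname migrationToMw
#' @export
mwToMigration <- function(axis, mw)
  (log10(mw) - axis@intercept) / axis@slope
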