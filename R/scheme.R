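#' Define a sectioning scheme
#'
#' How the separation plane is cut into sections.  \code{"strip36"} models an
#' 18 cm IPG strip cut into 36 equal 0.5 cm sections after isoelectric
#' focusing (one row); \code{"grid96"} models a gel cut into 96 sections as an
#' 8 Mw-row by 12 pI-column grid over a strip of \code{stripLength} cm and the
#' full migration range [0, 1]; \code{"custom"} takes explicit boundaries.
#' All intervals are half-open \code{[low, high)} with the final interval
#' closed, so the sections exactly partition the plane.
#'
#' @param mode \code{"strip36"}, \code{"grid96"} or \code{"custom"}.
#' @param stripLength strip length in cm (default 18 for strip36, 7 for
#'   grid96, matching the common strip formats).
#' @param rowBounds,colBounds boundary vectors for \code{mode = "custom"}
#'   (migration units and cm respectively).
#' @return a \linkS4class{SectionScheme}.
#' @examples
#' sectionScheme("strip36")
#' sectionScheme("grid96")
#' @export
sectionScheme <- function(mode = c("strip36", "grid96", "custom"),
                          stripLength = NULL, rowBounds = NULL,
                          colBounds = NULL) {
  mode <- match.arg(mode)
  if (mode == "strip36") {
    len <- if (is.null(stripLength)) 18 else stripLength
    new("SectionScheme", mode = mode, nRows = 1L, nCols = 36L,
        rowBounds = c(0, 1), colBounds = seq(0, len, length.out = 37L))
  } else if (mode == "grid96") {
    len <- if (is.null(stripLength)) 7 else stripLength
    new("SectionScheme", mode = mode, nRows = 8L, nCols = 12L,
        rowBounds = seq(0, 1, length.out = 9L),
        colBounds = seq(0, len, length.out = 13L))
  } else {
    if (is.null(rowBounds) || is.null(colBounds))
      stop("custom scheme needs rowBounds and colBounds")
    new("SectionScheme", mode = mode,
        nRows = length(rowBounds) - 1L, nCols = length(colBounds) - 1L,
        rowBounds = as.numeric(rowBounds), colBounds = as.numeric(colBounds))
  }
}

## Half-open interval lookup: index i such that x in [b[i], b[i+1]), with the
## final interval closed; NA when off range.
.halfOpenIndex <- function(x, bounds) {
  idx <- findInterval(x, bounds, rightmost.closed = TRUE, left.open = FALSE)
  idx[x < bounds[1] | x > bounds[length(bounds)]] <- NA_integer_
  as.integer(idx - 1L)   # 0-based
}

#' Locate the section containing a coordinate
#'
#' Maps a physical coordinate (strip position in cm, and relative migration
#' for multi-row schemes) to its unique section.  Coordinates outside the
#' sectioned area are flagged off-gel rather than silently dropped.
#'
#' @param scheme a \linkS4class{SectionScheme}.
#' @param position position(s) along the strip in cm.
#' @param migration relative migration value(s); ignored for single-row
#'   schemes.
#' @return data.frame with 0-based \code{row}, \code{col} and logical
#'   \code{off_gel}; off-gel coordinates have NA indices.
#' @examples
#' sc <- sectionScheme("strip36")
#' locateSection(sc, 0.75)    # col 1: floor(0.75 / 0.5)
#' locateSection(sc, 18)      # last section: final interval closed
#' @export
locateSection <- function(scheme, position, migration = 0) {
  col <- .halfOpenIndex(position, scheme@colBounds)
  if (scheme@nRows == 1L) {
    row <- ifelse(is.na(col), NA_integer_, 0L)
  } else {
    row <- .halfOpenIndex(migration, scheme@rowBounds)
  }
  if (length(row) == 1L && length(col) > 1L) row <- rep(row, length(col))
  data.frame(row = row, col = col, off_gel = is.na(row) | is.na(col))
}

#' Canonical section identifiers
#'
#' Section ids are \code{"s<col>"} for single-row schemes and
#' \code{"r<row>c<col>"} for grids, with 0-based zero-padded indices: the
#' interchange key between PSM tables and patterns.
#'
#' @param scheme a \linkS4class{SectionScheme}.
#' @param row,col 0-based section indices.
#' @return character vector of ids.
#' @export
sectionId <- function(scheme, row, col) {
  if (scheme@nRows == 1L) sprintf("s%02d", col)
  else sprintf("r%dc%02d", row, col)
}

#' @rdname sectionId
#' @param id section id string(s).
#' @return \code{parseSectionId}: data.frame with 0-based \code{row},
#'   \code{col}.
#' @export
parseSectionId <- function(scheme, id) {
  if (scheme@nRows == 1L) {
    m <- regmatches(id, regexec("^s([0-9]+)$", id))
    col <- vapply(m, function(x) if (length(x) == 2L) as.integer(x[2])
                  else NA_integer_, integer(1))
    row <- ifelse(is.na(col), NA_integer_, 0L)
  } else {
    m <- regmatches(id, regexec("^r([0-9]+)c([0-9]+)$", id))
    row <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[2])
                  else NA_integer_, integer(1))
    col <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[3])
                  else NA_integer_, integer(1))
  }
  if (any(is.na(row) | is.na(col)))
    stop("malformed section id: ", id[which(is.na(row) | is.na(col))[1]])
  if (any(col >= scheme@nCols) || any(row >= scheme@nRows))
    stop("section id outside scheme")
  data.frame(row = row, col = col)
}

#' pI window of a section column
#'
#' @param scheme a \linkS4class{SectionScheme}.
#' @param axis a \linkS4class{PiAxis} calibrating the strip.
#' @param col 0-based column index (vectorized).
#' @return data.frame with \code{pi_low}, \code{pi_high}.
#' @export
sectionPiWindow <- function(scheme, axis, col) {
  data.frame(pi_low = positionToPH(axis, scheme@colBounds[col + 1L]),
             pi_high = positionToPH(axis, scheme@colBounds[col + 2L]))
}
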