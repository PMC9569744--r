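#' Build a 2DE pattern from per-section quantification
#'
#' Converts a per-section protein quantification table into a
#' \linkS4class{Pattern2DE}: one virtual spot per (accession, section) with
#' that section's emPAI and pI window.  In single-row (semi-virtual) schemes
#' the Mw coordinate is the supplied theoretical chain mass; in grid schemes
#' it is the Mw at the section's migration midpoint on the calibrated Mw axis.
#'
#' @param quant data.frame with columns \code{accession}, \code{section_id},
#'   \code{empai} (as from \code{\link{proteinQuantTable}}), accepted proteins
#'   only.
#' @param scheme a \linkS4class{SectionScheme}.
#' @param piAxis a \linkS4class{PiAxis}.
#' @param mwAxis an \linkS4class{MwAxis}; required for multi-row schemes.
#' @param theoreticalMw named numeric vector accession -> Da; required for
#'   single-row schemes, where the second axis is theoretical by construction.
#' @param provenance optional named list of run metadata.
#' @return a \linkS4class{Pattern2DE}.
#' @export
buildPattern <- function(quant, scheme, piAxis, mwAxis = NULL,
                         theoreticalMw = NULL, provenance = list()) {
  if (!nrow(quant)) {
    sp <- data.frame(accession = character(0), row = integer(0),
                     col = integer(0), pi_low = numeric(0),
                     pi_high = numeric(0), mw = numeric(0),
                     empai = numeric(0))
    return(new("Pattern2DE", spots = sp, scheme = scheme,
               provenance = provenance))
  }
  rc <- parseSectionId(scheme, quant$section_id)
  win <- sectionPiWindow(scheme, piAxis, rc$col)
  if (scheme@nRows == 1L) {
    if (is.null(theoreticalMw))
      stop("single-row scheme needs theoreticalMw (accession -> Da)")
    missing <- setdiff(unique(quant$accession), names(theoreticalMw))
    if (length(missing))
      stop("no theoretical Mw for accession(s): ",
           paste(missing, collapse = ", "))
    mw <- unname(theoreticalMw[quant$accession])
  } else {
    if (is.null(mwAxis)) stop("multi-row scheme needs a calibrated mwAxis")
    mid <- (scheme@rowBounds[rc$row + 1L] + scheme@rowBounds[rc$row + 2L]) / 2
    mw <- migrationToMw(mwAxis, mid)
  }
  sp <- data.frame(accession = quant$accession, row = rc$row, col = rc$col,
                   pi_low = win$pi_low, pi_high = win$pi_high, mw = mw,
                   empai = quant$empai)
  sp <- sp[order(sp$accession, sp$row, sp$col), , drop = FALSE]
  rownames(sp) <- NULL
  new("Pattern2DE", spots = sp, scheme = scheme, provenance = provenance)
}

#' Bounding box of a protein's spots
#'
#' @param pattern a \linkS4class{Pattern2DE}.
#' @param accession protein accession present in the pattern.
#' @return named numeric vector \code{pi_min}, \code{pi_max}, \code{mw_min},
#'   \code{mw_max} in axis units.
#' @export
spotExtent <- function(pattern, accession) {
  sp <- pattern@spots[pattern@spots$accession == accession, , drop = FALSE]
  if (!nrow(sp)) stop(sprintf("accession '%s' not in pattern", accession))
  c(pi_min = min(sp$pi_low), pi_max = max(sp$pi_high),
    mw_min = min(sp$mw), mw_max = max(sp$mw))
}

#' Compare two 2DE patterns
#'
#' Matches the spots of each shared accession between two patterns by greedy
#' nearest-neighbour pairing (closest pI-midpoint first) within tolerance
#' windows, and reports log2 emPAI ratios on matched pairs.  A pseudocount
#' keeps ratios finite when one side is zero.  Greedy matching (rather than
#' optimal assignment) is adequate because spot sets per protein are small
#' and tolerance windows rarely overlap.
#'
#' @param a,b \linkS4class{Pattern2DE} objects in the same axis units.
#' @param piTol maximum pI-midpoint distance for a match (pH units).
#' @param mwTolFraction maximum relative Mw difference for a match.
#' @param pseudocount added to both emPAI values in the log ratio
#'   (default 0.01).
#' @return list with \code{matches} (data.frame: accession, coordinates in
#'   both patterns, \code{empai_a}, \code{empai_b}, \code{log2_ratio}),
#'   \code{only_a} and \code{only_b} (unmatched spot tables).
#' @export
comparePatterns <- function(a, b, piTol = 0.5, mwTolFraction = 0.2,
                            pseudocount = 0.01) {
  sa <- a@spots; sb <- b@spots
  sa$piMid <- (sa$pi_low + sa$pi_high) / 2
  sb$piMid <- (sb$pi_low + sb$pi_high) / 2
  matches <- list()
  usedB <- rep(FALSE, nrow(sb))
  matchedA <- rep(FALSE, nrow(sa))
  for (i in seq_len(nrow(sa))) {
    cand <- which(!usedB & sb$accession == sa$accession[i] &
                    abs(sb$piMid - sa$piMid[i]) <= piTol &
                    abs(sb$mw - sa$mw[i]) <= mwTolFraction * sa$mw[i])
    if (!length(cand)) next
    j <- cand[which.min(abs(sb$piMid[cand] - sa$piMid[i]))]
    usedB[j] <- TRUE
    matchedA[i] <- TRUE
    matches[[length(matches) + 1L]] <- data.frame(
      accession = sa$accession[i],
      row_a = sa$row[i], col_a = sa$col[i],
      row_b = sb$row[j], col_b = sb$col[j],
      empai_a = sa$empai[i], empai_b = sb$empai[j],
      log2_ratio = log2((sa$empai[i] + pseudocount) /
                          (sb$empai[j] + pseudocount)))
  }
  matches <- if (length(matches)) do.call(rbind, matches)
  else data.frame(accession = character(0), row_a = integer(0),
                  col_a = integer(0), row_b = integer(0), col_b = integer(0),
                  empai_a = numeric(0), empai_b = numeric(0),
                  log2_ratio = numeric(0))
  list(matches = matches,
       only_a = sa[!matchedA, setdiff(names(sa), "piMid"), drop = FALSE],
       only_b = sb[!usedB, setdiff(names(sb), "piMid"), drop = FALSE])
}
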