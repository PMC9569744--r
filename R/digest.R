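#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is proline (the Keil
#' rule, as applied by the common search engines), and returns every peptide
#' with 0 to \code{maxMissed} internal missed cleavage sites together with its
#' 1-based coordinates on the chain and its mass on both scales.
#'
#' @param sequence chain amino-acid string.
#' @param maxMissed maximum number of internal missed cleavages (default 2,
#'   the usual search-engine setting).
#' @param keilRule if \code{FALSE}, cleave after every K/R regardless of a
#'   following proline.
#' @return data.frame with columns \code{sequence}, \code{start}, \code{end},
#'   \code{missed}, \code{mass_avg}, \code{mass_mono}, ordered by start
#'   position then missed cleavages.
#' @examples
#' digestTryptic("AAKPLRCCK", maxMissed = 0)   # K|P is not cleaved
#' @export
digestTryptic <- function(sequence, maxMissed = 2L, keilRule = TRUE) {
  aa <- .checkSequence(sequence)
  maxMissed <- as.integer(maxMissed)
  if (is.na(maxMissed) || maxMissed < 0L) stop("maxMissed must be >= 0")
  n <- length(aa)
  ## cleavage points: after position i
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites < n]
  if (keilRule) sites <- sites[aa[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)            # peptide k spans bounds[k]+1 .. bounds[k+1]
  nseg <- length(bounds) - 1L
  out <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    jmax <- min(maxMissed, nseg - i)
    js <- 0:jmax
    st <- bounds[i] + 1L
    en <- bounds[i + 1L + js]
    seqs <- vapply(en, function(e) paste(aa[st:e], collapse = ""), character(1))
    out[[i]] <- data.frame(sequence = seqs, start = st, end = en, missed = js)
  }
  pep <- do.call(rbind, out)
  pep$mass_avg <- vapply(pep$sequence, proteinMass, numeric(1),
                         kind = "average", USE.NAMES = FALSE)
  pep$mass_mono <- vapply(pep$sequence, proteinMass, numeric(1),
                          kind = "monoisotopic", USE.NAMES = FALSE)
  rownames(pep) <- NULL
  pep
}

#' Observability window for tryptic peptides
#'
#' The mass/length box inside which a tryptic peptide is considered
#' "theoretically observable" by the LC-MS/MS acquisition.  The default,
#' 500-4500 Da and 6-50 residues, is a typical Orbitrap acquisition range;
#' both ranges are closed intervals.
#'
#' @param minMass,maxMass mass bounds in Da.
#' @param minLength,maxLength length bounds in residues.
#' @return a list of class \code{"ObservabilityWindow"}.
#' @export
observabilityWindow <- function(minMass = 500, maxMass = 4500,
                                minLength = 6L, maxLength = 50L) {
  if (minMass >= maxMass) stop("minMass must be < maxMass")
  if (minLength >= maxLength) stop("minLength must be < maxLength")
  structure(list(minMass = minMass, maxMass = maxMass,
                 minLength = as.integer(minLength),
                 maxLength = as.integer(maxLength)),
            class = "ObservabilityWindow")
}

#' Filter peptides to the observable set
#'
#' @param peptides a digest table from \code{\link{digestTryptic}}.
#' @param window an \code{\link{observabilityWindow}}.
#' @param massScale which mass column to test against the window.
#' @return the subset of \code{peptides} inside the closed window.
#' @export
observablePeptides <- function(peptides, window = observabilityWindow(),
                               massScale = c("average", "monoisotopic")) {
  massScale <- match.arg(massScale)
  m <- if (massScale == "average") peptides$mass_avg else peptides$mass_mono
  len <- nchar(peptides$sequence)
  keep <- m >= window$minMass & m <= window$maxMass &
    len >= window$minLength & len <= window$maxLength
  peptides[keep, , drop = FALSE]
}

#' Count theoretically observable peptides (the emPAI denominator)
#'
#' Counts the distinct fully cleaved (0 missed cleavages) peptide sequences of
#' a chain inside the observability window.  Restricting to fully cleaved
#' peptides keeps the count non-redundant: missed-cleavage variants cover the
#' same sequence twice.  Set \code{includeMissed = TRUE} to count
#' missed-cleavage peptides as well, for sensitivity analysis.
#'
#' @param chainSequence chain amino-acid string.
#' @param window an \code{\link{observabilityWindow}}.
#' @param maxMissed digestion depth when \code{includeMissed} is \code{TRUE}.
#' @param includeMissed include missed-cleavage peptides in the count.
#' @param massScale mass scale tested against the window.
#' @return integer count (may be 0; downstream emPAI then signals an error).
#' @export
countObservable <- function(chainSequence, window = observabilityWindow(),
                            maxMissed = 2L, includeMissed = FALSE,
                            massScale = "average") {
  pep <- digestTryptic(chainSequence,
                       maxMissed = if (includeMissed) maxMissed else 0L)
  obs <- observablePeptides(pep, window, massScale)
  length(unique(obs$sequence))
}
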