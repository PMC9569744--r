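#' @import methods
NULL

#' Modification: a counted post-translational modification
#'
#' A \code{Modification} describes \code{count} copies of one modification kind
#' carried by a proteoform.  It records the mass it adds on both mass scales
#' and how it changes the ionizable-group inventory: each phosphate contributes
#' two acidic groups (pKa 1.2 and 6.5), each sialic acid (NeuAc) one acidic
#' group (pKa 2.6), and each lysine acetylation removes one lysine amine
#' (a negative \code{copies} entry in \code{ionizable}).  Neutral sugars and
#' oxidation change mass only.
#'
#' @slot kind one of \code{"phospho"}, \code{"acetyl"}, \code{"carbamidomethyl"},
#'   \code{"oxidation"}, \code{"glyco"}.
#' @slot count non-negative integer number of copies.
#' @slot glycanComposition named integer vector over Hex, HexNAc, NeuAc, Fuc
#'   (empty unless \code{kind == "glyco"}).
#' @slot massDeltaAvg,massDeltaMono total added mass in Da (all copies).
#' @slot ionizable data.frame with columns \code{group} ("acidic"/"basic"),
#'   \code{pKa}, \code{copies}; negative copies remove groups of that pKa.
#' @name Modification-class
#' @aliases Modification-class
#' @exportClass Modification
setClass("Modification", representation(
  kind = "character",
  count = "integer",
  glycanComposition = "integer",
  massDeltaAvg = "numeric",
  massDeltaMono = "numeric",
  ionizable = "data.frame"
))

setValidity("Modification", function(object) {
  msg <- character(0)
  if (!(object@kind %in% c("phospho", "acetyl", "carbamidomethyl",
                           "oxidation", "glyco")))
    msg <- c(msg, sprintf("unknown modification kind '%s'", object@kind))
  if (length(object@count) != 1L || is.na(object@count) || object@count < 0L)
    msg <- c(msg, "count must be a single non-negative integer")
  if (object@massDeltaAvg < 0 || object@massDeltaMono < 0)
    msg <- c(msg, "mass deltas must be non-negative for additive PTMs")
  if (object@kind != "glyco" && length(object@glycanComposition) &&
      any(object@glycanComposition > 0L))
    msg <- c(msg, "glycanComposition must be empty unless kind is 'glyco'")
  if (nrow(object@ionizable) &&
      (any(object@ionizable$pKa <= 0) || any(object@ionizable$pKa >= 14)))
    msg <- c(msg, "ionizable pKa values must lie in (0, 14)")
  if (length(msg)) msg else TRUE
})

#' ProteinRecord: a database sequence with chain annotations
#'
#' Container for one database entry: the full (precursor) sequence, the
#' annotated chain ranges (signal-cleaved mature chains, subunit chains), and
#' optional counts of annotatable modification sites used to bound proteoform
#' construction.
#'
#' @slot accession UniProt-style accession.
#' @slot entryName UniProt entry name (may be \code{""}).
#' @slot sequence one-letter amino-acid string over the 20 canonical residues.
#' @slot chains data.frame with columns \code{name}, \code{start}, \code{end}
#'   (1-based inclusive residue coordinates on \code{sequence}).
#' @slot siteCounts named integer vector, modification kind -> number of
#'   annotatable sites (empty means unconstrained).
#' @name ProteinRecord-class
#' @aliases ProteinRecord-class
#' @exportClass ProteinRecord
setClass("ProteinRecord", representation(
  accession = "character",
  entryName = "character",
  sequence = "character",
  chains = "data.frame",
  siteCounts = "integer"
))

setValidity("ProteinRecord", function(object) {
  msg <- character(0)
  if (length(object@accession) != 1L || !nzchar(object@accession))
    msg <- c(msg, "accession must be a single non-empty string")
  aa <- tryCatch(.checkSequence(object@sequence), error = function(e) e)
  if (inherits(aa, "error")) {
    msg <- c(msg, conditionMessage(aa))
  } else if (nrow(object@chains)) {
    n <- length(aa)
    ok <- with(object@chains, start >= 1L & start <= end & end <= n)
    if (!all(ok))
      msg <- c(msg, sprintf("chain '%s' outside [1, %d]",
                            object@chains$name[which(!ok)[1]], n))
  }
  if (nrow(object@chains) && anyDuplicated(object@chains$name))
    msg <- c(msg, "duplicate chain names")
  if (length(msg)) msg else TRUE
})

#' Proteoform: one chain with one modification complement
#'
#' A proteoform is a specific molecular species: a mature chain of a parent
#' record plus a definite set of modifications, carrying its computed
#' isoelectric point (pH units) and average molecular mass (Da).  The mass
#' always equals the unmodified chain mass plus the summed modification deltas.
#'
#' @slot parent accession of the parent \linkS4class{ProteinRecord}.
#' @slot chainName name of the chain within the parent.
#' @slot sequence the chain subsequence.
#' @slot mods list of \linkS4class{Modification} objects.
#' @slot pI isoelectric point in pH units.
#' @slot mw average molecular mass in Da.
#' @slot abundanceWeight optional fraction in [0, 1] used in ensembles.
#' @name Proteoform-class
#' @aliases Proteoform-class
#' @exportClass Proteoform
setClass("Proteoform", representation(
  parent = "character",
  chainName = "character",
  sequence = "character",
  mods = "list",
  pI = "numeric",
  mw = "numeric",
  abundanceWeight = "numeric"
))

setValidity("Proteoform", function(object) {
  msg <- character(0)
  if (object@pI <= 0 || object@pI >= 14)
    msg <- c(msg, "pI must lie in (0, 14)")
  if (object@mw <= 0) msg <- c(msg, "Mw must be positive")
  if (length(object@abundanceWeight) &&
      (object@abundanceWeight < 0 || object@abundanceWeight > 1))
    msg <- c(msg, "abundanceWeight must lie in [0, 1]")
  expected <- proteinMass(object@sequence, object@mods, "average")
  if (abs(expected - object@mw) > 1e-6)
    msg <- c(msg, sprintf("Mw %.6f != chain mass + mod deltas %.6f",
                          object@mw, expected))
  if (length(msg)) msg else TRUE
})

#' PiAxis: calibration of strip position to pH
#'
#' Monotone piecewise-linear map between physical position along an immobilized
#' pH gradient strip (cm) and pH, defined by anchor points.  Queries outside
#' the anchored range are refused (no extrapolation).
#'
#' @slot anchors data.frame with strictly increasing \code{position} (cm) and
#'   strictly increasing \code{pH}.
#' @slot mode \code{"linear"} (two anchors) or \code{"piecewise_linear"}.
#' @name PiAxis-class
#' @aliases PiAxis-class
#' @exportClass PiAxis
setClass("PiAxis", representation(anchors = "data.frame", mode = "character"))

setValidity("PiAxis", function(object) {
  a <- object@anchors
  if (nrow(a) < 2L) return("at least 2 anchors required")
  if (any(diff(a$position) <= 0)) return("anchor positions must strictly increase")
  if (any(diff(a$pH) <= 0)) return("anchor pH values must strictly increase")
  TRUE
})

#' MwAxis: calibration of gel migration to molecular mass
#'
#' Log-linear calibration of SDS-PAGE migration: least-squares fit of
#' log10(Mw) against relative migration (0 = top of gel, 1 = dye front).
#' Larger proteins migrate less, so the fitted slope must be negative.
#'
#' @slot markers data.frame with columns \code{migration} (fraction in [0,1])
#'   and \code{mw} (Da).
#' @slot slope,intercept coefficients of log10(mw) = intercept + slope * migration.
#' @slot gelPercent \% acrylamide, metadata only.
#' @name MwAxis-class
#' @aliases MwAxis-class
#' @exportClass MwAxis
setClass("MwAxis", representation(
  markers = "data.frame", slope = "numeric", intercept = "numeric",
  gelPercent = "numeric"
))

setValidity("MwAxis", function(object) {
  if (nrow(object@markers) < 2L) return("at least 2 markers required")
  if (anyDuplicated(object@markers$migration))
    return("duplicate migration values")
  if (object@slope >= 0) return("fitted slope must be negative")
  TRUE
})

#' SectionScheme: how the gel or strip is cut
#'
#' Partition of the separation plane (or strip) into sections by half-open
#' intervals.  \code{grid96} is an 8 Mw-row by 12 pI-column grid; \code{strip36}
#' is a single row of 36 equal 0.5 cm sections over an 18 cm strip; custom
#' boundaries may be supplied.  Column boundaries are in strip position (cm),
#' row boundaries in relative migration.
#'
#' @slot mode \code{"grid96"}, \code{"strip36"} or \code{"custom"}.
#' @slot nRows,nCols section grid dimensions.
#' @slot rowBounds numeric vector of length nRows + 1 (migration units).
#' @slot colBounds numeric vector of length nCols + 1 (cm).
#' @name SectionScheme-class
#' @aliases SectionScheme-class
#' @exportClass SectionScheme
setClass("SectionScheme", representation(
  mode = "character", nRows = "integer", nCols = "integer",
  rowBounds = "numeric", colBounds = "numeric"
))

setValidity("SectionScheme", function(object) {
  msg <- character(0)
  if (length(object@colBounds) != object@nCols + 1L)
    msg <- c(msg, "colBounds must have nCols + 1 entries")
  if (object@nRows > 1L && length(object@rowBounds) != object@nRows + 1L)
    msg <- c(msg, "rowBounds must have nRows + 1 entries")
  if (any(diff(object@colBounds) <= 0))
    msg <- c(msg, "colBounds must strictly increase")
  if (length(object@rowBounds) > 1L && any(diff(object@rowBounds) <= 0))
    msg <- c(msg, "rowBounds must strictly increase")
  if (length(msg)) msg else TRUE
})

#' Pattern2DE: a set of virtual spots
#'
#' The central output object: one virtual spot per (protein, section), each
#' carrying the section's pI window, an Mw value (theoretical chain mass in
#' semi-virtual mode, section mid-Mw in sectional mode) and the emPAI measured
#' in that section.
#'
#' @slot spots data.frame with columns \code{accession}, \code{row}, \code{col}
#'   (0-based section indices), \code{pi_low}, \code{pi_high}, \code{mw},
#'   \code{empai}.
#' @slot scheme the \linkS4class{SectionScheme} shared by all spots.
#' @slot provenance named list of run metadata.
#' @name Pattern2DE-class
#' @aliases Pattern2DE-class
#' @exportClass Pattern2DE
setClass("Pattern2DE", representation(
  spots = "data.frame", scheme = "SectionScheme", provenance = "list"
))

setValidity("Pattern2DE", function(object) {
  sp <- object@spots
  need <- c("accession", "row", "col", "pi_low", "pi_high", "mw", "empai")
  if (!all(need %in% names(sp)))
    return(paste("spots must have columns:", paste(need, collapse = ", ")))
  if (nrow(sp)) {
    if (anyDuplicated(sp[c("accession", "row", "col")]))
      return("at most one spot per (accession, section)")
    if (any(sp$empai < 0)) return("emPAI must be non-negative")
    if (any(sp$row < 0L) || any(sp$row >= object@scheme@nRows) ||
        any(sp$col < 0L) || any(sp$col >= object@scheme@nCols))
      return("spot section indices outside the scheme")
  }
  TRUE
})
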