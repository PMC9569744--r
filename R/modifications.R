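#' Construct modification objects
#'
#' Constructors for the modification kinds the package models.  Each returns a
#' \linkS4class{Modification} carrying \code{count} copies, the total mass it
#' adds on both mass scales, and its effect on the ionizable-group inventory:
#' \describe{
#'   \item{\code{modPhospho}}{each phosphate adds 79.98 Da (average) and two
#'     acidic groups (pKa 1.2 and 6.5).}
#'   \item{\code{modAcetyl}}{each acetyl adds 42.04 Da and removes one lysine
#'     amine (pKa of the active set's K).}
#'   \item{\code{modOxidation}, \code{modCarbamidomethyl}}{mass only.}
#'   \item{\code{modGlycan}}{mass from the monomer composition (average
#'     residue masses Hex 162.14, HexNAc 203.20, NeuAc 291.26, Fuc 146.14);
#'     each NeuAc additionally contributes one acidic group (pKa 2.6).
#'     Neutral sugars change mass only.}
#' }
#'
#' @param count number of copies (non-negative integer).
#' @param Hex,HexNAc,NeuAc,Fuc monosaccharide counts of one glycan.
#' @param pka pKa set used to identify the lysine pKa removed by acetylation.
#' @return a \linkS4class{Modification}.
#' @examples
#' modPhospho(2)
#' modGlycan(Hex = 5, HexNAc = 4, NeuAc = 2)
#' @name modifications
NULL

.newMod <- function(kind, count, dAvg, dMono, ionizable = NULL, glycan = integer(0)) {
  count <- as.integer(count)
  if (is.na(count) || count < 0L) stop("count must be a non-negative integer")
  if (is.null(ionizable))
    ionizable <- data.frame(group = character(0), pKa = numeric(0),
                            copies = numeric(0))
  new("Modification", kind = kind, count = count,
      glycanComposition = glycan,
      massDeltaAvg = count * dAvg, massDeltaMono = count * dMono,
      ionizable = ionizable)
}

#' @rdname modifications
#' @export
modPhospho <- function(count = 1L) {
  count <- as.integer(count)
  ion <- if (count > 0L)
    data.frame(group = "acidic", pKa = .PHOSPHO_PKA, copies = count)
  else NULL
  .newMod("phospho", count, .MOD_MASS$phospho["avg"], .MOD_MASS$phospho["mono"],
          ion)
}

#' @rdname modifications
#' @export
modAcetyl <- function(count = 1L, pka = pkaSet()) {
  count <- as.integer(count)
  ion <- if (count > 0L)
    data.frame(group = "basic", pKa = unname(pka$side_chain["K"]),
               copies = -count)
  else NULL
  .newMod("acetyl", count, .MOD_MASS$acetyl["avg"], .MOD_MASS$acetyl["mono"],
          ion)
}

#' @rdname modifications
#' @export
modOxidation <- function(count = 1L)
  .newMod("oxidation", count, .MOD_MASS$oxidation["avg"],
          .MOD_MASS$oxidation["mono"])

#' @rdname modifications
#' @export
modCarbamidomethyl <- function(count = 1L)
  .newMod("carbamidomethyl", count, .MOD_MASS$carbamidomethyl["avg"],
          .MOD_MASS$carbamidomethyl["mono"])

#' @rdname modifications
#' @export
modGlycan <- function(Hex = 0L, HexNAc = 0L, NeuAc = 0L, Fuc = 0L) {
  comp <- c(Hex = as.integer(Hex), HexNAc = as.integer(HexNAc),
            NeuAc = as.integer(NeuAc), Fuc = as.integer(Fuc))
  if (any(is.na(comp)) || any(comp < 0L))
    stop("glycan composition counts must be non-negative integers")
  dAvg <- sum(comp * .GLYCAN_MASS_AVG[names(comp)])
  dMono <- sum(comp * .GLYCAN_MASS_MONO[names(comp)])
  ion <- if (comp[["NeuAc"]] > 0L)
    data.frame(group = "acidic", pKa = .NEUAC_PKA, copies = comp[["NeuAc"]])
  else NULL
  m <- .newMod("glyco", 1L, dAvg, dMono, ion, glycan = comp)
  m
}
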