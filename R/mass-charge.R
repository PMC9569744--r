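#' Molecular mass of a (modified) polypeptide
#'
#' Sum of residue masses on the selected mass scale, plus one water, plus the
#' mass deltas of any modifications.  Average masses are the scale used for
#' gel coordinates throughout the package; monoisotopic masses serve
#' peptide-level bookkeeping.
#'
#' @param sequence one-letter amino-acid string (20 canonical residues only;
#'   B, Z, X, U, O are rejected rather than approximated, since silent mass
#'   errors would corrupt the Mw axis).
#' @param mods list of \linkS4class{Modification} objects (default none).
#' @param kind \code{"average"} (default) or \code{"monoisotopic"}.
#' @return mass in Da.
#' @examples
#' proteinMass("G")                      # glycine, 75.07 Da
#' proteinMass("GG")                     # 132.12 Da: two residues + one water
#' proteinMass("PEPTIDE", kind = "monoisotopic")
#' @export
proteinMass <- function(sequence, mods = list(),
                        kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  aa <- .checkSequence(sequence)
  mods <- .asModList(mods)
  if (kind == "average") {
    m <- sum(.AA_MASS_AVG[aa]) + .WATER_AVG
    m + sum(vapply(mods, function(x) x@massDeltaAvg, numeric(1)))
  } else {
    m <- sum(.AA_MASS_MONO[aa]) + .WATER_MONO
    m + sum(vapply(mods, function(x) x@massDeltaMono, numeric(1)))
  }
}

.asModList <- function(mods) {
  if (is(mods, "Modification")) return(list(mods))
  if (!is.list(mods)) stop("mods must be a list of Modification objects")
  for (m in mods)
    if (!is(m, "Modification")) stop("mods must contain Modification objects")
  mods
}

## Inventory of ionizable groups of a modified chain: data.frame
## (group = acidic|basic, pKa, n).  Modification deltas are merged by
## (group, pKa); negative deltas (lysine acetylation) must not overdraw.
.ionizableGroups <- function(aa, mods, pka) {
  counts <- table(factor(aa, levels = .CANONICAL_AA))
  grp <- data.frame(group = character(0), pKa = numeric(0), n = numeric(0))
  add <- function(group, pKa, nn) {
    if (nn == 0) return()
    grp <<- rbind(grp, data.frame(group = group, pKa = pKa, n = nn))
  }
  ## termini
  ntk <- pka$nterm
  add("basic", unname(if (aa[1] %in% names(ntk)) ntk[aa[1]] else ntk["default"]), 1)
  add("acidic", unname(pka$cterm["default"]), 1)
  ## side chains (position independent)
  for (res in pka$acidic)
    add("acidic", unname(pka$side_chain[res]), counts[[res]])
  for (res in pka$basic)
    add("basic", unname(pka$side_chain[res]), counts[[res]])
  ## modification deltas
  for (m in mods) {
    d <- m@ionizable
    if (nrow(d))
      grp <- rbind(grp, data.frame(group = d$group, pKa = d$pKa, n = d$copies))
  }
  grp <- stats::aggregate(n ~ group + pKa, grp, sum)
  if (any(grp$n < 0))
    stop("modifications remove more ionizable groups than the sequence has ",
         sprintf("(e.g. %.2f copies at pKa %.2f)",
                 grp$n[grp$n < 0][1], grp$pKa[grp$n < 0][1]))
  grp[grp$n > 0, , drop = FALSE]
}

#' Net charge of a (modified) polypeptide at a given pH
#'
#' Henderson-Hasselbalch net charge: basic groups contribute
#' \eqn{n/(1+10^{pH-pKa})}, acidic groups \eqn{-n/(1+10^{pKa-pH})}, with both
#' termini included and modification-induced groups merged in (phosphate: two
#' acidic groups, pKa 1.2 and 6.5; sialic acid: one acidic group, pKa 2.6;
#' lysine acetylation: one lysine amine removed).
#'
#' @inheritParams proteinMass
#' @param pH pH value(s) in [0, 14]; vectorized.
#' @param pka a pKa set from \code{\link{pkaSet}}.
#' @return signed net charge in elementary units, same length as \code{pH}.
#' @examples
#' netCharge("G", pH = 0)        # +1: both groups protonated
#' netCharge("G", pH = 3.55)     # +0.5: carboxyl half ionized
#' @export
netCharge <- function(sequence, mods = list(), pH, pka = pkaSet()) {
  if (any(pH < 0 | pH > 14)) stop("pH must lie in [0, 14]")
  aa <- .checkSequence(sequence)
  grp <- .ionizableGroups(aa, .asModList(mods), pka)
  b <- grp$group == "basic"
  q <- rep(0, length(pH))
  if (any(b))                            # groups x pH outer products
    q <- q + colSums(grp$n[b] / (1 + 10^outer(-grp$pKa[b], pH, "+")))
  if (any(!b))
    q <- q - colSums(grp$n[!b] / (1 + 10^outer(grp$pKa[!b], -pH, "+")))
  q
}

#' Isoelectric point by bisection
#'
#' The pI is the unique root of \code{\link{netCharge}} on [0, 14], located by
#' bisection to a tolerance of 1e-4 pH units.  Net charge is strictly
#' decreasing in pH, so the root is unique whenever the molecule carries at
#' least one acidic and one basic group; otherwise no sign change exists and
#' an error is raised.
#'
#' For comparisons against published tables, round the result to 2 decimals.
#'
#' @inheritParams netCharge
#' @param tol bisection tolerance in pH units.
#' @return pI in pH units (unrounded).
#' @examples
#' isoelectricPoint("G")   # (3.55 + 7.50) / 2 for the Bjellqvist set
#' @export
isoelectricPoint <- function(sequence, mods = list(), pka = pkaSet(),
                             tol = 1e-4) {
  aa <- .checkSequence(sequence)
  mods <- .asModList(mods)
  grp <- .ionizableGroups(aa, mods, pka)
  if (!any(grp$group == "acidic") || !any(grp$group == "basic"))
    stop("no isoelectric point: molecule needs at least one acidic and one ",
         "basic ionizable group")
  f <- function(p) netCharge(sequence, mods, p, pka)
  lo <- 0; hi <- 14
  flo <- f(lo); fhi <- f(hi)
  if (flo <= 0 || fhi >= 0)
    stop("no isoelectric point: net charge does not change sign on [0, 14]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
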