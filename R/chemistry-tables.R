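## Residue-level physical constants and pKa tables.
##
## Average residue masses follow the ExPASy Compute pI/Mw tables; monoisotopic
## masses are the standard unimod residue values.  Both are residue (dehydrated)
## masses: a chain mass is the residue sum plus one water.

.CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.AA_MASS_AVG <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.AA_MASS_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276, V =  99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER_AVG  <- 18.01524
.WATER_MONO <- 18.0105646863

## Average monosaccharide residue masses (glycosidic-bond, dehydrated).
.GLYCAN_MASS_AVG <- c(Hex = 162.14, HexNAc = 203.20, NeuAc = 291.26, Fuc = 146.14)
.GLYCAN_MASS_MONO <- c(Hex = 162.05282, HexNAc = 203.07937,
                       NeuAc = 291.09542, Fuc = 146.05791)

## Common PTM mass deltas (additive).
.MOD_MASS <- list(
  phospho          = c(avg = 79.9799, mono = 79.96633),
  oxidation        = c(avg = 15.9994, mono = 15.99491),
  acetyl           = c(avg = 42.0367, mono = 42.01057),
  carbamidomethyl  = c(avg = 57.0513, mono = 57.02146)
)

## Side-chain pKa of a phosphate group: first and second ionization.
.PHOSPHO_PKA <- c(1.2, 6.5)
## Carboxyl pKa of N-acetylneuraminic (sialic) acid.
.NEUAC_PKA <- 2.6

#' Ionization constants for isoelectric-point computation
#'
#' Returns one of three published pKa tables used for protein net-charge and
#' isoelectric-point computation.  The Bjellqvist set (default throughout the
#' package) uses the Bjellqvist side-chain values with residue-specific
#' N-terminal amine pKas and a uniform alpha-carboxyl pKa of 3.55; side-chain
#' pKas are position independent.  This is the convention that reproduces the
#' published reference pI values of the packaged plasma-protein chains.  The
#' EMBOSS and Lehninger sets are provided for sensitivity checks.
#'
#' @param name one of \code{"bjellqvist"}, \code{"emboss"}, \code{"lehninger"}.
#' @return A list with components \code{name}, \code{side_chain} (named vector,
#'   acidic pKas for D, E, C, Y and basic for H, K, R), \code{acidic}/\code{basic}
#'   (the residue letters in each class), \code{nterm} (named vector of
#'   residue-specific alpha-amino pKas plus \code{default}) and \code{cterm}
#'   (alpha-carboxyl \code{default}).
#' @examples
#' pkaSet()$side_chain[["D"]]
#' @export
pkaSet <- function(name = c("bjellqvist", "emboss", "lehninger")) {
  name <- match.arg(name)
  switch(name,
    bjellqvist = list(
      name = "bjellqvist",
      side_chain = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00,
                     H = 5.98, K = 10.00, R = 12.00),
      acidic = c("D", "E", "C", "Y"),
      basic  = c("H", "K", "R"),
      nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.70, G = 7.50, default = 7.50),
      cterm = c(default = 3.55)
    ),
    emboss = list(
      name = "emboss",
      side_chain = c(D = 3.90, E = 4.10, C = 8.50, Y = 10.10,
                     H = 6.50, K = 10.80, R = 12.50),
      acidic = c("D", "E", "C", "Y"),
      basic  = c("H", "K", "R"),
      nterm = c(default = 8.60),
      cterm = c(default = 3.60)
    ),
    lehninger = list(
      name = "lehninger",
      side_chain = c(D = 3.86, E = 4.25, C = 8.33, Y = 10.07,
                     H = 6.00, K = 10.53, R = 12.48),
      acidic = c("D", "E", "C", "Y"),
      basic  = c("H", "K", "R"),
      nterm = c(default = 9.69),
      cterm = c(default = 2.34)
    )
  )
}

## Validate a sequence string; returns the vector of residues or stops with the
## position of the first offending character.
.checkSequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L)
    stop("sequence must be a single non-empty character string")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(aa %in% .CANONICAL_AA))
  if (length(bad))
    stop(sprintf("non-canonical residue '%s' at position %d", aa[bad[1]], bad[1]))
  aa
}
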