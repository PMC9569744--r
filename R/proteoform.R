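#' Create a protein record
#'
#' @param accession UniProt-style accession.
#' @param sequence precursor amino-acid sequence (canonical alphabet).
#' @param entryName optional UniProt entry name.
#' @param chains data.frame with columns \code{name}, \code{start}, \code{end}
#'   (1-based inclusive); default one chain \code{"full"} spanning the
#'   sequence.
#' @param siteCounts optional named integer vector of annotatable modification
#'   sites per kind (e.g. \code{c(phospho = 3)}); used to bound proteoform
#'   construction.
#' @return a \linkS4class{ProteinRecord}.
#' @examples
#' rec <- proteinRecord("P1", "MKWVTFISLLFLFSSAYS",
#'                      chains = data.frame(name = "mature", start = 2,
#'                                          end = 18))
#' chainSequence(rec, "mature")
#' @export
proteinRecord <- function(accession, sequence, entryName = "",
                          chains = NULL, siteCounts = integer(0)) {
  if (is.null(chains))
    chains <- data.frame(name = "full", start = 1L,
                         end = nchar(sequence))
  chains$start <- as.integer(chains$start)
  chains$end <- as.integer(chains$end)
  new("ProteinRecord", accession = accession, entryName = entryName,
      sequence = toupper(sequence), chains = chains,
      siteCounts = structure(as.integer(siteCounts),
                             names = names(siteCounts)))
}

#' Extract a chain subsequence from a record
#'
#' @param record a \linkS4class{ProteinRecord}.
#' @param chainName name of an annotated chain.
#' @return the chain's amino-acid string.
#' @export
chainSequence <- function(record, chainName) {
  i <- match(chainName, record@chains$name)
  if (is.na(i))
    stop(sprintf("unknown chain '%s' in record %s (has: %s)", chainName,
                 record@accession, paste(record@chains$name, collapse = ", ")))
  substr(record@sequence, record@chains$start[i], record@chains$end[i])
}

#' Construct a proteoform and compute its coordinates
#'
#' Builds the molecular species "chain of \code{record} carrying \code{mods}"
#' and computes its isoelectric point and average molecular mass.  When the
#' record carries \code{siteCounts} for a modification kind, requesting more
#' copies than annotated sites is an error.
#'
#' @inheritParams chainSequence
#' @param mods list of \linkS4class{Modification} objects.
#' @param pka pKa set for the pI computation (default Bjellqvist).
#' @param abundanceWeight optional ensemble weight in [0, 1].
#' @return a \linkS4class{Proteoform}.
#' @examples
#' rec <- proteinRecord("X1", "MADSEKHHALKRGGW",
#'                      chains = data.frame(name = "m", start = 2, end = 15))
#' pf <- makeProteoform(rec, "m", list(modPhospho(1)))
#' piValue(pf); mwValue(pf)
#' @export
makeProteoform <- function(record, chainName, mods = list(),
                           pka = pkaSet(), abundanceWeight = numeric(0)) {
  mods <- .asModList(mods)
  if (length(record@siteCounts)) {
    for (m in mods) {
      avail <- record@siteCounts[m@kind]
      if (!is.na(avail) && m@count > avail)
        stop(sprintf("%d %s copies requested but only %d annotated site(s) in %s",
                     m@count, m@kind, avail, record@accession))
    }
  }
  seq <- chainSequence(record, chainName)
  new("Proteoform", parent = record@accession, chainName = chainName,
      sequence = seq, mods = mods,
      pI = isoelectricPoint(seq, mods, pka),
      mw = proteinMass(seq, mods, "average"),
      abundanceWeight = abundanceWeight)
}

#' Theoretical pI/Mw table for annotated chains
#'
#' Convenience wrapper computing the unmodified theoretical coordinates of
#' every annotated chain of one or more records, the quantities printed in
#' virtual 2DE reference tables (pI rounded to 2 decimals, Mw in Da).
#'
#' @param records a \linkS4class{ProteinRecord} or list of them.
#' @param pka pKa set (default Bjellqvist).
#' @return data.frame with columns \code{accession}, \code{chain},
#'   \code{length}, \code{pI} (2 decimals), \code{mw} (unrounded Da).
#' @export
theoreticalPiMw <- function(records, pka = pkaSet()) {
  if (is(records, "ProteinRecord")) records <- list(records)
  out <- do.call(rbind, lapply(records, function(rec) {
    do.call(rbind, lapply(rec@chains$name, function(cn) {
      s <- chainSequence(rec, cn)
      data.frame(accession = rec@accession, chain = cn, length = nchar(s),
                 pI = round(isoelectricPoint(s, pka = pka), 2),
                 mw = proteinMass(s))
    }))
  }))
  rownames(out) <- NULL
  out
}
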