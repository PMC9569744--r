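#' Count distinct identified peptides
#'
#' The emPAI numerator: the number of distinct peptide sequences identified
#' for an accession within one section.  Modification state is collapsed by
#' default (a peptide with and without oxidation counts once), so that heavily
#' modified proteoforms are not inflated; set
#' \code{collapseMods = FALSE} to count modified forms separately.
#'
#' @param psm PSM data.frame with columns \code{section_id}, \code{accession},
#'   \code{peptide}, \code{mods} (rows are assumed to have passed score
#'   gating).
#' @param accession protein accession to count for.
#' @param sectionId section to count in.
#' @param collapseMods collapse modification states (default \code{TRUE}).
#' @return integer count of distinct peptides.
#' @export
countObserved <- function(psm, accession, sectionId, collapseMods = TRUE) {
  rows <- psm[psm$accession == accession & psm$section_id == sectionId, ,
              drop = FALSE]
  if (!nrow(rows)) return(0L)
  key <- toupper(rows$peptide)
  if (!collapseMods) key <- paste(key, rows$mods, sep = "|")
  length(unique(key))
}

#' Exponentially modified protein abundance index
#'
#' PAI is the number of identified peptides divided by the number of
#' theoretically observable tryptic peptides; emPAI is its exponential form,
#' \eqn{10^{PAI} - 1}, approximately proportional to the protein's molar
#' amount.
#'
#' @param nObs identified distinct peptides (numerator); vectorized.
#' @param nObsbl theoretically observable peptides (denominator, >= 1).
#' @return data.frame with columns \code{pai} and \code{empai}.
#' @examples
#' emPAI(10, 20)    # pai 0.5, empai 10^0.5 - 1 = 2.1623
#' @export
emPAI <- function(nObs, nObsbl) {
  if (any(nObsbl < 1))
    stop("protein has no observable peptides (nObsbl = 0): emPAI undefined")
  if (any(nObs < 0)) stop("nObs must be non-negative")
  pai <- nObs / nObsbl
  data.frame(pai = pai, empai = 10^pai - 1)
}

#' Apply the identification acceptance filters
#'
#' Implements the identification rule used for all protein identifications:
#' a protein is accepted only if it has at least \code{minUnique} distinct
#' unique peptides (peptides mapping to a single accession in the searched
#' database) with scores passing the confidence threshold.
#'
#' @param psm PSM data.frame with columns \code{accession}, \code{peptide},
#'   \code{score}, \code{is_unique} (and \code{section_id} when
#'   \code{per = "section"}).
#' @param minUnique minimum distinct unique peptides (default 2).
#' @param scoreThreshold minimum score; rows below are ignored.
#' @param per \code{"section"} (default) evaluates the rule within each
#'   section, as each section is a separate identification experiment;
#'   \code{"run"} evaluates it over the whole table.
#' @return for \code{per = "run"} a character vector of accepted accessions;
#'   for \code{per = "section"} a data.frame with columns \code{section_id},
#'   \code{accession} of accepted pairs.
#' @export
acceptProteins <- function(psm, minUnique = 2L, scoreThreshold = 0,
                           per = c("section", "run")) {
  per <- match.arg(per)
  ok <- psm[psm$score >= scoreThreshold & psm$is_unique, , drop = FALSE]
  if (per == "run") {
    if (!nrow(ok)) return(character(0))
    n <- tapply(toupper(ok$peptide), ok$accession,
                function(p) length(unique(p)))
    return(sort(names(n)[n >= minUnique]))
  }
  if (!nrow(ok))
    return(data.frame(section_id = character(0), accession = character(0)))
  agg <- stats::aggregate(peptide ~ section_id + accession, ok,
                          function(p) length(unique(toupper(p))))
  acc <- agg[agg$peptide >= minUnique, c("section_id", "accession")]
  acc <- acc[order(acc$section_id, acc$accession), , drop = FALSE]
  rownames(acc) <- NULL
  acc
}

#' Per-section protein quantification table
#'
#' Runs the full quantification step: gate PSMs by score, apply the
#' unique-peptide acceptance rule, count distinct identified peptides per
#' (accession, section), and compute PAI and emPAI against the supplied
#' observable-peptide counts.
#'
#' @inheritParams acceptProteins
#' @param nObsbl named integer vector, accession -> number of theoretically
#'   observable tryptic peptides.
#' @param collapseMods collapse modification states when counting (see
#'   \code{\link{countObserved}}).
#' @return data.frame with columns \code{accession}, \code{section_id},
#'   \code{n_obs}, \code{n_obsbl}, \code{pai}, \code{empai}.
#' @export
proteinQuantTable <- function(psm, nObsbl, minUnique = 2L, scoreThreshold = 0,
                              per = c("section", "run"),
                              collapseMods = TRUE) {
  per <- match.arg(per)
  gated <- psm[psm$score >= scoreThreshold, , drop = FALSE]
  if (per == "run") {
    keep <- acceptProteins(psm, minUnique, scoreThreshold, per = "run")
    gated <- gated[gated$accession %in% keep, , drop = FALSE]
  } else {
    acc <- acceptProteins(psm, minUnique, scoreThreshold, per = "section")
    gated <- merge(gated, acc, by = c("section_id", "accession"))
  }
  if (!nrow(gated))
    return(data.frame(accession = character(0), section_id = character(0),
                      n_obs = integer(0), n_obsbl = integer(0),
                      pai = numeric(0), empai = numeric(0)))
  missing <- setdiff(unique(gated$accession), names(nObsbl))
  if (length(missing))
    stop("no observable-peptide count for accession(s): ",
         paste(missing, collapse = ", "))
  pairs <- unique(gated[c("accession", "section_id")])
  pairs <- pairs[order(pairs$accession, pairs$section_id), , drop = FALSE]
  pairs$n_obs <- mapply(function(a, s)
    countObserved(gated, a, s, collapseMods), pairs$accession,
    pairs$section_id)
  pairs$n_obsbl <- as.integer(nObsbl[pairs$accession])
  q <- emPAI(pairs$n_obs, pairs$n_obsbl)
  pairs$pai <- q$pai
  pairs$empai <- q$empai
  rownames(pairs) <- NULL
  pairs
}

#' Normalize emPAI values to molar percentages
#'
#' @param empai non-negative emPAI values, at least one positive.
#' @return percentages summing to 100.
#' @export
molarFraction <- function(empai) {
  if (any(empai < 0)) stop("emPAI values must be non-negative")
  s <- sum(empai)
  if (s == 0) stop("all emPAI values are zero: molar fractions undefined")
  empai / s * 100
}
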