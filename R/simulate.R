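## Run a function under a local, explicitly seeded RNG stream, restoring any
## global RNG state afterwards: all simulator randomness flows from one seed.
.withSeed <- function(seed, expr) {
  force(seed)   # must precede the state snapshot: seed may draw from the RNG
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Simulate a proteoform spot train
#'
#' Enumerates the proteoform ensemble of one chain under a simple PTM model:
#' \code{nPhosphoSites} phosphorylation sites occupied independently with
#' probability \code{occupancy} (so the phosphate count k = 0..n carries
#' binomial(n, occupancy) weight), crossed with a discrete set of glycoforms
#' with given weights.  Each species' pI and Mw are computed from the chain
#' plus its modifications; weights multiply and sum to 1.  Charge-altering
#' modifications (phosphate, sialic acid) shift successive species to lower
#' pI, producing the characteristic acidic spot train.
#'
#' @param record a \linkS4class{ProteinRecord}.
#' @param chainName chain to modify.
#' @param nPhosphoSites number of phosphorylation sites (>= 0).
#' @param occupancy per-site phosphorylation probability in [0, 1].
#' @param glycoforms list of \code{list(glycan = modGlycan(...) or NULL,
#'   weight = w)}; weights must sum to 1.  Default: one unglycosylated form.
#' @param pka pKa set for pI computation.
#' @return list of \linkS4class{Proteoform} objects with abundance weights;
#'   see \code{\link{ensembleTable}} for a tabular view.
#' @examples
#' rec <- proteinRecord("X1", "MADSEKHHALKRGGWSSTK")
#' tr <- simulateTrain(rec, "full", nPhosphoSites = 2, occupancy = 0.5)
#' ensembleTable(tr)
#' @export
simulateTrain <- function(record, chainName, nPhosphoSites = 0L,
                          occupancy = 0.5, glycoforms = NULL,
                          pka = pkaSet()) {
  if (occupancy < 0 || occupancy > 1) stop("occupancy must lie in [0, 1]")
  nPhosphoSites <- as.integer(nPhosphoSites)
  if (is.null(glycoforms))
    glycoforms <- list(list(glycan = NULL, weight = 1))
  gw <- vapply(glycoforms, function(g) g$weight, numeric(1))
  if (abs(sum(gw) - 1) > 1e-8) stop("glycoform weights must sum to 1")
  out <- list()
  for (k in 0:nPhosphoSites) {
    wk <- stats::dbinom(k, nPhosphoSites, occupancy)
    for (g in glycoforms) {
      mods <- list()
      if (k > 0L) mods <- c(mods, modPhospho(k))
      if (!is.null(g$glycan)) mods <- c(mods, list(g$glycan))
      w <- wk * g$weight
      if (w == 0) next
      out[[length(out) + 1L]] <- makeProteoform(
        record, chainName, mods, pka, abundanceWeight = w)
    }
  }
  out
}

#' Tabular view of a proteoform ensemble
#'
#' @param ensemble list of \linkS4class{Proteoform} objects (e.g. from
#'   \code{\link{simulateTrain}}).
#' @return data.frame with \code{accession}, \code{chain}, \code{n_phospho},
#'   \code{n_neuac}, \code{pI}, \code{mw}, \code{weight}.
#' @export
ensembleTable <- function(ensemble) {
  do.call(rbind, lapply(ensemble, function(p) {
    np <- sum(vapply(p@mods, function(m)
      if (m@kind == "phospho") m@count else 0L, integer(1)))
    ns <- sum(vapply(p@mods, function(m)
      if (m@kind == "glyco") m@glycanComposition[["NeuAc"]] else 0L,
      integer(1)))
    data.frame(accession = p@parent, chain = p@chainName, n_phospho = np,
               n_neuac = ns, pI = p@pI, mw = p@mw,
               weight = abundanceWeight(p))
  }))
}

#' Expected per-section quantification of an ensemble
#'
#' The noise-free forward model: each species is placed in the section
#' containing its pI; within a section the expected number of distinct
#' observed peptides is \code{min(nObsbl, depth * weight * nObsbl)} summed
#' over co-locating species (capped at saturation), and the expected emPAI
#' follows from the PAI formula.
#'
#' @param ensemble list of \linkS4class{Proteoform} objects with weights.
#' @param scheme single-row \linkS4class{SectionScheme}.
#' @param axis \linkS4class{PiAxis} calibrating the strip.
#' @param depth expected peptide observations per unit abundance weight,
#'   relative to saturation.
#' @param nObsbl observable-peptide count of the chain.
#' @return data.frame with \code{accession}, \code{section_id},
#'   \code{expected_n}, \code{empai}.
#' @export
expectedQuant <- function(ensemble, scheme, axis, depth, nObsbl) {
  tab <- ensembleTable(ensemble)
  pos <- phToPosition(axis, tab$pI)
  loc <- locateSection(scheme, pos)
  tab$section_id <- ifelse(loc$off_gel, NA_character_,
                           sectionId(scheme, loc$row, loc$col))
  tab <- tab[!is.na(tab$section_id), , drop = FALSE]
  lam <- stats::aggregate(weight ~ accession + section_id, tab, sum)
  lam$expected_n <- pmin(nObsbl, depth * lam$weight * nObsbl)
  lam$empai <- 10^(lam$expected_n / nObsbl) - 1
  lam[order(lam$accession, lam$section_id),
      c("accession", "section_id", "expected_n", "empai")]
}

#' Simulate a per-section peptide identification table
#'
#' The stochastic forward model used to test the reconstruction end to end.
#' For each proteoform species: its pI receives Gaussian focusing jitter
#' (\code{jitterSD}, pH units) and is located to a strip section; the number
#' of distinct observed peptides is drawn as
#' \code{min(nObsbl, Poisson(depth * weight * nObsbl))}; that many peptides
#' are sampled without replacement from the chain's observable fully cleaved
#' peptides and emitted as PSM rows.  Species focused outside the calibrated
#' range are counted as off-gel, not silently dropped.  A fixed seed yields
#' byte-identical output.
#'
#' @param ensemble list of \linkS4class{Proteoform} objects with weights.
#' @param scheme single-row \linkS4class{SectionScheme}.
#' @param axis \linkS4class{PiAxis}.
#' @param depth expected observations per unit abundance (must be > 0).
#' @param jitterSD Gaussian pI jitter standard deviation in pH units
#'   (default 0.05, emulating focusing imperfection).
#' @param seed integer seed; all randomness flows from it.
#' @param window observability window used to define the samplable peptides.
#' @return list with \code{psm} (a PSM data.frame: section_id, accession,
#'   peptide, mods, score, is_unique), \code{n_obsbl} (named vector),
#'   \code{expected} (the jitter-free \code{\link{expectedQuant}} table) and
#'   \code{off_gel} (species count that focused off the calibrated range).
#' @export
simulateSectionTable <- function(ensemble, scheme, axis, depth = 5,
                                 jitterSD = 0.05, seed = 1L,
                                 window = observabilityWindow()) {
  if (depth <= 0) stop("depth must be positive")
  if (jitterSD < 0) stop("jitterSD must be non-negative")
  tab <- ensembleTable(ensemble)
  chains <- unique(tab[c("accession", "chain")])
  if (nrow(chains) != length(unique(chains$accession)))
    stop("one chain per accession is assumed in the simulator")
  seqs <- vapply(ensemble, function(p) p@sequence, character(1))
  names(seqs) <- tab$accession
  obsPeps <- lapply(split(seqs, names(seqs)), function(s) {
    unique(observablePeptides(digestTryptic(s[[1]], maxMissed = 0L),
                              window)$sequence)
  })
  nObsbl <- vapply(obsPeps, length, integer(1))
  if (any(nObsbl == 0L))
    stop("chain with no observable peptides: ",
         paste(names(nObsbl)[nObsbl == 0L], collapse = ", "))
  res <- .withSeed(seed, {
    rows <- list()
    offGel <- 0L
    for (i in seq_len(nrow(tab))) {
      w <- tab$weight[i]
      if (w == 0) next
      acc <- tab$accession[i]
      piJ <- tab$pI[i] + stats::rnorm(1, 0, jitterSD)
      pos <- tryCatch(phToPosition(axis, piJ), error = function(e) NA_real_)
      if (is.na(pos)) { offGel <- offGel + 1L; next }
      loc <- locateSection(scheme, pos)
      if (loc$off_gel) { offGel <- offGel + 1L; next }
      nObs <- min(nObsbl[[acc]], stats::rpois(1, depth * w * nObsbl[[acc]]))
      if (nObs == 0L) next
      peps <- sample(obsPeps[[acc]], nObs, replace = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        section_id = sectionId(scheme, loc$row, loc$col), accession = acc,
        peptide = peps, mods = "", score = 100, is_unique = TRUE)
    }
    list(rows = rows, offGel = offGel)
  })
  psm <- if (length(res$rows)) do.call(rbind, res$rows)
  else data.frame(section_id = character(0), accession = character(0),
                  peptide = character(0), mods = character(0),
                  score = numeric(0), is_unique = logical(0))
  ## distinct peptides per (accession, section): co-locating species may have
  ## drawn the same peptide
  psm <- unique(psm)
  psm <- psm[order(psm$section_id, psm$accession, psm$peptide), , drop = FALSE]
  rownames(psm) <- NULL
  expected <- do.call(rbind, lapply(split(tab, tab$accession), function(tt) {
    acc <- tt$accession[1]
    ens <- ensemble[tab$accession == acc]
    expectedQuant(ens, scheme, axis, depth, nObsbl[[acc]])
  }))
  rownames(expected) <- NULL
  list(psm = psm, n_obsbl = nObsbl, expected = expected,
       off_gel = res$offGel)
}

#' Recovery metrics of a reconstruction against simulated ground truth
#'
#' For each protein: the emPAI-weighted pI centroid of the reconstructed
#' spots versus the weight-averaged true pI; the set of truth-occupied
#' sections recovered; and the detected versus true train width in sections.
#'
#' @param pattern reconstructed \linkS4class{Pattern2DE}.
#' @param ensemble the simulated ground-truth proteoform list.
#' @param scheme,axis the sectioning scheme and pI axis used throughout.
#' @return data.frame with one row per accession: \code{centroid_pi},
#'   \code{true_centroid_pi}, \code{centroid_error}, \code{n_true_sections},
#'   \code{n_recovered}, \code{recovered_fraction}, \code{width_detected},
#'   \code{width_true}.
#' @export
recoveryReport <- function(pattern, ensemble, scheme, axis) {
  tab <- ensembleTable(ensemble)
  tab <- tab[tab$weight > 0, , drop = FALSE]
  loc <- locateSection(scheme, phToPosition(axis, tab$pI))
  tab$col <- loc$col
  sp <- pattern@spots
  do.call(rbind, lapply(split(tab, tab$accession), function(tt) {
    acc <- tt$accession[1]
    truthCols <- sort(unique(tt$col))
    mine <- sp[sp$accession == acc & sp$empai > 0, , drop = FALSE]
    recovered <- intersect(truthCols, mine$col)
    piMid <- (mine$pi_low + mine$pi_high) / 2
    cen <- if (nrow(mine)) sum(piMid * mine$empai) / sum(mine$empai)
    else NA_real_
    trueCen <- sum(tt$pI * tt$weight) / sum(tt$weight)
    data.frame(accession = acc,
               centroid_pi = cen, true_centroid_pi = trueCen,
               centroid_error = abs(cen - trueCen),
               n_true_sections = length(truthCols),
               n_recovered = length(recovered),
               recovered_fraction = length(recovered) / length(truthCols),
               width_detected = if (nrow(mine))
                 diff(range(mine$col)) + 1L else 0L,
               width_true = diff(range(truthCols)) + 1L)
  }))
}
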