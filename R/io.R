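#' Read protein records from FASTA with a chain sidecar table
#'
#' Parses UniProt-style headers (\code{sp|ACCESSION|ENTRY_NAME description});
#' plain headers fall back to the first whitespace-delimited token as the
#' accession.  Chain ranges come from a sidecar tab-separated table rather
#' than UniProt feature files.
#'
#' @param path FASTA file path.
#' @param chainTable optional data.frame (or TSV path) with columns
#'   \code{accession}, \code{chain_name}, \code{start}, \code{end}; records
#'   without rows get a single \code{"full"} chain.
#' @param siteCounts optional named list accession -> named integer vector of
#'   modifiable-site counts.
#' @return named list of \linkS4class{ProteinRecord} objects.
#' @export
readProteinFasta <- function(path, chainTable = NULL, siteCounts = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("empty FASTA file: ", path)
  headers <- names(seqs)
  m <- regmatches(headers, regexec("^(sp|tr)\\|([^|]+)\\|(\\S+)", headers))
  acc <- mapply(function(h, mm) if (length(mm)) mm[3]
                else strsplit(h, "\\s+")[[1]][1], headers, m)
  entry <- vapply(m, function(mm) if (length(mm)) mm[4] else "", character(1))
  dup <- which(duplicated(acc))
  if (length(dup))
    stop(sprintf("duplicate accession '%s' (records %d and %d)",
                 acc[dup[1]], match(acc[dup[1]], acc), dup[1]))
  if (is.character(chainTable)) chainTable <- readChainTable(chainTable)
  recs <- lapply(seq_along(seqs), function(i) {
    chains <- NULL
    if (!is.null(chainTable)) {
      rows <- chainTable[chainTable$accession == acc[i], , drop = FALSE]
      if (nrow(rows))
        chains <- data.frame(name = rows$chain_name, start = rows$start,
                             end = rows$end)
    }
    sc <- siteCounts[[acc[i]]]
    proteinRecord(acc[i], as.character(seqs[[i]]), entryName = entry[i],
                  chains = chains,
                  siteCounts = if (is.null(sc)) integer(0) else sc)
  })
  names(recs) <- acc
  recs
}

#' @rdname readProteinFasta
#' @export
readChainTable <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("accession", "chain_name", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column ", miss[1], " in ", path)
  tab
}

#' Read a peptide-identification (PSM) table
#'
#' Tab-separated with a header row and \code{#}-prefixed provenance lines.
#' Mandatory columns: \code{section_id}, \code{accession}, \code{peptide},
#' \code{mods}, \code{score}, \code{is_unique}; extra columns are preserved.
#' Malformed rows (empty peptide, non-finite score) are counted and dropped
#' with a warning; if more than \code{maxMalformed} of rows are malformed the
#' read aborts.
#'
#' @param path file path.
#' @param maxMalformed maximum tolerated malformed-row fraction (default 1\%).
#' @return PSM data.frame.
#' @export
readPsmTable <- function(path, maxMalformed = 0.01) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("section_id", "accession", "peptide", "mods", "score",
            "is_unique")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column ", miss[1])
  tab$score <- suppressWarnings(as.numeric(tab$score))
  tab$is_unique <- as.logical(tab$is_unique)
  tab$mods[is.na(tab$mods)] <- ""
  bad <- !nzchar(tab$peptide) | is.na(tab$peptide) | !is.finite(tab$score) |
    is.na(tab$is_unique)
  if (any(bad)) {
    frac <- mean(bad)
    if (frac > maxMalformed)
      stop(sprintf("%d of %d rows malformed (%.1f%% > %.1f%% tolerated)",
                   sum(bad), nrow(tab), 100 * frac, 100 * maxMalformed))
    warning(sprintf("dropped %d malformed row(s)", sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

## provenance header block: "# key=value" lines
.provenanceLines <- function(provenance)
  sprintf("# %s=%s", names(provenance),
          vapply(provenance, function(v) paste(format(v), collapse = ","),
                 character(1)))

#' Write a PSM table
#'
#' @param psm PSM data.frame.
#' @param path output path.
#' @param provenance named list written as \code{# key=value} header lines.
#' @export
writePsmTable <- function(psm, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(.provenanceLines(provenance), con)
  utils::write.table(psm, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.PATTERN_FORMAT_VERSION <- 1L

#' Write / read a 2DE pattern table
#'
#' Lossless tab-separated round trip of a \linkS4class{Pattern2DE}, including
#' a provenance header block (\code{# key=value}) that records the format
#' version and the section scheme.  Residue coordinates in files are 1-based;
#' section indices are 0-based.
#'
#' @param pattern a \linkS4class{Pattern2DE}.
#' @param path file path.
#' @return \code{readPattern} returns the reconstructed
#'   \linkS4class{Pattern2DE}.
#' @export
writePattern <- function(pattern, path) {
  sc <- pattern@scheme
  head <- c(
    pattern_format_version = .PATTERN_FORMAT_VERSION,
    scheme_mode = sc@mode, n_rows = sc@nRows, n_cols = sc@nCols,
    row_bounds = paste(sprintf("%.10g", sc@rowBounds), collapse = ","),
    col_bounds = paste(sprintf("%.10g", sc@colBounds), collapse = ","))
  prov <- pattern@provenance
  prov <- prov[setdiff(names(prov), names(head))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceLines(as.list(c(head, prov))), con)
  sp <- pattern@spots
  num <- c("pi_low", "pi_high", "mw", "empai")
  sp[num] <- lapply(sp[num], function(x) sprintf("%.10g", x))
  utils::write.table(sp, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePattern
#' @export
readPattern <- function(path) {
  lines <- readLines(path)
  hl <- grep("^# ", lines, value = TRUE)
  kv <- regmatches(hl, regexec("^# ([^=]+)=(.*)$", hl))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  names(vals) <- keys
  ver <- suppressWarnings(as.integer(vals["pattern_format_version"]))
  if (is.na(ver) || ver != .PATTERN_FORMAT_VERSION)
    stop("pattern format version mismatch: file has '",
         vals["pattern_format_version"], "', reader expects ",
         .PATTERN_FORMAT_VERSION)
  scheme <- new("SectionScheme", mode = unname(vals["scheme_mode"]),
                nRows = as.integer(vals["n_rows"]),
                nCols = as.integer(vals["n_cols"]),
                rowBounds = as.numeric(strsplit(vals["row_bounds"],
                                                ",")[[1]]),
                colBounds = as.numeric(strsplit(vals["col_bounds"],
                                                ",")[[1]]))
  body <- lines[!grepl("^# ", lines)]
  sp <- if (length(body) > 1L)
    utils::read.delim(text = paste(body, collapse = "\n"),
                      stringsAsFactors = FALSE)
  else data.frame(accession = character(0), row = integer(0),
                  col = integer(0), pi_low = numeric(0),
                  pi_high = numeric(0), mw = numeric(0), empai = numeric(0))
  extra <- setdiff(keys, c("pattern_format_version", "scheme_mode", "n_rows",
                           "n_cols", "row_bounds", "col_bounds"))
  new("Pattern2DE", spots = sp, scheme = scheme,
      provenance = as.list(vals[extra]))
}

#' Read axis calibration tables
#'
#' \code{readPiAnchors} reads a tab-separated anchor table (columns
#' \code{position}, \code{pH}) into a \linkS4class{PiAxis};
#' \code{readMwMarkers} reads a marker ladder (columns \code{migration},
#' \code{mw}) into an \linkS4class{MwAxis}.
#'
#' @param path file path.
#' @param gelPercent \% acrylamide metadata for the Mw axis.
#' @return the calibrated axis object.
#' @export
readPiAnchors <- function(path)
  piAxis(utils::read.delim(path, comment.char = "#"))

#' @rdname readPiAnchors
#' @export
readMwMarkers <- function(path, gelPercent = 14)
  mwAxis(utils::read.delim(path, comment.char = "#"), gelPercent)

#' Packaged reference plasma-protein fixtures
#'
#' Loads the eight packaged human plasma protein sequences (serum albumin,
#' haptoglobin, hemoglobin alpha and beta, transthyretin, apolipoprotein
#' A-II, alpha-1-acid glycoprotein 1, C-reactive protein) with their mature
#' chain annotations, used in examples and validation.
#'
#' @return named list of \linkS4class{ProteinRecord} objects.
#' @examples
#' recs <- plasmaFixtures()
#' theoreticalPiMw(recs[["P00738"]])
#' @export
plasmaFixtures <- function() {
  readProteinFasta(
    system.file("extdata", "plasma8.fasta", package = "virtual2DE",
                mustWork = TRUE),
    system.file("extdata", "plasma8_chains.tsv", package = "virtual2DE",
                mustWork = TRUE))
}
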