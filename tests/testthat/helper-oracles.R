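## Independent oracles, deliberately written with different algorithms than
## the package implementations they check.

## Brute-force tryptic digest: enumerate every substring and keep those whose
## boundaries are cleavage boundaries and whose internal cleavage-site count
## is within the missed-cleavage budget.
oracleDigest <- function(sequence, maxMissed, keilRule = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  isCut <- function(i) {                 # TRUE if bond after position i is cut
    if (i <= 0 || i >= n) return(TRUE)   # chain ends
    aa[i] %in% c("K", "R") && !(keilRule && aa[i + 1] == "P")
  }
  out <- list()
  for (st in 1:n) for (en in st:n) {
    if (!isCut(st - 1) || !isCut(en)) next
    internal <- if (en > st) sum(vapply((st):(en - 1), isCut, logical(1)))
    else 0L
    if (internal > maxMissed) next
    out[[length(out) + 1L]] <- data.frame(
      sequence = paste(aa[st:en], collapse = ""),
      start = st, end = en, missed = internal)
  }
  do.call(rbind, out)
}

## Grid-scan isoelectric point: argmin of |net charge| over a fine pH grid.
oracleGridPI <- function(sequence, mods = list(), pka = pkaSet(),
                         step = 1e-4) {
  grid <- seq(0, 14, by = step)
  q <- netCharge(sequence, mods, grid, pka)
  grid[which.min(abs(q))]
}

## Random peptide with guaranteed acidic + basic groups.
randomPeptide <- function(len, withKR = TRUE) {
  aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE)
  paste(aa, collapse = "")
}

## Shared toy objects for map-building tests.
linearAxis18 <- function()
  piAxis(data.frame(position = c(0, 18), pH = c(3, 11)))

toyMarkers <- function()
  data.frame(migration = c(0.2, 0.8), mw = c(1e5, 1e4))
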