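#' Accessors for virtual2DE objects
#'
#' Small accessor generics: \code{accession} returns the accession of a record
#' or the parent accession of a proteoform; \code{chainRanges} the chain
#' annotation table of a record; \code{spots} the spot table of a pattern;
#' \code{schemeOf} its section scheme; \code{piValue} and \code{mwValue} the
#' computed coordinates of a proteoform; \code{abundanceWeight} its ensemble
#' weight.
#'
#' @param x a virtual2DE object.
#' @return the slot value (see details per class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))
#' @rdname accessors
#' @export
setGeneric("chainRanges", function(x) standardGeneric("chainRanges"))
#' @rdname accessors
#' @export
setGeneric("spots", function(x) standardGeneric("spots"))
#' @rdname accessors
#' @export
setGeneric("schemeOf", function(x) standardGeneric("schemeOf"))
#' @rdname accessors
#' @export
setGeneric("piValue", function(x) standardGeneric("piValue"))
#' @rdname accessors
#' @export
setGeneric("mwValue", function(x) standardGeneric("mwValue"))
#' @rdname accessors
#' @export
setGeneric("abundanceWeight", function(x) standardGeneric("abundanceWeight"))

#' @rdname accessors
setMethod("accession", "ProteinRecord", function(x) x@accession)
#' @rdname accessors
setMethod("accession", "Proteoform", function(x) x@parent)
#' @rdname accessors
setMethod("chainRanges", "ProteinRecord", function(x) x@chains)
#' @rdname accessors
setMethod("spots", "Pattern2DE", function(x) x@spots)
#' @rdname accessors
setMethod("schemeOf", "Pattern2DE", function(x) x@scheme)
#' @rdname accessors
setMethod("piValue", "Proteoform", function(x) x@pI)
#' @rdname accessors
setMethod("mwValue", "Proteoform", function(x) x@mw)
#' @rdname accessors
setMethod("abundanceWeight", "Proteoform", function(x)
  if (length(x@abundanceWeight)) x@abundanceWeight else NA_real_)

setMethod("show", "ProteinRecord", function(object) {
  cat(sprintf("ProteinRecord %s (%s), %d aa, %d chain(s)\n",
              object@accession,
              if (nzchar(object@entryName)) object@entryName else "-",
              nchar(object@sequence), nrow(object@chains)))
  if (nrow(object@chains))
    cat(sprintf("  %s: %d-%d\n", object@chains$name,
                object@chains$start, object@chains$end), sep = "")
})

setMethod("show", "Modification", function(object) {
  comp <- object@glycanComposition
  extra <- if (object@kind == "glyco" && length(comp))
    paste0(" [", paste(sprintf("%s%d", names(comp), comp), collapse = " "), "]")
  else ""
  cat(sprintf("Modification: %d x %s%s (+%.4f Da avg)\n",
              object@count, object@kind, extra, object@massDeltaAvg))
})

setMethod("show", "Proteoform", function(object) {
  nm <- sum(vapply(object@mods, function(m) m@count, integer(1)))
  cat(sprintf("Proteoform %s/%s: pI %.2f, Mw %.0f Da, %d modification copies\n",
              object@parent, object@chainName, object@pI, object@mw, nm))
})

setMethod("show", "PiAxis", function(object) {
  a <- object@anchors
  cat(sprintf("PiAxis (%s): %d anchors, %.1f-%.1f cm -> pH %.2f-%.2f\n",
              object@mode, nrow(a), min(a$position), max(a$position),
              min(a$pH), max(a$pH)))
})

setMethod("show", "MwAxis", function(object) {
  cat(sprintf(
    "MwAxis: %d markers, log10(Mw) = %.3f %+.3f x migration (%g%% gel)\n",
    nrow(object@markers), object@intercept, object@slope, object@gelPercent))
})

setMethod("show", "SectionScheme", function(object) {
  cat(sprintf("SectionScheme '%s': %d row(s) x %d column(s) = %d sections\n",
              object@mode, object@nRows, object@nCols,
              object@nRows * object@nCols))
})

setMethod("show", "Pattern2DE", function(object) {
  sp <- object@spots
  cat(sprintf("Pattern2DE: %d spot(s), %d protein(s), scheme '%s'\n",
              nrow(sp), length(unique(sp$accession)), object@scheme@mode))
  if (nrow(sp))
    cat(sprintf("  total emPAI %.3f; pI window %.2f-%.2f\n",
                sum(sp$empai), min(sp$pi_low), max(sp$pi_high)))
})
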