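#' @rdname GenomeBuild
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeBuild
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeBuild
#' @export
setGeneric("chromClass", function(x) standardGeneric("chromClass"))

#' @rdname GenomeBuild
#' @export
setGeneric("autosomes", function(x) standardGeneric("autosomes"))

#' @rdname GenomeBuild
#' @export
setGeneric("xChromosome", function(x) standardGeneric("xChromosome"))

#' @rdname SignalTrack
#' @export
setGeneric("trackValues", function(x, chrom = NULL) standardGeneric("trackValues"))

#' @rdname SignalTrack
#' @export
setGeneric("trackKind", function(x) standardGeneric("trackKind"))

#' @rdname SignalTrack
#' @export
setGeneric("trackResolution", function(x) standardGeneric("trackResolution"))

#' @rdname SignalTrack
#' @export
setGeneric("trackGenome", function(x) standardGeneric("trackGenome"))

#' Standardize a log2-ratio track to z-scores
#'
#' @param track a [SignalTrack-class] of kind `"log2-ratio"` (or `"z-score"`,
#'   in which case standardization is re-applied and is idempotent).
#' @param reference `"autosomes"` to center and scale against autosomal bins
#'   only (the convention for X-enrichment analysis), or `"all"` to use every
#'   chromosome (the convention used for marks depleted on X, e.g. H4K20me3).
#' @param ... unused.
#' @return a [SignalTrack-class] of kind `"z-score"`.
#' @export
setGeneric("standardize", function(track, reference = c("autosomes", "all"), ...)
    standardGeneric("standardize"))

#' X:autosome enrichment statistic
#'
#' Median signal over X-chromosome bins minus the median over all autosomal
#' bins pooled — the scalar summary of chromosome-wide X enrichment.
#'
#' @param x a [SignalTrack-class].
#' @param ... unused.
#' @return a single numeric value.
#' @export
setGeneric("xaEnrichment", function(x, ...) standardGeneric("xaEnrichment"))

#' @rdname ProfileMatrix
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname ProfileMatrix
#' @export
setGeneric("binOffsets", function(x) standardGeneric("binOffsets"))

#' @rdname FusionMap
#' @export
setGeneric("fusionSite", function(x) standardGeneric("fusionSite"))

#' @rdname FusionMap
#' @export
setGeneric("fusionSegments", function(x) standardGeneric("fusionSegments"))
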