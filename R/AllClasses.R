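#' @import methods
#' @importFrom stats median quantile rnorm runif rpois rlnorm sd var setNames
#'   aggregate cor lm coef
#' @importFrom utils read.delim write.table head tail
NULL

#' GenomeBuild: chromosome names, lengths and autosome/X classification
#'
#' A minimal genome description: chromosome names, lengths in base pairs,
#' and a chromosome class used throughout the package to split signal into
#' the autosomal reference set and the X chromosome.
#'
#' @slot chromNames character vector of unique chromosome names.
#' @slot chromLengths integer vector of chromosome lengths (bp), parallel to
#'   `chromNames`.
#' @slot chromClass character vector, each element `"autosome"` or `"X"`,
#'   parallel to `chromNames`.
#'
#' @details A valid build has at least one autosome and at most one X-class
#' chromosome, mirroring the C. elegans karyotype (I-V plus X) the analysis
#' was designed around.
#'
#' @seealso [GenomeBuild()] for the user-facing constructor.
#' @exportClass GenomeBuild
setClass("GenomeBuild",
    representation(
        chromNames   = "character",
        chromLengths = "integer",
        chromClass   = "character"
    )
)

setValidity("GenomeBuild", function(object) {
    msg <- character()
    n <- length(object@chromNames)
    if (length(object@chromLengths) != n || length(object@chromClass) != n)
        msg <- c(msg, "chromNames, chromLengths and chromClass must have equal length")
    if (anyDuplicated(object@chromNames))
        msg <- c(msg, "chromosome names must be unique")
    if (n > 0 && any(is.na(object@chromLengths) | object@chromLengths <= 0L))
        msg <- c(msg, "all chromosome lengths must be positive")
    if (!all(object@chromClass %in% c("autosome", "X")))
        msg <- c(msg, "chromosome class must be 'autosome' or 'X'")
    if (n > 0 && sum(object@chromClass == "autosome") < 1L)
        msg <- c(msg, "a build needs at least one autosome")
    if (sum(object@chromClass == "X") > 1L)
        msg <- c(msg, "a build may contain at most one X-class chromosome")
    if (length(msg)) msg else TRUE
})

#' SignalTrack: binned per-chromosome signal values
#'
#' Fixed-resolution numeric signal along every chromosome of a
#' [GenomeBuild-class]. The `kind` slot records where the values sit in the
#' processing chain: raw counts, log2 ChIP/Input ratios, or z-scores
#' (ratios standardized against a reference chromosome set).
#'
#' @slot values named list of numeric vectors, one per chromosome; element
#'   `i` covers base pairs `[(i-1)*resolution, i*resolution)`. `NA` marks
#'   missing signal.
#' @slot genome the [GenomeBuild-class] the track lives on.
#' @slot resolution integer, bp per bin.
#' @slot kind one of `"raw-count"`, `"log2-ratio"`, `"z-score"`.
#' @slot sample character label (e.g. genotype or antibody).
#' @slot replicate integer replicate id (`NA` for averaged tracks).
#'
#' @exportClass SignalTrack
setClass("SignalTrack",
    representation(
        values     = "list",
        genome     = "GenomeBuild",
        resolution = "integer",
        kind       = "character",
        sample     = "character",
        replicate  = "integer"
    )
)

setValidity("SignalTrack", function(object) {
    msg <- character()
    g <- object@genome
    if (length(object@resolution) != 1L || is.na(object@resolution) ||
        object@resolution < 1L)
        msg <- c(msg, "resolution must be a single integer >= 1")
    if (!object@kind %in% c("raw-count", "log2-ratio", "z-score"))
        msg <- c(msg, "kind must be 'raw-count', 'log2-ratio' or 'z-score'")
    if (!setequal(names(object@values), g@chromNames))
        msg <- c(msg, "values must be named by exactly the genome's chromosomes")
    else {
        expected <- ceiling(g@chromLengths / as.double(object@resolution))
        got <- lengths(object@values)[g@chromNames]
        if (!all(got == expected))
            msg <- c(msg, "per-chromosome vector lengths must equal ceiling(length/resolution)")
        if (!all(vapply(object@values, is.numeric, logical(1))))
            msg <- c(msg, "values must be numeric vectors")
    }
    if (length(msg)) msg else TRUE
})

#' ProfileMatrix: anchor-aligned signal matrix over genes or regions
#'
#' Rows are genes or regions, columns are fixed-width bins over a window
#' positioned on a common anchor (TSS, TES or region center). Minus-strand
#' rows are orientation-flipped so column 1 is always biologically upstream.
#'
#' @slot matrix numeric matrix (rows x bins), `NA` where the window leaves
#'   the chromosome.
#' @slot rowIds character row identifiers (gene or region ids).
#' @slot rowChrom character chromosome of each row.
#' @slot anchor one of `"TSS"`, `"TES"`, `"center"`.
#' @slot upstream,downstream integer window extent in bp on each side of the
#'   anchor.
#' @slot binSize integer bin width in bp.
#'
#' @exportClass ProfileMatrix
setClass("ProfileMatrix",
    representation(
        matrix     = "matrix",
        rowIds     = "character",
        rowChrom   = "character",
        anchor     = "character",
        upstream   = "integer",
        downstream = "integer",
        binSize    = "integer"
    )
)

setValidity("ProfileMatrix", function(object) {
    msg <- character()
    if ((object@upstream + object@downstream) %% object@binSize != 0L)
        msg <- c(msg, "upstream + downstream must be an exact multiple of binSize")
    ncols <- (object@upstream + object@downstream) %/% object@binSize
    if (ncol(object@matrix) != ncols)
        msg <- c(msg, "matrix column count must equal (upstream+downstream)/binSize")
    if (nrow(object@matrix) != length(object@rowIds) ||
        nrow(object@matrix) != length(object@rowChrom))
        msg <- c(msg, "rowIds and rowChrom must match the matrix rows")
    if (!object@anchor %in% c("TSS", "TES", "center"))
        msg <- c(msg, "anchor must be 'TSS', 'TES' or 'center'")
    if (length(msg)) msg else TRUE
})

#' FusionMap: coordinate map of a chromosome fusion
#'
#' Ordered segments mapping source chromosomes into one fused coordinate
#' system, modelling strains such as the X;II end-to-end fusion used to assay
#' ectopic spreading of X-enriched chromatin marks past the fusion point.
#'
#' @slot segments data.frame with columns `source`, `sourceStart`,
#'   `sourceEnd` (1-based closed), `orientation` (`"forward"`/`"reverse"`),
#'   `fusedStart`, `fusedEnd`. Fused intervals are contiguous, non-overlapping
#'   and cover `[1, fusedLength]`.
#' @slot fusedName character name of the fused chromosome.
#' @slot fusedLength integer total length.
#' @slot fusionSite integer; the junction lies between fused positions
#'   `fusionSite` and `fusionSite + 1` (1-based).
#'
#' @exportClass FusionMap
setClass("FusionMap",
    representation(
        segments    = "data.frame",
        fusedName   = "character",
        fusedLength = "integer",
        fusionSite  = "integer"
    )
)

setValidity("FusionMap", function(object) {
    seg <- object@segments
    need <- c("source", "sourceStart", "sourceEnd", "orientation",
              "fusedStart", "fusedEnd")
    if (!all(need %in% names(seg)))
        return(sprintf("segments must have columns: %s", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(seg) > 0) {
        o <- order(seg$fusedStart)
        seg <- seg[o, ]
        if (seg$fusedStart[1] != 1L || seg$fusedEnd[nrow(seg)] != object@fusedLength)
            msg <- c(msg, "fused segments must cover [1, fusedLength]")
        if (nrow(seg) > 1 &&
            any(seg$fusedStart[-1] != seg$fusedEnd[-nrow(seg)] + 1L))
            msg <- c(msg, "fused segments must be contiguous and non-overlapping")
        if (any(seg$sourceEnd - seg$sourceStart != seg$fusedEnd - seg$fusedStart))
            msg <- c(msg, "source and fused interval widths must match")
        if (!all(seg$orientation %in% c("forward", "reverse")))
            msg <- c(msg, "orientation must be 'forward' or 'reverse'")
    }
    if (length(msg)) msg else TRUE
})
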