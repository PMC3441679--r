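#' Build an end-to-end chromosome fusion map
#'
#' Models a fusion karyotype by joining two full-length chromosomes end to
#' end: `left` keeps its coordinates, `right` is appended forward, and the
#' junction sits between them — the coordinate frame of an X;II fusion strain
#' in which the right end of X meets the left end of II. Breakpoint-resected
#' variants can be built directly with [FusionMap()].
#'
#' @param genome a [GenomeBuild-class] containing both chromosomes.
#' @param left,right chromosome names; `left` occupies fused coordinates
#'   `[1, len(left)]`, `right` occupies `[len(left)+1, len(left)+len(right)]`.
#' @param fusedName name for the fused chromosome.
#' @return a [FusionMap-class].
#' @export
buildFusion <- function(genome, left, right,
                        fusedName = paste0(left, "_", right, "_fusion")) {
    sl <- chromLengths(genome)
    if (!all(c(left, right) %in% names(sl)))
        stop("both chromosomes must be present in the genome")
    if (left == right)
        stop("cannot fuse a chromosome to itself")
    l1 <- sl[[left]]; l2 <- sl[[right]]
    seg <- data.frame(
        source = c(left, right),
        sourceStart = c(1L, 1L),
        sourceEnd = c(l1, l2),
        orientation = "forward",
        fusedStart = c(1L, l1 + 1L),
        fusedEnd = c(l1, l1 + l2),
        stringsAsFactors = FALSE)
    new("FusionMap", segments = seg, fusedName = fusedName,
        fusedLength = as.integer(l1 + l2), fusionSite = as.integer(l1))
}

#' Construct a FusionMap from explicit segments
#'
#' @param segments data.frame with columns `source`, `sourceStart`,
#'   `sourceEnd` (1-based closed), `orientation`, `fusedStart`, `fusedEnd`.
#' @param fusedName fused chromosome name.
#' @param fusionSite 1-based fused coordinate immediately left of the
#'   junction of interest.
#' @return a [FusionMap-class].
#' @export
FusionMap <- function(segments, fusedName, fusionSite) {
    new("FusionMap", segments = segments, fusedName = fusedName,
        fusedLength = as.integer(max(segments$fusedEnd)),
        fusionSite = as.integer(fusionSite))
}

#' @rdname FusionMap
#' @param x a FusionMap.
#' @export
setMethod("fusionSite", "FusionMap", function(x) x@fusionSite)

#' @rdname FusionMap
#' @export
setMethod("fusionSegments", "FusionMap", function(x) x@segments)

setMethod("show", "FusionMap", function(object) {
    cat(sprintf("FusionMap '%s' (%d bp), junction after position %d\n",
                object@fusedName, object@fusedLength, object@fusionSite))
    print(object@segments, row.names = FALSE)
})

#' Map positions between source and fused coordinates
#'
#' `mapToFusion` converts 1-based source-chromosome positions to fused
#' coordinates; `mapFromFusion` is its inverse. The mapping is a bijection
#' over the covered bases; reverse-oriented segments are handled.
#'
#' @param map a [FusionMap-class].
#' @param chrom source chromosome name (recycled over `pos`).
#' @param pos integer vector of 1-based positions.
#' @return integer vector of mapped positions (for `mapFromFusion`, a
#'   data.frame with columns `chrom` and `pos`).
#' @export
mapToFusion <- function(map, chrom, pos) {
    seg <- map@segments
    chrom <- rep_len(chrom, length(pos))
    out <- rep(NA_integer_, length(pos))
    for (i in seq_len(nrow(seg))) {
        hit <- chrom == seg$source[i] & pos >= seg$sourceStart[i] &
               pos <= seg$sourceEnd[i]
        if (!any(hit)) next
        off <- pos[hit] - seg$sourceStart[i]
        out[hit] <- if (seg$orientation[i] == "forward")
            seg$fusedStart[i] + off else seg$fusedEnd[i] - off
    }
    if (anyNA(out))
        stop("position not covered by the fusion map: ",
             paste(head(paste0(chrom[is.na(out)], ":", pos[is.na(out)]), 3),
                   collapse = ", "))
    as.integer(out)
}

#' @rdname mapToFusion
#' @param fusedPos integer vector of 1-based fused coordinates.
#' @export
mapFromFusion <- function(map, fusedPos) {
    seg <- map@segments
    chrom <- rep(NA_character_, length(fusedPos))
    pos <- rep(NA_integer_, length(fusedPos))
    for (i in seq_len(nrow(seg))) {
        hit <- fusedPos >= seg$fusedStart[i] & fusedPos <= seg$fusedEnd[i]
        if (!any(hit)) next
        off <- fusedPos[hit] - seg$fusedStart[i]
        chrom[hit] <- seg$source[i]
        pos[hit] <- if (seg$orientation[i] == "forward")
            seg$sourceStart[i] + off else seg$sourceEnd[i] - off
    }
    if (anyNA(pos))
        stop("fused position not covered by the map: ",
             paste(head(fusedPos[is.na(pos)], 3), collapse = ", "))
    data.frame(chrom = chrom, pos = as.integer(pos))
}

#' GenomeBuild of the fused karyotype
#'
#' The fused chromosome plus any chromosomes of `genome` not consumed by the
#' fusion. An X;autosome fusion chromosome is a mixed entity, so its class
#' must be chosen explicitly; the default `"autosome"` keeps the build valid
#' on its own, and which chromosome set counts as the standardization
#' reference in a fusion strain is left to the caller.
#'
#' @param map a [FusionMap-class].
#' @param genome the source [GenomeBuild-class].
#' @param fusedClass class assigned to the fused chromosome.
#' @return a [GenomeBuild-class].
#' @export
fusionGenome <- function(map, genome, fusedClass = "autosome") {
    cls <- chromClass(genome)
    used <- unique(map@segments$source)
    restNames <- setdiff(chromNames(genome), used)
    lens <- c(setNames(map@fusedLength, map@fusedName),
              chromLengths(genome)[restNames])
    GenomeBuild(lens, c(fusedClass, unname(cls[restNames])))
}

# mean of a track over a fused-coordinate interval [s0, e0) (0-based):
# if the track lives on the fused chromosome, read it directly; otherwise
# map the interval back to its source chromosome (assumes the interval is
# inside one segment, which holds for flanks measured from the junction)
.fusedIntervalMean <- function(track, map, s0, e0) {
    sl <- chromLengths(track@genome)
    if (map@fusedName %in% names(sl)) {
        return(.intervalMean(track@values[[map@fusedName]], track@resolution,
                             sl[[map@fusedName]], s0, e0))
    }
    src <- mapFromFusion(map, c(s0 + 1L, e0))
    if (src$chrom[1] != src$chrom[2])
        stop("interval spans a segment boundary; split it at the junction")
    lo <- min(src$pos); hi <- max(src$pos)
    .intervalMean(track@values[[src$chrom[1]]], track@resolution,
                  sl[[src$chrom[1]]], lo - 1L, hi)
}

#' Ectopic spreading score at the fusion junction
#'
#' Mean z-score over the autosome-derived flank just past the fusion site in
#' the fusion strain, minus the mean over the same source bases in the
#' normal-karyotype control. Positive values indicate ectopic spreading of
#' the mark into autosomal sequence.
#'
#' @param fusionTrack [SignalTrack-class] on fused coordinates.
#' @param controlTrack [SignalTrack-class] on the normal karyotype (or on
#'   fused coordinates; both are accepted).
#' @param map a [FusionMap-class].
#' @param flank flank width in bp past the junction; truncated with a
#'   warning if it exceeds the autosomal segment.
#' @return a single numeric score.
#' @export
spreadingScore <- function(fusionTrack, controlTrack, map, flank) {
    if (flank <= 0) stop("flank must be positive")
    avail <- map@fusedLength - map@fusionSite
    if (flank > avail) {
        warning("flank truncated to the autosomal segment (", avail, " bp)")
        flank <- avail
    }
    s0 <- map@fusionSite          # 0-based coordinate of the first base past the junction
    e0 <- s0 + flank
    .fusedIntervalMean(fusionTrack, map, s0, e0) -
        .fusedIntervalMean(controlTrack, map, s0, e0)
}

#' Spreading decay curve past the fusion junction
#'
#' Per-bin difference (fusion minus control) as a function of distance from
#' the fusion site into the autosomal segment.
#'
#' @param fusionTrack,controlTrack,map as in [spreadingScore()].
#' @param maxDist how far past the junction to go, in bp.
#' @param bin bin width in bp.
#' @return data.frame with columns `distance` (bin midpoint, bp from the
#'   junction), `fusion`, `control`, `difference`.
#' @export
spreadingCurve <- function(fusionTrack, controlTrack, map, maxDist, bin) {
    avail <- map@fusedLength - map@fusionSite
    if (maxDist > avail) {
        warning("maxDist truncated to the autosomal segment (", avail, " bp)")
        maxDist <- avail
    }
    nbin <- maxDist %/% bin
    starts <- map@fusionSite + (seq_len(nbin) - 1L) * bin
    fus <- vapply(starts, function(s)
        .fusedIntervalMean(fusionTrack, map, s, s + bin), numeric(1))
    ctl <- vapply(starts, function(s)
        .fusedIntervalMean(controlTrack, map, s, s + bin), numeric(1))
    data.frame(distance = starts - map@fusionSite + bin / 2,
               fusion = fus, control = ctl, difference = fus - ctl)
}

#' Write a fusion map as TSV
#'
#' @param map a [FusionMap-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFusionMap <- function(map, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fused=%s length=%d fusionSite=%d",
                       map@fusedName, map@fusedLength, map@fusionSite), con)
    write.table(map@segments, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
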