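#' Construct a SignalTrack
#'
#' @param values named list of per-chromosome numeric vectors (names must be
#'   exactly the genome's chromosomes; element `i` covers
#'   `[(i-1)*resolution, i*resolution)`).
#' @param genome a [GenomeBuild-class].
#' @param resolution bp per bin.
#' @param kind `"raw-count"`, `"log2-ratio"` or `"z-score"`.
#' @param sample sample label.
#' @param replicate replicate id.
#' @return a [SignalTrack-class].
#' @export
SignalTrack <- function(values, genome, resolution, kind = "log2-ratio",
                        sample = NA_character_, replicate = NA_integer_) {
    new("SignalTrack",
        values = lapply(values, as.numeric),
        genome = genome,
        resolution = as.integer(resolution),
        kind = kind,
        sample = as.character(sample),
        replicate = as.integer(replicate))
}

#' @rdname SignalTrack
#' @param x a SignalTrack.
#' @param chrom optional chromosome name; when given, returns that
#'   chromosome's numeric vector, else the full named list.
#' @export
setMethod("trackValues", "SignalTrack", function(x, chrom = NULL) {
    if (is.null(chrom)) x@values else x@values[[chrom]]
})

#' @rdname SignalTrack
#' @export
setMethod("trackKind", "SignalTrack", function(x) x@kind)

#' @rdname SignalTrack
#' @export
setMethod("trackResolution", "SignalTrack", function(x) x@resolution)

#' @rdname SignalTrack
#' @export
setMethod("trackGenome", "SignalTrack", function(x) x@genome)

setMethod("show", "SignalTrack", function(object) {
    cat(sprintf("SignalTrack (%s) at %d bp resolution, %d chromosome(s)\n",
                object@kind, object@resolution, length(object@values)))
    if (!is.na(object@sample))
        cat("  sample:", object@sample,
            if (!is.na(object@replicate)) paste0("replicate ", object@replicate)
            else "", "\n")
    cat("  bins:", sum(lengths(object@values)),
        sprintf("(%.1f%% missing)\n",
                100 * mean(is.na(unlist(object@values, use.names = FALSE)))))
})

.checkCompatible <- function(a, b) {
    if (!identical(a@genome@chromNames, b@genome@chromNames) ||
        !identical(a@genome@chromLengths, b@genome@chromLengths))
        stop("tracks are on different genomes")
    if (a@resolution != b@resolution)
        stop("tracks have different resolutions")
    invisible(TRUE)
}

# bp-weighted mean of track values over genomic [s0, e0) (0-based half-open),
# clipped to the chromosome; NA values drop out with their weight
.intervalMean <- function(v, res, chromLen, s0, e0) {
    s0 <- max(s0, 0)
    e0 <- min(e0, chromLen)
    if (e0 <= s0) return(NA_real_)
    first <- floor(s0 / res)
    last <- floor((e0 - 1) / res)
    idx <- (first:last) + 1L
    binStart <- (first:last) * res
    w <- pmin(binStart + res, e0, chromLen) - pmax(binStart, s0)
    val <- v[idx]
    ok <- !is.na(val) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(val[ok] * w[ok]) / sum(w[ok])
}

#' Bin interval signal onto a fixed-resolution track
#'
#' Converts a `GRanges` with a `score` column (e.g. an imported bedGraph)
#' into a [SignalTrack-class] by bp-weighted averaging of the scores covering
#' each bin. Bins covered by no record are missing.
#'
#' @param gr `GRanges` with numeric `score`.
#' @param genome a [GenomeBuild-class].
#' @param resolution bp per bin.
#' @param kind track kind of the values (default `"log2-ratio"`).
#' @param sample,replicate metadata passed to [SignalTrack()].
#' @return a [SignalTrack-class].
#' @export
binSignal <- function(gr, genome, resolution, kind = "log2-ratio",
                      sample = NA_character_, replicate = NA_integer_) {
    sl <- chromLengths(genome)
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- unname(sl)
    score <- S4Vectors::mcols(gr)$score
    if (is.null(score)) stop("ranges must carry a numeric 'score' column")
    wsum <- GenomicRanges::coverage(gr, weight = as.numeric(score))
    wcov <- GenomicRanges::coverage(gr)
    values <- lapply(names(sl), function(chrom) {
        n <- ceiling(sl[[chrom]] / resolution)
        starts <- (seq_len(n) - 1L) * resolution + 1L
        ends <- pmin(starts + resolution - 1L, sl[[chrom]])
        vs <- IRanges::viewSums(IRanges::Views(wsum[[chrom]], starts, ends))
        vc <- IRanges::viewSums(IRanges::Views(wcov[[chrom]], starts, ends))
        out <- ifelse(vc > 0, vs / vc, NA_real_)
        as.numeric(out)
    })
    names(values) <- names(sl)
    SignalTrack(values, genome, resolution, kind, sample, replicate)
}

#' Read a signal track from bedGraph, wiggle or TSV
#'
#' @param path input file. TSV fallback expects four columns
#'   `chrom, start, end, value` with 0-based half-open coordinates.
#' @param genome a [GenomeBuild-class].
#' @param resolution bp per bin for the returned track.
#' @param format `"auto"` (by extension), `"bedGraph"`, `"wig"` or `"tsv"`.
#' @param kind,sample,replicate metadata for the returned track.
#' @return a [SignalTrack-class].
#' @export
readTrack <- function(path, genome, resolution,
                      format = c("auto", "bedGraph", "wig", "tsv"),
                      kind = "log2-ratio", sample = NA_character_,
                      replicate = NA_integer_) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.(bg|bedgraph)$", path, ignore.case = TRUE))
            "bedGraph"
        else if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig"
        else "tsv"
    }
    gr <- if (format == "tsv") {
        df <- read.delim(path, header = FALSE, comment.char = "#",
                         col.names = c("chrom", "start", "end", "value"))
        GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               score = df$value)
    } else {
        rtracklayer::import(path, format = if (format == "wig") "WIG" else "bedGraph")
    }
    binSignal(gr, genome, resolution, kind, sample, replicate)
}

#' Write a signal track as bedGraph
#'
#' Missing bins are omitted (bedGraph has no missing-value representation);
#' re-importing at the same resolution reproduces the track.
#'
#' @param track a [SignalTrack-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTrack <- function(track, path) {
    sl <- chromLengths(track@genome)
    res <- track@resolution
    parts <- lapply(names(track@values), function(chrom) {
        v <- track@values[[chrom]]
        keep <- which(!is.na(v))
        if (!length(keep)) return(NULL)
        starts <- (keep - 1L) * res + 1L
        data.frame(chrom = chrom, start = starts,
                   end = pmin(starts + res - 1L, sl[[chrom]]),
                   score = v[keep])
    })
    df <- do.call(rbind, parts)
    gr <- if (!is.null(df) && nrow(df))
        GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               score = df$score, seqinfo = .seqinfoFor(track@genome))
    else GenomicRanges::GRanges()
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Log2 ChIP/Input ratio of two raw tracks
#'
#' `log2((chip + pseudocount) / (input + pseudocount))` per bin; bins where
#' both tracks are zero come out 0.
#'
#' @param chip,input [SignalTrack-class] objects of kind `"raw-count"` on
#'   the same genome and resolution.
#' @param pseudocount positive value added to both numerator and denominator.
#' @return a [SignalTrack-class] of kind `"log2-ratio"`.
#' @export
log2Ratio <- function(chip, input, pseudocount = 1) {
    .checkCompatible(chip, input)
    if (pseudocount <= 0) stop("pseudocount must be > 0")
    values <- mapply(function(c, i) log2((c + pseudocount) / (i + pseudocount)),
                     chip@values, input@values, SIMPLIFY = FALSE)
    SignalTrack(values, chip@genome, chip@resolution, "log2-ratio",
                chip@sample, chip@replicate)
}

#' @rdname standardize
#' @details The reference mean and standard deviation are computed over the
#' reference bins only (the population form of the standard deviation,
#' dividing by N) and the affine transform is applied to every bin, so
#' X-chromosome values are expressed in autosomal standard deviation units.
#' After `reference = "autosomes"`, autosomal z-scores have mean 0 and
#' standard deviation 1 exactly; `reference = "all"` does the same over all
#' chromosomes pooled.
#' @export
setMethod("standardize", "SignalTrack", function(track,
        reference = c("autosomes", "all"), ...) {
    reference <- match.arg(reference)
    refChroms <- if (reference == "autosomes") autosomes(track@genome)
                 else chromNames(track@genome)
    if (!length(refChroms)) stop("reference chromosome set is empty")
    refv <- unlist(track@values[refChroms], use.names = FALSE)
    refv <- refv[!is.na(refv)]
    if (!length(refv)) stop("reference set has no non-missing values")
    mu <- mean(refv)
    sigma <- sqrt(mean((refv - mu)^2))
    if (sigma == 0) stop("degenerate scale: reference signal is constant")
    values <- lapply(track@values, function(v) (v - mu) / sigma)
    SignalTrack(values, track@genome, track@resolution, "z-score",
                track@sample, track@replicate)
})

#' Average replicate tracks element-wise
#'
#' Biological replicates are averaged after standardization. A bin's mean is
#' taken over the replicates present there as long as at most one replicate
#' is missing; with two or more replicates missing the bin is missing.
#'
#' @param tracks non-empty list of [SignalTrack-class] objects sharing
#'   genome, resolution and kind.
#' @return a [SignalTrack-class] with `replicate = NA`.
#' @export
averageTracks <- function(tracks) {
    if (!length(tracks)) stop("need at least one track to average")
    ref <- tracks[[1]]
    for (t in tracks[-1]) {
        .checkCompatible(ref, t)
        if (t@kind != ref@kind) stop("tracks have different kinds")
    }
    n <- length(tracks)
    values <- lapply(names(ref@values), function(chrom) {
        m <- vapply(tracks, function(t) t@values[[chrom]],
                    numeric(length(ref@values[[chrom]])))
        m <- matrix(m, ncol = n)
        nMiss <- rowSums(is.na(m))
        out <- rowMeans(m, na.rm = TRUE)
        out[nMiss > 1L | nMiss >= n] <- NA_real_
        out
    })
    names(values) <- names(ref@values)
    SignalTrack(values, ref@genome, ref@resolution, ref@kind,
                ref@sample, NA_integer_)
}

# sliding median with truncated windows at the ends; half is in bins
.slideMedian <- function(v, half) {
    n <- length(v)
    if (half == 0L || n == 0L) return(v)
    k <- 2L * half + 1L
    if (!anyNA(v) && n >= k) {
        out <- stats::runmed(v, k, endrule = "keep")
        for (i in seq_len(half)) {
            out[i] <- median(v[1:min(n, i + half)])
            j <- n - i + 1L
            out[j] <- median(v[max(1L, j - half):n])
        }
        out
    } else {
        vapply(seq_len(n), function(i) {
            w <- v[max(1L, i - half):min(n, i + half)]
            w <- w[!is.na(w)]
            if (length(w)) median(w) else NA_real_
        }, numeric(1))
    }
}

#' Sliding median smoothing along chromosomes
#'
#' Each bin is replaced by the median of the values in a centered window of
#' `window` bp, truncated at chromosome ends (no padding or wrap-around);
#' missing values are excluded from each window's median. The window spans
#' `2 * floor(window / (2 * resolution)) + 1` bins, so it is always centered.
#'
#' @param track a [SignalTrack-class].
#' @param window window width in bp (default 1 kb, the width used for
#'   chromosome-level boxplot summaries).
#' @return a smoothed [SignalTrack-class] of the same kind.
#' @export
medianSmooth <- function(track, window = 1000) {
    if (window < track@resolution)
        stop("smoothing window must be at least one bin (window >= resolution)")
    half <- as.integer(floor(window / (2 * track@resolution)))
    values <- lapply(track@values, .slideMedian, half = half)
    SignalTrack(values, track@genome, track@resolution, track@kind,
                track@sample, track@replicate)
}

#' Per-chromosome distribution summary
#'
#' Median, quartiles and 2.5th/97.5th percentiles of track values per
#' chromosome — the numbers behind chromosome-level box-and-whisker
#' summaries. Percentiles use linear interpolation between closest ranks
#' (`quantile` type 7); missing values are excluded.
#'
#' @param track a [SignalTrack-class].
#' @return data.frame with columns `chrom`, `class`, `n`, `p2.5`, `q25`,
#'   `median`, `q75`, `p97.5`.
#' @export
chromosomeSummary <- function(track) {
    cls <- chromClass(track@genome)
    rows <- lapply(names(track@values), function(chrom) {
        v <- track@values[[chrom]]
        v <- v[!is.na(v)]
        if (!length(v))
            stop("chromosome has no non-missing values: ", chrom)
        q <- quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7,
                      names = FALSE)
        data.frame(chrom = chrom, class = unname(cls[chrom]), n = length(v),
                   p2.5 = q[1], q25 = q[2], median = q[3], q75 = q[4],
                   p97.5 = q[5])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' @rdname xaEnrichment
#' @details Computed as `median(X bins) - median(all autosomal bins pooled)`,
#' typically after standardization, replicate averaging and median smoothing.
#' Zero means the X signal distribution is centered like the autosomes;
#' positive values measure chromosome-wide X enrichment in z units.
#' @export
setMethod("xaEnrichment", "SignalTrack", function(x, ...) {
    xc <- xChromosome(x@genome)
    if (is.na(xc)) stop("genome has no X-class chromosome")
    xv <- x@values[[xc]]
    av <- unlist(x@values[autosomes(x@genome)], use.names = FALSE)
    median(xv, na.rm = TRUE) - median(av, na.rm = TRUE)
})
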