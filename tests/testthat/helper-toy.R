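# small builders and independent oracles shared across the suite

toyGenome <- function(lens = c(chrI = 1000L, chrX = 800L), classes = NULL) {
    GenomeBuild(lens, classes)
}

# constant-valued track
constTrack <- function(genome, resolution, value, kind = "log2-ratio") {
    sl <- chromLengths(genome)
    values <- lapply(sl, function(l) rep(value, ceiling(l / resolution)))
    SignalTrack(values, genome, resolution, kind)
}

trackFrom <- function(values, genome, resolution, kind = "log2-ratio") {
    SignalTrack(values, genome, resolution, kind)
}

# a GRanges of gene features on one strand
toyGenes <- function(chrom, starts, ends, strands, ids = NULL,
                     seqlens = NULL) {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(starts, ends), strand = strands)
    S4Vectors::mcols(gr)$kind <- "gene"
    S4Vectors::mcols(gr)$gene_id <- ids %||% paste0("g", seq_along(gr))
    if (!is.null(seqlens)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlens)
        GenomeInfoDb::seqlengths(gr) <- unname(seqlens)
    }
    gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force intergenic oracle: mark every annotated base, scan runs
bruteIntergenic <- function(features, chromLens, minLength) {
    out <- list()
    for (chrom in names(chromLens)) {
        occ <- logical(chromLens[[chrom]])
        f <- features[features$chrom == chrom, , drop = FALSE]
        if (nrow(f)) for (i in seq_len(nrow(f)))
            occ[f$start[i]:f$end[i]] <- TRUE   # 1-based closed
        r <- rle(occ)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        free <- !r$values & r$lengths >= minLength
        if (any(free))
            out[[chrom]] <- data.frame(chrom = chrom,
                                       start = starts[free], end = ends[free])
    }
    if (!length(out)) return(data.frame(chrom = character(0),
                                        start = integer(0), end = integer(0)))
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
}

# naive truncated sliding median
slideMedianOracle <- function(v, half) {
    n <- length(v)
    vapply(seq_len(n), function(i) {
        w <- v[max(1, i - half):min(n, i + half)]
        w <- w[!is.na(w)]
        if (length(w)) median(w) else NA_real_
    }, numeric(1))
}

# a fast, quiet synthetic configuration for unit tests
testConfig <- function(nGenes = 60, resolution = 100, ...) {
    syntheticConfig(chromLengths = c(chrI = 4e5, chrX = 4e5),
                    nGenes = nGenes, resolution = resolution, ...)
}
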