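#' @rdname ProfileMatrix
#' @param x a ProfileMatrix.
#' @export
setMethod("profileValues", "ProfileMatrix", function(x) {
    m <- x@matrix
    rownames(m) <- x@rowIds
    m
})

#' @rdname ProfileMatrix
#' @details `binOffsets` returns each column's start offset in bp relative
#' to the anchor (negative = upstream).
#' @export
setMethod("binOffsets", "ProfileMatrix", function(x) {
    seq(-x@upstream, x@downstream - x@binSize, by = x@binSize)
})

setMethod("show", "ProfileMatrix", function(object) {
    cat(sprintf("ProfileMatrix: %d rows x %d bins of %d bp, anchored at %s (-%d/+%d bp)\n",
                nrow(object@matrix), ncol(object@matrix), object@binSize,
                object@anchor, object@upstream, object@downstream))
})

# core window extractor; anchors are 0-based boundary coordinates, strands
# "+"/"-"/"*"; minus-strand rows are flipped so column 1 is 5' upstream
.profileMatrix <- function(track, chroms, anchors0, strands, ids,
                           anchor, upstream, downstream, bin) {
    upstream <- as.integer(upstream)
    downstream <- as.integer(downstream)
    bin <- as.integer(bin)
    if ((upstream + downstream) %% bin != 0L)
        stop("upstream + downstream must be an exact multiple of the bin size")
    ncols <- (upstream + downstream) %/% bin
    sl <- chromLengths(track@genome)
    unknown <- setdiff(unique(chroms), names(sl))
    if (length(unknown))
        stop("unknown chromosome for rows: ",
             paste(head(ids[chroms %in% unknown], 3), collapse = ", "))
    res <- track@resolution
    m <- matrix(NA_real_, nrow = length(ids), ncol = ncols)
    for (r in seq_along(ids)) {
        v <- track@values[[chroms[r]]]
        len <- sl[[chroms[r]]]
        a0 <- anchors0[r]
        if (strands[r] == "-") {
            starts <- a0 + upstream - seq_len(ncols) * bin
        } else {
            starts <- a0 - upstream + (seq_len(ncols) - 1L) * bin
        }
        for (j in seq_len(ncols))
            m[r, j] <- .intervalMean(v, res, len, starts[j], starts[j] + bin)
    }
    new("ProfileMatrix", matrix = m, rowIds = as.character(ids),
        rowChrom = as.character(chroms), anchor = anchor,
        upstream = upstream, downstream = downstream, binSize = bin)
}

#' Meta-gene profile anchored at TSS or TES
#'
#' Positions a window on each gene's anchor respecting strand (upstream is
#' always 5' of the gene), splits it into fixed bins, and fills each bin
#' with the bp-weighted mean of the track values it overlaps. Bins outside
#' the chromosome are missing. The conventional windows are 1 kb/1 kb around
#' the TSS and 1.5 kb/1 kb around the TES, at 50-bp bins.
#'
#' @param track a [SignalTrack-class] (typically z-scores).
#' @param genes `GRanges` of gene models with strand and `gene_id`.
#' @param anchor `"TSS"` or `"TES"`.
#' @param upstream,downstream window extent in bp on the 5' and 3' side of
#'   the anchor.
#' @param bin bin width in bp (default 50).
#' @return a [ProfileMatrix-class] with one row per gene.
#' @export
anchoredProfile <- function(track, genes, anchor = c("TSS", "TES"),
                            upstream = 1000, downstream = 1000, bin = 50) {
    anchor <- match.arg(anchor)
    st <- as.character(BiocGenerics::strand(genes))
    # 0-based boundary at the 5' edge of the anchor base, so that a + gene
    # and a - gene anchored at the same boundary give mirror-image rows
    s0 <- BiocGenerics::start(genes) - 1L
    e0 <- BiocGenerics::end(genes)
    a0 <- if (anchor == "TSS") ifelse(st == "-", e0, s0)
          else ifelse(st == "-", s0, e0)
    ids <- S4Vectors::mcols(genes)$gene_id
    if (is.null(ids)) ids <- paste0("gene", seq_along(genes))
    .profileMatrix(track, as.character(GenomeInfoDb::seqnames(genes)),
                   a0, st, ids, anchor, upstream, downstream, bin)
}

#' Center-anchored profile over regions
#'
#' Strand-less analogue of [anchoredProfile()] for intergenic regions:
#' windows are centered on [regionCenter()] positions.
#'
#' @param track a [SignalTrack-class].
#' @param regions `GRanges` of regions.
#' @param flank window half-width in bp on each side of the center.
#' @param bin bin width in bp.
#' @return a [ProfileMatrix-class] with one row per region.
#' @export
centeredProfile <- function(track, regions, flank = 5000, bin = 50) {
    centers0 <- regionCenter(regions) - 1L
    ids <- S4Vectors::mcols(regions)$region_id
    if (is.null(ids))
        ids <- sprintf("%s:%d-%d",
                       as.character(GenomeInfoDb::seqnames(regions)),
                       BiocGenerics::start(regions) - 1L,
                       BiocGenerics::end(regions))
    .profileMatrix(track, as.character(GenomeInfoDb::seqnames(regions)),
                   centers0, rep("*", length(regions)), ids,
                   "center", flank, flank, bin)
}

#' Assign genes to expression/chromosome-class groups
#'
#' Splits genes into autosomal and X-linked and labels the top and bottom
#' expression quintiles of each class (`A-top20`, `A-bottom20`, `X-top20`,
#' `X-bottom20`; everything else `none`). Group sizes are
#' `floor(fraction * n)` and ties are broken deterministically by gene id.
#'
#' @param expr named numeric vector of expression values (one per gene).
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param genome a [GenomeBuild-class] giving each chromosome's class.
#' @param quantileScope `"per-class"` ranks X genes among X genes and
#'   autosomal among autosomal (the default, keeping the four groups
#'   proportional); `"global"` ranks all genes together and then splits the
#'   global quintiles by class.
#' @param fraction quantile fraction (default 0.2).
#' @return a factor named by gene id with levels `A-top20`, `A-bottom20`,
#'   `X-top20`, `X-bottom20`, `none`.
#' @export
assignGroups <- function(expr, genes, genome,
                         quantileScope = c("per-class", "global"),
                         fraction = 0.2) {
    quantileScope <- match.arg(quantileScope)
    ids <- S4Vectors::mcols(genes)$gene_id
    cls <- chromClass(genome)[as.character(GenomeInfoDb::seqnames(genes))]
    if (anyNA(cls)) stop("every gene needs a chromosome with a known class")
    keep <- ids %in% names(expr)
    labels <- setNames(rep("none", length(ids)), ids)
    classTag <- c(autosome = "A", X = "X")
    if (quantileScope == "per-class") {
        for (cl in c("autosome", "X")) {
            cid <- ids[keep & cls == cl]
            n <- length(cid)
            if (n < 5L) {
                if (n > 0L)
                    warning("fewer than 5 ", cl, " genes; class skipped")
                next
            }
            k <- floor(fraction * n)
            ord <- cid[order(expr[cid], cid)]
            labels[ord[seq_len(k)]] <- paste0(classTag[cl], "-bottom20")
            labels[ord[seq.int(n - k + 1L, n)]] <- paste0(classTag[cl], "-top20")
        }
    } else {
        cid <- ids[keep]
        n <- length(cid)
        if (n >= 5L) {
            k <- floor(fraction * n)
            ord <- cid[order(expr[cid], cid)]
            bottom <- ord[seq_len(k)]
            top <- ord[seq.int(n - k + 1L, n)]
            tag <- classTag[cls[match(cid, ids)]]
            names(tag) <- cid
            labels[bottom] <- paste0(tag[bottom], "-bottom20")
            labels[top] <- paste0(tag[top], "-top20")
        } else warning("fewer than 5 genes; no groups assigned")
    }
    factor(labels,
           levels = c("A-top20", "A-bottom20", "X-top20", "X-bottom20", "none"))
}

#' Per-group, per-bin summary of a profile matrix
#'
#' Mean signal and 95% confidence interval of the mean (normal
#' approximation, `mean +/- 1.96 * sd / sqrt(n)`, sample standard deviation)
#' for every group at every bin. Bins where a row is missing drop that row
#' from the bin's `n`. Groups with no rows are omitted with a warning; the CI
#' is undefined (missing) where `n < 2`.
#'
#' @param profile a [ProfileMatrix-class].
#' @param groups factor or character vector of group labels, either named by
#'   row id or parallel to the rows. The label `"none"` is dropped.
#' @return data.frame with columns `group`, `offset` (bin start relative to
#'   the anchor, bp), `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
profileSummary <- function(profile, groups) {
    m <- profile@matrix
    if (!is.null(names(groups)))
        groups <- groups[profile@rowIds]
    if (length(groups) != nrow(m))
        stop("groups must cover every profile row")
    groups <- as.character(groups)
    offsets <- binOffsets(profile)
    levelsUsed <- setdiff(unique(groups[!is.na(groups)]), "none")
    rows <- list()
    for (g in sort(levelsUsed)) {
        sub <- m[groups == g & !is.na(groups), , drop = FALSE]
        if (nrow(sub) == 0L) {
            warning("empty group omitted: ", g)
            next
        }
        n <- colSums(!is.na(sub))
        mu <- colMeans(sub, na.rm = TRUE)
        mu[n == 0L] <- NA_real_
        sdv <- apply(sub, 2, function(col) sd(col[!is.na(col)]))
        half <- ifelse(n >= 2L, 1.96 * sdv / sqrt(n), NA_real_)
        rows[[g]] <- data.frame(group = g, offset = offsets, mean = mu,
                                ci_lo = mu - half, ci_hi = mu + half, n = n)
    }
    if (!length(rows))
        stop("no non-empty groups to summarize")
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Center-anchored intergenic meta-profile by chromosome class
#'
#' Profiles long annotation-free regions aligned at their centers and
#' summarizes by chromosome class (autosome vs X) — the analysis showing
#' that X enrichment covers intergenic space far from any gene.
#'
#' @param track a [SignalTrack-class] (typically z-scores).
#' @param regions `GRanges` from [findIntergenic()] (metadata column
#'   `chromClass` is used as the grouping; recomputed from the track's
#'   genome when absent).
#' @param flank half-window in bp (default 5 kb).
#' @param bin bin width in bp (default 50).
#' @return data.frame as from [profileSummary()], groups `autosome`/`X`.
#' @export
intergenicProfile <- function(track, regions, flank = 5000, bin = 50) {
    pm <- centeredProfile(track, regions, flank = flank, bin = bin)
    cls <- S4Vectors::mcols(regions)$chromClass
    if (is.null(cls))
        cls <- unname(chromClass(track@genome)[
            as.character(GenomeInfoDb::seqnames(regions))])
    profileSummary(pm, as.character(cls))
}

#' Write a profile summary as TSV
#'
#' @param summary data.frame from [profileSummary()] or
#'   [intergenicProfile()].
#' @param path output path.
#' @param header optional comment line (without leading `#`) written first.
#' @return invisibly, `path`.
#' @export
writeProfileSummary <- function(summary, path, header = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    write.table(summary, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
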