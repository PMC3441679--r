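#' Construct a GenomeBuild
#'
#' @param chromLengths named numeric/integer vector of chromosome lengths in
#'   bp; names are the chromosome names.
#' @param chromClass optional character vector (`"autosome"`/`"X"`) parallel
#'   to `chromLengths`. By default a chromosome whose name contains an
#'   `"X"` is classified as the X chromosome, following the C. elegans
#'   naming scheme (`chrI`-`chrV`, `chrX`).
#' @return a [GenomeBuild-class].
#' @examples
#' gb <- GenomeBuild(c(chrI = 15e6, chrX = 17e6))
#' chromClass(gb)
#' @export
GenomeBuild <- function(chromLengths, chromClass = NULL) {
    if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
        stop("chromLengths must be named by chromosome")
    if (is.null(chromClass))
        chromClass <- ifelse(grepl("X", names(chromLengths)), "X", "autosome")
    new("GenomeBuild",
        chromNames   = names(chromLengths),
        chromLengths = as.integer(chromLengths),
        chromClass   = as.character(chromClass))
}

#' @rdname GenomeBuild
#' @param x a GenomeBuild.
#' @export
setMethod("chromNames", "GenomeBuild", function(x) x@chromNames)

#' @rdname GenomeBuild
#' @export
setMethod("chromLengths", "GenomeBuild",
    function(x) setNames(x@chromLengths, x@chromNames))

#' @rdname GenomeBuild
#' @export
setMethod("chromClass", "GenomeBuild",
    function(x) setNames(x@chromClass, x@chromNames))

#' @rdname GenomeBuild
#' @export
setMethod("autosomes", "GenomeBuild",
    function(x) x@chromNames[x@chromClass == "autosome"])

#' @rdname GenomeBuild
#' @export
setMethod("xChromosome", "GenomeBuild", function(x) {
    xc <- x@chromNames[x@chromClass == "X"]
    if (length(xc) == 0L) NA_character_ else xc
})

setMethod("show", "GenomeBuild", function(object) {
    cat("GenomeBuild with", length(object@chromNames), "chromosomes\n")
    df <- data.frame(chrom = object@chromNames,
                     length = object@chromLengths,
                     class = object@chromClass)
    print(df, row.names = FALSE)
})

.seqinfoFor <- function(genome) {
    GenomeInfoDb::Seqinfo(seqnames = genome@chromNames,
                          seqlengths = genome@chromLengths)
}

#' Load genome annotation from GFF3 or BED
#'
#' Reads features into a `GRanges`. GFF3 coordinates (1-based closed) and
#' BED coordinates (0-based half-open) are both converted by the parser to
#' the 1-based closed convention `GRanges` uses, so downstream interval
#' arithmetic never sees a mixed convention. The returned ranges carry
#' metadata columns `kind` (the GFF3 `type`, or `"gene"` for BED) and
#' `gene_id`.
#'
#' @param path path to the annotation file.
#' @param dialect `"auto"` (by file extension), `"gff3"` or `"bed"`.
#' @param genome optional [GenomeBuild-class]; when supplied, features beyond
#'   chromosome bounds raise an error.
#' @return a `GRanges` sorted within chromosomes.
#' @export
loadAnnotation <- function(path, dialect = c("auto", "gff3", "bed"),
                           genome = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("annotation file not found: ", path)
    if (dialect == "auto") {
        dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
    }
    lines <- readLines(path, warn = FALSE)
    if (!any(nzchar(lines) & !startsWith(lines, "#"))) {
        warning("annotation file is empty: ", path)
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$kind <- character(0)
        S4Vectors::mcols(gr)$gene_id <- character(0)
        return(gr)
    }
    gr <- tryCatch(
        rtracklayer::import(path, format = if (dialect == "bed") "BED" else "GFF3"),
        error = function(e) stop("failed to parse ", path, " as ", dialect,
                                 ": ", conditionMessage(e)))
    mc <- S4Vectors::mcols(gr)
    if (dialect == "bed") {
        gene_id <- if ("name" %in% names(mc)) as.character(mc$name)
                   else paste0("feat", seq_along(gr))
        kind <- rep("gene", length(gr))
    } else {
        kind <- if ("type" %in% names(mc)) as.character(mc$type)
                else rep("feature", length(gr))
        gene_id <- rep(NA_character_, length(gr))
        for (col in c("ID", "Name", "gene_id"))
            if (col %in% names(mc))
                gene_id <- ifelse(is.na(gene_id), as.character(mc[[col]]), gene_id)
        gene_id[is.na(gene_id)] <- paste0("feat", which(is.na(gene_id)))
    }
    out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                  IRanges::ranges(gr),
                                  strand = BiocGenerics::strand(gr))
    S4Vectors::mcols(out)$kind <- kind
    S4Vectors::mcols(out)$gene_id <- gene_id
    if (!is.null(genome)) {
        sl <- chromLengths(genome)
        sn <- as.character(GenomeInfoDb::seqnames(out))
        unknown <- setdiff(unique(sn), names(sl))
        if (length(unknown))
            stop("annotation chromosomes absent from genome: ",
                 paste(unknown, collapse = ", "))
        bad <- BiocGenerics::end(out) > sl[sn] | BiocGenerics::start(out) < 1L
        if (any(bad))
            stop("feature beyond chromosome bounds: ",
                 paste(head(S4Vectors::mcols(out)$gene_id[bad], 3), collapse = ", "))
        GenomeInfoDb::seqlevels(out) <- names(sl)
        GenomeInfoDb::seqlengths(out) <- unname(sl)
    }
    sort(out, ignore.strand = TRUE)
}

#' Extract gene models from an annotation
#'
#' Keeps gene-kind features (or everything if the annotation has no `kind`
#' distinctions) and checks GeneModel invariants: defined strand and valid
#' coordinates.
#'
#' @param annotation `GRanges` from [loadAnnotation()] or equivalent, with
#'   `gene_id` metadata.
#' @param kinds feature kinds treated as genes.
#' @return a `GRanges` of genes with `gene_id`.
#' @export
geneModels <- function(annotation, kinds = c("gene")) {
    mc <- S4Vectors::mcols(annotation)
    gr <- if ("kind" %in% names(mc) && any(mc$kind %in% kinds))
        annotation[mc$kind %in% kinds] else annotation
    if (length(gr) && any(as.character(BiocGenerics::strand(gr)) == "*"))
        stop("gene models need an explicit strand")
    gr
}

#' TSS and TES anchor positions
#'
#' Strand-aware transcript start/end anchors. Positions are returned as the
#' 1-based coordinate of the boundary base: for a `+` gene the TSS is its
#' `start` and the TES its `end`; for a `-` gene the TSS is its `end` and the
#' TES its `start`.
#'
#' @param genes `GRanges` of gene models with strand.
#' @return integer vector of positions, named by `gene_id` when present.
#' @export
tssPositions <- function(genes) {
    st <- as.character(BiocGenerics::strand(genes))
    pos <- ifelse(st == "-", BiocGenerics::end(genes), BiocGenerics::start(genes))
    ids <- S4Vectors::mcols(genes)$gene_id
    if (!is.null(ids)) names(pos) <- ids
    pos
}

#' @rdname tssPositions
#' @export
tesPositions <- function(genes) {
    st <- as.character(BiocGenerics::strand(genes))
    pos <- ifelse(st == "-", BiocGenerics::start(genes), BiocGenerics::end(genes))
    ids <- S4Vectors::mcols(genes)$gene_id
    if (!is.null(ids)) names(pos) <- ids
    pos
}

#' Find long annotation-free intergenic regions
#'
#' Returns every maximal interval of at least `minLength` bp that overlaps
#' no annotated feature on either strand, bounded by features and chromosome
#' ends. These regions are the basis of the intergenic meta-profile that
#' shows X enrichment extends beyond genes.
#'
#' @param annotation `GRanges` of features ("any annotation": every record,
#'   any kind, either strand).
#' @param genome a [GenomeBuild-class] sharing the annotation's chromosome
#'   names.
#' @param minLength minimum region length in bp (default 10 kb).
#' @return `GRanges` with metadata columns `center` (see [regionCenter()])
#'   and `chromClass`.
#' @export
findIntergenic <- function(annotation, genome, minLength = 10000) {
    sl <- chromLengths(genome)
    if (length(annotation)) {
        sn <- unique(as.character(GenomeInfoDb::seqnames(annotation)))
        unknown <- setdiff(sn, names(sl))
        if (length(unknown))
            stop("annotation chromosomes absent from genome: ",
                 paste(unknown, collapse = ", "))
    }
    si <- .seqinfoFor(genome)
    whole <- GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, unname(sl)),
                                    seqinfo = si)
    occupied <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(annotation),
                                       IRanges::ranges(annotation))
    GenomeInfoDb::seqlevels(occupied) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(occupied) <- si
    occupied <- GenomicRanges::reduce(occupied)
    free <- GenomicRanges::setdiff(whole, occupied)
    free <- free[BiocGenerics::width(free) >= minLength]
    free <- sort(free)
    S4Vectors::mcols(free)$center <- regionCenter(free)
    S4Vectors::mcols(free)$chromClass <-
        unname(chromClass(genome)[as.character(GenomeInfoDb::seqnames(free))])
    free
}

#' Center position of regions
#'
#' The center base of a region, with the floor convention for even lengths:
#' in 0-based half-open terms the center of `[s, e)` is `floor((s + e) / 2)`;
#' the returned value is that position's 1-based coordinate, so the center of
#' a region spanning bases 1..10000 is 5001 (0-based 5000).
#'
#' @param regions a `GRanges`.
#' @return integer vector of 1-based center positions.
#' @export
regionCenter <- function(regions) {
    s0 <- BiocGenerics::start(regions) - 1L
    e0 <- BiocGenerics::end(regions)
    as.integer(floor((s0 + e0) / 2)) + 1L
}

#' Write intergenic regions as BED3 plus a center/length table
#'
#' @param regions `GRanges` from [findIntergenic()].
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>_centers.tsv`.
#' @return invisibly, the two paths written.
#' @export
writeIntergenic <- function(regions, prefix) {
    bed <- paste0(prefix, ".bed")
    tsv <- paste0(prefix, "_centers.tsv")
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(regions)),
                     start = BiocGenerics::start(regions) - 1L,
                     end = BiocGenerics::end(regions))
    write.table(df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    df2 <- cbind(df,
                 center = S4Vectors::mcols(regions)$center - 1L,
                 length = BiocGenerics::width(regions))
    write.table(df2, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(bed = bed, tsv = tsv))
}

#' Write an annotation as GFF3
#'
#' @param annotation `GRanges` with `kind` and `gene_id` metadata.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAnnotationGFF3 <- function(annotation, path) {
    gr <- annotation
    mc <- S4Vectors::mcols(gr)
    out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                  IRanges::ranges(gr),
                                  strand = BiocGenerics::strand(gr))
    S4Vectors::mcols(out)$type <- if ("kind" %in% names(mc)) mc$kind else "gene"
    S4Vectors::mcols(out)$ID <- if ("gene_id" %in% names(mc)) mc$gene_id
                                else paste0("feat", seq_along(gr))
    S4Vectors::mcols(out)$source <- "xachrom"
    rtracklayer::export(out, path, format = "GFF3")
    invisible(path)
}
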