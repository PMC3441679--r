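#' Quantile-normalize a probe intensity matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' each column's sorted values are replaced by the across-sample mean of the
#' order statistics, with ties receiving the mean of the quantile values
#' they span. Delegates to `limma::normalizeQuantiles(..., ties = TRUE)`.
#'
#' @param mat numeric matrix, probes x samples.
#' @return matrix of the same shape; with a single column the input is
#'   returned unchanged with a warning.
#' @export
quantileNormalize <- function(mat) {
    mat <- as.matrix(mat)
    if (ncol(mat) < 2L) {
        warning("quantile normalization needs >= 2 samples; returning input")
        return(mat)
    }
    out <- limma::normalizeQuantiles(mat, ties = TRUE)
    dimnames(out) <- dimnames(mat)
    out
}

#' Summarize probe values to one expression value per gene
#'
#' Per gene and sample, the median of that gene's probe values (expression
#' arrays here carry three 60-mer probes per gene; the median is this
#' package's single-value summarizer).
#'
#' @param mat numeric matrix, probes x samples.
#' @param probeGenes character vector, parallel to rows, naming each probe's
#'   gene. Every probe must map to exactly one gene.
#' @return numeric matrix, genes x samples, rows named by gene.
#' @export
summarizeGenes <- function(mat, probeGenes) {
    mat <- as.matrix(mat)
    if (length(probeGenes) != nrow(mat))
        stop("probeGenes must map every probe (row) to a gene")
    if (anyNA(probeGenes) || any(!nzchar(probeGenes)))
        stop("every probe must map to exactly one gene")
    genes <- sort(unique(probeGenes))
    out <- vapply(seq_len(ncol(mat)), function(j)
        vapply(genes, function(g) median(mat[probeGenes == g, j]), numeric(1)),
        numeric(length(genes)))
    out <- matrix(out, nrow = length(genes),
                  dimnames = list(genes, colnames(mat)))
    out
}

#' Mean signal over a gene body
#'
#' bp-weighted mean of track values over each gene's `[start, end)`
#' interval, with fractional end bins weighted by their overlap.
#'
#' @param track a [SignalTrack-class].
#' @param genes `GRanges` of gene models with `gene_id`.
#' @return numeric vector named by gene id.
#' @export
geneBodySignal <- function(track, genes) {
    sl <- chromLengths(track@genome)
    chroms <- as.character(GenomeInfoDb::seqnames(genes))
    unknown <- setdiff(unique(chroms), names(sl))
    ids <- S4Vectors::mcols(genes)$gene_id
    if (is.null(ids)) ids <- paste0("gene", seq_along(genes))
    if (length(unknown))
        stop("gene off the track's genome: ",
             paste(head(ids[chroms %in% unknown], 3), collapse = ", "))
    res <- track@resolution
    out <- vapply(seq_along(genes), function(i)
        .intervalMean(track@values[[chroms[i]]], res, sl[[chroms[i]]],
                      BiocGenerics::start(genes)[i] - 1L,
                      BiocGenerics::end(genes)[i]),
        numeric(1))
    setNames(out, ids)
}

#' Spearman correlation of signal and expression by chromosome class
#'
#' Spearman rank correlation (average ranks for ties) between per-gene
#' signal and expression, computed separately for autosomal and X-linked
#' genes — the statistic showing gene-body signal tracks transcript levels
#' on both chromosome classes.
#'
#' @param signals numeric vector named by gene id (e.g. from
#'   [geneBodySignal()]).
#' @param expr numeric vector named by gene id.
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param genome a [GenomeBuild-class].
#' @return named numeric vector `c(autosome = rho_A, X = rho_X)`; `NA` when
#'   a class has constant ranks or fewer than 3 genes.
#' @export
signalExpressionCorrelation <- function(signals, expr, genes, genome) {
    ids <- S4Vectors::mcols(genes)$gene_id
    cls <- chromClass(genome)[as.character(GenomeInfoDb::seqnames(genes))]
    common <- ids[ids %in% names(signals) & ids %in% names(expr)]
    vapply(c(autosome = "autosome", X = "X"), function(cl) {
        gid <- common[cls[match(common, ids)] == cl]
        if (length(gid) < 3L) return(NA_real_)
        s <- signals[gid]; e <- expr[gid]
        ok <- !is.na(s) & !is.na(e)
        if (sum(ok) < 3L) return(NA_real_)
        suppressWarnings(rho <- cor(s[ok], e[ok], method = "spearman"))
        rho
    }, numeric(1))
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns `strain`, `gene`, `replicate`, `ct`.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("strain", "gene", "replicate", "ct")
    if (!all(need %in% names(df)))
        stop("Ct table needs columns: ", paste(need, collapse = ", "))
    df
}

#' Relative expression from qPCR Ct values (delta-delta-Ct)
#'
#' Per strain and gene, replicate-mean Ct values give
#' `dCt = Ct(gene) - Ct(reference gene)`; `ddCt = dCt(strain) -
#' dCt(calibrator strain)`; fold change `= efficiency^(-ddCt)`, so the
#' calibrator strain is 1 for every gene and the reference gene is 1 in
#' every strain. The conventional setup normalizes to an autosomal
#' reference gene (W07G4.4) with the wild-type strain (N2) as calibrator.
#' 95% CIs propagate the replicate variance of the Ct means into the
#' exponent (normal approximation, log-symmetric interval).
#'
#' @param ct data.frame with columns `strain`, `gene`, `replicate`, `ct`.
#' @param referenceGene reference (housekeeping) gene id.
#' @param calibratorStrain strain whose expression defines fold 1.
#' @param efficiency amplification efficiency (2 = perfect doubling per
#'   cycle).
#' @return data.frame with columns `strain`, `gene`, `fold`, `ci_lo`,
#'   `ci_hi`.
#' @export
qpcrRelativeExpression <- function(ct, referenceGene, calibratorStrain,
                                   efficiency = 2.0) {
    need <- c("strain", "gene", "replicate", "ct")
    if (!all(need %in% names(ct)))
        stop("Ct table needs columns: ", paste(need, collapse = ", "))
    if (any(ct$ct <= 0)) stop("Ct values must be positive")
    if (!calibratorStrain %in% ct$strain)
        stop("calibrator strain absent from table: ", calibratorStrain)
    strains <- unique(ct$strain)
    missingRef <- strains[!vapply(strains, function(s)
        any(ct$strain == s & ct$gene == referenceGene), logical(1))]
    if (length(missingRef))
        stop("reference gene missing for strain: ",
             paste(missingRef, collapse = ", "))
    agg <- aggregate(ct ~ strain + gene, data = ct, FUN = function(v)
        c(mean = mean(v), var = if (length(v) > 1) var(v) else 0, n = length(v)))
    stat <- data.frame(strain = agg$strain, gene = agg$gene,
                       mean = agg$ct[, "mean"],
                       se2 = agg$ct[, "var"] / agg$ct[, "n"])
    getRow <- function(s, g) stat[stat$strain == s & stat$gene == g, ]
    rows <- list()
    for (s in strains) {
        ref <- getRow(s, referenceGene)
        refCal <- getRow(calibratorStrain, referenceGene)
        for (g in unique(stat$gene[stat$strain == s])) {
            tgt <- getRow(s, g)
            tgtCal <- getRow(calibratorStrain, g)
            if (nrow(tgtCal) == 0L) next
            dct <- tgt$mean - ref$mean
            dctCal <- tgtCal$mean - refCal$mean
            ddct <- dct - dctCal
            if (s == calibratorStrain) {
                se <- 0
                ddct <- 0
            } else {
                se <- sqrt(tgt$se2 + ref$se2 + tgtCal$se2 + refCal$se2)
            }
            rows[[paste(s, g)]] <- data.frame(
                strain = s, gene = g,
                fold = efficiency^(-ddct),
                ci_lo = efficiency^(-(ddct + 1.96 * se)),
                ci_hi = efficiency^(-(ddct - 1.96 * se)))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
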