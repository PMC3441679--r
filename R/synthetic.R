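#' Configuration for the synthetic data generator
#'
#' Bundles every tunable of the synthetic study: a two-chromosome genome
#' (one autosome, one X), gene placement, log-normal expression, the signal
#' model on the log2-ratio scale (baseline, expression coupling, X genic and
#' intergenic boosts, replicate noise), the fusion-spreading model and the
#' qPCR model. Defaults encode the wild-type condition the analyses assume:
#' a 1.5 z-unit chromosome-wide X boost covering genic and intergenic space,
#' 2 biological replicates with independent Gaussian noise (sd 0.3), and a
#' true two-fold rise of dosage-compensated X-linked genes in
#' compensation-defective mutants.
#'
#' @param chromLengths named chromosome lengths (default 5 Mb autosome +
#'   5 Mb X).
#' @param nGenes number of genes across the genome (default 500), allocated
#'   to chromosomes proportionally to length.
#' @param geneLengthRange uniform bounds on gene length in bp.
#' @param minGap minimum intergenic gap in bp; remaining free space is
#'   spread between genes by a broken-stick draw, so a realistic tail of
#'   long (>10 kb) intergenic gaps arises.
#' @param exprMeanlog,exprSdlog log-normal expression parameters (natural
#'   log scale).
#' @param baseline baseline signal b, z units.
#' @param coupling expression coupling alpha, z units per log2 expression,
#'   applied over gene bodies.
#' @param xGenicBoost,xIntergenicBoost additive X-chromosome boosts (z
#'   units) over genic and intergenic X space in the wild type.
#' @param noiseSd per-replicate Gaussian noise sd, z units.
#' @param replicates number of biological replicates.
#' @param resolution track resolution, bp per bin.
#' @param backgroundSd sd of a bin-level background component shared across
#'   replicates and genotypes (locus-specific chromatin signal). `NULL`
#'   (default) auto-calibrates it so emitted tracks have autosomal variance
#'   `targetAutosomalSd^2`, emulating data that were standardized to unit
#'   autosomal variance; set 0 to disable.
#' @param targetAutosomalSd target autosomal sd for the auto-calibration.
#' @param set4Elevation global baseline elevation used by the
#'   `"set4-like"` genotype (X boosts removed, overall signal raised).
#' @param countLambda mean input coverage for the Poisson raw-count mode.
#' @param spreadAmplitude,spreadLength fusion-strain ectopic spreading:
#'   amplitude a (z units) and exponential decay length L (bp) past the
#'   junction.
#' @param fusionResolution track resolution for the fusion experiment
#'   (default 25 bp, emulating per-base-pair coverage pipelines).
#' @param fusionReplicates replicates per strain in the fusion experiment.
#' @param qpcrTrueFold true fold rise of dosage-compensated X genes in
#'   mutant strains (default 2).
#' @param qpcrCtSd replicate Ct noise sd (cycles).
#' @param qpcrReplicates qPCR replicates per strain and gene.
#' @param qpcrStrains strains, the first being the wild-type calibrator.
#' @param qpcrGenes assayed genes; `qpcrReferenceGene` must be among them.
#' @param qpcrXGenes the dosage-compensated X-linked subset of `qpcrGenes`.
#' @param qpcrReferenceGene autosomal normalization gene.
#' @return a list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(chromLengths = c(chrI = 5e6, chrX = 5e6),
                            nGenes = 500,
                            geneLengthRange = c(1000, 5000),
                            minGap = 200,
                            exprMeanlog = 3, exprSdlog = 1.5,
                            baseline = 0, coupling = 0.15,
                            xGenicBoost = 1.5, xIntergenicBoost = 1.5,
                            noiseSd = 0.3, replicates = 2, resolution = 100,
                            backgroundSd = NULL, targetAutosomalSd = 1,
                            set4Elevation = 0.5, countLambda = 50,
                            spreadAmplitude = 1, spreadLength = 1e5,
                            fusionResolution = 25, fusionReplicates = 2,
                            qpcrTrueFold = 2, qpcrCtSd = 0.1,
                            qpcrReplicates = 3,
                            qpcrStrains = c("N2", "dpy-21"),
                            qpcrGenes = c("W07G4.4", "act-1", "apl-1",
                                          "aco-1", "ajm-1"),
                            qpcrXGenes = c("apl-1", "aco-1", "ajm-1"),
                            qpcrReferenceGene = "W07G4.4") {
    cfg <- as.list(environment())
    stopifnot(all(cfg$chromLengths > 0), cfg$nGenes >= 0,
              cfg$geneLengthRange[1] > 0,
              diff(cfg$geneLengthRange) >= 0,
              cfg$noiseSd >= 0, cfg$replicates >= 1, cfg$resolution >= 1,
              cfg$qpcrTrueFold > 0, cfg$qpcrCtSd >= 0,
              cfg$qpcrReferenceGene %in% cfg$qpcrGenes)
    class(cfg) <- "SyntheticConfig"
    cfg
}

# fixed sub-stream offsets from the master seed, so each component is
# independently reproducible
.SEED_GENOME <- 11L
.SEED_BACKGROUND <- 23L
.SEED_FUSION_BG <- 29L
.SEED_QPCR <- 53L
.SEED_CHIP_BASE <- 1000L

#' Generate a synthetic genome, gene annotation and expression table
#'
#' Places non-overlapping genes along each chromosome (lengths uniform in
#' `geneLengthRange`, gaps = `minGap` plus a broken-stick share of the free
#' space) and draws log-normal expression. Deterministic given `seed`.
#'
#' @param config a [syntheticConfig()].
#' @param seed master seed.
#' @return list with elements `genome` ([GenomeBuild-class]), `genes`
#'   (`GRanges` with `kind` and `gene_id`), `expression` (named numeric).
#' @export
generateGenome <- function(config, seed) {
    set.seed(seed + .SEED_GENOME)
    sl <- config$chromLengths
    genome <- GenomeBuild(sl)
    nc <- round(config$nGenes * sl / sum(sl))
    # fix rounding drift on the last chromosome
    nc[length(nc)] <- config$nGenes - sum(nc[-length(nc)])
    allGr <- list()
    exprs <- numeric(0)
    for (ci in seq_along(sl)) {
        chrom <- names(sl)[ci]
        n <- nc[[ci]]
        if (n <= 0) next
        glen <- floor(runif(n, config$geneLengthRange[1],
                            config$geneLengthRange[2] + 1))
        free <- sl[[ci]] - sum(glen) - (n + 1) * config$minGap
        if (free < 0)
            stop("infeasible packing: genes exceed chromosome ", chrom)
        brk <- diff(c(0, sort(runif(n)), 1))
        gaps <- config$minGap + floor(brk * free)
        starts <- cumsum(gaps[seq_len(n)] + c(0, glen[-n])) + 1L
        gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(starts, width = glen),
            strand = sample(c("+", "-"), n, replace = TRUE))
        GenomeInfoDb::seqlevels(gr) <- names(sl)
        ids <- sprintf("%s_g%04d", chrom, seq_len(n))
        S4Vectors::mcols(gr)$kind <- "gene"
        S4Vectors::mcols(gr)$gene_id <- ids
        allGr[[chrom]] <- gr
        exprs <- c(exprs, setNames(
            rlnorm(n, config$exprMeanlog, config$exprSdlog), ids))
    }
    genes <- if (length(allGr)) do.call(c, unname(allGr))
             else GenomicRanges::GRanges()
    if (length(genes) == 0L) {
        S4Vectors::mcols(genes)$kind <- character(0)
        S4Vectors::mcols(genes)$gene_id <- character(0)
    }
    GenomeInfoDb::seqlevels(genes) <- names(sl)
    GenomeInfoDb::seqlengths(genes) <- unname(sl)
    list(genome = genome, genes = genes, expression = exprs)
}

# latent per-bin mean signal (z units) for a genotype, at `resolution`
.latentMu <- function(genomeData, config, genotype, resolution) {
    genome <- genomeData$genome
    genes <- genomeData$genes
    expr <- genomeData$expression
    sl <- chromLengths(genome)
    cls <- chromClass(genome)
    base <- config$baseline +
        if (genotype == "set4-like") config$set4Elevation else 0
    dX <- if (genotype == "WT") config$xGenicBoost else 0
    dIg <- if (genotype == "WT") config$xIntergenicBoost else 0
    ids <- S4Vectors::mcols(genes)$gene_id
    w <- config$coupling * log2(expr[ids])
    covFrac <- GenomicRanges::coverage(genes)
    covExpr <- GenomicRanges::coverage(genes, weight = as.numeric(w))
    lapply(setNames(names(sl), names(sl)), function(chrom) {
        n <- ceiling(sl[[chrom]] / resolution)
        starts <- (seq_len(n) - 1L) * resolution + 1L
        ends <- pmin(starts + resolution - 1L, sl[[chrom]])
        g <- as.numeric(IRanges::viewMeans(
            IRanges::Views(covFrac[[chrom]], starts, ends)))
        e <- as.numeric(IRanges::viewMeans(
            IRanges::Views(covExpr[[chrom]], starts, ends)))
        mu <- base + e
        if (cls[[chrom]] == "X") mu <- mu + dX * g + dIg * (1 - g)
        mu
    })
}

# shared bin-level background; variance auto-calibrated so that per-replicate
# autosomal variance is targetAutosomalSd^2 (matching standardized data)
.backgroundSd <- function(muList, config, genome) {
    if (!is.null(config$backgroundSd)) return(config$backgroundSd)
    av <- unlist(muList[autosomes(genome)], use.names = FALSE)
    varMu <- mean((av - mean(av))^2)
    sqrt(max(0, config$targetAutosomalSd^2 - varMu - config$noiseSd^2))
}

.drawBackground <- function(genome, resolution, sdBg, seed,
                            offset = .SEED_BACKGROUND) {
    set.seed(seed + offset)
    sl <- chromLengths(genome)
    lapply(setNames(names(sl), names(sl)), function(chrom)
        rnorm(ceiling(sl[[chrom]] / resolution), 0, sdBg))
}

#' Generate replicate ChIP and input tracks for a genotype
#'
#' The latent per-bin mean is `baseline + coupling * log2(expression)` over
#' gene bodies, plus (wild type only) the X genic boost over genic X bins
#' and the X intergenic boost over the rest of the X. `"dcc-mutant"` removes
#' both X boosts; `"set4-like"` removes them and raises the baseline
#' globally. A background component (shared across replicates and genotypes)
#' models locus-specific signal; each replicate adds independent Gaussian
#' noise. In the default mode chip tracks are emitted as pre-formed
#' log2-ratio tracks with matched null input tracks; `mode = "counts"`
#' emits Poisson raw-count chip/input pairs for the [log2Ratio()] entry
#' point.
#'
#' @param genomeData output of [generateGenome()].
#' @param config a [syntheticConfig()].
#' @param genotype `"WT"`, `"dcc-mutant"` or `"set4-like"`.
#' @param seed master seed (the same seed used for [generateGenome()] keeps
#'   background and genome in register).
#' @param mode `"log2ratio"` (default) or `"counts"`.
#' @return list with elements `chip` and `input`, each a list of
#'   [SignalTrack-class] replicates, plus `truth` (the latent parameters).
#' @export
generateChipExperiment <- function(genomeData, config,
        genotype = c("WT", "dcc-mutant", "set4-like"), seed,
        mode = c("log2ratio", "counts")) {
    genotype <- match.arg(genotype)
    mode <- match.arg(mode)
    genome <- genomeData$genome
    mu <- .latentMu(genomeData, config, genotype, config$resolution)
    # autosomal latent variance is genotype-invariant (X boosts do not touch
    # autosomes; the set4-like elevation is a constant), so calibrating on
    # this genotype's mu gives the same background sd for every genotype
    sdBg <- .backgroundSd(mu, config, genome)
    bg <- .drawBackground(genome, config$resolution, sdBg, seed)
    gi <- match(genotype, c("WT", "dcc-mutant", "set4-like"))
    chip <- vector("list", config$replicates)
    input <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
        set.seed(seed + .SEED_CHIP_BASE * gi + r)
        if (mode == "log2ratio") {
            values <- mapply(function(m, b)
                m + b + rnorm(length(m), 0, config$noiseSd),
                mu, bg, SIMPLIFY = FALSE)
            chip[[r]] <- SignalTrack(values, genome, config$resolution,
                                     "log2-ratio", genotype, r)
            nullv <- lapply(mu, function(m)
                rnorm(length(m), 0, config$noiseSd))
            input[[r]] <- SignalTrack(nullv, genome, config$resolution,
                                      "log2-ratio", paste0(genotype, "-input"), r)
        } else {
            lam <- mapply(function(m, b)
                config$countLambda * 2^(m + b), mu, bg, SIMPLIFY = FALSE)
            cvals <- lapply(lam, function(l) as.numeric(rpois(length(l), l)))
            ivals <- lapply(lam, function(l)
                as.numeric(rpois(length(l), config$countLambda)))
            chip[[r]] <- SignalTrack(cvals, genome, config$resolution,
                                     "raw-count", genotype, r)
            input[[r]] <- SignalTrack(ivals, genome, config$resolution,
                                      "raw-count", paste0(genotype, "-input"), r)
        }
    }
    list(chip = chip, input = input,
         truth = list(genotype = genotype, backgroundSd = sdBg,
                      xGenicBoost = if (genotype == "WT") config$xGenicBoost else 0,
                      xIntergenicBoost = if (genotype == "WT") config$xIntergenicBoost else 0))
}

#' Generate a fusion-strain spreading experiment
#'
#' Builds the fusion karyotype (X joined, forward, to the left end of the
#' first autosome), then emits replicate-averaged wild-type-style tracks for
#' the normal karyotype (control) and the fusion strain, in which
#' `spreadAmplitude * exp(-d / spreadLength)` is added to the
#' autosome-derived segment at distance `d` past the junction. The
#' bin-level background is shared between the strains (same underlying
#' genome), so it cancels in fusion-minus-control contrasts just as locus
#' effects cancel in a matched strain comparison.
#'
#' @param config a [syntheticConfig()].
#' @param seed master seed.
#' @return list with `map` ([FusionMap-class]), `fusionTrack`,
#'   `controlTrack` ([SignalTrack-class], replicate-averaged),
#'   `genomeData`, `fusionGenome` and `truth`.
#' @export
generateFusionExperiment <- function(config, seed) {
    genomeData <- generateGenome(config, seed)
    genome <- genomeData$genome
    res <- config$fusionResolution
    xc <- xChromosome(genome)
    if (is.na(xc)) stop("fusion experiment needs an X chromosome")
    auto <- autosomes(genome)[1]
    map <- buildFusion(genome, left = xc, right = auto)
    fgenome <- fusionGenome(map, genome)
    mu <- .latentMu(genomeData, config, "WT", res)
    sdBg <- .backgroundSd(mu, config, genome)
    bg <- .drawBackground(genome, res, sdBg, seed, offset = .SEED_FUSION_BG)
    latent <- mapply(`+`, mu, bg, SIMPLIFY = FALSE)
    # fused latent signal: concatenate source bins in fused order (chromosome
    # lengths are multiples of the resolution in the default configuration;
    # otherwise the junction bin is approximated by the left segment's bin)
    fusedLatent <- c(latent[[xc]], latent[[auto]])
    nRight <- length(latent[[auto]])
    d <- (seq_len(nRight) - 0.5) * res
    fusedLatent[length(latent[[xc]]) + seq_len(nRight)] <-
        fusedLatent[length(latent[[xc]]) + seq_len(nRight)] +
        config$spreadAmplitude * exp(-d / config$spreadLength)
    fusedLatent <- fusedLatent[seq_len(ceiling(map@fusedLength / res))]
    avg <- function(latentList, genomeObj, sampleTag, seedBase) {
        reps <- lapply(seq_len(config$fusionReplicates), function(r) {
            set.seed(seed + seedBase + r)
            values <- lapply(latentList, function(m)
                m + rnorm(length(m), 0, config$noiseSd))
            SignalTrack(values, genomeObj, res, "log2-ratio", sampleTag, r)
        })
        averageTracks(reps)
    }
    controlTrack <- avg(latent, genome, "control", 7000L)
    fusionTrack <- avg(setNames(list(fusedLatent), map@fusedName),
                       GenomeBuild(setNames(map@fusedLength, map@fusedName),
                                   "autosome"),
                       "fusion", 8000L)
    list(map = map, fusionTrack = fusionTrack, controlTrack = controlTrack,
         genomeData = genomeData, fusionGenome = fgenome,
         truth = list(amplitude = config$spreadAmplitude,
                      decayLength = config$spreadLength,
                      backgroundSd = sdBg))
}

#' Generate a synthetic qPCR Ct table
#'
#' Each gene gets a base Ct; dosage-compensated X-linked genes in
#' non-calibrator strains are shifted down by `log_efficiency(trueFold)`
#' cycles (two-fold rise = one cycle at efficiency 2); a random strain
#' offset models loading differences (removed by reference-gene
#' normalization); replicate noise is Gaussian with sd `qpcrCtSd`.
#'
#' @param config a [syntheticConfig()].
#' @param seed master seed.
#' @param efficiency amplification efficiency used to convert fold to
#'   cycles.
#' @return data.frame with columns `strain`, `gene`, `replicate`, `ct`;
#'   attribute `truth` records the per-strain-gene true fold.
#' @export
generateQpcr <- function(config, seed, efficiency = 2.0) {
    set.seed(seed + .SEED_QPCR)
    genes <- config$qpcrGenes
    strains <- config$qpcrStrains
    calibrator <- strains[1]
    baseCt <- setNames(runif(length(genes), 18, 25), genes)
    strainOffset <- setNames(rnorm(length(strains), 0, 0.5), strains)
    strainOffset[calibrator] <- 0
    rows <- list()
    truth <- list()
    for (s in strains) for (g in genes) {
        fold <- if (s != calibrator && g %in% config$qpcrXGenes)
            config$qpcrTrueFold else 1
        truth[[paste(s, g)]] <- data.frame(strain = s, gene = g, fold = fold)
        for (r in seq_len(config$qpcrReplicates)) {
            ctv <- baseCt[[g]] + strainOffset[[s]] -
                log(fold) / log(efficiency) +
                rnorm(1, 0, config$qpcrCtSd)
            rows[[paste(s, g, r)]] <- data.frame(
                strain = s, gene = g, replicate = r, ct = ctv)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- do.call(rbind, unname(truth))
    out
}
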