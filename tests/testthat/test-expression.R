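test_that("quantile normalization equalizes sample distributions", {
    m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
    qn <- quantileNormalize(m)
    expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
    expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))
    # identical columns unchanged
    m2 <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
    expect_equal(quantileNormalize(m2), m2)
    # invariant: all columns share the same sorted vector
    set.seed(4)
    m3 <- matrix(rlnorm(60), ncol = 3)
    qn3 <- quantileNormalize(m3)
    expect_equal(sort(qn3[, 1]), sort(qn3[, 2]))
    expect_equal(sort(qn3[, 2]), sort(qn3[, 3]))
    expect_warning(one <- quantileNormalize(m[, 1, drop = FALSE]), ">= 2")
    expect_equal(one, m[, 1, drop = FALSE])
})

test_that("probe-to-gene summarization is a per-gene median", {
    m <- matrix(c(2, 4, 9, 10, 20, 2, 4, 9, 10, 20), ncol = 2,
                dimnames = list(NULL, c("s1", "s2")))
    genes <- c("gA", "gA", "gA", "gB", "gB")
    s <- summarizeGenes(m, genes)
    expect_equal(s["gA", "s1"], 4)    # odd count
    expect_equal(s["gB", "s1"], 15)   # even count -> midpoint
    # permuting probes changes nothing
    p <- sample(5)
    expect_equal(summarizeGenes(m[p, ], genes[p]), s)
    expect_error(summarizeGenes(m, genes[1:3]), "every probe")
})

test_that("gene-body signal is a bp-weighted mean with fractional end bins", {
    gb <- toyGenome(c(chrI = 1000L, chrX = 500L))
    tr <- constTrack(gb, 100, 2.5, "z-score")
    genes <- toyGenes("chrI", 151, 450, "+", ids = "g1")
    expect_equal(unname(geneBodySignal(tr, genes)), 2.5)
    # half at 0, half at 2
    v <- list(chrI = rep(c(0, 2), each = 5), chrX = rep(0, 5))
    tr2 <- trackFrom(v, gb, 100, "z-score")
    half <- toyGenes("chrI", 401, 600, "+", ids = "h")
    expect_equal(unname(geneBodySignal(tr2, half)), 1)
    # fractional-bin weighting agrees with a per-bp oracle
    set.seed(5)
    vals <- rnorm(10)
    tr3 <- trackFrom(list(chrI = vals, chrX = rep(0, 5)), gb, 100, "z-score")
    for (i in 1:10) {
        s <- sample(900, 1); e <- s + sample(100, 1)
        g <- toyGenes("chrI", s, e, "+", ids = "r")
        perBp <- mean(vals[ceiling(s:e / 100)])
        expect_equal(unname(geneBodySignal(tr3, g)), perBp)
    }
    off <- toyGenes("chrII", 1, 10, "+")
    expect_error(geneBodySignal(tr, off), "off the track")
})

test_that("signal-expression correlation is per-class Spearman with tie handling", {
    gb <- toyGenome(c(chrI = 10000L, chrX = 10000L))
    ids <- c(paste0("a", 1:5), paste0("x", 1:5))
    genes <- toyGenes(rep(c("chrI", "chrX"), each = 5),
                      rep(seq(1, 8001, 2000), 2), rep(seq(1000, 9000, 2000), 2),
                      rep("+", 10), ids = ids)
    # strictly increasing / decreasing
    sig <- setNames(c(1:5, 5:1), ids)
    expr <- setNames(rep(1:5, 2), ids)
    rho <- signalExpressionCorrelation(sig, expr, genes, gb)
    expect_equal(unname(rho["autosome"]), 1)
    expect_equal(unname(rho["X"]), -1)
    # hand-written pairs with a tie: equals Pearson on average ranks
    sigT <- setNames(c(1, 2, 2, 4, 7, 1:5), ids)
    exprT <- setNames(c(3, 1, 5, 2, 4, 1:5), ids)
    rhoT <- signalExpressionCorrelation(sigT, exprT, genes, gb)
    oracle <- cor(rank(c(1, 2, 2, 4, 7)), rank(c(3, 1, 5, 2, 4)))
    expect_equal(unname(rhoT["autosome"]), oracle)
    # constant ranks are undefined
    sigC <- setNames(c(rep(1, 5), 1:5), ids)
    rhoC <- signalExpressionCorrelation(sigC, expr, genes, gb)
    expect_true(is.na(rhoC["autosome"]))
    expect_equal(unname(rhoC["X"]), 1)
})

test_that("delta-delta-Ct folds follow the textbook identities", {
    ct <- expand.grid(strain = c("N2", "mut"), gene = c("ref", "tgt"),
                      replicate = 1:2, stringsAsFactors = FALSE)
    ct$ct <- 20
    # mutant target one cycle lower -> fold 2 at efficiency 2
    ct$ct[ct$strain == "mut" & ct$gene == "tgt"] <- 19
    rel <- qpcrRelativeExpression(ct, "ref", "N2")
    expect_equal(rel$fold[rel$strain == "mut" & rel$gene == "tgt"], 2)
    expect_true(all(rel$fold[rel$strain == "N2"] == 1))
    expect_true(all(rel$fold[rel$gene == "ref"] == 1))
    # shift equivariance: adding a constant to one strain's Cts changes nothing
    ct2 <- ct
    ct2$ct[ct2$strain == "mut"] <- ct2$ct[ct2$strain == "mut"] + 3.7
    expect_equal(qpcrRelativeExpression(ct2, "ref", "N2")$fold, rel$fold)
    # efficiency scales the exponent base
    rel15 <- qpcrRelativeExpression(ct, "ref", "N2", efficiency = 1.5)
    expect_equal(rel15$fold[rel15$strain == "mut" & rel15$gene == "tgt"], 1.5)
    # missing reference gene is an error naming the strain
    bad <- ct[!(ct$strain == "mut" & ct$gene == "ref"), ]
    expect_error(qpcrRelativeExpression(bad, "ref", "N2"), "mut")
})

test_that("qPCR CIs cover a simulated true fold", {
    cfg <- testConfig()
    ct <- generateQpcr(cfg, 11)
    rel <- qpcrRelativeExpression(ct, cfg$qpcrReferenceGene,
                                  cfg$qpcrStrains[1])
    mutX <- rel[rel$strain != cfg$qpcrStrains[1] &
                rel$gene %in% cfg$qpcrXGenes, ]
    expect_true(all(mutX$ci_lo <= 2 & 2 <= mutX$ci_hi))
    expect_true(all(mutX$ci_lo < mutX$fold & mutX$fold < mutX$ci_hi))
    # X-linked dosage-compensated genes rise above autosomal ones in the mutant
    mutA <- rel[rel$strain != cfg$qpcrStrains[1] &
                !rel$gene %in% cfg$qpcrXGenes, ]
    expect_gt(min(mutX$fold), max(mutA$fold))
})

test_that("the shipped qPCR primer table matches the assay design", {
    path <- system.file("extdata", "qpcr_primers.tsv", package = "xachrom")
    primers <- read.delim(path)
    expect_setequal(primers$gene,
                    c("W07G4.4", "act-1", "apl-1", "aco-1", "ajm-1"))
    expect_equal(sort(unique(primers$chromosome)), c("V", "X"))
    expect_true(all(grepl("^[ACGT]+$", primers$forward)))
    expect_true(all(nchar(primers$forward) == 24))
})
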