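test_that("log2 ratio matches hand arithmetic and identity cases", {
    gb <- toyGenome(c(chrI = 200L, chrX = 100L))
    chip <- trackFrom(list(chrI = c(3, 5), chrX = 4), gb, 100, "raw-count")
    input <- trackFrom(list(chrI = c(1, 1), chrX = 4), gb, 100, "raw-count")
    lr <- log2Ratio(chip, input, pseudocount = 1)
    expect_equal(trackValues(lr, "chrI"), c(1, log2(3)))
    expect_equal(trackValues(lr, "chrX"), 0)   # chip = input
    expect_equal(trackKind(lr), "log2-ratio")
    # both zero -> 0
    z <- log2Ratio(constTrack(gb, 100, 0, "raw-count"),
                   constTrack(gb, 100, 0, "raw-count"))
    expect_true(all(unlist(trackValues(z)) == 0))
    # contract errors
    gb2 <- toyGenome(c(chrI = 300L, chrX = 100L))
    expect_error(log2Ratio(chip, constTrack(gb2, 100, 1, "raw-count")),
                 "different genomes")
    expect_error(log2Ratio(chip, constTrack(gb, 50, 1, "raw-count")),
                 "resolution")
})

test_that("standardization centers and scales the reference set only", {
    # autosomal values {-1, +1}, X value {3}: population mu=0 sd=1 -> unchanged
    gb <- GenomeBuild(c(chrI = 2, chrX = 1))
    tr <- trackFrom(list(chrI = c(-1, 1), chrX = 3), gb, 1)
    z <- standardize(tr, reference = "autosomes")
    expect_equal(trackValues(z, "chrI"), c(-1, 1))
    expect_equal(trackValues(z, "chrX"), 3)
    expect_equal(trackKind(z), "z-score")
    # constant reference -> degenerate scale
    expect_error(standardize(constTrack(gb, 1, 5)), "degenerate")
})

test_that("standardization contract holds on synthetic data and is idempotent", {
    cfg <- testConfig()
    gd <- generateGenome(cfg, 7)
    tr <- generateChipExperiment(gd, cfg, "WT", 7)$chip[[1]]
    z <- standardize(tr, reference = "autosomes")
    av <- unlist(trackValues(z)[autosomes(gd$genome)], use.names = FALSE)
    expect_lt(abs(mean(av)), 1e-9)
    expect_lt(abs(sqrt(mean((av - mean(av))^2)) - 1), 1e-9)
    z2 <- standardize(z, reference = "autosomes")
    expect_equal(unlist(trackValues(z2)), unlist(trackValues(z)),
                 tolerance = 1e-9)
    # reference = "all" centers the pooled values instead
    zAll <- standardize(tr, reference = "all")
    allv <- unlist(trackValues(zAll), use.names = FALSE)
    expect_lt(abs(mean(allv)), 1e-9)
    expect_lt(abs(sqrt(mean((allv - mean(allv))^2)) - 1), 1e-9)
})

test_that("replicate averaging is element-wise, order-invariant, NA-aware", {
    gb <- GenomeBuild(c(chrI = 2, chrX = 1))
    t1 <- trackFrom(list(chrI = c(0, 2), chrX = 1), gb, 1)
    t2 <- trackFrom(list(chrI = c(2, 0), chrX = 2), gb, 1)
    t3 <- trackFrom(list(chrI = c(4, 4), chrX = 6), gb, 1)
    avg <- averageTracks(list(t1, t2, t3))
    expect_equal(trackValues(avg, "chrI"), c(2, 2))
    expect_equal(trackValues(avg, "chrX"), 3)
    perm <- averageTracks(list(t3, t1, t2))
    expect_equal(trackValues(perm), trackValues(avg))
    expect_equal(trackValues(averageTracks(list(t1)), "chrI"), c(0, 2))
    # one replicate missing at a bin -> mean of the present ones;
    # two missing -> missing
    tN1 <- trackFrom(list(chrI = c(NA, 2), chrX = NA), gb, 1)
    tN2 <- trackFrom(list(chrI = c(NA, 4), chrX = 2), gb, 1)
    a2 <- averageTracks(list(t1, tN1, t3))
    expect_equal(trackValues(a2, "chrI"), c(2, 8 / 3))
    a3 <- averageTracks(list(t1, tN1, tN2))
    expect_equal(trackValues(a3, "chrI"), c(NA_real_, 8 / 3))
    expect_error(averageTracks(list()), "at least one")
})

test_that("median smoothing matches the naive sliding-window oracle", {
    gb1 <- GenomeBuild(c(chrI = 5, chrX = 1))
    tr <- trackFrom(list(chrI = c(1, 2, 9, 2, 1), chrX = 0), gb1, 1)
    sm <- medianSmooth(tr, window = 3)
    expect_equal(trackValues(sm, "chrI"), c(1.5, 2, 2, 2, 1.5))
    # a lone spike is erased
    spike <- c(rep(0, 10), 10, rep(0, 10))
    gb2 <- GenomeBuild(c(chrI = 21, chrX = 1))
    sp <- medianSmooth(trackFrom(list(chrI = spike, chrX = 0), gb2, 1), 3)
    expect_equal(trackValues(sp, "chrI")[11], 0)
    # constant track unchanged
    gb3 <- toyGenome(c(chrI = 1000L, chrX = 500L))
    cs <- medianSmooth(constTrack(gb3, 10, 2.5), 110)
    expect_true(all(unlist(trackValues(cs)) == 2.5))
    expect_error(medianSmooth(constTrack(gb3, 10, 1), 5), "window")
    # random tracks with and without missing values, both code paths
    set.seed(1)
    for (rep in 1:20) {
        n <- sample(5:400, 1)
        v <- rnorm(n)
        if (rep %% 2 == 0) v[sample(n, n %/% 10)] <- NA
        res <- sample(1:20, 1)
        window <- res * sample(1:9, 1)
        gb <- GenomeBuild(c(chrI = n * res, chrX = res))
        sm <- medianSmooth(trackFrom(list(chrI = v, chrX = 0), gb, res), window)
        half <- floor(window / (2 * res))
        expect_equal(trackValues(sm, "chrI"), slideMedianOracle(v, half))
    }
})

test_that("chromosome summaries use interpolated percentiles", {
    gb <- GenomeBuild(c(chrI = 100, chrX = 10))
    tr <- trackFrom(list(chrI = as.numeric(1:100), chrX = rep(7, 10)), gb, 1)
    s <- chromosomeSummary(tr)
    i <- s[s$chrom == "chrI", ]
    expect_equal(i$median, 50.5)
    expect_equal(i$q25, quantile(1:100, 0.25, names = FALSE))
    expect_equal(i$p2.5, quantile(1:100, 0.025, names = FALSE))
    x <- s[s$chrom == "chrX", ]
    expect_true(all(x[c("p2.5", "q25", "median", "q75", "p97.5")] == 7))
    # ordering invariant
    expect_true(all(s$p2.5 <= s$q25 & s$q25 <= s$median &
                    s$median <= s$q75 & s$q75 <= s$p97.5))
    trNA <- trackFrom(list(chrI = as.numeric(1:100),
                           chrX = rep(NA_real_, 10)), gb, 1)
    expect_error(chromosomeSummary(trNA), "chrX")
})

test_that("X:autosome enrichment is a shifted-median contrast", {
    gb <- GenomeBuild(c(chrI = 100, chrX = 100))
    v <- rnorm(100)
    tr <- trackFrom(list(chrI = v, chrX = v + 0.7), gb, 1)
    expect_equal(xaEnrichment(tr), 0.7)
    same <- trackFrom(list(chrI = v, chrX = v), gb, 1)
    expect_equal(xaEnrichment(same), 0)
    noX <- SignalTrack(list(chrI = v), GenomeBuild(c(chrI = 100)), 1)
    expect_error(xaEnrichment(noX), "no X")
})

test_that("tracks survive a bedGraph round trip", {
    gb <- toyGenome(c(chrI = 1000L, chrX = 500L))
    set.seed(3)
    values <- list(chrI = rnorm(10), chrX = rnorm(5))
    values$chrI[4] <- NA
    tr <- SignalTrack(values, gb, 100, "z-score")
    path <- tempfile(fileext = ".bedGraph")
    writeTrack(tr, path)
    back <- readTrack(path, gb, 100, kind = "z-score")
    expect_equal(trackValues(back), trackValues(tr), tolerance = 1e-6)
})
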