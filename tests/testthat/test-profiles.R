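test_that("expression quintile groups are sized and tie-broken deterministically", {
    gb <- toyGenome(c(chrI = 20000L, chrX = 20000L))
    genes <- toyGenes(rep(c("chrI", "chrX"), each = 10),
                      rep(seq(1, 19000, by = 2000), 2),
                      rep(seq(1000, 20000, by = 2000), 2),
                      rep("+", 20),
                      ids = c(paste0("a", 1:10), paste0("x", 1:10)))
    expr <- setNames(c(1:10, 10:1), c(paste0("a", 1:10), paste0("x", 1:10)))
    g <- assignGroups(expr, genes, gb)
    expect_equal(names(g)[g == "A-top20"], c("a9", "a10"))
    expect_equal(names(g)[g == "A-bottom20"], c("a1", "a2"))
    expect_equal(names(g)[g == "X-top20"], c("x1", "x2"))
    expect_equal(sum(g == "none"), 12)
    # all-equal expression: tie-break by id, sizes still floor(0.2 n)
    gTie <- assignGroups(setNames(rep(1, 20), names(expr)), genes, gb)
    expect_equal(names(gTie)[gTie == "A-top20"], c("a8", "a9"))  # lexicographic
    expect_equal(sum(gTie == "X-bottom20"), 2)
    # degenerate class skipped with warning
    few <- toyGenes(c("chrI", "chrI", "chrI", "chrI", "chrI", "chrX", "chrX"),
                    seq(1, 601, by = 100), seq(50, 650, by = 100),
                    rep("+", 7), ids = paste0("g", 1:7))
    fexpr <- setNames(1:7, paste0("g", 1:7))
    expect_warning(gFew <- assignGroups(fexpr, few, gb), "fewer than 5 X")
    expect_true(all(gFew[c("g6", "g7")] == "none"))
    # global scope ranks across classes
    gGlob <- assignGroups(expr, genes, gb, quantileScope = "global")
    expect_equal(sum(gGlob %in% c("A-top20", "X-top20")), 4)
})

test_that("anchored profiles have the right shape and respect strand", {
    gb <- toyGenome(c(chrI = 10000L, chrX = 5000L))
    tr <- constTrack(gb, 50, 1.25, "z-score")
    genes <- toyGenes("chrI", 4001, 6000, "+", ids = "g1")
    pm <- anchoredProfile(tr, genes, "TSS", 1000, 1000, 50)
    expect_equal(ncol(profileValues(pm)), 40)
    expect_true(all(profileValues(pm) == 1.25))
    expect_equal(binOffsets(pm)[1], -1000)
    # TES window 1.5 kb / 1 kb -> 50 columns
    pmTes <- anchoredProfile(tr, genes, "TES", 1500, 1000, 50)
    expect_equal(ncol(profileValues(pmTes)), 50)
    expect_error(anchoredProfile(tr, genes, "TSS", 1000, 1030, 50),
                 "multiple")
    bad <- toyGenes("chrXIV", 1, 100, "+")
    expect_error(anchoredProfile(tr, bad, "TSS", 100, 100, 50), "unknown")
})

test_that("plus and minus genes anchored on a step edge are mirror images", {
    gb <- toyGenome(c(chrI = 10000L, chrX = 5000L))
    p <- 5000   # step: 0 before 0-based position 5000, 1 from there on
    values <- list(chrI = c(rep(0, p / 50), rep(1, p / 50)),
                   chrX = rep(0, 100))
    tr <- trackFrom(values, gb, 50, "z-score")
    genes <- toyGenes(c("chrI", "chrI"), c(p + 1, 3001), c(7000, p),
                      c("+", "-"), ids = c("plus", "minus"))
    pm <- anchoredProfile(tr, genes, "TSS", 1000, 1000, 50)
    m <- profileValues(pm)
    expect_equal(m["plus", ], rev(m["minus", ]))
    expect_equal(unname(m["plus", ]), c(rep(0, 20), rep(1, 20)))
})

test_that("out-of-chromosome window bins are missing", {
    gb <- toyGenome(c(chrI = 2000L, chrX = 1000L))
    tr <- constTrack(gb, 50, 1, "z-score")
    genes <- toyGenes("chrI", 101, 700, "+", ids = "edge")
    pm <- anchoredProfile(tr, genes, "TSS", 1000, 1000, 50)
    m <- profileValues(pm)[1, ]
    expect_true(all(is.na(m[1:18])))   # window starts 900 bp before chrI
    expect_true(all(m[19:40] == 1))
})

test_that("gene-body indicator tracks profile as body ~1, distal flank ~0", {
    gb <- toyGenome(c(chrI = 50000L, chrX = 1000L))
    genes <- toyGenes("chrI", c(10001, 30001), c(14000, 34000), c("+", "+"))
    cov <- GenomicRanges::coverage(genes)[["chrI"]]
    values <- list(chrI = as.numeric(IRanges::viewMeans(IRanges::Views(cov,
                       seq(1, 49951, by = 50), seq(50, 50000, by = 50)))),
                   chrX = rep(0, 20))
    tr <- trackFrom(values, gb, 50, "z-score")
    pm <- anchoredProfile(tr, genes, "TSS", 1000, 1000, 50)
    m <- profileValues(pm)
    expect_true(all(m[, 21:40] == 1))  # first kb of the body
    expect_true(all(m[, 1:19] == 0))   # upstream flank
})

test_that("profile summaries follow the normal-approximation CI", {
    gb <- toyGenome(c(chrI = 10000L, chrX = 5000L))
    values <- list(chrI = rep(c(0, 2), each = 100), chrX = rep(0, 100))
    tr <- trackFrom(values, gb, 50, "z-score")
    # two + genes sitting in the constant-0 and constant-2 stretches
    genes <- toyGenes("chrI", c(2001, 7001), c(3000, 8000), c("+", "+"),
                      ids = c("lo", "hi"))
    pm <- anchoredProfile(tr, genes, "TSS", 500, 500, 50)
    s <- profileSummary(pm, setNames(c("grp", "grp"), c("lo", "hi")))
    expect_equal(unique(s$mean), 1)
    half <- (s$ci_hi - s$ci_lo) / 2
    expect_equal(unique(round(half, 10)), round(1.96 * sd(c(0, 2)) / sqrt(2), 10))
    expect_true(all(s$n == 2))
    # identical rows -> zero-width CI
    s2 <- profileSummary(pm, setNames(c("a", "b"), c("lo", "hi")))
    expect_equal(s2$ci_lo[s2$group == "a"], s2$ci_hi[s2$group == "a"])
    # group means equal a naive per-group loop
    grp <- setNames(c("g1", "g2"), c("lo", "hi"))
    sN <- profileSummary(pm, grp)
    m <- profileValues(pm)
    for (g in c("g1", "g2"))
        expect_equal(sN$mean[sN$group == g],
                     unname(colMeans(m[names(grp)[grp == g], , drop = FALSE])))
    expect_error(profileSummary(pm, c("a")), "every profile row")
})

test_that("intergenic profiles are center-anchored with 200 columns by default", {
    gb <- toyGenome(c(chrI = 60000L, chrX = 60000L))
    values <- list(chrI = rep(0, 1200), chrX = rep(1, 1200))
    tr <- trackFrom(values, gb, 50, "z-score")
    regions <- GenomicRanges::GRanges(c("chrI", "chrX"),
        IRanges::IRanges(c(20001, 20001), c(40000, 40000)))
    pm <- centeredProfile(tr, regions, flank = 5000, bin = 50)
    expect_equal(ncol(profileValues(pm)), 200)
    s <- intergenicProfile(tr, regions)
    expect_equal(unique(s$mean[s$group == "autosome"]), 0)
    expect_equal(unique(s$mean[s$group == "X"]), 1)
})
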