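test_that("IUPAC scanning matches degenerate positions and both strands", {
    h <- iupacScan("GAAA", "GNAR", bothStrands = FALSE)
    expect_equal(nrow(h), 1L)
    expect_equal(c(h$start, h$end), c(1L, 4L))
    expect_equal(nrow(iupacScan("GCAC", "GNAR", bothStrands = FALSE)), 0L)
    ## a minus-strand hit is reported in plus coordinates with the
    ## minus-strand text
    m <- iupacScan(revComp("GAAA"), "GNAR")
    expect_equal(m$strand, "-")
    expect_equal(m$matched, "GAAA")
    expect_error(iupacScan("ACGT", "GQAR"), "IUPAC")
})

test_that("IUPAC scanning equals the naive position-by-position oracle", {
    set.seed(41)
    pats <- c("GNAR", "TTAATA", "RGCGGCAGG", "YNNK", "WSSW")
    for (i in 1:60) {
        s <- randomSeq(sample(50:300, 1))
        p <- sample(pats, 1)
        got <- iupacScan(s, p, bothStrands = FALSE)
        expect_equal(got$start, oracleIupacScan(s, p), info = paste(i, p))
    }
})

test_that("candidate scan ranks the planted locus first", {
    for (seed in c(2, 9, 17)) {
        loc <- buildLocus(locusParams(seed = seed))
        cand <- scanCandidateLoci(loc$genome, h8bPattern = "RGCGGCAGG")
        expect_gt(nrow(cand), 0)
        expect_lte(cand$start[1], loc$truth@circleStart)
        expect_gte(cand$end[1], loc$truth@circleEnd - 50L)
        expect_equal(cand$strand[1], "+")
    }
})

test_that("a degenerate whole-genome window yields exactly one candidate", {
    loc <- buildLocus(locusParams(seed = 4))
    n <- nchar(as.character(loc$genome[[1]]))
    cand <- scanCandidateLoci(loc$genome, h8bPattern = "RGCGGCAGG",
                              window = n, minFold = 0)
    expect_equal(nrow(cand), 1L)
    expect_equal(c(cand$start, cand$end), c(1L, n))
})

test_that("a motif-free random genome produces no candidates", {
    set.seed(12)
    g <- randomSeq(800)
    ## remove any chance h8b hits so the genome is genuinely motif-free
    while (nrow(iupacScan(g, "RGCGGCAGG")) > 0) g <- randomSeq(800)
    cand <- scanCandidateLoci(g, h8bPattern = "RGCGGCAGG", minFold = 0.6)
    expect_equal(nrow(cand), 0L)
})

test_that("tetraloop context check distinguishes hairpin loops", {
    ## constructed hairpin: 5-bp stem, GAAA loop, flanked by unpaired As
    win <- "AAAAGGCAGGAAACTGCCAAAA"
    hit <- as.integer(regexpr("GAAA", win))
    expect_true(tetraloopContext(win, hit))
    ## the same motif in a fully unpaired context
    expect_false(tetraloopContext("AAAAAAGAAAAAAA", 7L))
})

test_that("tetraloop context agrees with direct inspection of the fold", {
    set.seed(71)
    for (i in 1:10) {
        win <- paste0(randomSeq(6), "GGCAGGAAACTGCC", randomSeq(6))
        hit <- 11L                      # loop position inside the cassette
        f <- nussinovFold(win)
        p <- pairedBases(f)
        loopFree <- !any(11:14 %in% c(p[, 1], p[, 2]))
        closed <- any(p[, 1] == 10L & p[, 2] == 15L) &&
                  any(p[, 1] == 9L & p[, 2] == 16L)
        expect_equal(tetraloopContext(win, hit), loopFree && closed,
                     info = win)
    }
})
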