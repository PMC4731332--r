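test_that("the junction caller recovers the planted circle exactly", {
    for (seed in c(3, 14, 26)) {
        run <- runCallStages(seed)
        expect_length(run$junctions, 1L)
        j <- run$junctions[[1]]
        expect_equal(acceptor(j), run$truth@circleStart)
        expect_equal(donor(j), run$truth@circleEnd)
        expect_equal(circleLength(j), 309L)
        expect_gte(junctionSupport(j), 2L)
        ## every reported junction has internally identical votes
        v <- attr(run$junctions, "votes")
        v <- v[v$readId %in% j@readIds, ]
        expect_true(all(v$acceptor == acceptor(j) & v$donor == donor(j)))
    }
})

test_that("precursor-only reads yield no junction evidence", {
    loc <- buildLocus(locusParams(seed = 31))
    sim <- simulateReads(loc$genome, loc$truth,
                         readSimParams(nPrecursor = 120, nCircular = 0,
                                       seed = 9))
    aln <- alignReads(sim$reads, loc$genome)
    jx <- detectCircularJunctions(aln, sim$reads, loc$genome)
    expect_length(jx, 0L)
    expect_equal(nrow(attr(jx, "votes")), 0L)
})

test_that("the support threshold is respected", {
    loc <- buildLocus(locusParams(seed = 12))
    g <- as.character(loc$genome[[1]])
    A <- loc$truth@circleStart; D <- loc$truth@circleEnd
    ## one synthetic junction-spanning read: 40 nt before D, 35 nt from A
    rd <- paste0(substring(g, D - 39, D), substring(g, A, A + 34))
    reads <- makeReads(rd, ids = "jr1")
    aln <- alignReads(reads, loc$genome)
    one <- detectCircularJunctions(aln, reads, loc$genome, minSupport = 1L)
    expect_length(one, 1L)
    expect_equal(acceptor(one[[1]]), A)
    expect_equal(donor(one[[1]]), D)
    expect_equal(junctionSupport(one[[1]]), 1L)
    two <- detectCircularJunctions(aln, reads, loc$genome, minSupport = 2L)
    expect_length(two, 0L)
})

test_that("circle length arithmetic", {
    j <- new("CircularJunction", seqId = "s", acceptor = 101L, donor = 409L,
             strand = "+", support = 3L, readIds = c("a", "b", "c"))
    expect_equal(circleLength(j), 309L)
    j1 <- new("CircularJunction", seqId = "s", acceptor = 1L, donor = 1L,
              strand = "+", support = 1L, readIds = "a")
    expect_equal(circleLength(j1), 1L)
})

test_that("TSS calling finds the anchored 5' peak and refuses ties", {
    run <- runCallStages(18)
    prof <- coverageProfiles(run$aln, run$loc$genome)
    tss <- callTss(prof, run$junctions[[1]])
    expect_s4_class(tss, "TssCall")
    expect_equal(tssPosition(tss), run$truth@tss)
    expect_equal(leaderLength(tss), run$truth@leaderLen)

    ## two equal peaks are ambiguous: no call
    j <- run$junctions[[1]]
    fake <- prof
    fake$starts5Plus[] <- 0L
    fake$starts5Plus[acceptor(j) - c(10L, 20L)] <- 5L
    expect_null(callTss(fake, j))
    ## no 5' starts in the window: no call
    fake$starts5Plus[] <- 0L
    expect_null(callTss(fake, j))
})

test_that("TATA search reports the nearest upstream match with both offsets", {
    run <- runCallStages(22)
    prof <- coverageProfiles(run$aln, run$loc$genome)
    tss <- callTss(prof, run$junctions[[1]])
    hit <- findTata(run$loc$genome, tss)
    expect_equal(hit$offset, 26L)
    expect_equal(hit$matched, "TTAATA")
    expect_equal(hit$offsetFromStart, 31L)
    ## absent pattern: no call
    expect_null(findTata(run$loc$genome, tss, pattern = "GGGCCCGG"))
    ## two matches: the one closest to the TSS wins
    g <- paste0(strrep("C", 30), "TTAATA", strrep("C", 10), "TTAATA",
                strrep("C", 5), "G", strrep("C", 30))
    hit2 <- findTata(g, tss = 53L)
    expect_equal(hit2$start, 47L)
    expect_equal(hit2$offset, 0L)
})

test_that("BHB detection recovers the planted motif and validates it", {
    run <- runCallStages(7)
    j <- run$junctions[[1]]
    bhb <- findBhb(run$loc$genome, j)
    expect_gt(length(bhb), 0)
    top <- bhb[[1]]
    tr <- run$truth@bhb
    expect_equal(unname(top@helices), unname(tr@helices))
    expect_equal(top@bulge1, tr@bulge1)
    expect_equal(top@bulge2, tr@bulge2)
    expect_equal(bhbScore(top), 13L)
    expect_true(validateJunctionBhb(j, bhb))
    ## a BHB shifted by one nucleotide no longer validates
    shifted <- top
    shifted@bulge1 <- top@bulge1 - 1L
    shifted@cleavage1 <- top@cleavage1 - 1L
    expect_false(validateJunctionBhb(j, shifted))
    ## empty candidate list: vacuous false with a diagnostic
    v <- validateJunctionBhb(j, list())
    expect_false(v)
    expect_match(attr(v, "reason"), "no BHB")
})

test_that("a 3-bp central helix is rejected by the enumerator", {
    ## probe strands built from the generator's cassette geometry
    s1 <- "AACAGGCACAGAGGCGTGAA"        # outer1, bulge, central GAGG, outer2
    s2 <- "AACACGGATCCTCGCCTGAA"        # outer2', bulge, central', outer1'
    hits <- enumerateBhb(s1, s2)
    expect_gt(length(hits), 0)
    expect_true(all(vapply(hits, function(b)
        unname(b@helices["central", "s1End"] -
               b@helices["central", "s1Start"] + 1L), integer(1)) == 4L))
    ## break the central helix down to 3 possible pairs
    s1broken <- sub("GAGG", "GAGT", s1, fixed = TRUE)
    broken <- enumerateBhb(s1broken, s2)
    cl <- lapply(broken, cleavageSites)
    expect_false(any(vapply(cl, function(x) identical(x, c(10L, 9L)),
                            logical(1))))
})

test_that("swapping the strands yields mirrored motifs with equal scores", {
    set.seed(61)
    for (i in 1:10) {
        s1 <- randomSeq(30); s2 <- randomSeq(30)
        a <- enumerateBhb(s1, s2)
        b <- enumerateBhb(s2, s1)
        expect_equal(length(a), length(b), info = i)
        expect_equal(sort(vapply(a, bhbScore, integer(1))),
                     sort(vapply(b, bhbScore, integer(1))), info = i)
    }
})

test_that("cleavage prediction follows the shared cut-offset convention", {
    run <- runCallStages(9)
    j <- run$junctions[[1]]
    top <- findBhb(run$loc$genome, j)[[1]]
    expect_equal(predictCleavage(top, cutOffset = 2L),
                 c(acceptor(j), donor(j) + 1L))
    ## offsets 1 and 2 differ by exactly one position
    expect_equal(predictCleavage(top, 2L) - predictCleavage(top, 1L),
                 c(1L, 1L))
    expect_error(predictCleavage(top, 3L), "cutOffset")
    ## bulge arithmetic: bulge starting at 50 cut after the 2nd nucleotide
    b <- top
    b@bulge1 <- c(50L, 52L); b@cleavage1 <- 52L
    b@strand <- "+"
    expect_equal(predictCleavage(b, 2L)[1], 52L)
})

test_that("the whole caller works on the minus strand", {
    run <- runCallStages(16)
    rcg <- Biostrings::reverseComplement(run$loc$genome)
    names(rcg) <- "synthetic_locus"
    n <- nchar(as.character(rcg[[1]]))
    aln <- alignReads(run$reads, rcg)
    jx <- detectCircularJunctions(aln, run$reads, rcg)
    expect_length(jx, 1L)
    j <- jx[[1]]
    expect_equal(j@strand, "-")
    expect_equal(acceptor(j), n - run$truth@circleEnd + 1L)
    expect_equal(donor(j), n - run$truth@circleStart + 1L)
    tss <- callTss(coverageProfiles(aln, rcg), j)
    expect_equal(leaderLength(tss), run$truth@leaderLen)
    tata <- findTata(rcg, tss, strand = "-")
    expect_equal(tata$offset, 26L)
    expect_true(validateJunctionBhb(j, findBhb(rcg, j)))
})
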