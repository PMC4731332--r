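test_that("default locus encodes the published geometry", {
    loc <- buildLocus(locusParams(seed = 1))
    tr <- loc$truth
    expect_equal(circleLength(tr), 309L)
    expect_equal(tr@leaderLen, 23L)
    expect_equal(tr@tataOffset, 26L)
    expect_equal(tr@tss, tr@circleStart - tr@leaderLen)
    expect_equal(substring(as.character(loc$genome[[1]]),
                           tr@tataStart, tr@tataEnd), "TTAATA")
    ## truth cleavage sites coincide with the circle boundaries
    expect_equal(cleavageSites(tr@bhb),
                 c(tr@circleStart, tr@circleEnd + 1L))
    ## every truth cleavage site lies inside a truth bulge interval
    expect_true(tr@bhb@cleavage1 >= tr@bhb@bulge1[1] &&
                tr@bhb@cleavage1 <= tr@bhb@bulge1[2])
    expect_true(tr@bhb@cleavage2 >= tr@bhb@bulge2[1] &&
                tr@bhb@cleavage2 <= tr@bhb@bulge2[2])
})

test_that("locus construction is deterministic and additive in segments", {
    a <- buildLocus(locusParams(seed = 42))
    b <- buildLocus(locusParams(seed = 42))
    expect_identical(as.character(a$genome), as.character(b$genome))
    c <- buildLocus(locusParams(seed = 43))
    expect_false(identical(as.character(a$genome), as.character(c$genome)))

    ## genome length equals the sum of the declared segment plan
    p <- locusParams(circleLen = 60L, leaderLen = 5L, flankLen = 20L,
                     trailerLen = 15L, cdbox = FALSE, seed = 3)
    g <- buildLocus(p)$genome
    expect_equal(nchar(as.character(g[[1]])),
                 p$flankLen + nchar(p$tataSeq) + p$tataOffset +
                 p$leaderLen + p$circleLen + p$trailerLen + p$flankLen)
})

test_that("overlapping planted elements are rejected", {
    expect_error(buildLocus(locusParams(gnarPos = 5L)), "cassette|overlap")
    expect_error(buildLocus(locusParams(gnarPos = 100L, h8bPos = 103L)),
                 "overlap")
    expect_error(buildLocus(locusParams(trailerLen = 5L)), "trailer")
})

test_that("error-free reads are exact substrings of their templates", {
    loc <- buildLocus(locusParams(seed = 8))
    sim <- simulateReads(loc$genome, loc$truth,
                         readSimParams(nPrecursor = 40, nCircular = 40,
                                       seed = 2))
    g <- as.character(loc$genome[[1]])
    circ <- substring(g, loc$truth@circleStart, loc$truth@circleEnd)
    circ2 <- paste0(circ, circ)
    prec <- substring(g, loc$truth@tss, loc$truth@trailerEnd)
    lab <- sim$truth@reads
    for (i in seq_along(sim$reads)) {
        rd <- as.character(sim$reads[[i]])
        tmpl <- if (lab$origin[i] == "circular") circ2 else prec
        expect_true(grepl(rd, tmpl, fixed = TRUE), info = names(sim$reads)[i])
    }
    ## same seed => byte-identical reads; zero requested reads => empty set
    sim2 <- simulateReads(loc$genome, loc$truth,
                          readSimParams(nPrecursor = 40, nCircular = 40,
                                        seed = 2))
    expect_identical(as.character(sim$reads), as.character(sim2$reads))
    empty <- simulateReads(loc$genome, loc$truth,
                           readSimParams(nPrecursor = 0, nCircular = 0))
    expect_length(empty$reads, 0L)
})

test_that("junction-spanning fraction follows the uniform-start expectation", {
    loc <- buildLocus(locusParams(circleLen = 200L, seed = 13))
    R <- 75L; n <- 1000L
    sim <- simulateReads(loc$genome, loc$truth,
                         readSimParams(nPrecursor = 0, nCircular = n,
                                       readLen = R, seed = 99))
    C <- circleLength(loc$truth)
    pExp <- (R - 1) / C                    # spanning with >= 1 nt each side
    obs <- sum(sim$truth@reads$junctionSpanning)
    sdBin <- sqrt(n * pExp * (1 - pExp))
    expect_lt(abs(obs - n * pExp), 3 * sdBin)
})

test_that("read length must stay below the circle length", {
    loc <- buildLocus(locusParams(circleLen = 60L, seed = 5))
    expect_error(simulateReads(loc$genome, loc$truth,
                               readSimParams(readLen = 60L)),
                 "circle")
})

test_that("adapter read-through appears on short fragments and trims away", {
    loc <- buildLocus(locusParams(seed = 21))
    adapter <- "TGGAATTCTCGGGTGCCAAGG"
    sim <- simulateReads(loc$genome, loc$truth,
                         readSimParams(nPrecursor = 30, nCircular = 30,
                                       adapter = adapter, fragLenMin = 20L,
                                       seed = 7))
    withAd <- vapply(as.character(sim$reads), function(s)
        grepl(substring(adapter, 1, 8), s, fixed = TRUE), logical(1))
    expect_gt(sum(withAd), 0)
    trimmed <- trimAdapter(sim$reads, adapter)
    stillAd <- vapply(as.character(trimmed), function(s)
        grepl(substring(adapter, 1, 8), s, fixed = TRUE), logical(1))
    expect_equal(sum(stillAd), 0L)
})
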