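test_that("quality trimming keeps uniformly good reads and drops bad ones", {
    good <- makeReads("ACGTACGTAC")                      # Q40 everywhere
    expect_equal(as.character(qualityTrim(good)), "ACGTACGTAC",
                 ignore_attr = TRUE)
    bad <- makeReads("ACGTACGTAC", qstring(rep(2L, 10)))  # p ~ 0.63 > 0.05
    expect_equal(Biostrings::width(qualityTrim(bad)), 0L)
})

test_that("mottBounds equals the exhaustive max-sum substring oracle", {
    set.seed(23)
    for (i in 1:300) {
        q <- sample(2:41, sample(5:40, 1), replace = TRUE)
        expect_equal(mottBounds(q), oracleMott(q), info = paste(q, collapse = ","))
    }
})

test_that("reads with too many ambiguities after trimming are discarded", {
    r <- makeReads(c("ACGTNNACGTACGT", "ACGNNNGT"))
    out <- qualityTrim(r, maxAmbiguities = 2L)
    expect_equal(Biostrings::width(out), c(14L, 0L))
})

test_that("adapter trimming removes admissible suffixes only", {
    adapter <- "TGGAATTCTCGGGTGCCAAGG"
    insert <- "ACGTACGTACGTACGTACGT"
    expect_equal(trimAdapter(paste0(insert, adapter), adapter), insert)
    expect_equal(trimAdapter(insert, "GGGGGGGG"), insert)
    ## one mismatch in a 20-nt overlap is within the 10% tolerance
    ad20 <- substring(adapter, 1, 20)
    mut <- ad20
    substring(mut, 10, 10) <- if (substring(mut, 10, 10) == "A") "C" else "A"
    expect_equal(trimAdapter(paste0(insert, mut), adapter), insert)
    ## two mismatches in a 10-nt overlap exceed it
    ad10 <- substring(adapter, 1, 10)
    mut2 <- ad10
    substring(mut2, 2, 3) <- if (substring(mut2, 2, 3) == "GG") "CC" else "GG"
    expect_equal(trimAdapter(paste0(insert, mut2), adapter),
                 paste0(insert, mut2))
    ## qualities are trimmed alongside
    r <- makeReads(paste0(insert, adapter))
    tr <- trimAdapter(r, adapter)
    expect_equal(Biostrings::width(tr), nchar(insert))
    expect_equal(nchar(as.character(Biostrings::quality(tr))[1]),
                 nchar(insert))
})

test_that("length filter keeps exactly the reads at or above the cutoff", {
    r <- makeReads(c(randomSeq(14), randomSeq(15), randomSeq(16)))
    kept <- lengthFilter(r)
    expect_equal(Biostrings::width(kept), c(15L, 16L))
    expect_equal(names(kept), names(r)[2:3])
    expect_length(lengthFilter(makeReads(character(0))), 0L)
    expect_equal(as.character(lengthFilter(r, minLen = 1L)),
                 as.character(r), ignore_attr = TRUE)
    ## monotone: raising the cutoff never adds reads
    for (m in c(1L, 10L, 15L, 16L, 20L))
        expect_true(all(as.character(lengthFilter(r, m + 1L)) %in%
                        as.character(lengthFilter(r, m))))
})

test_that("exact reads align full-length; reverse-complement maps to minus", {
    set.seed(5)
    gen <- randomSeq(400)
    rd <- substring(gen, 101, 130)
    a <- alignReads(stats::setNames(rd, "r1"), gen)
    expect_equal(nrow(a), 1L)
    expect_equal(a$score, 30L)
    expect_equal(c(a$refStart, a$refEnd), c(101L, 130L))
    expect_equal(c(a$readStart, a$readEnd), c(1L, 30L))
    expect_equal(a$strand, "+")

    b <- alignReads(stats::setNames(revComp(rd), "r2"), gen)
    expect_equal(b$strand, "-")
    expect_equal(c(b$refStart, b$refEnd), c(101L, 130L))
})

test_that("split reads soft-clip the shorter arm at the best placement", {
    set.seed(6)
    ch <- strsplit(randomSeq(500), "")[[1]]
    ## block chance single-base extension of either arm across the split
    if (ch[71] == ch[301]) ch[71] <- setdiff(c("A", "C", "G", "T"),
                                             c(ch[301], ch[70]))[1]
    if (ch[300] == ch[70]) ch[300] <- setdiff(c("A", "C", "G", "T"),
                                              c(ch[70], ch[301]))[1]
    gen <- paste0(ch, collapse = "")
    rd <- paste0(substring(gen, 51, 70), substring(gen, 301, 315))
    a <- alignReads(stats::setNames(rd, "r1"), gen)
    expect_equal(max(a$score), 20L)
    top <- a[which.max(a$score), ]
    expect_equal(c(top$refStart, top$refEnd), c(51L, 70L))
    expect_equal(c(top$readStart, top$readEnd), c(1L, 20L))
    ## soft clip partitions the read together with the aligned interval
    expect_equal(top$readLen - top$readEnd, 15L)
})

test_that("alignment score equals full Smith-Waterman on seeded reads", {
    ## reads of >= 51 nt with <= 3 substitutions always contain an exact
    ## 12-mer (pigeonhole), the regime where seed-and-extend is exact
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -4,
                                                    baseOnly = TRUE)
    set.seed(31)
    for (i in 1:40) {
        gl <- sample(100:500, 1)
        gen <- randomSeq(gl)
        rl <- sample(51:60, 1)
        st <- sample(1:(gl - rl + 1), 1)
        rd <- strsplit(substring(gen, st, st + rl - 1), "")[[1]]
        nmut <- sample(0:3, 1)
        for (k in sample(rl, nmut))
            rd[k] <- sample(setdiff(c("A", "C", "G", "T"), rd[k]), 1)
        rd <- paste0(rd, collapse = "")
        a <- alignReads(stats::setNames(rd, "r"), gen)
        o <- Biostrings::pairwiseAlignment(rd, gen, type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 6, gapExtension = 1)
        expect_gt(nrow(a), 0)
        expect_equal(max(a$score), Biostrings::score(o), info = i)
    }
})

test_that("coverage profiles are strand-aware and conserve aligned bases", {
    aln <- data.frame(readId = c("a", "b"), seqId = "g",
                      refStart = c(11L, 11L), refEnd = c(20L, 20L),
                      strand = c("+", "-"), readStart = 1L, readEnd = 10L,
                      readLen = 10L, score = 10L, nMismatch = 0L,
                      nGap = 0L, nBest = 1L)
    p <- coverageProfiles(aln, 30L)
    expect_equal(sum(p$depthPlus), 10L)
    expect_equal(which(p$starts5Plus == 1L), 11L)
    expect_equal(which(p$starts5Minus == 1L), 20L)     # 5' end of a minus read
    expect_equal(sum(p$depthPlus) + sum(p$depthMinus),
                 sum(aln$refEnd - aln$refStart + 1L))
})
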