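## Shared synthetic-run helpers: build a locus, simulate ~30x reads and run
## the processing + calling stages directly (without the window scan, which
## is exercised separately).

simulateDepth30 <- function(truth, err = 0, readLen = 75L, seed = 1L) {
    C <- circleLength(truth)
    prec <- truth@trailerEnd - truth@tss + 1L
    readSimParams(nPrecursor = as.integer(ceiling(30 * prec / readLen)),
                  nCircular = as.integer(ceiling(30 * C / readLen)),
                  readLen = readLen, err = err, seed = seed)
}

runCallStages <- function(seed, circleLen = 309L, leaderLen = 23L,
                          err = 0) {
    loc <- buildLocus(locusParams(circleLen = circleLen,
                                  leaderLen = leaderLen, seed = seed))
    sim <- simulateReads(loc$genome, loc$truth,
                         simulateDepth30(loc$truth, err = err,
                                         seed = seed + 5000L))
    aln <- alignReads(sim$reads, loc$genome)
    jx <- detectCircularJunctions(aln, sim$reads, loc$genome)
    list(loc = loc, reads = sim$reads, truth = sim$truth, aln = aln,
         junctions = jx)
}
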