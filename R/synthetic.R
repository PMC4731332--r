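## Synthetic locus and read generator.  The generator's defaults encode the
## published geometry of the permuted SRP RNA locus: a 309-nt circularized
## block, a 23-nt leader, a TTAATA TATA box 26 nt upstream of the TSS, a
## GNAR tetraloop and a helix-8b motif inside the circle, a BHB at the
## leader/trailer junction flanks whose bulge cuts fall exactly at the
## circle boundaries, and an adjacent C/D box sRNA gene.

## BHB cassette planted around the circle boundaries (acceptor A = first
## mature base, donor D = last mature base, both 1-based):
##   strand 1, positions (A-8)..(A+9):
##     A | CAGGC (outer1) | ACA (bulge1, cut after 2nd nt -> A) |
##     GAGG (central) | CGTG (outer2) | A
##   strand 2, positions (D-6)..(D+11):
##     A | CACG (outer2') | GAT (bulge2, cut after 2nd nt -> D+1) |
##     CCTC (central') | GCCTG (outer1') | A
## The single 'A' borders block helix extension beyond the planted motif,
## and the bulge letters are chosen so that no helix can absorb them and so
## that the genome continuation differs from the circle continuation on
## both sides of the junction (local alignments of junction-spanning reads
## therefore stop exactly at the termini).
.BHB_S1 <- c("A", "C","A","G","G","C", "A","C","A", "G","A","G","G",
             "C","G","T","G", "A")
.BHB_S2 <- c("A", "C","A","C","G", "G","A","T", "C","C","T","C",
             "G","C","C","T","G", "A")
.GNAR_HAIRPIN <- c("G","G","C","A","G", "G","A","A","A", "C","T","G","C","C")

#' Parameters of a synthetic permuted-RNA locus
#'
#' Defaults are the study conditions of the discovered locus: a 309-nt
#' circle, 23-nt leader and a TTAATA box separated from the TSS by 26 nt.
#'
#' @param circleLen Circle (mature RNA) length C in nt (default 309).
#' @param leaderLen Leader length L in nt (default 23, must be >= 1).
#' @param trailerLen Trailer length in nt (default 40, must be >= 12 so the
#'   trailer holds the BHB cassette).
#' @param tataOffset Gap in nt between the TATA box 3' base and the TSS
#'   (default 26).
#' @param tataSeq TATA box sequence (default `"TTAATA"`).
#' @param gnarPos Circle-local position of the planted GNAR tetraloop
#'   (default `round(0.35 * circleLen)`).
#' @param h8bPos Circle-local position of the planted helix-8b motif
#'   (default `round(0.62 * circleLen)`).
#' @param h8bPattern IUPAC pattern to instantiate and plant (default the
#'   package placeholder `"RGCGGCAGG"`).
#' @param cdbox Plant an adjacent C/D-box-like sRNA gene (default `TRUE`).
#' @param cdboxSpacing,cdboxLen Spacing after the trailer and gene length.
#' @param flankLen Random flank length on each side (default 150).
#' @param gc Background GC fraction (default 0.5).
#' @param seed Integer seed (default 1).
#' @return A list of class `"LocusParams"`.
#' @export
locusParams <- function(circleLen = 309L, leaderLen = 23L, trailerLen = 40L,
                        tataOffset = 26L, tataSeq = "TTAATA",
                        gnarPos = NULL, h8bPos = NULL,
                        h8bPattern = "RGCGGCAGG",
                        cdbox = TRUE, cdboxSpacing = 30L, cdboxLen = 60L,
                        flankLen = 150L, gc = 0.5, seed = 1L) {
    if (is.null(gnarPos)) gnarPos <- as.integer(round(0.35 * circleLen))
    if (is.null(h8bPos)) h8bPos <- as.integer(round(0.62 * circleLen))
    p <- list(circleLen = as.integer(circleLen),
              leaderLen = as.integer(leaderLen),
              trailerLen = as.integer(trailerLen),
              tataOffset = as.integer(tataOffset),
              tataSeq = .normSeq(tataSeq),
              gnarPos = as.integer(gnarPos), h8bPos = as.integer(h8bPos),
              h8bPattern = .normSeq(h8bPattern),
              cdbox = isTRUE(cdbox),
              cdboxSpacing = as.integer(cdboxSpacing),
              cdboxLen = as.integer(cdboxLen),
              flankLen = as.integer(flankLen),
              gc = as.numeric(gc), seed = as.integer(seed))
    class(p) <- "LocusParams"
    p
}

## instantiate an IUPAC pattern as a concrete sequence (random choice per
## degenerate position, under the caller's RNG state)
.instantiateIupac <- function(pattern) {
    tab <- Biostrings::IUPAC_CODE_MAP
    vapply(.seqChars(pattern), function(ch) {
        opts <- .seqChars(tab[[ch]])
        if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1L), USE.NAMES = FALSE)
}

#' Build a synthetic genomic locus with ground truth
#'
#' Assembles `flank | TATA | gap | leader | circle | trailer | spacer |
#' C/D box sRNA | flank` over an i.i.d. background with configurable GC
#' content, planting (i) a BHB cassette at the circle boundaries whose
#' bulge cleavage points (cut after the second bulge nucleotide) fall
#' exactly at the mature termini, (ii) a GNAR tetraloop as the loop of a
#' 5-bp hairpin, and (iii) an instantiation of the helix-8b pattern.
#' Spurious TATA matches that would out-compete the planted box in the
#' TSS-proximal search window are scrubbed from the background.
#'
#' @param params A [locusParams()] list.
#' @return List with elements `genome` (a named
#'   [Biostrings::DNAStringSet]), `truth` (a [LocusTruth-class]) and
#'   `features` (a [GenomicRanges::GRanges]).
#' @examples
#' loc <- buildLocus(locusParams(seed = 7))
#' circleLength(loc$truth)   # 309
#' @export
buildLocus <- function(params = locusParams()) {
    stopifnot(inherits(params, "LocusParams"))
    p <- params
    if (p$leaderLen < 1L) stop("leaderLen must be >= 1")
    if (p$trailerLen < 12L) stop("trailerLen must hold the BHB cassette (>= 12 nt)")
    if (p$circleLen < 40L) stop("circleLen too small to hold the planted motifs")
    if (p$tataOffset < 0L) stop("tataOffset must be non-negative")
    ## circle-local intervals of planted elements
    gnarIv <- c(p$gnarPos - 5L, p$gnarPos + 8L)
    h8bIv <- c(p$h8bPos, p$h8bPos + nchar(p$h8bPattern) - 1L)
    edgeLo <- 10L                      # cassette occupies circle-local 1..10
    edgeHi <- p$circleLen - 6L         # and (C-6)..C
    if (gnarIv[1] <= edgeLo || gnarIv[2] >= edgeHi ||
        h8bIv[1] <= edgeLo || h8bIv[2] >= edgeHi)
        stop("planted motifs overlap the circle-boundary cassette")
    if (max(gnarIv[1], h8bIv[1]) <= min(gnarIv[2], h8bIv[2]))
        stop("planted GNAR and h8b elements overlap")

    .withSeed(p$seed, {
        ## coordinates
        tataStart <- p$flankLen + 1L
        tataEnd <- tataStart + nchar(p$tataSeq) - 1L
        tss <- tataEnd + p$tataOffset + 1L
        A <- tss + p$leaderLen          # first mature base
        D <- A + p$circleLen - 1L       # last mature base
        trailerEnd <- D + p$trailerLen
        if (p$cdbox) {
            cdStart <- trailerEnd + p$cdboxSpacing + 1L
            cdEnd <- cdStart + p$cdboxLen - 1L
            total <- cdEnd + p$flankLen
        } else {
            cdStart <- NA_integer_; cdEnd <- NA_integer_
            total <- trailerEnd + p$flankLen
        }
        baseProb <- c(A = (1 - p$gc) / 2, C = p$gc / 2,
                      G = p$gc / 2, T = (1 - p$gc) / 2)
        g <- sample(names(baseProb), total, replace = TRUE, prob = baseProb)

        locked <- logical(total)
        plant <- function(at, chars) {
            iv <- at:(at + length(chars) - 1L)
            if (iv[1] < 1L || iv[length(iv)] > total)
                stop("planted element outside the genome")
            if (any(locked[iv]))
                stop("planted elements overlap")
            g[iv] <<- chars
            locked[iv] <<- TRUE
        }
        plant(tataStart, .seqChars(p$tataSeq))
        plant(A - 8L, .BHB_S1)
        plant(D - 6L, .BHB_S2)
        plant(A + p$gnarPos - 1L - 5L, .GNAR_HAIRPIN)
        h8bConcrete <- .instantiateIupac(p$h8bPattern)
        plant(A + p$h8bPos - 1L, h8bConcrete)
        if (p$cdbox) {
            plant(cdStart, .seqChars("ATGATGA"))
            plant(cdEnd - 3L, .seqChars("CTGA"))
        }

        ## scrub spurious TATA matches in the TSS-proximal search window so
        ## the planted box is the nearest match to the TSS
        tl <- nchar(p$tataSeq)
        scrubLo <- max(1L, tss - 40L - tl)
        repeat {
            win <- paste0(g[scrubLo:(tss - 1L)], collapse = "")
            hits <- Biostrings::start(Biostrings::matchPattern(
                p$tataSeq, Biostrings::DNAString(win))) + scrubLo - 1L
            hits <- hits[hits != tataStart]
            if (!length(hits)) break
            for (h in hits) {
                iv <- h:(h + tl - 1L)
                free <- iv[!locked[iv]]
                if (!length(free)) next
                i <- free[[1L]]
                g[i] <- sample(setdiff(c("A", "C", "G", "T"), g[i]), 1L)
            }
        }

        genomeSeq <- paste0(g, collapse = "")
        seqId <- "synthetic_locus"
        genome <- Biostrings::DNAStringSet(genomeSeq)
        names(genome) <- seqId

        truthBhb <- new("BhbMotif", seqId = seqId, strand = "+",
            helices = matrix(c(A - 7L, A - 3L, D + 6L, D + 10L,
                               A + 1L, A + 4L, D + 2L, D + 5L,
                               A + 5L, A + 8L, D - 5L, D - 2L),
                             nrow = 3L, byrow = TRUE,
                             dimnames = list(c("outer1", "central", "outer2"),
                                             c("s1Start", "s1End",
                                               "s2Start", "s2End"))),
            bulge1 = c(A - 2L, A), bulge2 = c(D - 1L, D + 1L),
            cleavage1 = A, cleavage2 = D + 1L,
            arrangement = "s1First", score = 13L, coords = "genomic")
        validObject(truthBhb)

        truth <- new("LocusTruth", seqId = seqId,
            circleStart = A, circleEnd = D,
            tss = tss, leaderLen = p$leaderLen,
            tataStart = tataStart, tataEnd = tataEnd,
            tataOffset = p$tataOffset,
            gnarStart = A + p$gnarPos - 1L,
            h8bStart = A + p$h8bPos - 1L,
            h8bEnd = A + p$h8bPos + nchar(p$h8bPattern) - 2L,
            trailerEnd = trailerEnd,
            cdbox = c(cdStart, cdEnd),
            bhb = truthBhb,
            reads = data.frame())
        validObject(truth)

        featStart <- c(tss, tataStart, tss, A, A - 8L, D - 6L)
        featEnd <- c(trailerEnd, tataEnd, A - 1L, D, A + 9L, D + 11L)
        featKind <- c("gene", "tata_box", "leader", "circle", "bhb", "bhb")
        featName <- c("precursor", "tata", "leader", "mature_circle",
                      "bhb_acceptor_flank", "bhb_donor_flank")
        if (p$cdbox) {
            featStart <- c(featStart, cdStart); featEnd <- c(featEnd, cdEnd)
            featKind <- c(featKind, "cdbox_srna")
            featName <- c(featName, "cdbox_srna")
        }
        features <- makeFeatures(seqId, featStart, featEnd,
                                 strand = "+", kind = featKind,
                                 name = featName)
        list(genome = genome, truth = truth, features = features)
    })
}

#' Parameters for read simulation
#'
#' @param nPrecursor,nCircular Read counts from the linear precursor and the
#'   circular mature RNA.
#' @param readLen Read length in nt (default 75; must be >= 15 and smaller
#'   than the circle so a read crosses the junction at most once).
#' @param err Per-base substitution error probability (default 0,
#'   must be < 0.25).
#' @param qualModel `"constant"` (Q40) or `"ramp"` (Q40 falling to Q25).
#' @param adapter Optional 3' adapter appended to fragments shorter than
#'   `readLen` (read-through), then truncated to `readLen`.
#' @param fragLenMin Minimum fragment length; fragments are drawn uniformly
#'   in `[fragLenMin, readLen]` (default `readLen`, i.e. fixed-length).
#' @param fracTssAnchored Fraction of precursor reads starting exactly at
#'   the TSS, emulating intact primary 5' termini captured by small-RNA
#'   adapter ligation (default 0.6); the rest are uniform substrings.
#' @param seed Integer seed.
#' @return A list of class `"ReadSimParams"`.
#' @export
readSimParams <- function(nPrecursor = 150L, nCircular = 130L,
                          readLen = 75L, err = 0, qualModel = "constant",
                          adapter = NULL, fragLenMin = NULL,
                          fracTssAnchored = 0.6, seed = 1L) {
    if (readLen < 15L) stop("readLen must be >= 15")
    if (err < 0 || err >= 0.25) stop("err must be in [0, 0.25)")
    if (is.null(fragLenMin)) fragLenMin <- readLen
    p <- list(nPrecursor = as.integer(nPrecursor),
              nCircular = as.integer(nCircular),
              readLen = as.integer(readLen), err = as.numeric(err),
              qualModel = match.arg(qualModel, c("constant", "ramp")),
              adapter = if (is.null(adapter)) NULL else .normSeq(adapter),
              fragLenMin = as.integer(fragLenMin),
              fracTssAnchored = as.numeric(fracTssAnchored),
              seed = as.integer(seed))
    class(p) <- "ReadSimParams"
    p
}

.qualString <- function(len, model) {
    if (len == 0L) return("")
    q <- if (model == "constant") rep(40L, len)
         else round(seq(40L, 25L, length.out = len))
    paste0(strsplit(rawToChar(as.raw(q + 33L)), "")[[1L]], collapse = "")
}

.mutate <- function(chars, err) {
    if (err <= 0) return(chars)
    hit <- which(runif(length(chars)) < err)
    for (i in hit)
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    chars
}

#' Simulate precursor and circular reads from a synthetic locus
#'
#' Precursor reads are substrings of `[tss, trailerEnd]`: a configurable
#' fraction starts exactly at the TSS (intact 5' termini), the rest start
#' uniformly.  Circular reads are substrings of the doubled circle string
#' restricted to start within the circle, so a read may cross the
#' ligation junction (at most once, since `readLen < C`).  Substitution
#' errors are applied i.i.d. per base.  The returned truth object labels
#' every read's origin and junction-spanning status.
#'
#' @param genome Genome from [buildLocus()].
#' @param truth The matching [LocusTruth-class].
#' @param simParams A [readSimParams()] list.
#' @return List with `reads` (a [Biostrings::QualityScaledDNAStringSet])
#'   and `truth` (the input truth with its `reads` label table filled).
#' @export
simulateReads <- function(genome, truth, simParams = readSimParams()) {
    stopifnot(inherits(simParams, "ReadSimParams"), is(truth, "LocusTruth"))
    sp <- simParams
    g <- .asSeqChar(genome)
    A <- truth@circleStart; D <- truth@circleEnd
    C <- D - A + 1L
    if (sp$readLen >= C)
        stop("readLen must be smaller than the circle length")
    .withSeed(sp$seed, {
        circ <- substring(g, A, D)
        circ2 <- paste0(circ, circ)
        precSeq <- substring(g, truth@tss, truth@trailerEnd)
        pn <- nchar(precSeq)
        if (pn < sp$readLen)
            stop("precursor span shorter than readLen")
        drawFrag <- function() {
            if (sp$fragLenMin >= sp$readLen) sp$readLen
            else sample(sp$fragLenMin:sp$readLen, 1L)
        }
        ids <- character(0); seqs <- character(0); quals <- character(0)
        lab <- list(); k <- 0L
        addRead <- function(id, frag, origin, start, spanning) {
            if (!is.null(sp$adapter) && nchar(frag) < sp$readLen)
                frag <- substring(paste0(frag, sp$adapter), 1L, sp$readLen)
            chars <- .mutate(.seqChars(frag), sp$err)
            k <<- k + 1L
            ids[k] <<- id
            seqs[k] <<- paste0(chars, collapse = "")
            quals[k] <<- .qualString(length(chars), sp$qualModel)
            lab[[k]] <<- data.frame(readId = id, origin = origin,
                                    start = start,
                                    junctionSpanning = spanning)
        }
        if (sp$nPrecursor > 0L) for (i in seq_len(sp$nPrecursor)) {
            fl <- drawFrag()
            anchored <- runif(1L) < sp$fracTssAnchored
            s <- if (anchored) 1L else sample.int(pn - fl + 1L, 1L)
            frag <- substring(precSeq, s, s + fl - 1L)
            addRead(sprintf("prec_%05d", i), frag, "precursor",
                    truth@tss + s - 1L, FALSE)
        }
        if (sp$nCircular > 0L) for (i in seq_len(sp$nCircular)) {
            fl <- drawFrag()
            s <- sample.int(C, 1L)
            frag <- substring(circ2, s, s + fl - 1L)
            spanning <- (s + fl - 1L) > C
            addRead(sprintf("circ_%05d", i), frag, "circular", s, spanning)
        }
        reads <- Biostrings::QualityScaledDNAStringSet(
            Biostrings::DNAStringSet(seqs[seq_len(k)]),
            Biostrings::PhredQuality(quals[seq_len(k)]))
        names(reads) <- ids[seq_len(k)]
        labels <- if (k > 0L) do.call(rbind, lab[seq_len(k)])
                  else data.frame(readId = character(0),
                                  origin = character(0),
                                  start = integer(0),
                                  junctionSpanning = logical(0))
        rownames(labels) <- NULL
        truth@reads <- labels
        list(reads = reads, truth = truth)
    })
}
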