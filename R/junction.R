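## Circularization-junction calling from soft-clipped reads, TSS/leader and
## TATA inference, BHB detection at the junction flanks, and
## cross-validation of predicted cleavage against the observed termini.

## unique best-mismatch match of `clip` inside genome[lo..hi]; returns the
## 1-based genomic start, or NA when there is no admissible match or the
## best-mismatch level is ambiguous
.clipMatch <- function(clip, genomeDna, lo, hi, maxMismatch) {
    if (hi - lo + 1L < nchar(clip)) return(NA_integer_)
    region <- Biostrings::subseq(genomeDna, lo, hi)
    pat <- Biostrings::DNAString(clip)
    for (mm in 0:maxMismatch) {
        st <- Biostrings::start(
            Biostrings::matchPattern(pat, region, max.mismatch = mm))
        if (length(st) == 1L) return(st + lo - 1L)
        if (length(st) > 1L) return(NA_integer_)
    }
    NA_integer_
}

#' Call circularization junctions from soft-clipped alignments
#'
#' Reads that span the ligated termini of a circular RNA align with one arm
#' and carry the distant terminus as a soft clip.  For every read with a
#' unique best alignment and a clip of at least `minClip` nt: a 3'-side clip
#' (in reference orientation) on an alignment ending at donor D must match
#' the genome starting at some acceptor A upstream; a 5'-side clip on an
#' alignment starting at A must match the genome ending at some donor D
#' downstream.  Each such read votes for the coordinate pair (A, D); votes
#' for non-identical pairs are never merged, and junctions reaching
#' `minSupport` identical votes are reported (best-supported first).  The
#' full vote table, including discordant votes, is attached as attribute
#' `"votes"`.
#'
#' @param aln Alignments from [alignReads()].
#' @param reads The read set that produced `aln` (sequences by id).
#' @param genome The reference sequence.
#' @param minClip Minimum soft-clip length considered (default 8).
#' @param minSupport Minimum identical votes to report (default 2).
#' @param maxClipMismatch Mismatches tolerated when re-placing the clip
#'   (default 1); among admissible placements the fewest-mismatch level is
#'   used and ambiguity within it discards the vote.
#' @param searchRadius Maximum distance between the clip placement and the
#'   aligned segment (default 1000), reflecting an intragenic, contiguous
#'   circle rather than a trans-chimera.
#' @return List of [CircularJunction-class], attribute `"votes"` holds the
#'   per-read vote table.
#' @export
detectCircularJunctions <- function(aln, reads, genome, minClip = 8L,
                                    minSupport = 2L, maxClipMismatch = 1L,
                                    searchRadius = 1000L) {
    g <- .asSeqChar(genome)
    genomeDna <- Biostrings::DNAString(g)
    n <- nchar(g)
    seqId <- .seqIdOf(genome)
    seqs <- as.character(reads)
    votes <- list(); k <- 0L
    if (nrow(aln)) {
        uni <- aln[aln$nBest == 1L, , drop = FALSE]
        for (i in seq_len(nrow(uni))) {
            row <- uni[i, ]
            readSeq <- seqs[[row$readId]]
            oriented <- if (row$strand == "+") readSeq else revComp(readSeq)
            rl <- nchar(oriented)
            leftClip <- row$readStart - 1L
            rightClip <- rl - row$readEnd
            if (rightClip >= minClip) {
                clip <- substring(oriented, row$readEnd + 1L, rl)
                a <- .clipMatch(clip, genomeDna,
                                max(1L, row$refEnd - searchRadius),
                                row$refEnd, maxMismatch = maxClipMismatch)
                if (!is.na(a) && a < row$refEnd) {
                    k <- k + 1L
                    votes[[k]] <- data.frame(readId = row$readId,
                                             acceptor = a,
                                             donor = row$refEnd,
                                             strand = row$strand)
                }
            }
            if (leftClip >= minClip) {
                clip <- substring(oriented, 1L, leftClip)
                a <- .clipMatch(clip, genomeDna, row$refStart,
                                min(n, row$refStart + searchRadius),
                                maxMismatch = maxClipMismatch)
                if (!is.na(a)) {
                    d <- a + nchar(clip) - 1L
                    if (d > row$refStart) {
                        k <- k + 1L
                        votes[[k]] <- data.frame(readId = row$readId,
                                                 acceptor = row$refStart,
                                                 donor = d,
                                                 strand = row$strand)
                    }
                }
            }
        }
    }
    if (k == 0L) {
        out <- list()
        attr(out, "votes") <- data.frame(readId = character(0),
                                         acceptor = integer(0),
                                         donor = integer(0),
                                         strand = character(0))
        return(out)
    }
    vt <- unique(do.call(rbind, votes))
    grp <- split(vt, paste(vt$strand, vt$acceptor, vt$donor, sep = ":"))
    support <- vapply(grp, nrow, integer(1L))
    grp <- grp[order(-support, vapply(grp, function(x) x$acceptor[1L],
                                      integer(1L)))]
    out <- list()
    for (gset in grp) {
        if (nrow(gset) < minSupport) next
        out[[length(out) + 1L]] <- new("CircularJunction",
            seqId = seqId, acceptor = gset$acceptor[1L],
            donor = gset$donor[1L], strand = gset$strand[1L],
            support = nrow(gset), readIds = gset$readId)
    }
    rownames(vt) <- NULL
    attr(out, "votes") <- vt
    out
}

#' Call the precursor transcription start site
#'
#' Takes the strand-matched 5'-start profile upstream of the mature 5'
#' terminus and reports the position with the highest start count, provided
#' that peak holds at least `minFrac` of all 5' starts in the window; a tie
#' for the maximum, or an empty window, is a no-call (`NULL`).
#'
#' @param profiles Output of [coverageProfiles()].
#' @param junction The [CircularJunction-class] defining the mature terminus.
#' @param searchWindow Window size upstream of the terminus (default 60).
#' @param minFrac Minimum fraction of window 5' starts at the peak
#'   (default 0.5).
#' @return A [TssCall-class], or `NULL` for a no-call.
#' @export
callTss <- function(profiles, junction, searchWindow = 60L, minFrac = 0.5) {
    n <- profiles$length
    if (junction@strand == "+") {
        lo <- max(1L, junction@acceptor - searchWindow)
        hi <- junction@acceptor - 1L
        if (hi < lo) return(NULL)
        v <- profiles$starts5Plus[lo:hi]
    } else {
        lo <- junction@donor + 1L
        hi <- min(n, junction@donor + searchWindow)
        if (hi < lo) return(NULL)
        v <- profiles$starts5Minus[lo:hi]
    }
    tot <- sum(v)
    if (tot == 0L) return(NULL)
    peak <- max(v)
    if (sum(v == peak) > 1L) return(NULL)          # ambiguous
    if (peak / tot < minFrac) return(NULL)
    pos <- (lo:hi)[which.max(v)]
    leader <- if (junction@strand == "+") junction@acceptor - pos
              else pos - junction@donor
    new("TssCall", pos = pos, leaderLen = as.integer(leader),
        support = as.integer(peak), frac = peak / tot)
}

#' Locate the TATA box upstream of a TSS
#'
#' Searches the promoter-proximal window for the TATA pattern and reports
#' the match nearest to the TSS (fewest mismatches first).  Both offset
#' conventions are returned: `offset` is the gap between the motif 3' base
#' and the TSS, `offsetFromStart` the gap measured from the motif 5' base.
#'
#' @param genome Reference sequence.
#' @param tss TSS coordinate (a [TssCall-class] or integer).
#' @param pattern TATA pattern (default `"TTAATA"`).
#' @param searchWindow Search window upstream of the TSS (default 40).
#' @param maxMismatch Mismatches tolerated (default 0).
#' @param strand Strand of the transcript (default `"+"`).
#' @return List with `start`, `end`, `strand`, `matched`, `offset`,
#'   `offsetFromStart`, or `NULL` if there is no match.
#' @export
findTata <- function(genome, tss, pattern = "TTAATA", searchWindow = 40L,
                     maxMismatch = 0L, strand = "+") {
    g <- .asSeqChar(genome)
    n <- nchar(g)
    if (is(tss, "TssCall")) tss <- tssPosition(tss)
    pl <- nchar(pattern)
    if (strand == "+") {
        lo <- max(1L, tss - searchWindow - pl + 1L); hi <- tss - 1L
    } else {
        lo <- tss + 1L; hi <- min(n, tss + searchWindow + pl - 1L)
    }
    if (hi - lo + 1L < pl) return(NULL)
    region <- Biostrings::DNAString(substring(g, lo, hi))
    pat <- Biostrings::DNAString(.normSeq(pattern))
    if (strand == "-") pat <- Biostrings::reverseComplement(pat)
    for (mm in 0:maxMismatch) {
        m <- Biostrings::matchPattern(pat, region, max.mismatch = mm,
                                      fixed = c(pattern = FALSE,
                                                subject = TRUE))
        if (!length(m)) next
        st <- Biostrings::start(m) + lo - 1L
        en <- Biostrings::end(m) + lo - 1L
        if (strand == "+") {
            keep <- en < tss
            if (!any(keep)) next
            st <- st[keep]; en <- en[keep]
            pick <- which.max(en)             # nearest to the TSS
            off <- tss - en[pick] - 1L
            offStart <- tss - st[pick] - 1L
        } else {
            keep <- st > tss
            if (!any(keep)) next
            st <- st[keep]; en <- en[keep]
            pick <- which.min(st)
            off <- st[pick] - tss - 1L
            offStart <- en[pick] - tss - 1L
        }
        txt <- substring(g, st[pick], en[pick])
        if (strand == "-") txt <- revComp(txt)
        return(list(start = st[pick], end = en[pick], strand = strand,
                    matched = txt, offset = off,
                    offsetFromStart = offStart))
    }
    NULL
}

## ---- BHB enumeration ---------------------------------------------------

## Enumerate BHB configurations between two strands (local 1-based coords).
## The duplex is walked from the strand1 5' end: outer helix (>= minOuter),
## a 3-nt bulge on one strand, the 4-bp central helix, a 3-nt bulge on the
## other strand, and a second outer helix.  `cutOffset` places the cut
## after the cutOffset-th bulge nucleotide (5'->3' on its own strand).
.enumerateBhbLocal <- function(c1chars, c2chars, minOuter = 2L,
                               allowGu = TRUE, cutOffset = 2L) {
    n1 <- length(c1chars); n2 <- length(c2chars)
    ok <- function(i, j) i >= 1L && i <= n1 && j >= 1L && j <= n2 &&
        canPair(c1chars[i], c2chars[j], allowGu)
    maxRun <- function(i0, j0, di, dj) {
        L <- 0L
        while (ok(i0 + di * L, j0 + dj * L)) L <- L + 1L
        L
    }
    out <- list(); k <- 0L
    for (c1 in seq_len(n1 - 3L)) {
        for (c2 in 4:n2) {
            ## central helix: (c1+t) pairs (c2-t), t = 0..3
            if (!(ok(c1, c2) && ok(c1 + 1L, c2 - 1L) &&
                  ok(c1 + 2L, c2 - 2L) && ok(c1 + 3L, c2 - 3L))) next
            for (arr in c("s1First", "s2First")) {
                if (arr == "s1First") {
                    ## bulge on strand1 before the central helix,
                    ## bulge on strand2 after it
                    b1 <- c(c1 - 3L, c1 - 1L)
                    b2 <- c(c2 - 6L, c2 - 4L)
                    la <- maxRun(c1 - 4L, c2 + 1L, -1L, +1L)
                    lb <- maxRun(c1 + 4L, c2 - 7L, +1L, -1L)
                    h1 <- c(c1 - 4L - la + 1L, c1 - 4L, c2 + 1L, c2 + la)
                    h2 <- c(c1 + 4L, c1 + 4L + lb - 1L, c2 - 7L - lb + 1L,
                            c2 - 7L)
                } else {
                    ## mirror image: bulge on strand2 before the central
                    ## helix, bulge on strand1 after it
                    b1 <- c(c1 + 4L, c1 + 6L)
                    b2 <- c(c2 + 1L, c2 + 3L)
                    la <- maxRun(c1 - 1L, c2 + 4L, -1L, +1L)
                    lb <- maxRun(c1 + 7L, c2 - 4L, +1L, -1L)
                    h1 <- c(c1 - 1L - la + 1L, c1 - 1L, c2 + 4L, c2 + 3L + la)
                    h2 <- c(c1 + 7L, c1 + 6L + lb, c2 - 4L - lb + 1L, c2 - 4L)
                }
                if (la < minOuter || lb < minOuter) next
                if (b1[1] < 1L || b1[2] > n1 || b2[1] < 1L || b2[2] > n2)
                    next
                k <- k + 1L
                out[[k]] <- new("BhbMotif", seqId = NA_character_,
                    strand = "*",
                    helices = matrix(c(h1,
                                       c1, c1 + 3L, c2 - 3L, c2,
                                       h2), nrow = 3L, byrow = TRUE,
                                     dimnames = list(
                                         c("outer1", "central", "outer2"),
                                         c("s1Start", "s1End",
                                           "s2Start", "s2End"))),
                    bulge1 = as.integer(b1), bulge2 = as.integer(b2),
                    cleavage1 = as.integer(b1[1] + cutOffset),
                    cleavage2 = as.integer(b2[1] + cutOffset),
                    arrangement = arr, score = as.integer(4L + la + lb),
                    coords = "local")
            }
        }
    }
    out
}

#' Enumerate BHB motifs between two strands
#'
#' Exhaustively enumerates bulge-helix-bulge configurations between two
#' antiparallel strands: outer helix (>= `minOuter` bp, maximal), 3-nt
#' unpaired bulge, central 4-bp helix, 3-nt unpaired bulge on the other
#' strand, outer helix.  Coordinates in the result are local to the strands.
#' Swapping the two strands yields the mirrored motifs with identical
#' scores.
#'
#' @param s1,s2 Nucleotide strands, each 5' to 3'.
#' @param minOuter Minimum outer helix length (default 2).
#' @param allowGu Allow G:U pairs (default `TRUE`).
#' @param cutOffset Cut after this bulge nucleotide, 1 or 2 (default 2).
#' @return List of [BhbMotif-class], score-descending.
#' @export
enumerateBhb <- function(s1, s2, minOuter = 2L, allowGu = TRUE,
                         cutOffset = 2L) {
    if (!cutOffset %in% c(1L, 2L)) stop("cutOffset must be 1 or 2")
    res <- .enumerateBhbLocal(.seqChars(.normSeq(s1)),
                              .seqChars(.normSeq(s2)),
                              minOuter = as.integer(minOuter),
                              allowGu = isTRUE(allowGu),
                              cutOffset = as.integer(cutOffset))
    res[order(-vapply(res, bhbScore, integer(1L)))]
}

#' Detect BHB motifs at the junction flanks
#'
#' Extracts the two flank strands around the mature termini (the transcript
#' segment crossing the acceptor and the one crossing the donor), enumerates
#' all BHB configurations between them, maps coordinates back to the genome
#' and ranks by score (total paired bases), ties broken by proximity of the
#' predicted cleavage to the observed termini.
#'
#' @param genome Reference sequence.
#' @param junction The called [CircularJunction-class].
#' @param flank Half-width of each strand window in nt (default 18, must be
#'   >= 10 to hold a minimal motif).
#' @param minOuter,allowGu,cutOffset Passed to [enumerateBhb()].
#' @return List of [BhbMotif-class] in genomic coordinates, best first.
#' @export
findBhb <- function(genome, junction, flank = 18L, minOuter = 2L,
                    allowGu = TRUE, cutOffset = 2L) {
    if (flank < 10L) stop("flank must be >= 10")
    g <- .asSeqChar(genome)
    n <- nchar(g)
    A <- junction@acceptor; D <- junction@donor
    if (junction@strand == "+") {
        lo1 <- A - flank; hi1 <- A + flank - 1L
        lo2 <- D + 1L - flank; hi2 <- D + flank
        if (lo1 < 1L || hi2 > n) stop("junction too close to the sequence end")
        s1 <- substring(g, lo1, hi1)
        s2 <- substring(g, lo2, hi2)
        mapS1 <- function(x) x + lo1 - 1L
        mapS2 <- function(x) x + lo2 - 1L
    } else {
        ## transcript space on the minus strand: the acceptor-side flank
        ## crosses the genomic donor, the donor-side flank the acceptor
        lo1 <- D - flank + 1L; hi1 <- D + flank
        lo2 <- A - flank; hi2 <- A + flank - 1L
        if (lo2 < 1L || hi1 > n) stop("junction too close to the sequence end")
        s1 <- revComp(substring(g, lo1, hi1))
        s2 <- revComp(substring(g, lo2, hi2))
        mapS1 <- function(x) hi1 - x + 1L
        mapS2 <- function(x) hi2 - x + 1L
    }
    res <- enumerateBhb(s1, s2, minOuter = minOuter, allowGu = allowGu,
                        cutOffset = cutOffset)
    mapIv <- function(iv, f) {
        v <- sort(f(iv))
        as.integer(v)
    }
    gres <- lapply(res, function(b) {
        h <- b@helices
        hg <- h
        for (r in 1:3) {
            hg[r, 1:2] <- mapIv(h[r, 1:2], mapS1)
            hg[r, 3:4] <- mapIv(h[r, 3:4], mapS2)
        }
        new("BhbMotif", seqId = junction@seqId, strand = junction@strand,
            helices = hg,
            bulge1 = mapIv(b@bulge1, mapS1),
            bulge2 = mapIv(b@bulge2, mapS2),
            cleavage1 = as.integer(mapS1(b@cleavage1)),
            cleavage2 = as.integer(mapS2(b@cleavage2)),
            arrangement = b@arrangement, score = b@score,
            coords = "genomic")
    })
    expect <- .expectedCleavage(junction)
    dist <- vapply(gres, function(b)
        abs(b@cleavage1 - expect[1]) + abs(b@cleavage2 - expect[2]),
        numeric(1L))
    score <- vapply(gres, bhbScore, integer(1L))
    gres[order(-score, dist)]
}

## genomic cleavage positions implied by a junction: the first mature base
## on the acceptor-side strand and the first trailer base on the donor side
.expectedCleavage <- function(junction) {
    if (junction@strand == "+")
        c(junction@acceptor, junction@donor + 1L)
    else
        c(junction@donor, junction@acceptor - 1L)
}

#' Predicted cleavage positions of a BHB
#'
#' The splicing endonuclease cuts inside each 3-nt bulge; the cut is placed
#' after the `cutOffset`-th bulge nucleotide (5' to 3' on its own strand)
#' and reported as the coordinate of the first nucleotide 3' of the cut.
#' For minus-strand (genomic) motifs the bulge is read along the transcript,
#' i.e. descending genomic coordinates.
#'
#' @param bhb A [BhbMotif-class].
#' @param cutOffset 1 or 2 (default 2); the generator and the detector share
#'   this convention.
#' @return `c(cleavage1, cleavage2)`.
#' @export
predictCleavage <- function(bhb, cutOffset = 2L) {
    if (!cutOffset %in% c(1L, 2L)) stop("cutOffset must be 1 or 2")
    minus <- identical(bhb@strand, "-") && bhb@coords == "genomic"
    if (minus)
        c(bhb@bulge1[2] - cutOffset, bhb@bulge2[2] - cutOffset) +
            c(0L, 0L)
    else
        c(bhb@bulge1[1] + cutOffset, bhb@bulge2[1] + cutOffset)
}

#' Validate a BHB against an observed junction
#'
#' `TRUE` iff the BHB's predicted cleavage sites coincide exactly with the
#' junction termini (the ligated ends must be uniquely defined for the
#' ligase to restore the mature RNA).  An empty or missing BHB is `FALSE`
#' with a diagnostic attribute.
#'
#' @param junction A [CircularJunction-class].
#' @param bhb A [BhbMotif-class], a list of them (the top-ranked one is
#'   used), or `NULL`.
#' @param cutOffset Cut convention shared with [predictCleavage()].
#' @return Logical scalar; attribute `"reason"` explains a `FALSE`.
#' @export
validateJunctionBhb <- function(junction, bhb, cutOffset = 2L) {
    if (is.list(bhb)) bhb <- if (length(bhb)) bhb[[1L]] else NULL
    if (is.null(bhb)) {
        out <- FALSE
        attr(out, "reason") <- "no BHB motif detected"
        return(out)
    }
    pred <- predictCleavage(bhb, cutOffset = cutOffset)
    expect <- .expectedCleavage(junction)
    out <- all(pred == expect)
    if (!out)
        attr(out, "reason") <- sprintf(
            "predicted cleavage (%d, %d) != junction termini (%d, %d)",
            pred[1], pred[2], expect[1], expect[2])
    out
}
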