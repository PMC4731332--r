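## Quality trimming, adapter trimming, length filtering and local alignment
## with soft-clip bookkeeping -- the standard small RNA-Seq preprocessing
## settings (quality limit 0.05, max. 2 ambiguities, 15-nt length cutoff,
## mismatch cost 4) recast as explicit, oracle-testable algorithms.

#' Mott-style quality trimming bounds
#'
#' Converts each Phred score Q to an error probability p = 10^(-Q/10) and
#' returns the contiguous read segment maximizing `sum(limit - p)`.  Ties are
#' broken towards the leftmost start, then the longest segment.  If every
#' segment sum is non-positive the read trims to nothing.
#'
#' @param qual Integer vector of Phred scores.
#' @param limit Error-probability limit (default 0.05).
#' @return `c(start, end)` of the retained segment (1-based closed), or
#'   `c(0, -1)` for an empty result.
#' @export
mottBounds <- function(qual, limit = 0.05) {
    if (length(qual) == 0L) return(c(0L, -1L))
    s <- limit - 10^(-qual / 10)
    cs <- cumsum(s)
    eps <- 1e-12
    best <- 0; bi <- 0L; bj <- -1L
    minv <- 0; mini <- 0L
    for (j in seq_along(s)) {
        val <- cs[j] - minv
        if (val > best + eps) {
            best <- val; bi <- mini; bj <- j
        } else if (bj > 0L && abs(val - best) <= eps &&
                   (mini < bi || (mini == bi && j > bj))) {
            bi <- mini; bj <- j
        }
        if (cs[j] < minv - eps) { minv <- cs[j]; mini <- j }
    }
    if (bj < 0L) return(c(0L, -1L))
    c(bi + 1L, bj)
}

#' Quality-trim reads
#'
#' Applies [mottBounds()] to every read; after trimming, reads with more than
#' `maxAmbiguities` ambiguous bases (N) are discarded (trimmed to zero
#' length).  Reads that trim to nothing are kept as zero-length records so
#' that downstream [lengthFilter()] removes them explicitly.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param limit Error-probability limit (default 0.05).
#' @param maxAmbiguities Maximum N count after trimming (default 2).
#' @return A trimmed [Biostrings::QualityScaledDNAStringSet].
#' @export
qualityTrim <- function(reads, limit = 0.05, maxAmbiguities = 2L) {
    if (!is(reads, "QualityScaledDNAStringSet"))
        stop("qualityTrim requires reads with qualities")
    quals <- phredScores(reads)
    seqs <- as.character(reads)
    qstr <- as.character(Biostrings::quality(reads))
    n <- length(reads)
    outSeq <- character(n); outQ <- character(n)
    for (i in seq_len(n)) {
        b <- mottBounds(quals[[i]], limit)
        if (b[1] > 0L) {
            sq <- substring(seqs[i], b[1], b[2])
            if (sum(.seqChars(sq) == "N") > maxAmbiguities) {
                outSeq[i] <- ""; outQ[i] <- ""
            } else {
                outSeq[i] <- sq
                outQ[i] <- substring(qstr[i], b[1], b[2])
            }
        } else {
            outSeq[i] <- ""; outQ[i] <- ""
        }
    }
    res <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(outSeq),
        Biostrings::PhredQuality(outQ))
    names(res) <- names(reads)
    res
}

## length (in nt) of the read suffix that aligns to an adapter prefix
.adapterOverlap <- function(seq, adapter, minOverlap, maxMismatchFrac) {
    rl <- nchar(seq); al <- nchar(adapter)
    hi <- min(rl, al)
    if (hi < minOverlap) return(0L)
    rc <- .seqChars(seq); ac <- .seqChars(adapter)
    for (o in hi:minOverlap) {
        mm <- sum(rc[(rl - o + 1L):rl] != ac[1:o])
        if (mm <= maxMismatchFrac * o) return(o)
    }
    0L
}

#' Trim a 3' adapter
#'
#' Removes the longest read suffix that aligns to a prefix of the adapter
#' with overlap at least `minOverlap` and at most `maxMismatchFrac * overlap`
#' mismatches; reads without an adapter-like suffix are unchanged.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet],
#'   [Biostrings::DNAStringSet] or character vector.
#' @param adapter Adapter sequence (non-empty).
#' @param minOverlap Minimum adapter/read overlap (default 3).
#' @param maxMismatchFrac Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return Same container type as `reads`, trimmed.
#' @export
trimAdapter <- function(reads, adapter, minOverlap = 3L,
                        maxMismatchFrac = 0.1) {
    if (!nzchar(adapter)) stop("adapter must be non-empty")
    adapter <- .normSeq(adapter)
    seqs <- as.character(reads)
    keep <- vapply(seqs, function(s)
        nchar(s) - .adapterOverlap(s, adapter, minOverlap, maxMismatchFrac),
        integer(1L), USE.NAMES = FALSE)
    if (is.character(reads)) return(substring(seqs, 1L, keep))
    if (is(reads, "QualityScaledDNAStringSet")) {
        qstr <- substring(as.character(Biostrings::quality(reads)), 1L, keep)
        res <- Biostrings::QualityScaledDNAStringSet(
            Biostrings::DNAStringSet(substring(seqs, 1L, keep)),
            Biostrings::PhredQuality(qstr))
        names(res) <- names(reads)
        return(res)
    }
    res <- Biostrings::DNAStringSet(substring(seqs, 1L, keep))
    names(res) <- names(reads)
    res
}

#' Filter reads by minimum length
#'
#' Keeps exactly the reads of length `>= minLen`, preserving order.
#'
#' @param reads An XStringSet or character vector.
#' @param minLen Minimum retained length (default 15).
#' @return Same container type, filtered.
#' @export
lengthFilter <- function(reads, minLen = 15L) {
    len <- if (is.character(reads)) nchar(reads) else Biostrings::width(reads)
    reads[len >= minLen]
}

## exact k-mer index of a sequence: environment kmer -> integer start vector
.kmerIndex <- function(seqChar, k) {
    n <- nchar(seqChar)
    if (n < k) return(new.env(hash = TRUE))
    starts <- seq_len(n - k + 1L)
    kmers <- substring(seqChar, starts, starts + k - 1L)
    list2env(split(starts, kmers), hash = TRUE)
}

## candidate genome windows for one oriented read, from exact seed hits
.seedWindows <- function(readChar, index, readLen, refLen, k,
                         diagGap = 15L, pad = 20L) {
    np <- nchar(readChar) - k + 1L
    if (np < 1L) return(NULL)
    pos <- seq_len(np)
    kmers <- substring(readChar, pos, pos + k - 1L)
    hits <- mget(kmers, envir = index, ifnotfound = list(NULL))
    diags <- integer(0)
    for (t in seq_along(hits)) {
        h <- hits[[t]]
        if (!is.null(h)) diags <- c(diags, h - pos[t] + 1L)
    }
    if (!length(diags)) return(NULL)
    diags <- sort(unique(diags))
    grp <- cumsum(c(1L, diff(diags) > diagGap))
    lapply(split(diags, grp), function(d) {
        ws <- max(1L, min(d) - pad)
        we <- min(refLen, max(d) + readLen - 1L + pad)
        c(ws, we)
    })
}

#' Seed-and-extend local alignment of reads against a genome
#'
#' Exact `seedLen`-mer seeds located through a genome index nominate
#' windows, which are aligned by full local Smith-Waterman with affine gaps
#' (match `+1`, mismatch `-4` following the "mismatch cost 4" mapping
#' setting; a gap of length L costs `gapOpen + L * gapExtend`).  Both strands
#' are searched.  For every read the best-scoring alignment and all
#' co-optimal ones are reported; unaligned read ends are soft clips.
#'
#' @param reads XStringSet or named character vector of reads.
#' @param genome A [Biostrings::DNAStringSet], DNAString or character scalar.
#' @param match,mismatch Match/mismatch scores (default +1 / -4).
#' @param gapOpen,gapExtend Affine gap parameters (default 6 / 1).
#' @param seedLen Exact seed length (default 12).
#' @return data.frame with one row per reported alignment: `readId`,
#'   `seqId`, `refStart`, `refEnd`, `strand`, `readStart`, `readEnd`
#'   (coordinates on the aligned strand of the read, i.e. on the
#'   reverse-complemented read for minus-strand alignments; soft clips are
#'   `[1, readStart)` and `(readEnd, readLen]`), `readLen`, `score`,
#'   `nMismatch`, `nGap`, and `nBest` (number of co-optimal placements of
#'   that read).
#' @export
alignReads <- function(reads, genome, match = 1L, mismatch = -4L,
                       gapOpen = 6L, gapExtend = 1L, seedLen = 12L) {
    refChar <- .asSeqChar(genome)
    seqId <- .seqIdOf(genome)
    refLen <- nchar(refChar)
    if (refLen < seedLen) stop("genome shorter than the seed length")
    index <- .kmerIndex(refChar, seedLen)
    seqs <- as.character(reads)
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("read_", seq_along(seqs))
    res <- vector("list", length(seqs))
    empty <- data.frame(readId = character(0), seqId = character(0),
                        refStart = integer(0), refEnd = integer(0),
                        strand = character(0), readStart = integer(0),
                        readEnd = integer(0), readLen = integer(0),
                        score = integer(0), nMismatch = integer(0),
                        nGap = integer(0), nBest = integer(0))
    nres <- 0L
    for (r in seq_along(seqs)) {
        fwd <- seqs[[r]]
        rl <- nchar(fwd)
        if (rl < seedLen) next
        rev <- revComp(fwd)
        cand <- list()
        for (strand in c("+", "-")) {
            oriented <- if (strand == "+") fwd else rev
            wins <- .seedWindows(oriented, index, rl, refLen, seedLen)
            if (is.null(wins)) next
            seenWin <- character(0)
            for (w in wins) {
                key <- paste(w, collapse = ":")
                if (key %in% seenWin) next
                seenWin <- c(seenWin, key)
                aln <- .swAlignC(oriented, substring(refChar, w[1], w[2]),
                                 match, mismatch, gapOpen, gapExtend)
                if (aln$score <= 0L || !length(aln$refStart)) next
                cand[[length(cand) + 1L]] <- data.frame(
                    readId = ids[r], seqId = seqId,
                    refStart = aln$refStart + w[1] - 1L,
                    refEnd = aln$refEnd + w[1] - 1L,
                    strand = strand,
                    readStart = aln$readStart, readEnd = aln$readEnd,
                    readLen = rl,
                    score = aln$score,
                    nMismatch = aln$nMismatch, nGap = aln$nGap)
            }
        }
        if (!length(cand)) next
        all <- do.call(rbind, cand)
        best <- max(all$score)
        all <- all[all$score == best, , drop = FALSE]
        all <- all[!duplicated(all[, c("refStart", "refEnd", "strand",
                                       "readStart", "readEnd")]), ,
                   drop = FALSE]
        all$nBest <- nrow(all)
        nres <- nres + 1L
        res[[nres]] <- all
    }
    if (nres == 0L) return(empty)
    out <- do.call(rbind, res[seq_len(nres)])
    rownames(out) <- NULL
    out
}

#' Per-base depth and 5'-start profiles
#'
#' `depth[i]` counts the alignments covering position i (per strand);
#' `starts5[i]` counts the alignments whose biological 5' end maps to i
#' (the reference start for `+` alignments, the reference end for `-`).
#'
#' @param aln Alignment data.frame from [alignReads()].
#' @param genome The reference the alignments were made against (or its
#'   length as a single integer).
#' @return List with integer vectors `depthPlus`, `depthMinus`,
#'   `starts5Plus`, `starts5Minus` and the reference `length`.
#' @export
coverageProfiles <- function(aln, genome) {
    n <- if (is.numeric(genome)) as.integer(genome)
         else nchar(.asSeqChar(genome))
    prof <- function(rows) {
        d <- integer(n + 1L)
        if (nrow(rows)) {
            add <- tabulate(rows$refStart, nbins = n + 1L)
            sub <- tabulate(pmin(rows$refEnd + 1L, n + 1L), nbins = n + 1L)
            d <- add - sub
        }
        cumsum(d)[seq_len(n)]
    }
    plus <- aln[aln$strand == "+", , drop = FALSE]
    minus <- aln[aln$strand == "-", , drop = FALSE]
    list(depthPlus = prof(plus), depthMinus = prof(minus),
         starts5Plus = tabulate(plus$refStart, nbins = n),
         starts5Minus = tabulate(minus$refEnd, nbins = n),
         length = n)
}
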