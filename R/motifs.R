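## Candidate-locus nomination: degenerate (IUPAC) motif matching plus
## folding-potential scoring over sliding genomic windows.  The two anchor
## motifs are the GNAR tetraloop (G, any, A, purine) and the conserved
## SRP54-binding motif of helix 8b, whose consensus is a configurable
## pattern (see `defaultConfig()` for the documented placeholder).

#' Scan a sequence with a degenerate IUPAC pattern
#'
#' Reports every position matching the pattern under IUPAC degeneracy
#' (N = any, R = A/G, Y = C/T, ...).  Minus-strand hits are found with the
#' reverse-complemented pattern and reported in plus-strand coordinates;
#' their `matched` field is the minus-strand (reverse-complemented) text, so
#' it always satisfies the pattern.
#'
#' @param seq Subject sequence (character, DNAString or DNAStringSet).
#' @param pattern IUPAC pattern string.
#' @param bothStrands Also scan the minus strand (default `TRUE`).
#' @param patternName Name recorded in the output (defaults to the pattern).
#' @return data.frame with columns `pattern`, `seqId`, `start`, `end`,
#'   `strand`, `matched`.
#' @examples
#' iupacScan("TTGAAATT", "GNAR", bothStrands = FALSE)
#' @export
iupacScan <- function(seq, pattern, bothStrands = TRUE,
                      patternName = pattern) {
    subj <- Biostrings::DNAString(.asSeqChar(seq))
    seqId <- .seqIdOf(seq)
    pat <- tryCatch(Biostrings::DNAString(.normSeq(pattern)),
                    error = function(e)
                        stop("invalid IUPAC pattern '", pattern, "': ",
                             conditionMessage(e), call. = FALSE))
    scan1 <- function(p, strand) {
        m <- Biostrings::matchPattern(p, subj,
                                      fixed = c(pattern = FALSE,
                                                subject = TRUE))
        if (!length(m))
            return(NULL)
        st <- Biostrings::start(m); en <- Biostrings::end(m)
        txt <- as.character(m)
        if (strand == "-") txt <- revComp(txt)
        data.frame(pattern = patternName, seqId = seqId,
                   start = st, end = en, strand = strand, matched = txt)
    }
    out <- scan1(pat, "+")
    if (bothStrands) {
        rc <- Biostrings::reverseComplement(pat)
        out <- rbind(out, scan1(rc, "-"))
    }
    if (is.null(out))
        out <- data.frame(pattern = character(0), seqId = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), matched = character(0))
    rownames(out) <- NULL
    out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a genome for candidate permuted-SRP-RNA loci
#'
#' Slides windows across the genome; a window qualifies if it contains at
#' least one GNAR tetraloop hit and one helix-8b motif hit on the same
#' strand and its [pairingFraction()] reaches `minFold`.  The combined score
#' adds a fixed bonus per required motif to the fold score.  Overlapping
#' qualifying windows on the same strand are merged; candidates are ranked
#' by combined score (descending), ties by leftmost start.
#'
#' @param genome Character, DNAString or DNAStringSet.
#' @param h8bPattern IUPAC pattern for the helix-8b motif (required; the
#'   package default placeholder is in `defaultConfig()`).
#' @param gnarPattern IUPAC pattern for the tetraloop (default `"GNAR"`).
#' @param window,step Window size and stride in nt (defaults 400/50, sized
#'   to a ~300-nt gene).
#' @param minFold Minimum pairing fraction (default 0.5).
#' @param motifBonus Score bonus per required motif present (default 0.5).
#' @return data.frame of candidates: `seqId`, `start`, `end`, `strand`,
#'   `nGnar`, `nH8b`, `foldScore`, `combinedScore`, ranked best-first.
#' @export
scanCandidateLoci <- function(genome, h8bPattern, gnarPattern = "GNAR",
                              window = 400L, step = 50L, minFold = 0.5,
                              motifBonus = 0.5) {
    g <- .asSeqChar(genome)
    seqId <- .seqIdOf(genome)
    n <- nchar(g)
    if (window > n) window <- n
    if (window < max(nchar(gnarPattern), nchar(h8bPattern)))
        stop("window smaller than the longest pattern")
    gnar <- iupacScan(g, gnarPattern, bothStrands = TRUE)
    h8b <- iupacScan(g, h8bPattern, bothStrands = TRUE)
    starts <- unique(c(seq(1L, max(1L, n - window + 1L), by = step),
                       max(1L, n - window + 1L)))
    empty <- data.frame(seqId = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        nGnar = integer(0), nH8b = integer(0),
                        foldScore = numeric(0), combinedScore = numeric(0))
    rows <- list(); k <- 0L
    foldCache <- new.env(hash = TRUE)
    for (ws in starts) {
        we <- ws + window - 1L
        inWin <- function(h, str)
            sum(h$start >= ws & h$end <= we & h$strand == str)
        for (str in c("+", "-")) {
            ng <- inWin(gnar, str); nh <- inWin(h8b, str)
            if (ng < 1L || nh < 1L) next
            key <- as.character(ws)
            if (is.null(foldCache[[key]]))
                foldCache[[key]] <- pairingFraction(substring(g, ws, we))
            fs <- foldCache[[key]]
            if (fs < minFold) next
            k <- k + 1L
            rows[[k]] <- data.frame(seqId = seqId, start = ws, end = we,
                                    strand = str, nGnar = ng, nH8b = nh,
                                    foldScore = fs,
                                    combinedScore = fs + 2 * motifBonus)
        }
    }
    if (k == 0L) return(empty)
    cand <- do.call(rbind, rows)
    ## merge overlapping qualifying windows per strand
    merged <- list(); m <- 0L
    for (str in c("+", "-")) {
        cs <- cand[cand$strand == str, , drop = FALSE]
        if (!nrow(cs)) next
        cs <- cs[order(cs$start), , drop = FALSE]
        cur <- cs[1, , drop = FALSE]
        flush <- function(cur) {
            m <<- m + 1L
            merged[[m]] <<- cur
        }
        if (nrow(cs) > 1) for (i in 2:nrow(cs)) {
            if (cs$start[i] <= cur$end + 1L) {
                cur$end <- max(cur$end, cs$end[i])
                cur$nGnar <- max(cur$nGnar, cs$nGnar[i])
                cur$nH8b <- max(cur$nH8b, cs$nH8b[i])
                cur$foldScore <- max(cur$foldScore, cs$foldScore[i])
                cur$combinedScore <- max(cur$combinedScore,
                                         cs$combinedScore[i])
            } else {
                flush(cur)
                cur <- cs[i, , drop = FALSE]
            }
        }
        flush(cur)
    }
    out <- do.call(rbind, merged)
    out <- out[order(-out$combinedScore, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Is a tetraloop hit in hairpin-loop context?
#'
#' Folds the window with [nussinovFold()] and checks that the four hit bases
#' are unpaired and flanked by at least two closing base pairs, i.e. that the
#' motif forms a hairpin loop.
#'
#' @param windowSeq The sequence window (character).
#' @param hitStart 1-based start of the 4-nt hit within `windowSeq`.
#' @param minHairpin,allowGu Passed to [nussinovFold()].
#' @return Logical.
#' @export
tetraloopContext <- function(windowSeq, hitStart, minHairpin = 3L,
                             allowGu = TRUE) {
    w <- .normSeq(.asSeqChar(windowSeq))
    n <- nchar(w)
    stopifnot(hitStart >= 1L, hitStart + 3L <= n)
    fr <- nussinovFold(w, minHairpin = minHairpin, allowGu = allowGu)
    p <- pairedBases(fr)
    loop <- hitStart:(hitStart + 3L)
    if (any(loop %in% c(p[, 1], p[, 2]))) return(FALSE)
    hasPair <- function(i, j) any(p[, 1] == i & p[, 2] == j)
    hitStart - 2L >= 1L && hitStart + 5L <= n &&
        hasPair(hitStart - 1L, hitStart + 4L) &&
        hasPair(hitStart - 2L, hitStart + 5L)
}
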