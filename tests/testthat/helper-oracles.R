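## Independent brute-force oracles used to check the package's algorithms.
## These deliberately use naive enumeration, not the implementation's code
## paths.

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

## exhaustive max-sum substring of (limit - p) over all O(n^2) substrings,
## same tie rule as mottBounds: highest sum, then leftmost, then longest
oracleMott <- function(qual, limit = 0.05) {
    n <- length(qual)
    if (n == 0L) return(c(0L, -1L))
    s <- limit - 10^(-qual / 10)
    best <- 0; bi <- 0L; bj <- -1L
    eps <- 1e-12
    for (i in seq_len(n)) {
        acc <- 0
        for (j in i:n) {
            acc <- acc + s[j]
            better <- acc > best + eps
            tie <- abs(acc - best) <= eps && bj > 0L &&
                (i < bi || (i == bi && j > bj))
            if (better || tie) { best <- acc; bi <- i; bj <- j }
        }
    }
    if (bj < 0L) c(0L, -1L) else c(bi, bj)
}

## exhaustive maximum-matching count over all valid pair sets
oracleNussinovCount <- function(seq, minHairpin = 3L, allowGu = TRUE) {
    ch <- strsplit(toupper(seq), "")[[1]]
    n <- length(ch)
    rec <- function(avail) {
        if (length(avail) < 2L) return(0L)
        i <- avail[1L]
        rest <- avail[-1L]
        best <- rec(rest)                     # i unpaired
        for (j in rest) {
            if (j - i <= minHairpin) next
            if (!canPair(ch[i], ch[j], allowGu)) next
            ## non-crossing: partners of positions between i and j must stay
            ## inside (i, j); enforce by splitting the available positions
            inner <- rest[rest > i & rest < j]
            outer <- rest[rest > j]
            best <- max(best, 1L + rec(inner) + rec(outer))
        }
        best
    }
    rec(seq_len(n))
}

## position-by-position IUPAC scanner
IUPAC <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

oracleIupacScan <- function(seq, pattern) {
    sc <- strsplit(toupper(seq), "")[[1]]
    pc <- strsplit(toupper(pattern), "")[[1]]
    n <- length(sc); m <- length(pc)
    hits <- integer(0)
    if (n >= m) for (i in seq_len(n - m + 1L)) {
        ok <- TRUE
        for (t in seq_len(m)) {
            if (!(sc[i + t - 1L] %in% IUPAC[[pc[t]]])) { ok <- FALSE; break }
        }
        if (ok) hits <- c(hits, i)
    }
    hits
}

## brute-force maximal antiparallel helices: all (i, j, L) triples
oracleDuplexHelices <- function(s1, s2, minLen = 2L, allowGu = TRUE) {
    c1 <- strsplit(toupper(s1), "")[[1]]
    c2 <- strsplit(toupper(s2), "")[[1]]
    n1 <- length(c1); n2 <- length(c2)
    pair <- function(i, j) i >= 1 && i <= n1 && j >= 1 && j <= n2 &&
        canPair(c1[i], c2[j], allowGu)
    out <- list()
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
        if (!pair(i, j)) next
        if (pair(i - 1L, j + 1L)) next            # not a run start
        L <- 0L
        while (pair(i + L, j - L)) L <- L + 1L
        if (L >= minLen)
            out[[length(out) + 1L]] <- data.frame(i = i, j = j, length = L)
    }
    if (!length(out))
        return(data.frame(i = integer(0), j = integer(0),
                          length = integer(0)))
    res <- do.call(rbind, out)
    res[order(res$i, res$j), , drop = FALSE]
}

## Phred+33 quality string for tests
qstring <- function(q) {
    paste0(strsplit(rawToChar(as.raw(q + 33L)), "")[[1]], collapse = "")
}

makeReads <- function(seqs, quals = NULL, ids = NULL) {
    if (is.null(quals))
        quals <- vapply(nchar(seqs), function(n) qstring(rep(40L, n)), "")
    r <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(r) <- if (is.null(ids)) sprintf("r%03d", seq_along(seqs)) else ids
    r
}
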