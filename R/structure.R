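## Minimal RNA secondary-structure machinery: Watson-Crick (+ wobble)
## pairing rule, maximum base-pairing fold (Nussinov DP, compiled), and
## enumeration of antiparallel helices between two strands.

#' Can two nucleotides pair?
#'
#' Watson-Crick pairs (A:U/T, G:C) plus, by default, the G:U wobble pair --
#' the structure-preserving substitutions observed between orthologous
#' permuted SRP RNAs are G-C to G-U/A-U exchanges, so wobble pairs are part
#' of the pairing rule.
#'
#' @param a,b Single nucleotides (vectorized; T and U are equivalent).
#' @param allowGu Allow G:U wobble pairs (default `TRUE`).
#' @return Logical vector.
#' @examples
#' canPair("G", "C")          # TRUE
#' canPair("G", "U")          # TRUE (wobble)
#' canPair("A", "G")          # FALSE
#' @export
canPair <- function(a, b, allowGu = TRUE) {
    a <- toupper(chartr("U", "T", a))
    b <- toupper(chartr("U", "T", b))
    d <- paste0(a, b)
    ok <- d %in% c("AT", "TA", "GC", "CG")
    if (allowGu) ok <- ok | d %in% c("GT", "TG")
    ok
}

#' Maximum base-pairing fold (Nussinov)
#'
#' Maximizes the number of base pairs under [canPair()] and a minimum
#' hairpin-loop constraint, by dynamic programming with a deterministic
#' traceback (on ties the outermost pairing of the interval end is preferred
#' over bifurcation).  This is a folding-potential score, not a
#' thermodynamic model.
#'
#' @param seq Nucleotide string (T and U equivalent).
#' @param minHairpin Minimum number of unpaired bases in a hairpin loop
#'   (default 3, the standard steric constraint; a GNAR tetraloop is
#'   representable).
#' @param allowGu Allow G:U pairs (default `TRUE`).
#' @return A [FoldResult-class].
#' @examples
#' nPairs(nussinovFold("GGGAAAACCC"))   # 3
#' @export
nussinovFold <- function(seq, minHairpin = 3L, allowGu = TRUE) {
    s <- .normSeq(seq)
    if (nchar(s) < 1L) stop("sequence must be non-empty")
    r <- .nussinovFoldC(s, as.integer(minHairpin), isTRUE(allowGu))
    pairs <- r$pairs
    if (!is.matrix(pairs)) pairs <- matrix(integer(0), ncol = 2L)
    colnames(pairs) <- c("i", "j")
    new("FoldResult", seq = s, dotbracket = r$dotbracket,
        pairs = pairs, nPairs = as.integer(r$nPairs))
}

#' Pairing fraction of a sequence
#'
#' `2 * nPairs / length` from the maximum base-pairing fold; a score in
#' `[0, 1]` used as the folding-potential component of candidate-locus
#' ranking ("high potential for extended helical regions").
#'
#' @inheritParams nussinovFold
#' @return Numeric scalar in `[0, 1]`.
#' @export
pairingFraction <- function(seq, minHairpin = 3L, allowGu = TRUE) {
    s <- .normSeq(seq)
    if (nchar(s) < 2L) stop("sequence must be at least 2 nt")
    2 * .nussinovCountC(s, as.integer(minHairpin), isTRUE(allowGu)) / nchar(s)
}

#' Enumerate antiparallel duplex helices between two strands
#'
#' Finds all maximal helices in which `s1[i .. i+L-1]` pairs antiparallel
#' with `s2[j-L+1 .. j]` (so `s1[i]` pairs `s2[j]`), `L >= minLen`.  A helix
#' is maximal if it cannot be extended in either direction.
#'
#' @param s1,s2 Nucleotide strings (each read 5' to 3').
#' @param minLen Minimum helix length in base pairs (default 2).
#' @param allowGu Allow G:U pairs (default `TRUE`).
#' @return data.frame with columns `i` (start on `s1`), `j` (the `s2`
#'   position paired with `s1[i]`) and `length`.
#' @export
duplexHelices <- function(s1, s2, minLen = 2L, allowGu = TRUE) {
    c1 <- .seqChars(.normSeq(s1))
    c2 <- .seqChars(.normSeq(s2))
    n1 <- length(c1); n2 <- length(c2)
    if (n1 < 1L || n2 < 1L) stop("strands must be non-empty")
    P <- outer(c1, c2, function(x, y) canPair(x, y, allowGu))
    out <- vector("list", n1 + n2)
    k <- 0L
    ## helix pairs walk the anti-diagonal i + j = const
    for (d in 2L:(n1 + n2)) {
        is <- max(1L, d - n2):min(n1, d - 1L)
        v <- P[cbind(is, d - is)]
        r <- rle(v)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        hit <- which(r$values & r$lengths >= minLen)
        if (length(hit)) {
            k <- k + 1L
            i0 <- is[starts[hit]]
            out[[k]] <- data.frame(i = i0, j = d - i0,
                                   length = r$lengths[hit])
        }
    }
    if (k == 0L)
        return(data.frame(i = integer(0), j = integer(0),
                          length = integer(0)))
    res <- do.call(rbind, out[seq_len(k)])
    rownames(res) <- NULL
    res[order(res$i, res$j), , drop = FALSE]
}
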