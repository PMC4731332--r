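#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generator calls
#' do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

## normalize a nucleotide string: uppercase, optionally U -> T
.normSeq <- function(x, uToT = TRUE) {
    x <- toupper(x)
    if (uToT) x <- chartr("U", "T", x)
    x
}

.seqChars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## first sequence of a DNAStringSet / DNAString / character, as character
.asSeqChar <- function(genome) {
    if (is(genome, "DNAStringSet")) {
        if (length(genome) == 0L) stop("empty sequence set")
        as.character(genome[[1L]])
    } else if (is(genome, "DNAString")) {
        as.character(genome)
    } else if (is.character(genome)) {
        .normSeq(genome[[1L]])
    } else {
        stop("unsupported sequence container: ", class(genome)[1L])
    }
}

.seqIdOf <- function(genome, default = "seq") {
    nm <- if (is(genome, "DNAStringSet")) names(genome)[1L] else NULL
    if (is.null(nm) || is.na(nm) || nm == "") default else nm
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson style shuffle: permutes a nucleotide sequence while
#' preserving its exact dinucleotide composition, the standard null model for
#' RNA structure statistics.  Implemented as a random Eulerian walk on the
#' dinucleotide multigraph (last-edge spanning-tree construction).
#'
#' @param seq Character scalar, nucleotide sequence.
#' @return A shuffled sequence with identical dinucleotide counts.
#' @examples
#' s <- "ACGTACGTGGCC"
#' t <- dinucleotideShuffle(s)
#' nchar(t) == nchar(s)
#' @export
dinucleotideShuffle <- function(seq) {
    ch <- .seqChars(.normSeq(seq))
    n <- length(ch)
    if (n <= 2L) return(seq)
    letters <- unique(ch)
    first <- ch[1L]; last <- ch[n]
    ## adjacency lists of the dinucleotide multigraph
    edges <- split(ch[-1L], factor(ch[-n], levels = letters))
    for (attempt in seq_len(200L)) {
        adj <- lapply(edges, function(e) if (length(e) > 1L) sample(e) else e)
        ## pick, for every vertex except `last`, a terminal edge; the walk is
        ## Eulerian iff those terminal edges form a tree rooted at `last`.
        ## Simple rejection: do the walk and check it consumes all edges.
        ptr <- stats::setNames(rep(1L, length(letters)), letters)
        out <- character(n); out[1L] <- first
        v <- first; ok <- TRUE
        for (i in 2:n) {
            e <- adj[[v]]
            p <- ptr[[v]]
            if (p > length(e)) { ok <- FALSE; break }
            ptr[[v]] <- p + 1L
            v <- e[[p]]
            out[i] <- v
        }
        if (ok && all(vapply(letters, function(l)
                ptr[[l]] == length(adj[[l]]) + 1L, logical(1L))))
            return(paste0(out, collapse = ""))
    }
    stop("dinucleotide shuffle failed to find an Eulerian walk")
}
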