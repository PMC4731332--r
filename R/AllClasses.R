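## S4 classes for the central result objects.  All coordinates are 1-based
## and closed (IRanges convention); BED's 0-based half-open convention is
## produced only on export.

#' FoldResult: a maximum base-pairing secondary structure
#'
#' Result of [nussinovFold()]: the folded sequence, its dot-bracket string,
#' and the list of paired positions.
#'
#' @slot seq Character scalar, the folded sequence (DNA alphabet).
#' @slot dotbracket Character scalar, same length as `seq`.
#' @slot pairs Two-column integer matrix of paired positions (i < j, 1-based).
#' @slot nPairs Integer, number of base pairs.
#' @export
setClass("FoldResult", representation(
    seq = "character", dotbracket = "character",
    pairs = "matrix", nPairs = "integer"))

setValidity("FoldResult", function(object) {
    msg <- character()
    if (nchar(object@dotbracket) != nchar(object@seq))
        msg <- c(msg, "dotbracket length differs from sequence length")
    if (nrow(object@pairs) != object@nPairs)
        msg <- c(msg, "nPairs does not match the pair list")
    if (object@nPairs > 0) {
        p <- object@pairs
        if (any(p[, 1] >= p[, 2]))
            msg <- c(msg, "pairs must satisfy i < j")
        if (anyDuplicated(c(p[, 1], p[, 2])))
            msg <- c(msg, "a position participates in more than one pair")
    }
    db <- .seqChars(object@dotbracket)
    if (sum(db == "(") != sum(db == ")"))
        msg <- c(msg, "unbalanced dot-bracket string")
    if (length(msg)) msg else TRUE
})

#' CircularJunction: a called circularization junction
#'
#' The ligated 5'/3' termini of a circular mature RNA, in reference
#' coordinates: `acceptor` is the first (1-based) base of the mature RNA and
#' `donor` the last, so that on ligation `donor` is joined to `acceptor`.
#' All supporting reads vote for this identical coordinate pair; discordant
#' votes are never merged into one junction.
#'
#' @slot seqId Reference sequence name.
#' @slot acceptor Integer, first mature base (mature 5' terminus on `+`).
#' @slot donor Integer, last mature base (mature 3' terminus on `+`).
#' @slot strand `"+"` or `"-"`.
#' @slot support Integer, number of junction-spanning reads.
#' @slot readIds Character vector of supporting read identifiers.
#' @export
setClass("CircularJunction", representation(
    seqId = "character", acceptor = "integer", donor = "integer",
    strand = "character", support = "integer", readIds = "character"))

setValidity("CircularJunction", function(object) {
    msg <- character()
    if (object@acceptor > object@donor)
        msg <- c(msg, "acceptor must be <= donor")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (object@support < 0) msg <- c(msg, "support must be non-negative")
    if (length(msg)) msg else TRUE
})

#' TssCall: an inferred transcription start site
#'
#' @slot pos Integer, reference coordinate of the dominant precursor 5' end.
#' @slot leaderLen Integer, distance from the TSS to the mature 5' terminus.
#' @slot support Integer, 5'-start count at `pos`.
#' @slot frac Numeric, fraction of all 5' starts in the search window at `pos`.
#' @export
setClass("TssCall", representation(
    pos = "integer", leaderLen = "integer",
    support = "integer", frac = "numeric"))

setValidity("TssCall", function(object) {
    if (object@leaderLen < 1L) "leaderLen must be >= 1" else TRUE
})

#' BhbMotif: a bulge-helix-bulge processing motif
#'
#' Geometry of a BHB formed between two antiparallel strands: a central
#' four-base-pair helix flanked by two 3-nt unpaired bulges on opposite
#' strands, enclosed by outer helices of at least two base pairs.  The
#' splicing endonuclease cuts inside each bulge; `cleavage1`/`cleavage2`
#' record the first nucleotide 3' of each cut on its own strand.
#'
#' `helices` is a 3 x 4 integer matrix (rows `outer1`, `central`, `outer2`;
#' columns `s1Start`, `s1End`, `s2Start`, `s2End`).  `bulge1` lies on strand 1
#' and `bulge2` on strand 2, each as `c(start, end)`.  `coords` records
#' whether positions are local to the supplied strands or genomic.
#'
#' @slot seqId Reference name (`NA` for raw-strand enumeration).
#' @slot strand `"+"`, `"-"` (genomic) or `"*"` (local).
#' @slot helices 3 x 4 integer matrix of paired segments.
#' @slot bulge1,bulge2 Integer length-2 vectors, 3-nt unpaired bulges.
#' @slot cleavage1,cleavage2 Integer predicted cut positions.
#' @slot arrangement `"s1First"` or `"s2First"`: which strand's bulge
#'   precedes the central helix along the duplex walk.
#' @slot score Integer, total paired bases.
#' @slot coords `"local"` or `"genomic"`.
#' @export
setClass("BhbMotif", representation(
    seqId = "character", strand = "character", helices = "matrix",
    bulge1 = "integer", bulge2 = "integer",
    cleavage1 = "integer", cleavage2 = "integer",
    arrangement = "character", score = "integer", coords = "character"))

setValidity("BhbMotif", function(object) {
    msg <- character()
    h <- object@helices
    if (!all(dim(h) == c(3L, 2L * 2L)))
        msg <- c(msg, "helices must be a 3 x 4 matrix")
    else {
        len1 <- h[, 2] - h[, 1] + 1L
        len2 <- h[, 4] - h[, 3] + 1L
        if (any(len1 != len2))
            msg <- c(msg, "helix segment lengths differ between strands")
        if (len1[2] != 4L) msg <- c(msg, "central helix must be 4 bp")
        if (any(len1[c(1L, 3L)] < 2L))
            msg <- c(msg, "outer helices must be >= 2 bp")
    }
    for (b in list(object@bulge1, object@bulge2))
        if (b[2] - b[1] + 1L != 3L) msg <- c(msg, "bulges must be 3 nt")
    if (object@cleavage1 < object@bulge1[1] || object@cleavage1 > object@bulge1[2])
        msg <- c(msg, "cleavage1 must lie inside bulge1")
    if (object@cleavage2 < object@bulge2[1] || object@cleavage2 > object@bulge2[2])
        msg <- c(msg, "cleavage2 must lie inside bulge2")
    if (length(msg)) msg else TRUE
})

#' LocusTruth: ground truth of a synthetic locus
#'
#' Returned by [buildLocus()] and augmented by [simulateReads()]: the planted
#' circle interval, TSS/leader, TATA box, motif positions, BHB geometry and,
#' after simulation, per-read origin labels.
#'
#' @slot seqId Name of the synthetic sequence.
#' @slot circleStart,circleEnd Integer, first/last base of the circularized
#'   block (genomic, 1-based closed).
#' @slot tss Integer, transcription start site.
#' @slot leaderLen Integer, leader length.
#' @slot tataStart,tataEnd Integer, TATA box interval.
#' @slot tataOffset Integer, gap between the TATA 3' base and the TSS.
#' @slot gnarStart Integer, genomic start of the planted GNAR tetraloop.
#' @slot h8bStart,h8bEnd Integer, planted helix-8b motif interval.
#' @slot trailerEnd Integer, last base of the precursor transcript.
#' @slot cdbox Integer length-2 (or `NA`), the adjacent C/D box sRNA locus.
#' @slot bhb [BhbMotif-class] planted at the junction flanks.
#' @slot reads data.frame of per-read truth labels (filled by simulation).
#' @export
setClass("LocusTruth", representation(
    seqId = "character", circleStart = "integer", circleEnd = "integer",
    tss = "integer", leaderLen = "integer",
    tataStart = "integer", tataEnd = "integer", tataOffset = "integer",
    gnarStart = "integer", h8bStart = "integer", h8bEnd = "integer",
    trailerEnd = "integer",
    cdbox = "integer", bhb = "BhbMotif", reads = "data.frame"))

setValidity("LocusTruth", function(object) {
    msg <- character()
    if (object@circleEnd <= object@circleStart)
        msg <- c(msg, "circle interval is empty")
    if (object@tss != object@circleStart - object@leaderLen)
        msg <- c(msg, "tss must equal circleStart - leaderLen")
    if (length(msg)) msg else TRUE
})

## ---- generics and accessors -------------------------------------------

#' @describeIn CircularJunction-class First mature base.
#' @param object,x A `CircularJunction`.
#' @export
setGeneric("acceptor", function(object) standardGeneric("acceptor"))
#' @describeIn CircularJunction-class Last mature base.
#' @export
setGeneric("donor", function(object) standardGeneric("donor"))
#' @describeIn CircularJunction-class Number of supporting reads.
#' @export
setGeneric("junctionSupport", function(object) standardGeneric("junctionSupport"))

#' Length of a circular mature RNA
#'
#' For a junction with acceptor A and donor D (1-based closed), the circle is
#' D - A + 1 nt long.
#' @param object A [CircularJunction-class] or [LocusTruth-class].
#' @return Integer length in nucleotides.
#' @export
setGeneric("circleLength", function(object) standardGeneric("circleLength"))

#' @describeIn BhbMotif-class Total paired bases of the motif.
#' @param object A `BhbMotif`.
#' @export
setGeneric("bhbScore", function(object) standardGeneric("bhbScore"))

setMethod("acceptor", "CircularJunction", function(object) object@acceptor)
setMethod("donor", "CircularJunction", function(object) object@donor)
setMethod("junctionSupport", "CircularJunction", function(object) object@support)
setMethod("circleLength", "CircularJunction",
          function(object) object@donor - object@acceptor + 1L)
setMethod("circleLength", "LocusTruth",
          function(object) object@circleEnd - object@circleStart + 1L)
setMethod("bhbScore", "BhbMotif", function(object) object@score)

#' @describeIn TssCall-class TSS coordinate.
#' @param object A `TssCall`.
#' @export
setGeneric("tssPosition", function(object) standardGeneric("tssPosition"))
#' @describeIn TssCall-class Leader length in nt.
#' @export
setGeneric("leaderLength", function(object) standardGeneric("leaderLength"))
setMethod("tssPosition", "TssCall", function(object) object@pos)
setMethod("leaderLength", "TssCall", function(object) object@leaderLen)
setMethod("leaderLength", "LocusTruth", function(object) object@leaderLen)

setMethod("show", "CircularJunction", function(object) {
    cat("CircularJunction on ", object@seqId, " (", object@strand, "): ",
        object@acceptor, "..", object@donor,
        " (circle ", circleLength(object), " nt), support = ",
        object@support, " reads\n", sep = "")
})

setMethod("show", "TssCall", function(object) {
    cat("TssCall at ", object@pos, ", leader ", object@leaderLen,
        " nt, support ", object@support,
        " (", round(100 * object@frac, 1), "% of window 5' starts)\n",
        sep = "")
})

setMethod("show", "BhbMotif", function(object) {
    h <- object@helices
    cat("BhbMotif (", object@coords, " coordinates, score ", object@score,
        " paired bases)\n", sep = "")
    cat("  outer1 ", h[1, 1], "..", h[1, 2], " : ", h[1, 3], "..", h[1, 4],
        "   central ", h[2, 1], "..", h[2, 2], " : ", h[2, 3], "..", h[2, 4],
        "   outer2 ", h[3, 1], "..", h[3, 2], " : ", h[3, 3], "..", h[3, 4],
        "\n", sep = "")
    cat("  bulge1 (strand 1) ", object@bulge1[1], "..", object@bulge1[2],
        ", bulge2 (strand 2) ", object@bulge2[1], "..", object@bulge2[2],
        "; cleavage at ", object@cleavage1, " / ", object@cleavage2,
        "\n", sep = "")
})

setMethod("show", "LocusTruth", function(object) {
    cat("LocusTruth for ", object@seqId, ": circle ",
        object@circleStart, "..", object@circleEnd,
        " (", circleLength(object), " nt), leader ", object@leaderLen,
        " nt, TSS ", object@tss, ", TATA offset ", object@tataOffset,
        " nt, ", nrow(object@reads), " simulated reads\n", sep = "")
})

setMethod("show", "FoldResult", function(object) {
    cat("FoldResult: ", object@nPairs, " pairs\n", sep = "")
    if (nchar(object@seq) <= 80) {
        cat(" ", object@seq, "\n ", object@dotbracket, "\n", sep = "")
    }
})

#' @describeIn FoldResult-class Number of base pairs.
#' @param object A `FoldResult`.
#' @export
setGeneric("nPairs", function(object) standardGeneric("nPairs"))
setMethod("nPairs", "FoldResult", function(object) object@nPairs)

#' @describeIn FoldResult-class Dot-bracket string.
#' @export
setGeneric("dotBracket", function(object) standardGeneric("dotBracket"))
setMethod("dotBracket", "FoldResult", function(object) object@dotbracket)

#' @describeIn FoldResult-class Two-column matrix of paired positions.
#' @export
setGeneric("pairedBases", function(object) standardGeneric("pairedBases"))
setMethod("pairedBases", "FoldResult", function(object) object@pairs)

#' @describeIn BhbMotif-class Predicted cut positions `c(cleavage1, cleavage2)`.
#' @export
setGeneric("cleavageSites", function(object) standardGeneric("cleavageSites"))
setMethod("cleavageSites", "BhbMotif",
          function(object) c(object@cleavage1, object@cleavage2))
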