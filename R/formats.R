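## Readers/writers for the standard formats the pipeline touches, plus
## elementary sequence utilities.  Parsing is delegated to Biostrings and
## rtracklayer; these wrappers fix the package-wide conventions (uppercase,
## U -> T normalization, 1-based closed coordinates internally, convention
## conversion only at the GFF/BED boundary).

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param uToT Normalize U to T (default `TRUE`); the package works on a
#'   single DNA alphabet internally and re-substitutes U only in reports.
#' @return A [Biostrings::DNAStringSet] with uppercased sequences.
#' @export
readFasta <- function(path, uToT = TRUE) {
    raw <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e)
                        stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    seqs <- .normSeq(as.character(raw), uToT = uToT)
    out <- tryCatch(Biostrings::DNAStringSet(seqs),
                    error = function(e)
                        stop("non-IUPAC characters in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    names(out) <- names(raw)
    out
}

#' Write sequences as FASTA
#'
#' @param x A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, path, format = "fasta")
    invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a 4-line-record FASTQ file.
#' @return A [Biostrings::QualityScaledDNAStringSet] with Phred qualities.
#' @export
readFastq <- function(path) {
    x <- withCallingHandlers(
        tryCatch(
            Biostrings::readQualityScaledDNAStringSet(path,
                quality.scoring = "phred"),
            error = function(e)
                stop("malformed FASTQ in '", path, "': ",
                     conditionMessage(e), call. = FALSE)),
        warning = function(w) {
            ## the parser warns about dropping (empty) metadata columns
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    ## the C parser tolerates a quality line whose length differs from the
    ## sequence line; validate the 4-line record structure explicitly
    ln <- readLines(path, warn = FALSE)
    while (length(ln) && !nzchar(ln[length(ln)]))
        ln <- ln[-length(ln)]
    if (length(ln) %% 4L == 0L && length(ln) / 4L == length(x)) {
        bad <- which(nchar(ln[seq(2L, length(ln), by = 4L)]) !=
                     nchar(ln[seq(4L, length(ln), by = 4L)]))
        if (length(bad))
            stop("malformed FASTQ in '", path, "': sequence and quality ",
                 "lengths differ for record ", bad[1L], call. = FALSE)
    }
    x
}

#' Write reads as FASTQ (Phred+33)
#'
#' `writeFastq` then `readFastq` is the identity on ids, sequences and
#' qualities.
#'
#' @param x A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(x, path) {
    stopifnot(is(x, "QualityScaledDNAStringSet"))
    Biostrings::writeQualityScaledXStringSet(x, path)
    invisible(path)
}

#' Per-base Phred scores of a quality-scaled read set
#'
#' @param x A [Biostrings::QualityScaledDNAStringSet].
#' @return A list of integer vectors, one per read.
#' @export
phredScores <- function(x) {
    as(methods::as(Biostrings::quality(x), "IntegerList"), "list")
}

#' Build an annotation GRanges
#'
#' Convenience constructor for the feature table the generator and the
#' reporter share: one range per feature with a `kind` column (gene,
#' tata_box, leader, circle, cdbox_srna, bhb).
#'
#' @param seqId Reference sequence name.
#' @param start,end 1-based closed coordinates.
#' @param strand Strand, recycled.
#' @param kind Feature kind, recycled.
#' @param name Feature names.
#' @return A [GenomicRanges::GRanges] with `kind` (and `type`) metadata.
#' @export
makeFeatures <- function(seqId, start, end, strand = "+", kind = "gene",
                         name = kind) {
    if (length(start) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$kind <- character(0)
        S4Vectors::mcols(gr)$name <- character(0)
        S4Vectors::mcols(gr)$type <- character(0)
        return(gr)
    }
    gr <- GenomicRanges::GRanges(
        seqnames = seqId,
        ranges = IRanges::IRanges(start = start, end = end),
        strand = strand)
    S4Vectors::mcols(gr)$kind <- kind
    S4Vectors::mcols(gr)$name <- name
    ## rtracklayer uses 'type' for GFF3 column 3
    S4Vectors::mcols(gr)$type <- kind
    gr
}

#' Write features as GFF3 (1-based closed coordinates)
#'
#' @param features A [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGff <- function(features, path) {
    if (length(features) == 0L) {
        writeLines("##gff-version 3", path)
        return(invisible(path))
    }
    rtracklayer::export.gff3(features, path)
    invisible(path)
}

#' Write features as BED (0-based half-open coordinates)
#'
#' @param features A [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(features, path) {
    bed <- features
    nm <- S4Vectors::mcols(bed)$name
    S4Vectors::mcols(bed) <- NULL
    if (!is.null(nm)) S4Vectors::mcols(bed)$name <- nm
    rtracklayer::export.bed(bed, path)
    invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Maps all IUPAC ambiguity codes (N<->N, R<->Y, W<->W, S<->S, K<->M,
#' B<->V, D<->H) and is an involution.
#'
#' @param x Character vector of IUPAC nucleotide strings, or an XStringSet.
#' @return Reverse complement, same container type as the input.
#' @export
revComp <- function(x) {
    if (is(x, "DNAStringSet") || is(x, "DNAString"))
        return(Biostrings::reverseComplement(x))
    out <- vapply(x, function(s) {
        s <- .normSeq(s)
        rc <- tryCatch(Biostrings::reverseComplement(Biostrings::DNAString(s)),
                       error = function(e)
                           stop("non-IUPAC character in sequence: ",
                                conditionMessage(e), call. = FALSE))
        as.character(rc)
    }, character(1L), USE.NAMES = FALSE)
    out
}
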