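## Orchestration: configuration handling, the simulate -> process -> scan ->
## call pipeline, feature read counting and the machine-readable report.

#' Default pipeline configuration
#'
#' One namespaced block per stage; every tunable of the package appears here
#' with its default.  `reads$nPrecursor`/`reads$nCircular` of `NULL` are
#' resolved at run time to approximately 30x depth over the precursor and
#' the circle.
#'
#' @return Nested named list.
#' @export
defaultConfig <- function() {
    list(
        seed = 1L,
        verbosity = 1L,
        locus = list(circleLen = 309L, leaderLen = 23L, trailerLen = 40L,
                     tataOffset = 26L, tataSeq = "TTAATA",
                     gnarPos = NULL, h8bPos = NULL,
                     h8bPattern = "RGCGGCAGG",
                     cdbox = TRUE, cdboxSpacing = 30L, cdboxLen = 60L,
                     flankLen = 150L, gc = 0.5),
        reads = list(nPrecursor = NULL, nCircular = NULL, readLen = 75L,
                     err = 0, qualModel = "constant", adapter = NULL,
                     fracTssAnchored = 0.6),
        process = list(qualityLimit = 0.05, maxAmbiguities = 2L,
                       minLen = 15L, match = 1L, mismatch = -4L,
                       gapOpen = 6L, gapExtend = 1L, seedLen = 12L),
        scan = list(gnarPattern = "GNAR", h8bPattern = "RGCGGCAGG",
                    window = 400L, step = 50L, minFold = 0.5,
                    motifBonus = 0.5),
        call = list(minClip = 8L, minSupport = 2L, maxClipMismatch = 1L,
                    searchRadius = 1000L, tssWindow = 60L, tssMinFrac = 0.5,
                    tataPattern = "TTAATA", tataWindow = 40L,
                    tataMaxMismatch = 0L, bhbFlank = 18L, minOuter = 2L,
                    allowGu = TRUE, cutOffset = 2L))
}

## overlay user values onto defaults, rejecting unknown keys
.mergeConfig <- function(defaults, user, path = "") {
    if (is.null(user)) return(defaults)
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
        stop("unknown configuration key(s): ",
             paste0(path, bad, collapse = ", "))
    for (nm in names(user)) {
        if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
            defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]],
                                           paste0(path, nm, "$"))
        } else {
            defaults[[nm]] <- user[[nm]]
        }
    }
    defaults
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take their defaults.  A config
#' written with [writeConfig()] round-trips losslessly.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Nested named list.
#' @export
readConfig <- function(path = NULL) {
    cfg <- defaultConfig()
    if (!is.null(path))
        cfg <- .mergeConfig(cfg, yaml::read_yaml(path))
    cfg
}

#' Write a pipeline configuration as YAML
#'
#' @param config Nested list as returned by [defaultConfig()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Count alignments per annotated feature
#'
#' An alignment is assigned to a feature when its midpoint falls inside the
#' feature interval and the strands agree (`*` features accept both) -- the
#' simplest unambiguous rule for short reads over compact loci.
#'
#' @param aln Alignments from [alignReads()].
#' @param features A [GenomicRanges::GRanges] with a `name` (or `kind`)
#'   column.
#' @return Named integer vector of counts, one per feature.
#' @export
countFeatureReads <- function(aln, features) {
    nm <- S4Vectors::mcols(features)$name
    if (is.null(nm)) nm <- S4Vectors::mcols(features)$kind
    if (is.null(nm)) nm <- paste0("feature_", seq_along(features))
    mid <- (aln$refStart + aln$refEnd) %/% 2L
    fs <- GenomicRanges::start(features)
    fe <- GenomicRanges::end(features)
    fstr <- as.character(GenomicRanges::strand(features))
    counts <- integer(length(features))
    for (i in seq_along(features)) {
        okStrand <- fstr[i] == "*" | aln$strand == fstr[i]
        counts[i] <- sum(mid >= fs[i] & mid <= fe[i] & okStrand)
    }
    stats::setNames(counts, nm)
}

## two-line duplex rendering of a BHB for the report
.renderBhb <- function(genome, bhb) {
    g <- .asSeqChar(genome)
    h <- bhb@helices
    span1 <- c(min(h[, 1], bhb@bulge1[1]), max(h[, 2], bhb@bulge1[2]))
    span2 <- c(min(h[, 3], bhb@bulge2[1]), max(h[, 4], bhb@bulge2[2]))
    s1 <- substring(g, span1[1], span1[2])
    s2 <- substring(g, span2[1], span2[2])
    mark <- function(span, a, b, paired) {
        v <- rep(".", span[2] - span[1] + 1L)
        for (r in 1:3) {
            iv <- (h[r, a]:h[r, b]) - span[1] + 1L
            v[iv] <- if (paired == 1L) "(" else ")"
        }
        paste0(v, collapse = "")
    }
    list(strand1Seq = s1, strand1Struct = mark(span1, 1L, 2L, 1L),
         strand2Seq = s2, strand2Struct = mark(span2, 3L, 4L, 2L))
}

.jlist <- function(j) {
    list(seqId = j@seqId, acceptor = acceptor(j), donor = donor(j),
         strand = j@strand, support = junctionSupport(j),
         circleLength = circleLength(j))
}

.log <- function(cfg, ...) {
    if (isTRUE(cfg$verbosity > 0)) message(...)
}

#' Run the full discovery pipeline
#'
#' Executes simulate (optional) -> process (trim, filter, align) -> scan ->
#' call and returns a machine-readable report.  Identical config and seed
#' give an identical report.  When `outDir` is set, all stage artifacts are
#' written there (genome.fasta, reads.fastq, truth.json, features.gff3,
#' aln.tsv, candidates.tsv, motifs.bed, junction.bed, report.json).
#'
#' @param config Configuration list (see [defaultConfig()]).
#' @param outDir Optional output directory.
#' @param genome,reads Optional external inputs; when `NULL` the synthetic
#'   generator supplies them (simulate stage).
#' @param features Optional feature annotation ([GenomicRanges::GRanges])
#'   for read counting; defaults to the generator's features.
#' @return The report, a nested list; also written as `report.json` when
#'   `outDir` is set.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL,
                        genome = NULL, reads = NULL, features = NULL) {
    cfg <- .mergeConfig(defaultConfig(), config)
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    truth <- NULL
    ## -- simulate ---------------------------------------------------------
    if (is.null(genome)) {
        lp <- do.call(locusParams, c(cfg$locus, list(seed = cfg$seed)))
        loc <- buildLocus(lp)
        genome <- loc$genome
        truth <- loc$truth
        if (is.null(features)) features <- loc$features
        C <- circleLength(truth)
        prec <- truth@trailerEnd - truth@tss + 1L
        rcfg <- cfg$reads
        if (is.null(rcfg$nPrecursor))
            rcfg$nPrecursor <- as.integer(ceiling(30 * prec / rcfg$readLen))
        if (is.null(rcfg$nCircular))
            rcfg$nCircular <- as.integer(ceiling(30 * C / rcfg$readLen))
        sp <- do.call(readSimParams, c(rcfg, list(seed = cfg$seed + 1L)))
        sim <- simulateReads(genome, truth, sp)
        reads <- sim$reads
        truth <- sim$truth
        .log(cfg, "simulate: ", length(reads), " reads from ",
             nchar(.asSeqChar(genome)), " nt locus")
        if (!is.null(outDir)) {
            writeFasta(genome, file.path(outDir, "genome.fasta"))
            writeFastq(reads, file.path(outDir, "reads.fastq"))
            writeGff(features, file.path(outDir, "features.gff3"))
            jsonlite::write_json(.truthList(truth),
                                 file.path(outDir, "truth.json"),
                                 auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE)
        }
    } else if (is.null(reads)) {
        stop("stage 'process' failed: reads are required with an external genome")
    }
    ## -- process ----------------------------------------------------------
    pc <- cfg$process
    nRaw <- length(reads)
    trimmed <- if (is(reads, "QualityScaledDNAStringSet"))
        qualityTrim(reads, limit = pc$qualityLimit,
                    maxAmbiguities = pc$maxAmbiguities) else reads
    if (!is.null(cfg$reads$adapter))
        trimmed <- trimAdapter(trimmed, cfg$reads$adapter)
    kept <- lengthFilter(trimmed, minLen = pc$minLen)
    aln <- alignReads(kept, genome, match = pc$match,
                      mismatch = pc$mismatch, gapOpen = pc$gapOpen,
                      gapExtend = pc$gapExtend, seedLen = pc$seedLen)
    .log(cfg, "process: ", nRaw, " reads, ", length(kept),
         " after trimming/filtering, ",
         length(unique(aln$readId)), " aligned")
    if (!is.null(outDir))
        write.table(aln, file.path(outDir, "aln.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    ## -- scan -------------------------------------------------------------
    sc <- cfg$scan
    candidates <- scanCandidateLoci(genome, h8bPattern = sc$h8bPattern,
                                    gnarPattern = sc$gnarPattern,
                                    window = sc$window, step = sc$step,
                                    minFold = sc$minFold,
                                    motifBonus = sc$motifBonus)
    .log(cfg, "scan: ", nrow(candidates), " candidate locus/loci")
    if (!is.null(outDir)) {
        write.table(candidates, file.path(outDir, "candidates.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        hits <- rbind(iupacScan(genome, sc$gnarPattern),
                      iupacScan(genome, sc$h8bPattern))
        if (nrow(hits))
            writeBed(makeFeatures(hits$seqId, hits$start, hits$end,
                                  strand = hits$strand,
                                  kind = "motif", name = hits$pattern),
                     file.path(outDir, "motifs.bed"))
    }
    ## -- call -------------------------------------------------------------
    cl <- cfg$call
    profiles <- coverageProfiles(aln, genome)
    junctions <- detectCircularJunctions(aln, reads = kept, genome = genome,
                                         minClip = cl$minClip,
                                         minSupport = cl$minSupport,
                                         maxClipMismatch = cl$maxClipMismatch,
                                         searchRadius = cl$searchRadius)
    flags <- character(0)
    tss <- NULL; tata <- NULL; bhbTop <- NULL; bhbRender <- NULL
    concordant <- FALSE
    if (length(junctions)) {
        jx <- junctions[[1L]]
        tss <- callTss(profiles, jx, searchWindow = cl$tssWindow,
                       minFrac = cl$tssMinFrac)
        if (is.null(tss)) flags <- c(flags, "no TSS call")
        else {
            tata <- findTata(genome, tss, pattern = cl$tataPattern,
                             searchWindow = cl$tataWindow,
                             maxMismatch = cl$tataMaxMismatch,
                             strand = jx@strand)
            if (is.null(tata)) flags <- c(flags, "no TATA match")
        }
        bhb <- findBhb(genome, jx, flank = cl$bhbFlank,
                       minOuter = cl$minOuter, allowGu = cl$allowGu,
                       cutOffset = cl$cutOffset)
        concordant <- isTRUE(validateJunctionBhb(jx, bhb,
                                                 cutOffset = cl$cutOffset))
        if (length(bhb)) {
            bhbTop <- bhb[[1L]]
            bhbRender <- .renderBhb(genome, bhbTop)
        } else flags <- c(flags, "no BHB motif")
        if (!concordant) flags <- c(flags, "BHB cleavage discordant")
    } else {
        flags <- c(flags, "no junction evidence")
    }
    votes <- attr(junctions, "votes")
    nDiscordant <- if (length(junctions))
        sum(!(paste(votes$acceptor, votes$donor) %in%
              vapply(junctions, function(j)
                  paste(j@acceptor, j@donor), character(1L)))) else
        nrow(votes)
    featureCounts <- if (!is.null(features))
        countFeatureReads(aln, features) else NULL
    report <- list(
        provenance = list(package = "permacirc",
                          version = as.character(packageVersion("permacirc")),
                          seed = cfg$seed,
                          config = cfg),
        stageCounts = list(rawReads = nRaw,
                           afterTrimFilter = length(kept),
                           alignedReads = length(unique(aln$readId)),
                           uniqueBestReads = length(unique(
                               aln$readId[aln$nBest == 1L]))),
        candidates = candidates,
        junctions = lapply(junctions, .jlist),
        discordantVotes = nDiscordant,
        tss = if (!is.null(tss)) list(pos = tssPosition(tss),
                                      leaderLen = leaderLength(tss),
                                      support = tss@support,
                                      frac = tss@frac) else NULL,
        tata = tata,
        bhb = if (!is.null(bhbTop)) c(list(
                  score = bhbScore(bhbTop),
                  cleavage = as.list(stats::setNames(
                      cleavageSites(bhbTop), c("site1", "site2"))),
                  arrangement = bhbTop@arrangement), bhbRender) else NULL,
        validation = list(junctionBhbConcordant = concordant,
                          flags = flags),
        featureCounts = as.list(featureCounts),
        truth = if (!is.null(truth)) .truthList(truth) else NULL)
    if (!is.null(outDir)) {
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = 10, pretty = TRUE,
                             null = "null")
        if (length(junctions))
            writeBed(makeFeatures(junctions[[1L]]@seqId,
                                  acceptor(junctions[[1L]]),
                                  donor(junctions[[1L]]),
                                  strand = junctions[[1L]]@strand,
                                  kind = "circle", name = "junction"),
                     file.path(outDir, "junction.bed"))
        if (!is.null(features))
            writeGff(features, file.path(outDir, "features.gff3"))
    }
    report
}

## JSON-ready view of a LocusTruth (without the per-read table)
.truthList <- function(truth) {
    list(seqId = truth@seqId,
         circleStart = truth@circleStart, circleEnd = truth@circleEnd,
         circleLength = circleLength(truth),
         tss = truth@tss, leaderLen = truth@leaderLen,
         tataStart = truth@tataStart, tataEnd = truth@tataEnd,
         tataOffset = truth@tataOffset,
         gnarStart = truth@gnarStart,
         h8bStart = truth@h8bStart, h8bEnd = truth@h8bEnd,
         trailerEnd = truth@trailerEnd,
         cdbox = as.list(stats::setNames(truth@cdbox, c("start", "end"))),
         bhbCleavage = as.list(stats::setNames(
             cleavageSites(truth@bhb), c("site1", "site2"))),
         nReads = nrow(truth@reads))
}
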