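test_that("FASTA reading uppercases, normalizes U and round-trips", {
    fa <- tempfile(fileext = ".fasta")
    writeLines(c(">a", "acgu", ">b wrapped", "ACGT", "TTGG"), fa)
    x <- readFasta(fa)
    expect_equal(length(x), 2L)
    expect_equal(as.character(x[[1]]), "ACGT")
    expect_equal(Biostrings::width(x), c(4L, 8L))

    out <- tempfile(fileext = ".fasta")
    writeFasta(x, out)
    expect_equal(as.character(readFasta(out)), as.character(x),
                 ignore_attr = TRUE)
})

test_that("empty FASTA gives an empty set; bad characters error", {
    fa <- tempfile(fileext = ".fasta")
    file.create(fa)
    expect_length(readFasta(fa), 0L)
    writeLines(c(">a", "ACXZ9"), fa)
    expect_error(readFasta(fa), "IUPAC|malformed")
})

test_that("FASTQ round trip preserves id, sequence and qualities exactly", {
    r <- makeReads(c("ACGT", "GGGTTTAA"),
                   quals = c(qstring(c(40, 40, 2, 30)),
                             qstring(c(10:17))))
    fq <- tempfile(fileext = ".fastq")
    writeFastq(r, fq)
    back <- readFastq(fq)
    expect_equal(as.character(back), as.character(r), ignore_attr = TRUE)
    expect_equal(names(back), names(r))
    expect_equal(phredScores(back), phredScores(r), ignore_attr = TRUE)

    set.seed(11)
    seqs <- vapply(1:100, function(i) randomSeq(sample(15:60, 1)), "")
    quals <- vapply(nchar(seqs), function(n)
        qstring(sample(2:41, n, replace = TRUE)), "")
    big <- makeReads(seqs, quals)
    f1 <- tempfile(); f2 <- tempfile()
    writeFastq(big, f1)
    writeFastq(readFastq(f1), f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed FASTQ (short quality line) errors", {
    fq <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "III"), fq)
    expect_error(readFastq(fq), "FASTQ|quality")
})

test_that("GFF is 1-based closed and BED 0-based half-open for the same feature", {
    ft <- makeFeatures("chr", start = 1L, end = 10L, kind = "gene",
                       name = "g1")
    gff <- tempfile(fileext = ".gff3"); bed <- tempfile(fileext = ".bed")
    writeGff(ft, gff)
    writeBed(ft, bed)
    gl <- grep("^[^#]", readLines(gff), value = TRUE)
    gcols <- strsplit(gl[1], "\t")[[1]]
    expect_equal(gcols[4:5], c("1", "10"))
    bcols <- strsplit(readLines(bed)[1], "\t")[[1]]
    expect_equal(bcols[2:3], c("0", "10"))
    ## both encodings describe the identical interval after conversion
    back <- rtracklayer::import(bed)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(ft))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(ft))
})

test_that("empty feature list writes a header-only file", {
    ft <- makeFeatures(character(0), integer(0), integer(0))
    gff <- tempfile(fileext = ".gff3")
    writeGff(ft, gff)
    expect_true(all(grepl("^#", readLines(gff))))
})

test_that("revComp maps IUPAC codes and is a length-preserving involution", {
    expect_equal(revComp("ACGT"), "ACGT")
    expect_equal(revComp("AAA"), "TTT")
    expect_equal(revComp("NRYWSKMBVDH"), "DHBVKMSWRYN")
    expect_error(revComp("ACZQ"), "IUPAC")
    set.seed(3)
    for (i in 1:20) {
        x <- randomSeq(sample(1:80, 1),
                       alphabet = c("A", "C", "G", "T", "N", "R", "Y"))
        expect_identical(revComp(revComp(x)), x)
        expect_identical(nchar(revComp(x)), nchar(x))
    }
})
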