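# FASTA / GFF3 / RNAfold-dialect parsing and the screen output table.

test_that("FASTA reading validates and normalizes records", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">a", "ACGT"), fa)
    x <- readFastaRecords(fa)
    expect_identical(as.character(x), c(a = "ACGT"))

    writeLines(c(">a", "AC", "GU", ">b", "NNN"), fa)
    x <- readFastaRecords(fa)
    expect_identical(as.character(x), c(a = "ACGT", b = "NNN"))

    writeLines(c(">a", "AC GT"), fa)
    expect_error(readFastaRecords(fa), "position 3")

    writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
    expect_error(readFastaRecords(fa), "duplicate identifier 'a'")

    writeLines(character(0), fa)
    expect_error(readFastaRecords(fa), "no records")

    writeLines(c(">a", "ACgtn"), fa)
    x <- readFastaRecords(fa)
    expect_identical(as.character(x), c(a = "ACGTN"))
    expect_identical(S4Vectors::metadata(x)$softmask$a,
                     c(FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("FASTA write/read round-trips records", {
    fa <- withr::local_tempfile(fileext = ".fa")
    set.seed(5)
    recs <- setNames(
        vapply(1:4, function(i) paste0(
            sample(c("A", "C", "G", "T"), 70, TRUE), collapse = ""),
            character(1)),
        paste0("rec", 1:4))
    writeFastaRecords(recs, fa)
    expect_identical(as.character(readFastaRecords(fa)), recs)
})

test_that("GFF3 transcripts are assembled per strand", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tx\tgene\t10\t220\t.\t+\t.\tID=gene:g1;biotype=protein_coding",
        "chr1\tx\tmRNA\t10\t220\t.\t+\t.\tID=transcript:t1;Parent=gene:g1;biotype=protein_coding",
        "chr1\tx\tCDS\t10\t100\t.\t+\t0\tParent=transcript:t1",
        "chr1\tx\tthree_prime_UTR\t101\t220\t.\t+\t.\tParent=transcript:t1"),
        gff)
    m <- readGffTranscripts(gff)
    expect_length(m, 1L)
    tx <- m[["t1"]]
    expect_identical(geneId(tx), "g1")
    expect_equal(IRanges::start(tx@cds), 10L)
    expect_equal(IRanges::end(tx@utr3), 220L)

    # minus strand: UTR 1-120 precedes CDS 121-211 genomically but is
    # 3' of it in transcript orientation
    writeLines(c(
        "##gff-version 3",
        "chr1\tx\tgene\t1\t211\t.\t-\t.\tID=gene:g2",
        "chr1\tx\tmRNA\t1\t211\t.\t-\t.\tID=transcript:t2;Parent=gene:g2",
        "chr1\tx\tCDS\t121\t211\t.\t-\t0\tParent=transcript:t2",
        "chr1\tx\tthree_prime_UTR\t61\t120\t.\t-\t.\tParent=transcript:t2",
        "chr1\tx\tthree_prime_UTR\t1\t40\t.\t-\t.\tParent=transcript:t2"),
        gff)
    tx2 <- readGffTranscripts(gff)[["t2"]]
    # transcript order on minus strand: descending genomic start
    expect_equal(IRanges::start(tx2@utr3), c(61L, 1L))
    expect_equal(IRanges::end(tx2@utr3), c(120L, 40L))
})

test_that("transcripts without UTR features and orphan CDS are handled", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tx\tmRNA\t10\t100\t.\t+\t.\tID=transcript:t1",
        "chr1\tx\tCDS\t10\t100\t.\t+\t0\tParent=transcript:t1",
        "chr1\tx\tCDS\t300\t400\t.\t+\t0\tParent=transcript:missing"),
        gff)
    expect_warning(m <- readGffTranscripts(gff), "no resolvable parent")
    expect_length(m, 1L)
    expect_length(m[["t1"]]@utr3, 0L)
})

test_that("GFF reading is insensitive to feature line order", {
    g <- synthGenome(6, 0.5, seed = 9, dir = withr::local_tempdir())
    lines <- readLines(g$files["annotation"])
    hdr <- grepl("^#", lines)
    gff2 <- withr::local_tempfile(fileext = ".gff3")
    set.seed(1)
    writeLines(c(lines[hdr], sample(lines[!hdr])), gff2)
    m1 <- readGffTranscripts(g$files["annotation"])
    m2 <- readGffTranscripts(gff2)
    m2 <- m2[names(m1)]
    for (k in names(m1)) {
        expect_equal(IRanges::start(m1[[k]]@cds), IRanges::start(m2[[k]]@cds))
        expect_equal(IRanges::start(m1[[k]]@utr3),
                     IRanges::start(m2[[k]]@utr3))
        expect_identical(m1[[k]]@strand, m2[[k]]@strand)
    }
})

test_that("RNAfold dialect parsing handles energies and bad entries", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(">g", "GGGAAACCC", "(((...))) ( -1.20)"), f)
    x <- readRnafoldFile(f)
    expect_equal(mfe(x[["g"]]), -1.2)
    expect_equal(dotBracket(x[["g"]]), "(((...)))")

    writeLines(c(">g", "GGGAAACCC", "(((...)))"), f)
    expect_true(is.na(mfe(readRnafoldFile(f)[["g"]])))

    # unbalanced entry rejected individually, the rest kept
    writeLines(c(">bad", "GGGAAACCC", "(((...)) ( -1.20)",
                 ">ok", "GGGAAACCC", "(((...))) ( -2.10)"), f)
    expect_warning(x <- readRnafoldFile(f), "bad")
    expect_identical(names(x), "ok")

    writeLines(c(">g", "GGGAAACCCA", "(((...)))"), f)
    expect_error(readRnafoldFile(f), "does not match sequence length")
})

test_that("screen tables are deterministic and fixed-format", {
    row <- function(g, pass) data.frame(
        gene_id = g, window_length = 60L, truncated = FALSE,
        passed = pass, failure_reasons = if (pass) "" else "span",
        element_start = if (pass) 9L else NA_integer_,
        element_end = if (pass) 50L else NA_integer_,
        backend = "maxpair", stringsAsFactors = FALSE)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeScreenTable(rbind(row("gB", TRUE), row("gA", FALSE)), f)
    lines <- readLines(f)
    expect_equal(lines[1L], paste(
        "gene_id", "window_length", "truncated", "passed",
        "failure_reasons", "element_start", "element_end", "backend",
        sep = "\t"))
    expect_match(lines[2L], "^gA\t")
    expect_match(lines[3L], "^gB\t.*\t9\t50\tmaxpair$")
    # header-only for no calls
    writeScreenTable(row("x", TRUE)[0L, ], f)
    expect_length(readLines(f), 1L)
    # byte-identical regardless of input order
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeScreenTable(rbind(row("gA", FALSE), row("gB", TRUE)), f2)
    writeScreenTable(rbind(row("gB", TRUE), row("gA", FALSE)), f)
    expect_identical(readLines(f), readLines(f2))
})
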