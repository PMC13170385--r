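# Deterministic synthetic fixtures: planted hairpins whose unique
# maximum-weight structure is known by construction, toy genomes with
# ground-truth labels, and plate-reader tables with known readthrough
# efficiencies.
#
# Uniqueness by construction: stems use G on the 5' arm and C on the 3'
# arm, all unpaired regions (flanks, terminal loop, bulges) use A only.
# The only admissible pairs are then G:C with every G 5' of every C, and
# the single non-crossing perfect matching of two separated runs is the
# planted rainbow, so any maximum-weight structure equals the planted one.

#' @importFrom stats rlnorm runif
NULL

#' Plant a hairpin with controlled stem, loop and bulge geometry
#'
#' Generates a sequence whose unique maximum-base-pairing optimum is the
#' planted structure (see the package vignette for the uniqueness
#' argument), together with the ground-truth structure. Deterministic:
#' the same specification always yields the same output.
#'
#' @param stemLength number of base pairs in the stem (>= 3).
#' @param loopLength terminal loop length in nt (>= 3, the folding
#'   minimum; shorter loops cannot be an optimum and are rejected).
#' @param bulges list of bulge specifications, each
#'   \code{list(after = <pair index from the outer end, 1..stemLength-1>,
#'   side = "5prime"|"3prime", length = <nt>)}.
#' @param flank5,flank3 unpaired flank lengths in nt.
#' @return list with \code{sequence} (RNA), \code{structure} (the
#'   ground-truth [SecondaryStructure], backend \code{"truth"}),
#'   \code{span}, \code{elementStart}, \code{elementEnd} (positions within
#'   the sequence).
#' @examples
#' plantHairpin(16, 3)$span  # 35, the boundary span
#' @export
plantHairpin <- function(stemLength, loopLength = 4L, bulges = list(),
                         flank5 = 5L, flank3 = 5L) {
    stemLength <- as.integer(stemLength)
    loopLength <- as.integer(loopLength)
    if (stemLength < 3L)
        stop("uniqueness cannot be guaranteed for stems shorter than 3 bp")
    if (loopLength < 3L)
        stop("loops shorter than 3 nt cannot close a folded hairpin")
    for (b in bulges) {
        if (!all(c("after", "side", "length") %in% names(b)))
            stop("each bulge needs 'after', 'side' and 'length'")
        if (b$after < 1L || b$after >= stemLength)
            stop("bulge 'after' must be between 1 and stemLength - 1")
        if (!b$side %in% c("5prime", "3prime"))
            stop("bulge side must be '5prime' or '3prime'")
    }
    bulgeAt <- function(t, side) {
        len <- 0L
        for (b in bulges)
            if (b$after == t && b$side == side) len <- len + as.integer(b$length)
        len
    }
    seqCh <- character(0); dbCh <- character(0)
    add <- function(s, d) {
        seqCh <<- c(seqCh, s); dbCh <<- c(dbCh, d)
    }
    add(rep("A", flank5), rep(".", flank5))
    for (t in seq_len(stemLength)) {
        add("G", "(")
        n5 <- if (t < stemLength) bulgeAt(t, "5prime") else 0L
        if (n5) add(rep("A", n5), rep(".", n5))
    }
    add(rep("A", loopLength), rep(".", loopLength))
    for (t in rev(seq_len(stemLength))) {
        n3 <- if (t < stemLength) bulgeAt(t, "3prime") else 0L
        if (n3) add(rep("A", n3), rep(".", n3))
        add("C", ")")
    }
    add(rep("A", flank3), rep(".", flank3))
    sequence <- paste0(seqCh, collapse = "")
    db <- paste0(dbCh, collapse = "")
    elementStart <- flank5 + 1L
    elementEnd <- nchar(sequence) - flank3
    list(sequence = sequence,
         structure = secondaryStructure(sequence, db, backend = "truth"),
         span = elementEnd - elementStart + 1L,
         elementStart = elementStart, elementEnd = elementEnd)
}

.randomBases <- function(n, alphabet = c("A", "C")) {
    paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a toy annotated genome with planted stem-loops
#'
#' Builds a single-chromosome genome of \code{nGenes} genes, each with a
#' short CDS ending in a stop codon and a 3'UTR whose first \code{W}
#' nucleotides either embed a planted qualifying hairpin (a
#' \code{plantedFraction} of genes), a sub-span hairpin, or no structure
#' at all (unpairable A/C sequence). Both strands are represented and a
#' fixed proportion of genes carries a spliced (two-exon) 3'UTR. The truth
#' table records each gene's expected screen outcome.
#'
#' @param nGenes number of genes.
#' @param plantedFraction fraction of genes with a qualifying hairpin
#'   (rounded to a count).
#' @param W window width the fixtures are designed for.
#' @param seed RNG seed; output is a pure function of the arguments.
#' @param splicedFraction fraction of genes with a two-exon 3'UTR.
#' @param minusFraction fraction of genes on the minus strand.
#' @param dir optional output directory; when given, writes
#'   \code{genome.fa}, \code{annotation.gff3} and \code{truth.tsv}.
#' @return list with \code{genome} (named character vector of chromosome
#'   sequences), \code{transcripts} (list of [TranscriptModel]),
#'   \code{truth} (data.frame) and \code{files} (paths, when written).
#' @export
synthGenome <- function(nGenes = 20L, plantedFraction = 0.35, W = 60L,
                        seed = 1L, splicedFraction = 0.25,
                        minusFraction = 0.5, dir = NULL) {
    stopifnot(plantedFraction >= 0, plantedFraction <= 1)
    set.seed(seed)
    nGenes <- as.integer(nGenes)
    W <- as.integer(W)
    nPos <- as.integer(round(nGenes * plantedFraction))
    category <- rep("unstructured", nGenes)
    if (nPos) category[seq_len(nPos)] <- "qualifying"
    negIdx <- which(category == "unstructured")
    if (length(negIdx) > 1L)
        category[negIdx[seq_len(floor(length(negIdx) / 2))]] <- "subspan"
    category <- sample(category)

    chromParts <- character(0)
    offset <- 0L
    transcripts <- vector("list", nGenes)
    truth <- vector("list", nGenes)
    for (i in seq_len(nGenes)) {
        gid <- sprintf("sg%03d", i)
        tid <- paste0(gid, ".t1")
        stopDna <- sample(c("TAA", "TAG", "TGA"), 1L)
        cdsSeq <- paste0("ATG", .randomBases(24L, c("A", "C", "G", "T")),
                         stopDna)
        stem <- 0L; loop <- 0L; bulgeLen <- 0L
        if (category[i] == "qualifying") {
            stem <- sample(16:20, 1L)
            loop <- sample(3:10, 1L)
            bulgeLen <- sample(0:2, 1L)
            bulges <- if (bulgeLen)
                list(list(after = sample(seq_len(stem - 1L), 1L),
                          side = sample(c("5prime", "3prime"), 1L),
                          length = bulgeLen)) else list()
        } else if (category[i] == "subspan") {
            loop <- sample(3:10, 1L)
            stem <- sample(4:floor((34L - loop) / 2), 1L)
            bulges <- list()
        }
        if (category[i] == "unstructured") {
            window <- .randomBases(W)
            eStart <- NA_integer_; eEnd <- NA_integer_; span <- NA_integer_
        } else {
            span <- 2L * stem + loop + bulgeLen
            f5 <- sample(0:(W - span), 1L)
            ph <- plantHairpin(stem, loop, bulges, flank5 = f5,
                               flank3 = W - span - f5)
            window <- .toDNA(ph$sequence)
            eStart <- ph$elementStart; eEnd <- ph$elementEnd
        }
        utrSeq <- paste0(window, .randomBases(12L))
        spliced <- runif(1L) < splicedFraction
        strand <- if (runif(1L) < minusFraction) "-" else "+"

        if (spliced) {
            cut <- sample(10:(W - 10L), 1L)
            intron <- .randomBases(20L, c("A", "C", "G", "T"))
            fwd <- paste0(cdsSeq, substring(utrSeq, 1L, cut), intron,
                          substring(utrSeq, cut + 1L, nchar(utrSeq)))
            cdsLoc <- c(1L, nchar(cdsSeq))
            utrLoc <- rbind(
                c(nchar(cdsSeq) + 1L, nchar(cdsSeq) + cut),
                c(nchar(cdsSeq) + cut + 21L, nchar(fwd)))
        } else {
            fwd <- paste0(cdsSeq, utrSeq)
            cdsLoc <- c(1L, nchar(cdsSeq))
            utrLoc <- rbind(c(nchar(cdsSeq) + 1L, nchar(fwd)))
        }
        L <- nchar(fwd)
        block <- if (strand == "-")
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(fwd))) else fwd
        toGenomic <- function(lo, hi) {
            if (strand == "+") c(offset + lo, offset + hi)
            else c(offset + L - hi + 1L, offset + L - lo + 1L)
        }
        cdsG <- toGenomic(cdsLoc[1L], cdsLoc[2L])
        utrG <- t(apply(utrLoc, 1L, function(r) toGenomic(r[1L], r[2L])))
        transcripts[[i]] <- transcriptModel(
            gid, tid, "chrS", strand,
            cds = IRanges::IRanges(cdsG[1L], cdsG[2L]),
            utr3 = IRanges::IRanges(utrG[, 1L], utrG[, 2L]))
        chromParts <- c(chromParts, block,
                        .randomBases(25L, c("A", "C", "G", "T")))
        offset <- offset + L + 25L
        truth[[i]] <- data.frame(
            gene_id = gid, category = category[i],
            planted = category[i] == "qualifying",
            stem = stem, loop = loop, bulge = bulgeLen, span = span,
            element_start = if (is.na(eStart)) NA_integer_ else eStart + 3L,
            element_end = if (is.na(eEnd)) NA_integer_ else eEnd + 3L,
            strand = strand, spliced = spliced,
            stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    genome <- c(chrS = paste0(chromParts, collapse = ""))
    out <- list(genome = genome, transcripts = transcripts, truth = truth,
                files = NULL)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        fa <- file.path(dir, "genome.fa")
        gff <- file.path(dir, "annotation.gff3")
        tt <- file.path(dir, "truth.tsv")
        writeFastaRecords(genome, fa)
        .writeSynthGff3(transcripts, nchar(genome[["chrS"]]), gff)
        write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
        out$files <- c(genome = fa, annotation = gff, truth = tt)
    }
    out
}

# Ensembl-dialect GFF3 for a list of TranscriptModel.
.writeSynthGff3 <- function(transcripts, chromLen, path) {
    lines <- c("##gff-version 3",
               paste("##sequence-region chrS 1", chromLen))
    for (tx in transcripts) {
        lo <- min(IRanges::start(tx@cds), IRanges::start(tx@utr3))
        hi <- max(IRanges::end(tx@cds), IRanges::end(tx@utr3))
        f <- function(type, s, e, attrs)
            paste(tx@chrom, "synth", type, s, e, ".", tx@strand, ".",
                  attrs, sep = "\t")
        lines <- c(lines,
            f("gene", lo, hi, sprintf("ID=gene:%s;biotype=protein_coding",
                                      tx@geneId)),
            f("mRNA", lo, hi, sprintf(
                "ID=transcript:%s;Parent=gene:%s;biotype=protein_coding",
                tx@txId, tx@geneId)))
        cds <- tx@cds[order(IRanges::start(tx@cds))]
        for (k in seq_along(cds))
            lines <- c(lines, f("CDS", IRanges::start(cds)[k],
                                IRanges::end(cds)[k],
                                sprintf("ID=CDS:%s;Parent=transcript:%s",
                                        tx@txId, tx@txId)))
        utr <- tx@utr3[order(IRanges::start(tx@utr3))]
        for (k in seq_along(utr))
            lines <- c(lines, f("three_prime_UTR", IRanges::start(utr)[k],
                                IRanges::end(utr)[k],
                                sprintf("Parent=transcript:%s", tx@txId)))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Simulate a dual-luciferase plate table with known efficiencies
#'
#' Generates raw FLuc/RLuc counts whose background-corrected per-replicate
#' ratio carries multiplicative lognormal noise of the requested
#' coefficient of variation around the configured true ratio
#' (\code{efficiency / 100 * baseRatio}); the RLuc channel additionally
#' fluctuates with the same CV, as transfection efficiency does. With
#' \code{noiseCv = 0} the true efficiencies are recovered exactly.
#'
#' @param trueEfficiencies named numeric vector of true readthrough
#'   efficiencies in percent; include the sense-codon control at 100.
#' @param replicates replicates per construct.
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @param baseRatio corrected FLuc/RLuc ratio of a 100\%-readthrough
#'   construct (default 22, a typical sense-control level).
#' @param rlucLevel,flucBg,rlucBg instrument scale and constant
#'   backgrounds.
#' @return data.frame with columns \code{construct_id}, \code{replicate},
#'   \code{fluc}, \code{rluc}, \code{fluc_bg}, \code{rluc_bg}.
#' @export
synthLuminescence <- function(trueEfficiencies, replicates = 3L,
                              noiseCv = 0.1, seed = 1L, baseRatio = 22,
                              rlucLevel = 6e4, flucBg = 500, rlucBg = 1000) {
    stopifnot(noiseCv >= 0, !is.null(names(trueEfficiencies)))
    set.seed(seed)
    sdlog <- sqrt(log1p(noiseCv^2))
    noise <- function(n) if (noiseCv == 0) rep(1, n) else
        rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    rows <- lapply(names(trueEfficiencies), function(id) {
        ratio <- trueEfficiencies[[id]] / 100 * baseRatio
        rl <- rlucLevel * noise(replicates)
        fl <- ratio * rl * noise(replicates)
        data.frame(construct_id = id, replicate = seq_len(replicates),
                   fluc = flucBg + fl, rluc = rlucBg + rl,
                   fluc_bg = flucBg, rluc_bg = rlucBg,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
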