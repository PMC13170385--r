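#' @importFrom Biostrings readBStringSet DNAStringSet writeXStringSet
#'   reverseComplement subseq
#' @importFrom IRanges IRanges start end width
#' @importFrom utils write.table read.delim
NULL

#' Construct a TranscriptModel
#'
#' @param geneId,txId,chrom,strand identifiers, chromosome and strand.
#' @param cds,utr3 [IRanges::IRanges] of 1-based inclusive genomic
#'   segments (GFF3 convention); any order, stored in transcript order.
#' @param biotype annotation biotype.
#' @return a [TranscriptModel].
#' @export
transcriptModel <- function(geneId, txId, chrom, strand, cds,
                            utr3 = IRanges::IRanges(), biotype = "protein_coding") {
    decreasing <- identical(strand, "-")
    cds <- cds[order(IRanges::start(cds), decreasing = decreasing)]
    utr3 <- utr3[order(IRanges::start(utr3), decreasing = decreasing)]
    new("TranscriptModel", geneId = geneId, txId = txId, chrom = chrom,
        strand = strand, cds = cds, utr3 = utr3, biotype = biotype)
}

#' Read a FASTA file with validation and softmask flags
#'
#' Wraps [Biostrings::readBStringSet()] with the checks the screen relies
#' on: non-empty input, unique identifiers, a legal A/C/G/T/U/N alphabet
#' (U is converted to T for storage), and no whitespace inside residues.
#' Softmasked (lowercase) positions are stored uppercase with a per-record
#' logical mask kept in \code{metadata(x)$softmask}.
#'
#' @param path FASTA file (plain or gzip).
#' @return a [Biostrings::DNAStringSet] named by the full header lines,
#'   with \code{metadata(x)$softmask} a list of logical vectors.
#' @export
readFastaRecords <- function(path) {
    raw <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("no records in '", path, "'"))
    if (!length(raw)) stop("no records in '", path, "'")
    ids <- names(raw)
    if (any(!nzchar(ids))) stop("empty record identifier in '", path, "'")
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate identifier '", dup[1L], "' in '", path, "'")
    txt <- as.character(raw)
    softmask <- vector("list", length(txt))
    names(softmask) <- ids
    for (k in seq_along(txt)) {
        ch <- .splitChars(txt[k])
        bad <- which(!ch %in% c("A", "C", "G", "T", "U", "N",
                                "a", "c", "g", "t", "u", "n"))
        if (length(bad))
            stop("illegal character '", ch[bad[1L]], "' at position ",
                 bad[1L], " in record '", ids[k], "'")
        softmask[[k]] <- ch %in% c("a", "c", "g", "t", "u", "n")
    }
    out <- Biostrings::DNAStringSet(.toDNA(txt))
    names(out) <- ids
    S4Vectors::metadata(out)$softmask <- softmask
    out
}

#' Write sequences as FASTA
#'
#' Thin wrapper over [Biostrings::writeXStringSet()] so that
#' \code{readFastaRecords(writeFastaRecords(x))} round-trips.
#'
#' @param x a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @export
writeFastaRecords <- function(x, path) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(.toDNA(x))
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read transcript models from an Ensembl-dialect GFF3
#'
#' Builds one [TranscriptModel] per protein-coding mRNA carrying at least
#' one CDS segment. Transcripts lacking \code{three_prime_UTR} features are
#' returned with empty 3'UTR segments. Feature score and phase are ignored.
#' CDS or UTR features whose Parent does not resolve to an mRNA are skipped
#' with a warning; an unknown strand symbol on an mRNA is an error.
#'
#' @param path GFF3 file with gene/mRNA/CDS/three_prime_UTR features and
#'   ID/Parent attributes (Ensembl \code{gene:}/\code{transcript:} prefixes
#'   are stripped).
#' @return named list of [TranscriptModel] (names = transcript ids).
#' @export
readGffTranscripts <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    isTx <- type %in% c("mRNA", "transcript")
    tx <- gr[isTx]
    txId <- .normalizeFeatureId(tx$ID)
    if (anyNA(txId) || any(!nzchar(txId)))
        stop("mRNA feature without ID attribute")
    txParent <- .normalizeFeatureId(vapply(tx$Parent, function(p)
        if (length(p)) p[[1L]] else NA_character_, character(1)))
    txStrand <- as.character(BiocGenerics::strand(tx))
    if (any(!txStrand %in% c("+", "-")))
        stop("unknown strand symbol '", setdiff(txStrand, c("+", "-"))[1L],
             "' on transcript '", txId[which(!txStrand %in% c("+", "-"))[1L]],
             "'")
    txBiotype <- if (!is.null(tx$biotype)) tx$biotype else
        rep(NA_character_, length(tx))

    childOf <- function(what) {
        sub <- gr[type == what]
        par <- .normalizeFeatureId(vapply(sub$Parent, function(p)
            if (length(p)) p[[1L]] else NA_character_, character(1)))
        orphan <- is.na(par) | !par %in% txId
        if (any(orphan)) {
            warning(sum(orphan), " ", what,
                    " feature(s) with no resolvable parent mRNA skipped")
            sub <- sub[!orphan]; par <- par[!orphan]
        }
        split(IRanges::IRanges(BiocGenerics::start(sub),
                               BiocGenerics::end(sub)), par)
    }
    cdsBy <- childOf("CDS")
    utrBy <- childOf("three_prime_UTR")

    keep <- txId %in% names(cdsBy)
    models <- vector("list", sum(keep))
    idx <- which(keep)
    for (k in seq_along(idx)) {
        i <- idx[k]
        id <- txId[i]
        utr <- if (id %in% names(utrBy)) utrBy[[id]] else IRanges::IRanges()
        gene <- txParent[i]
        if (is.na(gene)) gene <- id
        models[[k]] <- transcriptModel(
            geneId = gene, txId = id,
            chrom = as.character(GenomeInfoDb::seqnames(tx))[i],
            strand = txStrand[i], cds = cdsBy[[id]], utr3 = utr,
            biotype = if (is.na(txBiotype[i])) "protein_coding"
                      else txBiotype[i])
    }
    names(models) <- txId[keep]
    models
}

#' Read an RNAfold-style structure file
#'
#' Parses the RNAfold text dialect: a header line, the sequence, then the
#' dot-bracket line with an optional trailing parenthesized free energy
#' (internal padding spaces tolerated, e.g. \code{"( -1.20)"}). Entries
#' with unbalanced brackets are rejected individually with a warning and
#' the remaining entries kept; a length mismatch between sequence and
#' structure is an error naming the entry.
#'
#' @param path structure file path.
#' @return named list of [SecondaryStructure] with
#'   \code{backend = "external"}.
#' @export
readRnafoldFile <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no records in '", path, "'")
    out <- list()
    for (h in seq_along(hdr)) {
        at <- hdr[h]
        stopAt <- if (h < length(hdr)) hdr[h + 1L] - 1L else length(lines)
        if (stopAt < at + 2L) {
            warning("incomplete entry '", lines[at], "' skipped")
            next
        }
        id <- sub("^>\\s*", "", lines[at])
        sq <- gsub("\\s", "", lines[at + 1L])
        st <- lines[at + 2L]
        m <- regmatches(st, regexec(
            "^([().]+)\\s*(\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\))?\\s*$", st))[[1L]]
        if (!length(m)) {
            warning("malformed structure line for entry '", id, "', skipped")
            next
        }
        db <- m[2L]
        mfe <- if (nzchar(m[4L])) as.numeric(m[4L]) else numeric(0)
        # unbalanced brackets reject the entry only; a length mismatch on
        # a well-formed structure is a malformed file and an error
        balanced <- tryCatch({ pairsFromDotBracket(db); TRUE },
                             error = function(e) FALSE)
        if (!balanced) {
            warning("entry '", id, "' rejected: unbalanced brackets")
            next
        }
        if (nchar(db) != nchar(sq))
            stop("entry '", id, "': structure length ", nchar(db),
                 " does not match sequence length ", nchar(sq))
        out[[id]] <- secondaryStructure(sq, db, mfe = mfe)
    }
    out
}

#' Write structures in the RNAfold text dialect
#'
#' Emits exactly the format [readRnafoldFile()] accepts: header, sequence,
#' then \code{"dotbracket ( mfe)"} (the energy field omitted when absent).
#'
#' @param structures named list of [SecondaryStructure].
#' @param path output path.
#' @export
writeRnafoldFile <- function(structures, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (id in names(structures)) {
        s <- structures[[id]]
        tail <- if (length(s@mfe))
            sprintf("%s (%6.2f)", s@dotbracket, s@mfe) else s@dotbracket
        writeLines(c(paste0(">", id), s@sequence, tail), con)
    }
    invisible(path)
}

#' Write screen results as a deterministic TSV
#'
#' Fixed header, rows sorted by gene id (locale-independent), element
#' coordinates in the +1-at-stop convention. Identical inputs give
#' byte-identical files.
#'
#' @param calls data.frame as returned by [runStemloopScreen()].
#' @param path output path.
#' @export
writeScreenTable <- function(calls, path) {
    cols <- c("gene_id", "window_length", "truncated", "passed",
              "failure_reasons", "element_start", "element_end", "backend")
    missing <- setdiff(cols, names(calls))
    if (length(missing))
        stop("calls table lacks column(s): ", paste(missing, collapse = ", "))
    calls <- calls[.lexOrder(calls$gene_id), cols, drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", eol = "\n")
    invisible(path)
}
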