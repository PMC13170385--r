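# Selection of each gene's most-upstream 3'UTR and extraction of the
# stop codon plus the first W nucleotides downstream, in the +1-at-stop
# coordinate convention (+1 = first base of the stop codon, so the window
# occupies +4 ... +(3+W)).

# Genomic coordinate of the stop codon's 3' end in gene orientation;
# smaller-is-more-upstream on +, larger-is-more-upstream on -.
.stopPosition <- function(tx) {
    if (tx@strand == "+") max(IRanges::end(tx@cds))
    else min(IRanges::start(tx@cds))
}

#' Select the transcript carrying a gene's most-upstream 3'UTR
#'
#' Among a gene's transcripts, returns the one whose stop codon lies most
#' 5' in gene orientation (equivalently whose 3'UTR starts most upstream of
#' the gene). Ties are broken by longer annotated 3'UTR, then by
#' lexicographic transcript id. Transcripts without 3'UTR segments are not
#' eligible; if none has one, a warning of class
#' \code{stemloopscreen_gene_skipped} is signalled and NULL returned.
#'
#' @param transcripts list of [TranscriptModel] for one gene.
#' @return a [TranscriptModel] or NULL.
#' @export
selectPrimaryUtr <- function(transcripts) {
    if (!length(transcripts)) stop("no transcripts supplied")
    has <- vapply(transcripts, function(tx) length(tx@utr3) > 0L, logical(1))
    if (!any(has)) {
        warning(structure(class = c("stemloopscreen_gene_skipped",
                                    "warning", "condition"),
                          list(message = paste0(
                              "gene '", transcripts[[1L]]@geneId,
                              "' skipped: no transcript with a 3'UTR"),
                              call = NULL)))
        return(NULL)
    }
    cand <- transcripts[has]
    stops <- vapply(cand, .stopPosition, numeric(1))
    minus <- cand[[1L]]@strand == "-"
    key <- if (minus) -stops else stops
    utrLen <- vapply(cand, function(tx) sum(IRanges::width(tx@utr3)),
                     numeric(1))
    ids <- vapply(cand, function(tx) tx@txId, character(1))
    cand[[order(key, -utrLen, ids, method = "radix")[1L]]]
}

# Spliced sequence of segments in transcript order; segs already stored in
# transcript order (descending starts on -). Returns uppercase DNA text.
.splicedSequence <- function(chromSeq, segs, strand) {
    if (!length(segs)) return("")
    parts <- as.character(Biostrings::subseq(
        rep(Biostrings::DNAStringSet(chromSeq), length(segs)),
        start = IRanges::start(segs), end = IRanges::end(segs)))
    if (strand == "-")
        parts <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(parts)))
    paste0(parts, collapse = "")
}

# Genomic coordinate of each spliced-transcript position, transcript order.
.splicedPositions <- function(segs, strand) {
    pos <- unlist(lapply(seq_along(segs), function(k) {
        p <- IRanges::start(segs)[k]:IRanges::end(segs)[k]
        if (strand == "-") rev(p) else p
    }))
    if (is.null(pos)) integer(0) else as.integer(pos)
}

#' Extract a stop-codon context from genome and transcript model
#'
#' Takes the last three CDS nucleotides in transcript orientation as the
#' stop codon (Ensembl convention: the CDS includes the stop) and the first
#' \code{W} nucleotides of the spliced 3'UTR as the window, reverse-
#' complemented for minus-strand genes and converted to the RNA alphabet.
#' Genes whose annotated UTR is shorter than \code{W} yield a shorter
#' window flagged truncated.
#'
#' @param genome named [Biostrings::DNAStringSet] (or named character
#'   vector) covering the transcript's chromosome.
#' @param tx a [TranscriptModel] with non-empty 3'UTR segments.
#' @param W requested window width in nt (60 or 80 in the screen).
#' @param strict when TRUE (default) a transcript whose last CDS triplet is
#'   not a stop codon is skipped with a warning and NULL returned;
#'   permissive mode keeps it.
#' @return a [StopContext] or NULL (strict-mode skip).
#' @examples
#' genome <- c(chr1 = paste0(strrep("A", 9), "ATGAAATAG",
#'                           strrep("C", 30), strrep("A", 30)))
#' tx <- transcriptModel("g1", "t1", "chr1", "+",
#'                       IRanges::IRanges(10, 18),
#'                       IRanges::IRanges(19, 78))
#' extractStopContext(genome, tx, W = 60)
#' @export
extractStopContext <- function(genome, tx, W = 60L, strict = TRUE) {
    W <- as.integer(W)
    if (!length(tx@utr3)) stop("transcript '", tx@txId, "' has no 3'UTR")
    if (!tx@chrom %in% names(genome))
        stop("genome does not cover chromosome '", tx@chrom, "'")
    chromSeq <- as.character(genome[[tx@chrom]])
    if (sum(IRanges::width(tx@cds)) < 3L)
        stop("transcript '", tx@txId, "' has CDS shorter than 3 nt")
    cdsSeq <- .splicedSequence(chromSeq, tx@cds, tx@strand)
    stopCodon <- .toRNA(substring(cdsSeq, nchar(cdsSeq) - 2L, nchar(cdsSeq)))
    if (!stopCodon %in% .STOP_CODONS && strict) {
        warning(structure(class = c("stemloopscreen_gene_skipped",
                                    "warning", "condition"),
                          list(message = paste0(
                              "gene '", tx@geneId, "' skipped: CDS ends in '",
                              stopCodon, "', not a stop triplet"),
                              call = NULL)))
        return(NULL)
    }
    utrSeq <- .splicedSequence(chromSeq, tx@utr3, tx@strand)
    utrPos <- .splicedPositions(tx@utr3, tx@strand)
    len <- min(W, nchar(utrSeq))
    window <- .toRNA(substring(utrSeq, 1L, len))
    new("StopContext", geneId = tx@geneId, txId = tx@txId,
        stopCodon = stopCodon, window = window, windowRequested = W,
        truncated = nchar(utrSeq) < W, strand = tx@strand,
        paperPos = if (len) 3L + seq_len(len) else integer(0),
        genomicPos = utrPos[seq_len(len)])
}

#' The offset map of a stop context
#'
#' @param ctx a [StopContext].
#' @return data.frame with columns \code{window_index}, \code{paper_pos}
#'   (+4, +5, ...) and \code{genomic_pos}.
#' @export
offsetMap <- function(ctx) {
    n <- nchar(ctx@window)
    data.frame(window_index = seq_len(n), paper_pos = ctx@paperPos,
               genomic_pos = ctx@genomicPos)
}

#' The SCR motif context: stop codon plus positions +4 to +9
#'
#' The hexamer immediately downstream of the stop codon (+4..+9) is the
#' readthrough-permissive sequence context; together with the stop triplet
#' it forms the SCR motif.
#'
#' @param ctx a [StopContext] with a window of at least 6 nt.
#' @return list with \code{stopCodon} and \code{plus4to9}.
#' @export
scrMotifContext <- function(ctx) {
    if (nchar(ctx@window) < 6L)
        stop("context too short: window has ", nchar(ctx@window),
             " nt, need 6")
    list(stopCodon = ctx@stopCodon, plus4to9 = substring(ctx@window, 1L, 6L))
}
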