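# Genome-wide orchestration: per gene, select the primary 3'UTR, extract
# the stop-codon window, fold (or look up an ingested structure) and
# classify; plus the gene-set overlap bookkeeping.

#' Run the genome-wide stem-loop screen
#'
#' For every gene: select the transcript with the most-upstream 3'UTR,
#' extract the stop codon plus first-\code{W}-nt window, obtain a secondary
#' structure (internal maximum-base-pairing folder, or an ingested
#' RNAfold-style structure matched by gene id), and classify it against the
#' criteria. Skipped genes are recorded with reasons; the screen never
#' folds internally when a structure file is supplied.
#'
#' @param genome named [Biostrings::DNAStringSet] or named character
#'   vector of chromosome sequences.
#' @param transcripts list of [TranscriptModel] (any order; grouped by
#'   gene id internally).
#' @param W window width in nt (60 or 80).
#' @param criteria a [HairpinCriteria].
#' @param backend \code{"maxpair"} (fold internally) or \code{"ingest"}
#'   (use \code{structures}).
#' @param structures named list of [SecondaryStructure] (from
#'   [readRnafoldFile()]) for ingest mode; matched to genes by identifier
#'   equality after whitespace truncation of the structure header.
#' @param scoring [PairScoring] for the maxpair backend.
#' @param strict passed to [extractStopContext()].
#' @return data.frame with one row per screened gene: \code{gene_id},
#'   \code{transcript_id}, \code{window_length}, \code{truncated},
#'   \code{passed}, \code{failure_reasons} (comma-joined),
#'   \code{element_start}/\code{element_end} (+1-at-stop coordinates, NA
#'   when failing), \code{mfe}, \code{backend}. Attributes:
#'   \code{skipped} (data.frame gene_id/reason) and \code{summary}
#'   (named counts).
#' @export
runStemloopScreen <- function(genome, transcripts, W = 60L,
                              criteria = hairpinCriteria(),
                              backend = c("maxpair", "ingest"),
                              structures = NULL,
                              scoring = pairScoring(), strict = TRUE) {
    backend <- match.arg(backend)
    if (backend == "ingest") {
        if (is.null(structures)) stop("ingest mode requires structures")
        names(structures) <- sub("\\s.*$", "", names(structures))
    }
    geneIds <- vapply(transcripts, function(tx) tx@geneId, character(1))
    byGene <- split(transcripts, geneIds)
    rows <- vector("list", length(byGene))
    skipped <- list()
    nWindows <- 0L
    for (g in names(byGene)) {
        tx <- withCallingHandlers(
            selectPrimaryUtr(byGene[[g]]),
            stemloopscreen_gene_skipped = function(w)
                invokeRestart("muffleWarning"))
        if (is.null(tx)) {
            skipped[[length(skipped) + 1L]] <-
                data.frame(gene_id = g, reason = "no_utr3")
            next
        }
        ctx <- tryCatch(
            withCallingHandlers(
                extractStopContext(genome, tx, W = W, strict = strict),
                stemloopscreen_gene_skipped = function(w)
                    invokeRestart("muffleWarning")),
            error = function(e) {
                skipped[[length(skipped) + 1L]] <<-
                    data.frame(gene_id = g, reason = "extraction_error")
                NULL
            })
        if (is.null(ctx)) {
            if (!length(skipped) ||
                skipped[[length(skipped)]]$gene_id != g)
                skipped[[length(skipped) + 1L]] <-
                    data.frame(gene_id = g, reason = "not_a_stop")
            next
        }
        nWindows <- nWindows + 1L
        if (backend == "ingest") {
            s <- structures[[g]]
            if (is.null(s)) {
                skipped[[length(skipped) + 1L]] <-
                    data.frame(gene_id = g, reason = "missing_structure")
                next
            }
        } else {
            s <- foldMaxPair(ctx@window, scoring)
        }
        call <- classifyStructure(s, criteria)
        rows[[g]] <- data.frame(
            gene_id = g, transcript_id = tx@txId,
            window_length = nchar(ctx@window), truncated = ctx@truncated,
            passed = call@passed,
            failure_reasons = paste(call@failureReasons, collapse = ","),
            element_start = if (call@passed)
                call@element@outerStart + 3L else NA_integer_,
            element_end = if (call@passed)
                call@element@outerEnd + 3L else NA_integer_,
            mfe = if (length(s@mfe)) s@mfe else NA_real_,
            backend = s@backend,
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(res))
        res <- data.frame(gene_id = character(0),
                          transcript_id = character(0),
                          window_length = integer(0), truncated = logical(0),
                          passed = logical(0), failure_reasons = character(0),
                          element_start = integer(0),
                          element_end = integer(0), mfe = numeric(0),
                          backend = character(0))
    res <- res[.lexOrder(res$gene_id), , drop = FALSE]
    rownames(res) <- NULL
    skipped <- if (length(skipped)) do.call(rbind, skipped) else
        data.frame(gene_id = character(0), reason = character(0))
    attr(res, "skipped") <- skipped
    attr(res, "summary") <- c(genes = length(byGene),
                              windows_extracted = nWindows,
                              structures_classified = nrow(res),
                              passes = sum(res$passed),
                              skipped = nrow(skipped))
    res
}

#' Three-set gene overlap analysis
#'
#' Computes all seven Venn regions for stem-loop, ribo-seq-evidence and
#' conserved-ORF gene sets plus the evidence intersection
#' \code{|stemloop intersect (riboseq union conserved)|}, i.e. the
#' stem-loop genes supported by at least one line of SCR evidence. Gene
#' identifiers are version-stripped before set algebra; duplicates within
#' a set are removed with a warning.
#'
#' @param stemloop,riboseq,conserved character vectors of gene ids.
#' @return list with \code{sizes}, \code{regions} (7 exclusive region
#'   counts), \code{pairwise}, \code{triple} and \code{evidence} counts,
#'   and \code{evidenceGenes} (the reconstructible evidence set).
#' @examples
#' overlapGeneSets(c("A", "B", "C"), c("B", "C", "D"), c("C", "E"))
#' @export
overlapGeneSets <- function(stemloop, riboseq, conserved) {
    clean <- function(x, nm) {
        x <- .normalizeGeneId(as.character(x))
        if (anyDuplicated(x)) {
            warning("duplicate ids in ", nm, " set deduplicated")
            x <- unique(x)
        }
        x
    }
    sl <- clean(stemloop, "stemloop")
    rs <- clean(riboseq, "riboseq")
    co <- clean(conserved, "conserved")
    evidenceGenes <- sort(intersect(sl, union(rs, co)))
    regions <- c(
        stemloop_only = length(setdiff(sl, union(rs, co))),
        riboseq_only = length(setdiff(rs, union(sl, co))),
        conserved_only = length(setdiff(co, union(sl, rs))),
        stemloop_riboseq = length(setdiff(intersect(sl, rs), co)),
        stemloop_conserved = length(setdiff(intersect(sl, co), rs)),
        riboseq_conserved = length(setdiff(intersect(rs, co), sl)),
        all_three = length(intersect(intersect(sl, rs), co)))
    list(
        sizes = c(stemloop = length(sl), riboseq = length(rs),
                  conserved = length(co)),
        regions = regions,
        pairwise = c(stemloop_riboseq = length(intersect(sl, rs)),
                     stemloop_conserved = length(intersect(sl, co)),
                     riboseq_conserved = length(intersect(rs, co))),
        triple = length(intersect(intersect(sl, rs), co)),
        evidence = length(evidenceGenes),
        evidenceGenes = evidenceGenes)
}

#' Combine the W = 60 and W = 80 screen runs
#'
#' Unions the evidence-supported stem-loop gene sets of the two window
#' widths, derives the novelty set (union minus a prior structure-
#' prediction list) and lists genes passing at one width only (alternative
#' structures at the longer window can displace a qualifying hairpin).
#'
#' @param evidence60,evidence80 character vectors: evidence-supported
#'   stem-loop genes of each run (e.g. \code{evidenceGenes} from
#'   [overlapGeneSets()]).
#' @param prior character vector of genes with previously predicted 3'UTR
#'   structures.
#' @return list with \code{union}, \code{novel}, \code{only60},
#'   \code{only80} (sorted gene vectors) and \code{counts}.
#' @export
combineWindowRuns <- function(evidence60, evidence80, prior = character(0)) {
    e60 <- unique(.normalizeGeneId(evidence60))
    e80 <- unique(.normalizeGeneId(evidence80))
    prior <- unique(.normalizeGeneId(prior))
    u <- sort(union(e60, e80))
    novel <- sort(setdiff(u, prior))
    only60 <- sort(setdiff(e60, e80))
    only80 <- sort(setdiff(e80, e60))
    list(union = u, novel = novel, only60 = only60, only80 = only80,
         counts = c(union = length(u), novel = length(novel),
                    only60 = length(only60), only80 = length(only80)))
}
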