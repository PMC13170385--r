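# Accessors and show methods; slots are not part of the API.

#' Accessors for SecondaryStructure
#'
#' @param x a [SecondaryStructure].
#' @return \code{dotBracket}: the dot-bracket string; \code{pairTable}:
#'   the partner vector; \code{mfe}: the energy/score (NA when absent);
#'   \code{structureSequence}: the RNA sequence.
#' @export
dotBracket <- function(x) x@dotbracket

#' @rdname dotBracket
#' @export
pairTable <- function(x) x@pairTable

#' @rdname dotBracket
#' @export
mfe <- function(x) if (length(x@mfe)) x@mfe else NA_real_

#' @rdname dotBracket
#' @export
structureSequence <- function(x) x@sequence

#' Accessors for StopContext and TranscriptModel
#'
#' @param x a [StopContext] or [TranscriptModel].
#' @return \code{geneId}: gene identifier; \code{stopCodon}: the stop
#'   triplet; \code{windowSequence}: the downstream window (RNA);
#'   \code{isTruncated}: whether the annotated UTR was shorter than
#'   requested.
#' @export
geneId <- function(x) x@geneId

#' @rdname geneId
#' @export
stopCodon <- function(x) x@stopCodon

#' @rdname geneId
#' @export
windowSequence <- function(x) x@window

#' @rdname geneId
#' @export
isTruncated <- function(x) x@truncated

#' Accessors for HairpinCall and VariantDesign
#'
#' @param x a [HairpinCall] or [VariantDesign].
#' @return \code{isStemLoop}: logical pass flag; \code{bestElement}: the
#'   best passing [HairpinElement] or NULL; \code{failureReasons}:
#'   character vector; \code{variantSequence}: the edited sequence;
#'   \code{stabilityDelta}: score change (positive = destabilized);
#'   \code{substitutions}: the substitution table.
#' @export
isStemLoop <- function(x) x@passed

#' @rdname isStemLoop
#' @export
bestElement <- function(x) x@element

#' @rdname isStemLoop
#' @export
failureReasons <- function(x) x@failureReasons

#' @rdname isStemLoop
#' @export
variantSequence <- function(x) x@sequence

#' @rdname isStemLoop
#' @export
stabilityDelta <- function(x) x@stabilityDelta

#' @rdname isStemLoop
#' @export
substitutions <- function(x) x@substitutions

setMethod("show", "SecondaryStructure", function(object) {
    cat("SecondaryStructure (", object@backend, ") of length ",
        nchar(object@sequence), "\n", sep = "")
    cat(" ", object@sequence, "\n ", object@dotbracket, "\n", sep = "")
    if (length(object@mfe))
        cat("  score: ", sprintf("%.2f", object@mfe), "\n", sep = "")
})

setMethod("show", "TranscriptModel", function(object) {
    cat("TranscriptModel ", object@txId, " (gene ", object@geneId, ") ",
        object@chrom, object@strand, "\n", sep = "")
    cat("  CDS segments: ", length(object@cds), "; 3'UTR segments: ",
        length(object@utr3), " (", sum(IRanges::width(object@utr3)),
        " nt)\n", sep = "")
})

setMethod("show", "StopContext", function(object) {
    cat("StopContext ", object@geneId, ": stop ", object@stopCodon,
        ", window ", nchar(object@window), "/", object@windowRequested,
        " nt (+4..+", 3L + nchar(object@window), ")",
        if (object@truncated) " [truncated]", "\n", sep = "")
    cat("  ", object@window, "\n", sep = "")
})

setMethod("show", "HairpinElement", function(object) {
    cat("HairpinElement span ", elementSpan(object), " [",
        object@outerStart, "..", object@outerEnd, "], helix ",
        nrow(object@helixPairs), " bp, loop ", loopLength(object),
        " nt, ", nrow(object@bulges), " bulge run(s)\n", sep = "")
})

setMethod("show", "HairpinCall", function(object) {
    if (object@passed) {
        cat("HairpinCall: stem-loop (span ", elementSpan(object@element),
            ")\n", sep = "")
    } else {
        cat("HairpinCall: not a stem-loop [",
            paste(object@failureReasons, collapse = ", "), "]\n", sep = "")
    }
})

setMethod("show", "VariantDesign", function(object) {
    cat("VariantDesign ", object@variantClass, ": ",
        nrow(object@substitutions), " substitution(s), stability delta ",
        sprintf("%+.2f", object@stabilityDelta), "\n", sep = "")
})

setMethod("show", "HairpinCriteria", function(object) {
    cat("HairpinCriteria: span >= ", object@minSpan, ", loop ",
        object@loopMin, "..", object@loopMax, ", bulge <= ",
        object@bulgeMax, " (", object@bulgeMode, ")\n", sep = "")
})
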