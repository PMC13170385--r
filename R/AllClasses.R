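#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom IRanges IRanges
#' @importFrom IRanges IRanges start end width
#' @importFrom stats setNames
NULL

.RNA_BASES <- c("A", "C", "G", "U")
.STOP_CODONS <- c("UAA", "UAG", "UGA")

#' TranscriptModel: one transcript with CDS and 3'UTR segments
#'
#' A minimal transcript model carrying the genomic anatomy the stem-loop
#' screen needs: strand, CDS segments and 3'UTR segments as 1-based
#' inclusive [IRanges::IRanges] on a named chromosome. Segments are stored
#' in transcript (5' to 3') order: ascending genomic coordinates on the
#' \code{+} strand, descending on \code{-}.
#'
#' @slot geneId gene identifier (Ensembl-style prefixes already stripped).
#' @slot txId transcript identifier.
#' @slot chrom chromosome / scaffold name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot cds CDS segments; under the Ensembl convention the CDS includes
#'   the stop codon.
#' @slot utr3 3'UTR segments; may be empty when the annotation lacks a
#'   \code{three_prime_UTR} feature.
#' @slot biotype annotation biotype (e.g. \code{"protein_coding"}), kept so
#'   callers can filter isoform classes.
#'
#' @export
setClass("TranscriptModel",
    slots = c(
        geneId = "character",
        txId = "character",
        chrom = "character",
        strand = "character",
        cds = "IRanges",
        utr3 = "IRanges",
        biotype = "character"
    )
)

setValidity("TranscriptModel", function(object) {
    msg <- character(0)
    if (length(object@geneId) != 1L || !nzchar(object@geneId))
        msg <- c(msg, "geneId must be a single non-empty string")
    if (length(object@txId) != 1L || !nzchar(object@txId))
        msg <- c(msg, "txId must be a single non-empty string")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    for (nm in c("cds", "utr3")) {
        seg <- slot(object, nm)
        if (length(seg) > 1L) {
            s <- seg[order(IRanges::start(seg))]
            if (any(IRanges::start(s)[-1L] <= IRanges::end(s)[-length(s)]))
                msg <- c(msg, paste0(nm, " segments overlap"))
        }
    }
    if (length(object@cds) && length(object@utr3)) {
        if (object@strand == "+" &&
            min(IRanges::start(object@utr3)) <= max(IRanges::end(object@cds)))
            msg <- c(msg, "on + strand the 3'UTR must start after the CDS end")
        if (object@strand == "-" &&
            max(IRanges::end(object@utr3)) >= min(IRanges::start(object@cds)))
            msg <- c(msg, "on - strand the 3'UTR must end before the CDS start")
    }
    if (length(msg)) msg else TRUE
})

#' StopContext: a stop codon plus the first W nucleotides of the 3'UTR
#'
#' One gene's stop codon together with the window of mRNA-level (spliced)
#' 3'UTR sequence immediately downstream, in the +1-at-stop coordinate
#' convention: position +1 is the first base of the stop codon, so window
#' position 1 is paper coordinate +4.
#'
#' @slot geneId,txId identifiers.
#' @slot stopCodon 3-letter RNA stop triplet (\code{UAA}/\code{UAG}/\code{UGA};
#'   other triplets only in permissive mode).
#' @slot window RNA window sequence, length at most \code{windowRequested}.
#' @slot windowRequested the requested window width W (60 or 80 typically).
#' @slot truncated TRUE when the annotated 3'UTR is shorter than W.
#' @slot strand source strand.
#' @slot paperPos integer vector, paper coordinate (+4, +5, ...) of each
#'   window position.
#' @slot genomicPos integer vector, genomic coordinate of each window
#'   position (NA where not genome-derived, e.g. after an insertion edit).
#'
#' @export
setClass("StopContext",
    slots = c(
        geneId = "character",
        txId = "character",
        stopCodon = "character",
        window = "character",
        windowRequested = "integer",
        truncated = "logical",
        strand = "character",
        paperPos = "integer",
        genomicPos = "integer"
    )
)

setValidity("StopContext", function(object) {
    msg <- character(0)
    n <- nchar(object@window)
    if (nchar(object@stopCodon) != 3L)
        msg <- c(msg, "stopCodon must be a triplet")
    if (n > object@windowRequested)
        msg <- c(msg, "window longer than requested width")
    if (length(object@paperPos) != n || (n > 0L && object@paperPos[1L] != 4L))
        msg <- c(msg, "paperPos must map window position 1 to +4")
    if (n > 1L && !all(diff(object@paperPos) == 1L))
        msg <- c(msg, "paperPos must be consecutive")
    if (length(object@genomicPos) != n)
        msg <- c(msg, "genomicPos must have one entry per window position")
    if (length(msg)) msg else TRUE
})

#' PairScoring: weights for the maximum-base-pairing folder
#'
#' Pair-class weights used by [foldMaxPair()]. Defaults (GC = 3, AU = 2,
#' GU = 1) rank helices qualitatively like thermodynamic stability: a
#' GC pair contributes three hydrogen bonds, AU two, and the GU wobble is
#' weakest. \code{minLoop} is the minimum number of unpaired bases a
#' hairpin loop must contain (3, the steric minimum).
#'
#' @slot GC,AU,GU positive pair weights.
#' @slot minLoop non-negative integer.
#' @export
setClass("PairScoring",
    slots = c(GC = "numeric", AU = "numeric", GU = "numeric",
              minLoop = "integer")
)

setValidity("PairScoring", function(object) {
    if (any(c(object@GC, object@AU, object@GU) <= 0))
        return("pair weights must be > 0")
    if (object@minLoop < 0L)
        return("minLoop must be >= 0")
    TRUE
})

#' SecondaryStructure: sequence, dot-bracket, pair table and optional MFE
#'
#' A nested (pseudoknot-free) RNA secondary structure. The pair table is an
#' integer vector with \code{pairTable[i] == j} when i pairs j (1-based,
#' symmetric) and NA for unpaired positions.
#'
#' @slot sequence RNA sequence (uppercase, U not T).
#' @slot dotbracket dot-bracket string of equal length.
#' @slot pairTable symmetric partner vector, NA = unpaired.
#' @slot mfe minimum free energy in kcal/mol if known (numeric(0) when
#'   absent). For the internal folder this is minus the total pair weight,
#'   so "lower = more stable" holds for both backends.
#' @slot backend \code{"external"} (ingested, e.g. RNAfold output) or
#'   \code{"maxpair"} (internal folder).
#' @export
setClass("SecondaryStructure",
    slots = c(
        sequence = "character",
        dotbracket = "character",
        pairTable = "integer",
        mfe = "numeric",
        backend = "character"
    )
)

setValidity("SecondaryStructure", function(object) {
    msg <- character(0)
    n <- nchar(object@sequence)
    if (nchar(object@dotbracket) != n)
        msg <- c(msg, "sequence and dotbracket lengths differ")
    if (length(object@pairTable) != n)
        msg <- c(msg, "pairTable length must equal sequence length")
    pt <- object@pairTable
    paired <- which(!is.na(pt))
    if (length(paired) && !all(pt[pt[paired]] == paired))
        msg <- c(msg, "pairTable is not symmetric")
    if (length(object@mfe) > 1L)
        msg <- c(msg, "mfe must be numeric(0) or a single value")
    if (!object@backend %in% c("external", "maxpair", "truth"))
        msg <- c(msg, "backend must be 'external', 'maxpair' or 'truth'")
    if (length(msg)) msg else TRUE
})

#' HairpinCriteria: the stem-loop selection thresholds
#'
#' The classification thresholds applied to each hairpin element: a minimum
#' element span (outer pair to outer pair, nt), an admissible terminal-loop
#' length range, and a maximum bulge run length within the stem. The named
#' preset \code{"paper2026"} carries the screen defaults
#' (span >= 35, loop 3..10, bulges <= 2).
#'
#' @slot minSpan minimum element span in nt.
#' @slot loopMin,loopMax admissible terminal loop lengths in nt.
#' @slot bulgeMax maximum length of an unpaired run interrupting the stem.
#' @slot bulgeMode \code{"each"}: each side of an interior interruption must
#'   satisfy \code{bulgeMax} independently; \code{"sum"}: the two sides of
#'   an internal loop are limited jointly.
#' @export
setClass("HairpinCriteria",
    slots = c(minSpan = "integer", loopMin = "integer", loopMax = "integer",
              bulgeMax = "integer", bulgeMode = "character")
)

setValidity("HairpinCriteria", function(object) {
    msg <- character(0)
    if (object@loopMin <= 0L || object@loopMin > object@loopMax)
        msg <- c(msg, "need 0 < loopMin <= loopMax")
    if (object@minSpan < object@loopMin + 2L)
        msg <- c(msg, "minSpan must be at least loopMin + 2")
    if (object@bulgeMax < 0L)
        msg <- c(msg, "bulgeMax must be >= 0")
    if (!object@bulgeMode %in% c("each", "sum"))
        msg <- c(msg, "bulgeMode must be 'each' or 'sum'")
    if (length(msg)) msg else TRUE
})

#' HairpinElement: one hairpin (helix + terminal loop + bulge runs)
#'
#' A single hairpin element extracted from a structure: the helix read from
#' its outermost pair inward to the pair closing the terminal loop,
#' absorbing stem interruptions (bulges / internal loops) on the way, and
#' stopping at a multiloop junction or the exterior loop.
#'
#' @slot outerStart,outerEnd positions of the outermost pair; element span
#'   is \code{outerEnd - outerStart + 1}.
#' @slot loopStart,loopEnd first/last position of the terminal loop
#'   (loopEnd < loopStart encodes an empty loop).
#' @slot helixPairs 2-column integer matrix of pairs ordered outer to inner.
#' @slot bulges data.frame with one row per unpaired run interrupting the
#'   helix: columns \code{interruption} (index, outer to inner),
#'   \code{side} ("5prime"/"3prime"), \code{start}, \code{length}.
#' @export
setClass("HairpinElement",
    slots = c(
        outerStart = "integer", outerEnd = "integer",
        loopStart = "integer", loopEnd = "integer",
        helixPairs = "matrix",
        bulges = "data.frame"
    )
)

#' HairpinCall: pass/fail classification of a structure or element
#'
#' @slot passed TRUE when at least one hairpin element satisfies the
#'   criteria.
#' @slot element the best passing [HairpinElement] (greatest span, ties to
#'   the 5'-most), or NULL.
#' @slot failureReasons subset of \code{no_hairpin}, \code{span},
#'   \code{loop}, \code{bulge}, \code{branched_only}; empty iff passed.
#' @export
setClass("HairpinCall",
    slots = c(passed = "logical", element = "ANY",
              failureReasons = "character")
)

setValidity("HairpinCall", function(object) {
    if (object@passed != (length(object@failureReasons) == 0L))
        return("passed must be TRUE exactly when failureReasons is empty")
    ok <- object@failureReasons %in%
        c("no_hairpin", "span", "loop", "bulge", "branched_only")
    if (!all(ok)) return("unknown failure reason")
    TRUE
})

#' VariantDesign: a substitution/edit set on a stem-loop sequence
#'
#' One designed sequence variant: destabilizing (DV), destabilizing-
#' compensated (DVC), stabilizing (SV), stabilizing-compensated (SVC), or a
#' length-changing edit (stem shift insertion / stem deletion).
#'
#' @slot baseSequence the sequence the design was derived from.
#' @slot sequence the edited sequence.
#' @slot substitutions data.frame with columns \code{pos}, \code{from},
#'   \code{to} (empty for insertion/deletion designs).
#' @slot variantClass one of DV, DVC, SV, SVC, shift, deletion.
#' @slot structure predicted [SecondaryStructure] of the variant under the
#'   active backend.
#' @slot stabilityDelta variant score minus base score on the MFE sign
#'   convention: positive = destabilized, negative = stabilized.
#' @slot details backend-specific bookkeeping (broken/created pairs, edited
#'   coordinate maps) used by the compensatory designers.
#' @export
setClass("VariantDesign",
    slots = c(
        baseSequence = "character",
        sequence = "character",
        substitutions = "data.frame",
        variantClass = "character",
        structure = "SecondaryStructure",
        stabilityDelta = "numeric",
        details = "list"
    )
)

setValidity("VariantDesign", function(object) {
    msg <- character(0)
    if (!object@variantClass %in% c("DV", "DVC", "SV", "SVC", "shift",
                                    "deletion"))
        msg <- c(msg, "unknown variantClass")
    subs <- object@substitutions
    if (nrow(subs)) {
        if (anyDuplicated(subs$pos))
            msg <- c(msg, "substitutions must reference distinct positions")
        got <- substring(object@baseSequence, subs$pos, subs$pos)
        if (!all(got == subs$from))
            msg <- c(msg, "substitution 'from' bases do not match baseSequence")
        edited <- .applySubstitutions(object@baseSequence, subs)
        if (edited != object@sequence)
            msg <- c(msg, "applying substitutions does not reproduce sequence")
    }
    if (length(msg)) msg else TRUE
})
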