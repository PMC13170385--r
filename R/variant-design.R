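# Stem-loop mutagenesis designs: destabilizing (DV), destabilizing-
# compensated (DVC), stabilizing (SV), stabilizing-compensated (SVC)
# substitution sets, plus distance (insertion) and stem-deletion edits.
#
# stabilityDelta is always variant score minus parent score on the MFE
# sign convention (positive = destabilized); for compensated designs the
# parent is the DV/SV design they rescue.

.foldBackend <- function(seq, scoring) foldMaxPair(seq, scoring)

.scoreOf <- function(seq, scoring) .foldBackend(seq, scoring)@mfe

.newDesign <- function(base, subs, class, scoring, details = list()) {
    seq <- .applySubstitutions(base, subs)
    str <- .foldBackend(seq, scoring)
    new("VariantDesign", baseSequence = base, sequence = seq,
        substitutions = subs, variantClass = class, structure = str,
        stabilityDelta = str@mfe - .scoreOf(base, scoring),
        details = details)
}

.emptySubs <- function() {
    data.frame(pos = integer(0), from = character(0), to = character(0),
               stringsAsFactors = FALSE)
}

# First base (fixed candidate order) that cannot pair base5 under WC+GU
# and differs from `avoid`; used when the primary rule would leave a
# pairable or identical base.
.nonPairingSubstitute <- function(base5, avoid) {
    for (cand in c("C", "A", "G", "U"))
        if (!.canPair(base5, cand) && cand != avoid) return(cand)
    stop("no non-pairing substitute exists")   # unreachable for ACGU
}

#' Design a destabilizing variant (DV)
#'
#' Disrupts selected stem pairs by substituting the 3'-side base of each
#' pair to the identity of its 5' partner (X:X never pairs under WC+GU);
#' if that rule would leave a pairable or unchanged base the documented
#' fallback picks the first of C/A/G/U that cannot pair the 5' base.
#'
#' @param s a [SecondaryStructure] of the base sequence.
#' @param pairs integer vector of positions naming the pairs to break
#'   (either side of each pair may be given).
#' @param scoring [PairScoring] for the internal backend.
#' @return a [VariantDesign] of class DV; its \code{stabilityDelta} is
#'   positive (destabilized) and a warning is raised if not.
#' @export
designDestabilizing <- function(s, pairs, scoring = pairScoring()) {
    pt <- s@pairTable
    b <- .splitChars(s@sequence)
    pairs <- unique(as.integer(pairs))
    bad <- pairs[is.na(pt[pairs])]
    if (length(bad))
        stop("position ", bad[1L], " is not paired in the structure")
    subs <- .emptySubs()
    broken <- matrix(integer(0), ncol = 2,
                     dimnames = list(NULL, c("i5", "j3")))
    for (p in pairs) {
        i5 <- min(p, pt[p]); j3 <- max(p, pt[p])
        to <- b[i5]
        if (.canPair(b[i5], to) || to == b[j3])
            to <- .nonPairingSubstitute(b[i5], b[j3])
        subs <- rbind(subs, data.frame(pos = j3, from = b[j3], to = to,
                                       stringsAsFactors = FALSE))
        broken <- rbind(broken, c(i5, j3))
    }
    subs <- subs[order(subs$pos), , drop = FALSE]
    rownames(subs) <- NULL
    d <- .newDesign(s@sequence, subs, "DV", scoring,
                    details = list(brokenPairs = broken))
    if (d@stabilityDelta <= 0)
        warning("DV design did not destabilize under the active backend")
    d
}

#' Design the compensatory rescue (DVC) of a destabilizing variant
#'
#' For each pair the DV broke by mutating its 3' base, mutates the 5'
#' partner to the Watson-Crick complement of the mutated base, recreating
#' the pair while leaving both positions different from the original
#' sequence (sequence divergence with structure restoration).
#'
#' @param dv a [VariantDesign] of class DV.
#' @param scoring [PairScoring].
#' @return a [VariantDesign] of class DVC whose \code{baseSequence} is the
#'   DV sequence.
#' @export
designCompensatory <- function(dv, scoring = pairScoring()) {
    if (dv@variantClass != "DV") stop("design is not a DV variant")
    broken <- dv@details$brokenPairs
    dvCh <- .splitChars(dv@sequence)
    subs <- .emptySubs()
    for (r in seq_len(nrow(broken))) {
        i5 <- broken[r, 1L]; j3 <- broken[r, 2L]
        subs <- rbind(subs, data.frame(
            pos = i5, from = dvCh[i5], to = .wcComplement(dvCh[j3]),
            stringsAsFactors = FALSE))
    }
    subs <- subs[order(subs$pos), , drop = FALSE]
    rownames(subs) <- NULL
    .newDesign(dv@sequence, subs, "DVC", scoring,
               details = list(restoredPairs = broken,
                              originalSequence = dv@baseSequence))
}

#' List the internal loops of a structure's hairpin elements
#'
#' Enumerates interior helix interruptions that are unpaired on both
#' strand sides (internal loops; one-sided bulges have a zero length on
#' one side and cannot be closed by substitution).
#'
#' @param s a [SecondaryStructure].
#' @return data.frame with one row per interruption: \code{element},
#'   \code{loop_id}, \code{start5}, \code{len5}, \code{start3},
#'   \code{len3}.
#' @export
internalLoops <- function(s) {
    elements <- enumerateHairpins(s)
    out <- data.frame(element = integer(0), loop_id = integer(0),
                      start5 = integer(0), len5 = integer(0),
                      start3 = integer(0), len3 = integer(0))
    for (e in seq_along(elements)) {
        bl <- elements[[e]]@bulges
        if (!nrow(bl)) next
        for (ii in sort(unique(bl$interruption))) {
            b5 <- bl[bl$interruption == ii & bl$side == "5prime", ,
                     drop = FALSE]
            b3 <- bl[bl$interruption == ii & bl$side == "3prime", ,
                     drop = FALSE]
            out <- rbind(out, data.frame(
                element = e, loop_id = ii,
                start5 = if (nrow(b5)) b5$start else NA_integer_,
                len5 = if (nrow(b5)) b5$length else 0L,
                start3 = if (nrow(b3)) b3$start else NA_integer_,
                len3 = if (nrow(b3)) b3$length else 0L))
        }
    }
    rownames(out) <- NULL
    out
}

#' Design a stabilizing variant (SV)
#'
#' Closes selected internal loops by new base pairs: for
#' \code{min(len5, len3)} opposing positions (aligned innermost-out), the
#' 3'-side base is substituted to the Watson-Crick complement of its 5'
#' counterpart.
#'
#' @param s a [SecondaryStructure].
#' @param loops row indices into [internalLoops()] naming the loops to
#'   close; by default all two-sided internal loops.
#' @param scoring [PairScoring].
#' @return a [VariantDesign] of class SV; \code{stabilityDelta} is
#'   negative (more stable) and a warning is raised if not.
#' @export
designStabilizing <- function(s, loops = NULL, scoring = pairScoring()) {
    il <- internalLoops(s)
    if (is.null(loops)) loops <- which(il$len5 > 0L & il$len3 > 0L)
    if (!length(loops)) stop("no internal loop to close")
    if (any(loops < 1L | loops > nrow(il)))
        stop("internal loop identifier out of range")
    b <- .splitChars(s@sequence)
    subs <- .emptySubs()
    created <- matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("p5", "p3")))
    for (r in loops) {
        if (il$len5[r] == 0L || il$len3[r] == 0L)
            stop("interruption ", r,
                 " is a one-sided bulge: not closable by substitution")
        k <- min(il$len5[r], il$len3[r])
        end5 <- il$start5[r] + il$len5[r] - 1L
        for (t in seq_len(k)) {
            p5 <- end5 - t + 1L
            p3 <- il$start3[r] + t - 1L
            subs <- rbind(subs, data.frame(
                pos = p3, from = b[p3], to = .wcComplement(b[p5]),
                stringsAsFactors = FALSE))
            created <- rbind(created, c(p5, p3))
        }
    }
    subs <- subs[order(subs$pos), , drop = FALSE]
    rownames(subs) <- NULL
    d <- .newDesign(s@sequence, subs, "SV", scoring,
                    details = list(createdPairs = created))
    if (d@stabilityDelta >= 0)
        warning("SV design did not stabilize under the active backend")
    d
}

#' Design the compensatory rescue (SVC) of a stabilizing variant
#'
#' For each pair the SV created, mutates the 5'-side partner to a base
#' that cannot pair the SV-mutated 3' base (first of C/A/G/U under WC+GU),
#' restoring the original internal-loop topology while keeping the
#' sequence different from the original. An SV with zero created pairs
#' yields the identity design.
#'
#' @param sv a [VariantDesign] of class SV.
#' @param scoring [PairScoring].
#' @return a [VariantDesign] of class SVC whose \code{baseSequence} is the
#'   SV sequence.
#' @export
designStabilizedCompensatory <- function(sv, scoring = pairScoring()) {
    if (sv@variantClass != "SV") stop("design is not an SV variant")
    created <- sv@details$createdPairs
    svCh <- .splitChars(sv@sequence)
    subs <- .emptySubs()
    for (r in seq_len(nrow(created))) {
        p5 <- created[r, 1L]; p3 <- created[r, 2L]
        subs <- rbind(subs, data.frame(
            pos = p5, from = svCh[p5],
            to = .nonPairingSubstitute(svCh[p3], svCh[p5]),
            stringsAsFactors = FALSE))
    }
    subs <- subs[order(subs$pos), , drop = FALSE]
    rownames(subs) <- NULL
    .newDesign(sv@sequence, subs, "SVC", scoring,
               details = list(openedPairs = created,
                              originalSequence = sv@baseSequence))
}

#' Stem distance (insertion) and stem deletion edits
#'
#' Insertion modes place 3, 6 or 9 given nucleotides immediately after
#' paper position +9 (i.e. after window position 6), displacing the
#' stem-loop away from the stop codon; \code{delete_stem} removes paper
#' positions +12 to +57 inclusive (46 nt). The offset map is remapped:
#' positions keep the contiguous +1-at-stop numbering, inserted bases have
#' no genomic coordinate.
#'
#' @param ctx a [StopContext] whose window covers the edited coordinates.
#' @param mode one of \code{"insert3"}, \code{"insert6"}, \code{"insert9"},
#'   \code{"delete_stem"}.
#' @param insertText RNA text of length 3/6/9 for the insertion modes.
#' @param scoring [PairScoring].
#' @return a [VariantDesign] of class \code{shift} or \code{deletion};
#'   \code{details} carries the edited [StopContext].
#' @export
shiftOrDeleteStem <- function(ctx, mode = c("insert3", "insert6", "insert9",
                                            "delete_stem"),
                              insertText = "", scoring = pairScoring()) {
    mode <- match.arg(mode)
    w <- ctx@window
    n <- nchar(w)
    if (mode == "delete_stem") {
        # paper +12..+57 = window indices 9..54
        if (n < 54L)
            stop("window does not cover paper positions +12..+57")
        keep <- setdiff(seq_len(n), 9:54)
        newWindow <- paste0(.splitChars(w)[keep], collapse = "")
        newGenomic <- ctx@genomicPos[keep]
        cls <- "deletion"
    } else {
        k <- c(insert3 = 3L, insert6 = 6L, insert9 = 9L)[[mode]]
        insertText <- .toRNA(insertText)
        if (nchar(insertText) != k)
            stop(mode, " requires ", k, " nucleotides, got ",
                 nchar(insertText))
        if (n < 6L) stop("window does not cover paper position +9")
        newWindow <- paste0(substring(w, 1L, 6L), insertText,
                            substring(w, 7L, n))
        newGenomic <- c(ctx@genomicPos[seq_len(6L)], rep(NA_integer_, k),
                        ctx@genomicPos[seq(7L, length.out = n - 6L)])
        cls <- "shift"
    }
    m <- nchar(newWindow)
    newCtx <- new("StopContext", geneId = ctx@geneId, txId = ctx@txId,
                  stopCodon = ctx@stopCodon, window = newWindow,
                  windowRequested = max(ctx@windowRequested, m),
                  truncated = ctx@truncated, strand = ctx@strand,
                  paperPos = if (m) 3L + seq_len(m) else integer(0),
                  genomicPos = newGenomic)
    str <- .foldBackend(newWindow, scoring)
    new("VariantDesign", baseSequence = w, sequence = newWindow,
        substitutions = .emptySubs(), variantClass = cls, structure = str,
        stabilityDelta = str@mfe - .scoreOf(w, scoring),
        details = list(context = newCtx, mode = mode))
}
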