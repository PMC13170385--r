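#' Stem-loop classification criteria
#'
#' Constructor for [HairpinCriteria]. The preset \code{"paper2026"} is the
#' screen default: element span at least 35 nt, terminal loop between 3 and
#' 10 nt, and no unpaired run (bulge) within the stem longer than 2 nt.
#'
#' @param preset \code{"paper2026"} or NULL to take the explicit arguments.
#' @param minSpan,loopMin,loopMax,bulgeMax thresholds (nt).
#' @param bulgeMode \code{"each"} (each side of an internal loop limited
#'   independently, the default) or \code{"sum"} (both sides jointly).
#' @return a [HairpinCriteria].
#' @examples
#' hairpinCriteria()
#' hairpinCriteria(NULL, minSpan = 20L, loopMax = 8L)
#' @export
hairpinCriteria <- function(preset = "paper2026", minSpan = 35L,
                            loopMin = 3L, loopMax = 10L, bulgeMax = 2L,
                            bulgeMode = "each") {
    if (!is.null(preset)) {
        if (!identical(preset, "paper2026"))
            stop("unknown criteria preset '", preset, "'")
        minSpan <- 35L; loopMin <- 3L; loopMax <- 10L; bulgeMax <- 2L
    }
    new("HairpinCriteria", minSpan = as.integer(minSpan),
        loopMin = as.integer(loopMin), loopMax = as.integer(loopMax),
        bulgeMax = as.integer(bulgeMax), bulgeMode = bulgeMode)
}

.terminalLoopPairs <- function(pt) {
    # closing pairs (i, j), i < j, with no paired position strictly inside
    open <- which(!is.na(pt) & pt > seq_along(pt))
    keep <- vapply(open, function(i) {
        j <- pt[i]
        j == i + 1L || all(is.na(pt[(i + 1L):(j - 1L)]))
    }, logical(1))
    open[keep]
}

# TRUE when some pair directly encloses >= 2 child helices (a multiloop).
.hasMultiloop <- function(pt) {
    term <- .terminalLoopPairs(pt)
    if (length(term) < 2L) return(FALSE)
    open <- which(!is.na(pt) & pt > seq_along(pt))
    for (i in open) {
        j <- pt[i]
        if (sum(term > i & term < j) >= 2L) return(TRUE)
    }
    FALSE
}

#' Enumerate hairpin elements of a secondary structure
#'
#' One element per terminal (hairpin) loop. Starting from the loop's
#' closing pair, the element extends outward through consecutive pairs,
#' absorbing interruptions where at least one strand side is unpaired
#' (bulges and internal loops, recorded per side), and stops at a multiloop
#' junction or at the exterior loop. Elements from different terminal loops
#' never share helix pairs.
#'
#' @param s a [SecondaryStructure].
#' @return list of [HairpinElement] ordered by 5' position (empty for
#'   structures without pairs).
#' @export
enumerateHairpins <- function(s) {
    pt <- s@pairTable
    term <- .terminalLoopPairs(pt)
    if (!length(term)) return(list())
    paired <- !is.na(pt)
    out <- lapply(term, function(i0) {
        j0 <- pt[i0]
        helix <- list(c(i0, j0))      # inner -> outer while walking
        bulges <- .emptyBulges()
        interruption <- 0L
        a <- i0; bpos <- j0
        repeat {
            # nearest paired position 5' of the current outer pair
            p <- a - 1L
            while (p >= 1L && !paired[p]) p <- p - 1L
            if (p < 1L) break                       # reached the exterior
            q <- pt[p]
            if (q <= bpos) break                    # sibling helix: junction
            # positions between bpos and q must be unpaired, otherwise the
            # enclosing pair (p, q) closes a multiloop
            if (q > bpos + 1L && any(paired[(bpos + 1L):(q - 1L)])) break
            left <- a - p - 1L
            right <- q - bpos - 1L
            if (left > 0L || right > 0L) {
                interruption <- interruption + 1L
                if (left > 0L)
                    bulges <- rbind(bulges, data.frame(
                        interruption = interruption, side = "5prime",
                        start = p + 1L, length = left,
                        stringsAsFactors = FALSE))
                if (right > 0L)
                    bulges <- rbind(bulges, data.frame(
                        interruption = interruption, side = "3prime",
                        start = bpos + 1L, length = right,
                        stringsAsFactors = FALSE))
            }
            helix[[length(helix) + 1L]] <- c(p, q)
            a <- p; bpos <- q
        }
        helix <- rev(helix)                         # outer -> inner
        hp <- do.call(rbind, helix)
        # renumber interruptions outer -> inner
        if (nrow(bulges)) {
            bulges$interruption <-
                max(bulges$interruption) - bulges$interruption + 1L
            bulges <- bulges[order(bulges$interruption, bulges$side), ,
                             drop = FALSE]
            rownames(bulges) <- NULL
        }
        new("HairpinElement",
            outerStart = hp[1L, 1L], outerEnd = hp[1L, 2L],
            loopStart = i0 + 1L, loopEnd = j0 - 1L,
            helixPairs = hp, bulges = bulges)
    })
    out[order(vapply(out, function(e) e@outerStart, integer(1)))]
}

#' Element span, terminal loop length, helix length
#'
#' @param e a [HairpinElement].
#' @return integer.
#' @export
elementSpan <- function(e) e@outerEnd - e@outerStart + 1L

#' @rdname elementSpan
#' @export
loopLength <- function(e) e@loopEnd - e@loopStart + 1L

#' Evaluate one hairpin element against criteria
#'
#' Passes iff the element span is at least \code{minSpan}, the terminal
#' loop length lies in \code{[loopMin, loopMax]}, and every bulge run obeys
#' \code{bulgeMax} (individually, or summed per internal loop under
#' \code{bulgeMode = "sum"}).
#'
#' @param e a [HairpinElement].
#' @param criteria a [HairpinCriteria].
#' @return a [HairpinCall] whose element slot is \code{e} when it passes.
#' @export
evaluateHairpin <- function(e, criteria = hairpinCriteria()) {
    reasons <- character(0)
    if (elementSpan(e) < criteria@minSpan) reasons <- c(reasons, "span")
    ll <- loopLength(e)
    if (ll < criteria@loopMin || ll > criteria@loopMax)
        reasons <- c(reasons, "loop")
    if (nrow(e@bulges)) {
        if (criteria@bulgeMode == "each") {
            if (any(e@bulges$length > criteria@bulgeMax))
                reasons <- c(reasons, "bulge")
        } else {
            per <- tapply(e@bulges$length, e@bulges$interruption, sum)
            if (any(per > criteria@bulgeMax))
                reasons <- c(reasons, "bulge")
        }
    }
    new("HairpinCall", passed = length(reasons) == 0L,
        element = if (length(reasons) == 0L) e else NULL,
        failureReasons = reasons)
}

#' Classify a structure as stem-loop or not
#'
#' A structure passes when at least one of its hairpin elements satisfies
#' the criteria; unpaired flanking tails and additional non-qualifying
#' elements are permitted. The best element is the passing one of greatest
#' span (ties broken 5'-most). When nothing passes the failure reasons of
#' all elements are aggregated; a fully unpaired structure fails with
#' \code{no_hairpin}, and structures whose helices are interrupted by
#' multiloop junctions additionally carry \code{branched_only}.
#'
#' @param s a [SecondaryStructure].
#' @param criteria a [HairpinCriteria].
#' @return a [HairpinCall].
#' @examples
#' s <- foldMaxPair(strrep("G", 18))  # no structure possible
#' classifyStructure(s)@failureReasons
#' @export
classifyStructure <- function(s, criteria = hairpinCriteria()) {
    elements <- enumerateHairpins(s)
    if (!length(elements))
        return(new("HairpinCall", passed = FALSE, element = NULL,
                   failureReasons = "no_hairpin"))
    calls <- lapply(elements, evaluateHairpin, criteria = criteria)
    ok <- which(vapply(calls, function(x) x@passed, logical(1)))
    if (length(ok)) {
        spans <- vapply(elements[ok], elementSpan, integer(1))
        starts <- vapply(elements[ok], function(e) e@outerStart, integer(1))
        best <- ok[order(-spans, starts)][1L]
        return(new("HairpinCall", passed = TRUE, element = elements[[best]],
                   failureReasons = character(0)))
    }
    reasons <- sort(unique(unlist(lapply(calls,
                                         function(x) x@failureReasons))))
    if (.hasMultiloop(s@pairTable))
        reasons <- sort(unique(c(reasons, "branched_only")))
    new("HairpinCall", passed = FALSE, element = NULL,
        failureReasons = reasons)
}
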