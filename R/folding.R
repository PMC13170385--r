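#' Pair-weight scheme for the maximum-base-pairing folder
#'
#' @param GC,AU,GU positive weights per pair class (defaults 3/2/1, the
#'   hydrogen-bond counts, so helix scores rank qualitatively like
#'   thermodynamic stability).
#' @param minLoop minimum hairpin loop length in nt (default 3).
#' @return a [PairScoring] object.
#' @examples
#' pairScoring()
#' pairScoring(GC = 1, AU = 1, GU = 1)  # plain pair counting
#' @export
pairScoring <- function(GC = 3, AU = 2, GU = 1, minLoop = 3L) {
    new("PairScoring", GC = as.numeric(GC), AU = as.numeric(AU),
        GU = as.numeric(GU), minLoop = as.integer(minLoop))
}

#' Convert dot-bracket notation to a pair table
#'
#' Stack-matches round brackets. The returned table is a 1-based integer
#' vector with \code{pt[i] == j} and \code{pt[j] == i} for each pair and NA
#' at unpaired positions; it is nested (pseudoknot-free) by construction.
#'
#' @param db dot-bracket string over \code{(}, \code{)}, \code{.}.
#' @return integer partner vector.
#' @examples
#' pairsFromDotBracket("((((...))))")
#' @export
pairsFromDotBracket <- function(db) {
    stopifnot(is.character(db), length(db) == 1L)
    ch <- .splitChars(db)
    bad <- which(!ch %in% c("(", ")", "."))
    if (length(bad))
        stop("illegal dot-bracket character '", ch[bad[1L]],
             "' at position ", bad[1L])
    n <- length(ch)
    pt <- rep(NA_integer_, n)
    stack <- integer(0)
    for (k in seq_len(n)) {
        if (ch[k] == "(") {
            stack <- c(stack, k)
        } else if (ch[k] == ")") {
            if (!length(stack))
                stop("unmatched ')' at position ", k)
            i <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pt[i] <- k
            pt[k] <- i
        }
    }
    if (length(stack))
        stop("unmatched '(' opened at position ", stack[length(stack)])
    pt
}

#' Convert a pair table back to dot-bracket notation
#'
#' Exact inverse of [pairsFromDotBracket()] on nested tables; crossing
#' (pseudoknotted) tables are rejected.
#'
#' @param pt integer partner vector (NA = unpaired), or a 2-column matrix
#'   of pairs.
#' @param n sequence length (required for the matrix form; inferred from
#'   the vector form).
#' @return dot-bracket string.
#' @export
dotBracketFromPairs <- function(pt, n = length(pt)) {
    if (is.matrix(pt)) {
        m <- pt
        pt <- rep(NA_integer_, n)
        for (r in seq_len(nrow(m))) {
            i <- min(m[r, ]); j <- max(m[r, ])
            pt[i] <- j; pt[j] <- i
        }
    }
    stopifnot(n == length(pt))
    ch <- rep(".", n)
    open <- which(!is.na(pt) & pt > seq_len(n))
    ch[open] <- "("
    ch[pt[open]] <- ")"
    db <- paste0(ch, collapse = "")
    back <- tryCatch(pairsFromDotBracket(db), error = function(e) NULL)
    if (is.null(back) || !identical(back, as.integer(pt)))
        stop("pseudoknot unsupported: pair table contains crossing pairs")
    db
}

#' Build a SecondaryStructure from sequence and dot-bracket
#'
#' @param sequence RNA (or DNA; T is converted to U) sequence.
#' @param dotbracket matching dot-bracket string.
#' @param mfe optional minimum free energy (kcal/mol).
#' @param backend provenance tag, \code{"external"} by default.
#' @return a [SecondaryStructure].
#' @export
secondaryStructure <- function(sequence, dotbracket, mfe = numeric(0),
                               backend = "external") {
    sequence <- .toRNA(sequence)
    if (nchar(sequence) != nchar(dotbracket))
        stop("sequence and dotbracket lengths differ (",
             nchar(sequence), " vs ", nchar(dotbracket), ")")
    new("SecondaryStructure", sequence = sequence, dotbracket = dotbracket,
        pairTable = pairsFromDotBracket(dotbracket),
        mfe = as.numeric(mfe), backend = backend)
}

# Weight of pairing bases a, b under a PairScoring; 0 when unpairable.
.pairWeight <- function(scoring) {
    W <- matrix(0, 5, 5, dimnames = list(c(.RNA_BASES, "N"),
                                         c(.RNA_BASES, "N")))
    W["G", "C"] <- W["C", "G"] <- scoring@GC
    W["A", "U"] <- W["U", "A"] <- scoring@AU
    W["G", "U"] <- W["U", "G"] <- scoring@GU
    W
}

#' Fold a sequence by nested base-pair weight maximization
#'
#' A self-contained folding backend: dynamic programming over subintervals
#' (Nussinov-style) maximizing the total pair weight of a nested structure
#' subject to the minimum loop length, with WC + GU wobble pairing and
#' unpairable N. Traceback is deterministic: whenever pairing the interval's
#' first position attains the optimum it is paired with the smallest
#' admissible partner, otherwise it is left unpaired.
#'
#' The reported \code{mfe} is minus the total pair weight so that
#' "lower = more stable" matches the thermodynamic MFE sign convention;
#' it is a stability score, not a free energy in kcal/mol.
#'
#' @param seq RNA or DNA sequence (A/C/G/U/T/N, case-insensitive).
#' @param scoring a [PairScoring]; see [pairScoring()].
#' @return a [SecondaryStructure] with \code{backend = "maxpair"}.
#' @examples
#' foldMaxPair("GGGAAACCC")
#' @export
foldMaxPair <- function(seq, scoring = pairScoring()) {
    seq <- .toRNA(seq)
    if (!nchar(seq)) stop("empty sequence")
    b <- .splitChars(seq)
    if (any(!b %in% c(.RNA_BASES, "N")))
        stop("illegal base '", setdiff(b, c(.RNA_BASES, "N"))[1L],
             "' in sequence")
    n <- length(b)
    W <- .pairWeight(scoring)
    minLoop <- scoring@minLoop
    M <- matrix(0, n, n)
    if (n >= minLoop + 2L) {
        for (d in (minLoop + 1L):(n - 1L)) {
            for (i in seq_len(n - d)) {
                j <- i + d
                best <- M[i + 1L, j]
                ks <- (i + minLoop + 1L):j
                w <- W[b[i], b[ks]]
                ok <- w > 0
                if (any(ok)) {
                    ks <- ks[ok]; w <- w[ok]
                    left <- ifelse(ks - 1L > i + 1L, M[cbind(i + 1L, ks - 1L)], 0)
                    # k - 1 == i + 1 means a single enclosed base: score 0;
                    # k - 1 > i + 1 reads the subinterval score
                    left[ks - 1L == i + 1L] <- 0
                    right <- ifelse(ks < j, M[cbind(pmin(ks + 1L, n), j)], 0)
                    best <- max(best, max(w + left + right))
                }
                M[i, j] <- best
            }
        }
    }
    # deterministic traceback
    pt <- rep(NA_integer_, n)
    stack <- list(c(1L, n))
    while (length(stack)) {
        iv <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        i <- iv[1L]; j <- iv[2L]
        while (i < j && j - i > minLoop) {
            target <- M[i, j]
            if (target == 0) break
            paired <- FALSE
            for (k in (i + minLoop + 1L):j) {
                w <- W[b[i], b[k]]
                if (w == 0) next
                left <- if (k - 1L > i + 1L) M[i + 1L, k - 1L] else 0
                right <- if (k < j) M[k + 1L, j] else 0
                if (w + left + right == target) {
                    pt[i] <- k; pt[k] <- i
                    if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
                    j <- k - 1L
                    i <- i + 1L
                    paired <- TRUE
                    break
                }
            }
            if (!paired) i <- i + 1L
        }
    }
    score <- M[1L, n]
    new("SecondaryStructure", sequence = seq,
        dotbracket = dotBracketFromPairs(pt, n),
        pairTable = pt, mfe = -score, backend = "maxpair")
}
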