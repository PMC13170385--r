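# Independent oracles and random generators used across the suite. These
# deliberately share no code with the package: the folding oracle
# enumerates nested structures recursively, the hairpin oracle
# characterizes element membership through terminal-loop enclosure counts.

# Maximum total pair weight over ALL nested structures (WC + GU, minimum
# loop length), by explicit enumeration of the choices at the interval's
# first position. Exponential in structure count; use only for small n.
oracleMaxPairScore <- function(seq, GC = 3, AU = 2, GU = 1, minLoop = 3) {
    b <- strsplit(seq, "", fixed = TRUE)[[1]]
    wt <- function(a, c) {
        p <- paste0(a, c)
        if (p %in% c("GC", "CG")) GC
        else if (p %in% c("AU", "UA")) AU
        else if (p %in% c("GU", "UG")) GU
        else 0
    }
    rec <- function(i, j) {
        if (j - i < minLoop + 1) return(0)
        best <- rec(i + 1, j)
        for (k in (i + minLoop + 1):j) {
            w <- wt(b[i], b[k])
            if (w == 0) next
            cand <- w + rec(i + 1, k - 1) + (if (k < j) rec(k + 1, j) else 0)
            if (cand > best) best <- cand
        }
        best
    }
    if (length(b) < 2) 0 else rec(1, length(b))
}

# Hairpin elements from a pair table by the enclosure characterization: a
# pair belongs to terminal loop t's element iff it encloses t's closing
# pair (or is it) and encloses exactly one terminal closing pair overall.
oracleHairpinElements <- function(pt) {
    n <- length(pt)
    open <- which(!is.na(pt) & pt > seq_len(n))
    encloses <- function(a, b, i) a <= i & pt[i] <= b
    terminals <- open[vapply(open, function(i) {
        j <- pt[i]
        !any(open > i & open < j)
    }, logical(1))]
    lapply(terminals, function(t0) {
        members <- open[vapply(open, function(a) {
            b <- pt[a]
            if (!(a <= t0 && pt[t0] <= b)) return(FALSE)
            sum(vapply(terminals, function(tt) encloses(a, b, tt),
                       logical(1))) == 1L
        }, logical(1))]
        members <- sort(members)                       # outer -> inner
        pairs <- cbind(members, pt[members])
        runs <- list()
        if (length(members) > 1L) {
            for (r in seq_len(length(members) - 1L)) {
                left <- unname(pairs[r + 1L, 1L] - pairs[r, 1L] - 1L)
                right <- unname(pairs[r, 2L] - pairs[r + 1L, 2L] - 1L)
                if (left > 0L)
                    runs[[length(runs) + 1L]] <-
                        c(side = "5prime", length = left)
                if (right > 0L)
                    runs[[length(runs) + 1L]] <-
                        c(side = "3prime", length = right)
            }
        }
        inner <- pairs[nrow(pairs), ]
        list(outer = pairs[1L, ], pairs = pairs,
             loopLength = inner[2L] - inner[1L] - 1L, bulgeRuns = runs)
    })
}

# Random nested dot-bracket of length n: repeatedly tries to add an
# admissible pair at unpaired, non-crossing positions.
randomNestedDotBracket <- function(n, tries = 2L * n, minLoop = 3L) {
    pt <- rep(NA_integer_, n)
    for (r in seq_len(tries)) {
        i <- sample.int(n, 1L)
        j <- sample.int(n, 1L)
        if (i > j) { tmp <- i; i <- j; j <- tmp }
        if (j - i <= minLoop || !is.na(pt[i]) || !is.na(pt[j])) next
        crossing <- FALSE
        for (a in which(!is.na(pt) & pt > seq_len(n))) {
            b <- pt[a]
            if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
                crossing <- TRUE
                break
            }
        }
        if (!crossing) { pt[i] <- j; pt[j] <- i }
    }
    ch <- rep(".", n)
    ch[which(!is.na(pt) & pt > seq_len(n))] <- "("
    ch[which(!is.na(pt) & pt < seq_len(n))] <- ")"
    paste0(ch, collapse = "")
}

randomRnaSequence <- function(n) {
    paste0(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Dot-bracket of a perfect hairpin with optional flanks, for boundary cases.
hairpinDotBracket <- function(stem, loop, flank5 = 0L, flank3 = 0L) {
    paste0(strrep(".", flank5), strrep("(", stem), strrep(".", loop),
           strrep(")", stem), strrep(".", flank3))
}

# Arbitrary letters consistent with a dot-bracket (G-C pairs), so that
# secondaryStructure() validity holds for hand-built structures.
sequenceForDotBracket <- function(db) {
    pt <- pairsFromDotBracket(db)
    ch <- rep("A", nchar(db))
    open <- which(!is.na(pt) & pt > seq_along(pt))
    ch[open] <- "G"
    ch[pt[open]] <- "C"
    paste0(ch, collapse = "")
}
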