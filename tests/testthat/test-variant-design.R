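# DV / DVC / SV / SVC mutagenesis designs and the distance/deletion edits.

test_that("destabilizing substitutions abolish pairing per the stated rule", {
    # G-C pair broken by C->G, A-U by U->A, G-U wobble by U->G
    s <- secondaryStructure("GAGCAAAAGCUU", "((((....))))")
    dv <- designDestabilizing(s, pairs = c(1, 2, 3))
    subs <- substitutions(dv)
    expect_equal(subs$pos, c(10L, 11L, 12L))
    expect_equal(subs[subs$pos == 10L, "to"], "G")   # G-C -> G/G
    expect_equal(subs[subs$pos == 11L, "to"], "A")   # A-U -> A/A
    expect_equal(subs[subs$pos == 12L, "to"], "G")   # G-U -> G/G
    canPair <- function(a, b) paste0(a, b) %in%
        c("AU", "UA", "GC", "CG", "GU", "UG")
    b <- strsplit(variantSequence(dv), "")[[1]]
    for (r in seq_len(nrow(dv@details$brokenPairs))) {
        i <- dv@details$brokenPairs[r, 1L]
        j <- dv@details$brokenPairs[r, 2L]
        expect_false(canPair(b[i], b[j]))
    }
    expect_error(designDestabilizing(s, pairs = 6), "not paired")
})

test_that("DV destabilizes and DVC restores structure on planted fixtures", {
    set.seed(43)
    for (r in 1:10) {
        ph <- plantHairpin(sample(8:14, 1L), sample(3:8, 1L))
        s <- foldMaxPair(ph$sequence)
        expect_identical(dotBracket(s), dotBracket(ph$structure))
        nPairs <- sum(!is.na(pairTable(s))) / 2L
        open <- which(!is.na(pairTable(s)) &
                      pairTable(s) > seq_along(pairTable(s)))
        pick <- sample(open, sample(1:2, 1L))
        dv <- designDestabilizing(s, pairs = pick)
        expect_gt(stabilityDelta(dv), 0)
        dvc <- designCompensatory(dv)
        expect_identical(dotBracket(dvc@structure), dotBracket(s))
        expect_equal(mfe(dvc@structure), mfe(s))
        # sequence diverges at both partners of every broken pair
        orig <- strsplit(ph$sequence, "")[[1]]
        fin <- strsplit(variantSequence(dvc), "")[[1]]
        for (q in seq_along(pick)) {
            i <- min(pick[q], pairTable(s)[pick[q]])
            j <- max(pick[q], pairTable(s)[pick[q]])
            expect_false(fin[i] == orig[i])
            expect_false(fin[j] == orig[j])
        }
        # delta signs are mirrored: DVC rescues exactly what DV lost
        expect_equal(stabilityDelta(dvc), -stabilityDelta(dv))
    }
})

test_that("SV closes internal loops and SVC reopens them", {
    mkLoop <- function(k) plantHairpin(12, 4, bulges = list(
        list(after = 5, side = "5prime", length = k),
        list(after = 5, side = "3prime", length = k)))
    for (k in 1:2) {
        ph <- mkLoop(k)
        s <- foldMaxPair(ph$sequence)
        il <- internalLoops(s)
        expect_equal(nrow(il), 1L)
        expect_equal(il$len5, k)
        sv <- designStabilizing(s)
        expect_equal(nrow(substitutions(sv)), k)     # k new pairs
        expect_lt(stabilityDelta(sv), 0)
        # all loop positions became paired
        expect_equal(sum(!is.na(pairTable(sv@structure))) / 2L,
                     sum(!is.na(pairTable(s))) / 2L + k)
        svc <- designStabilizedCompensatory(sv)
        expect_identical(dotBracket(svc@structure), dotBracket(s))
        expect_equal(stabilityDelta(svc), -stabilityDelta(sv))
        expect_false(variantSequence(svc) == ph$sequence)
    }
    # one-sided bulges cannot be closed by substitution
    ph1 <- plantHairpin(12, 4,
        bulges = list(list(after = 5, side = "5prime", length = 3)))
    s1 <- foldMaxPair(ph1$sequence)
    il1 <- internalLoops(s1)
    expect_equal(il1$len3, 0L)
    expect_error(designStabilizing(s1, loops = 1L), "not closable")
    expect_error(designStabilizing(s1), "no internal loop")
    # SVC of an SV with zero created pairs is the identity design
    svEmpty <- new("VariantDesign", baseSequence = ph1$sequence,
                   sequence = ph1$sequence,
                   substitutions = stemloopscreen:::.emptySubs(),
                   variantClass = "SV", structure = s1,
                   stabilityDelta = 0,
                   details = list(createdPairs = matrix(integer(0), ncol = 2)))
    svc0 <- designStabilizedCompensatory(svEmpty)
    expect_equal(nrow(substitutions(svc0)), 0L)
    expect_identical(variantSequence(svc0), ph1$sequence)
})

test_that("SVC substitutes to a base unpairable with the SV partner", {
    # A/A internal loop: SV closes A-U; SVC mutates the 5' A to C (C.U
    # does not pair under WC+GU)
    ph <- plantHairpin(10, 4, bulges = list(
        list(after = 4, side = "5prime", length = 1),
        list(after = 4, side = "3prime", length = 1)))
    s <- foldMaxPair(ph$sequence)
    sv <- designStabilizing(s)
    expect_equal(substitutions(sv)$to, "U")
    svc <- designStabilizedCompensatory(sv)
    expect_equal(substitutions(svc)$to, "C")
})

test_that("stability delta signs hold for every generated design", {
    set.seed(47)
    ok <- TRUE
    for (r in 1:25) {
        ph <- plantHairpin(sample(6:14, 1L), sample(3:8, 1L), bulges = list(
            list(after = 3, side = "5prime", length = 1),
            list(after = 3, side = "3prime", length = 1)))
        s <- foldMaxPair(ph$sequence)
        open <- which(!is.na(pairTable(s)) &
                      pairTable(s) > seq_along(pairTable(s)))
        dv <- designDestabilizing(s, sample(open, 1L))
        sv <- designStabilizing(s)
        ok <- ok && stabilityDelta(dv) > 0 && stabilityDelta(sv) < 0
    }
    expect_true(ok)
})

test_that("stem insertions shift the map and deletion removes +12..+57", {
    # hairpin starts at window position 9 so insertions after +9 land in
    # the 5' flank and only displace it
    ph <- plantHairpin(16, 4, flank5 = 8, flank3 = 16)   # 60-nt window
    ctx <- new("StopContext", geneId = "g", txId = "t", stopCodon = "UAG",
               window = ph$sequence, windowRequested = 60L,
               truncated = FALSE, strand = "+", paperPos = 4:63,
               genomicPos = 101:160)
    ins <- shiftOrDeleteStem(ctx, "insert3", "ACA")
    expect_equal(nchar(variantSequence(ins)), 63L)
    newCtx <- ins@details$context
    om <- offsetMap(newCtx)
    # the base formerly at +10 (window index 7, genomic 107) is now at +13
    expect_equal(om$paper_pos[om$genomic_pos == 107L & !is.na(om$genomic_pos)],
                 13L)
    expect_error(shiftOrDeleteStem(ctx, "insert6", "ACA"), "6 nucleotides")

    del <- shiftOrDeleteStem(ctx, "delete_stem")
    expect_equal(nchar(variantSequence(del)), 14L)       # 60 - 46
    expect_identical(del@variantClass, "deletion")

    # insert6 with a non-pairing spacer: planted hairpin still present,
    # displaced by 6 nt
    ins6 <- shiftOrDeleteStem(ctx, "insert6", "AAAAAA")
    cl0 <- classifyStructure(foldMaxPair(windowSequence(ctx)))
    cl6 <- classifyStructure(ins6@structure)
    expect_identical(isStemLoop(cl6), isStemLoop(cl0))
    expect_equal(bestElement(cl6)@outerStart,
                 bestElement(cl0)@outerStart + 6L)
})
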