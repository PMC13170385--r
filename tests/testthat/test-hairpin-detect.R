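# Hairpin element enumeration and the stem-loop classification criteria.

structureFor <- function(db) secondaryStructure(sequenceForDotBracket(db), db)

test_that("single and multiple hairpins are enumerated with their anatomy", {
    e <- enumerateHairpins(structureFor("((((...))))"))
    expect_length(e, 1L)
    expect_equal(elementSpan(e[[1L]]), 11L)
    expect_equal(loopLength(e[[1L]]), 3L)
    expect_equal(nrow(e[[1L]]@bulges), 0L)

    e2 <- enumerateHairpins(structureFor("((((...))))..((((....))))"))
    expect_length(e2, 2L)
    expect_equal(loopLength(e2[[2L]]), 4L)

    # outer helix 10, 3-nt 5' bulge, inner helix 8, loop 4
    db <- paste0(strrep("(", 10), "...", strrep("(", 8), "....",
                 strrep(")", 8), strrep(")", 10))
    e3 <- enumerateHairpins(structureFor(db))
    expect_length(e3, 1L)
    expect_equal(nrow(e3[[1L]]@helixPairs), 18L)
    expect_equal(e3[[1L]]@bulges$side, "5prime")
    expect_equal(e3[[1L]]@bulges$length, 3L)
    expect_length(enumerateHairpins(structureFor("......")), 0L)
})

test_that("criteria boundaries are enforced exactly", {
    crit <- hairpinCriteria()
    call <- function(db) classifyStructure(structureFor(db), crit)
    # span boundary: 16 bp + 3 nt loop = 35 passes, 15 bp + 4 nt = 34 fails
    expect_true(isStemLoop(call(hairpinDotBracket(16, 3))))
    f <- call(hairpinDotBracket(15, 4))
    expect_false(isStemLoop(f))
    expect_equal(failureReasons(f), "span")
    # loop boundaries: 3 and 10 pass, 2 and 11 fail
    expect_true(isStemLoop(call(hairpinDotBracket(16, 3))))
    expect_true(isStemLoop(call(hairpinDotBracket(16, 10))))
    expect_equal(failureReasons(call(hairpinDotBracket(17, 2))), "loop")
    expect_equal(failureReasons(call(hairpinDotBracket(16, 11))), "loop")
    # bulge boundary: 2 passes, 3 fails (10 + 8 bp helices, 4 nt loop)
    bulged <- function(b) paste0(strrep("(", 10), strrep(".", b),
                                 strrep("(", 8), "....", strrep(")", 8),
                                 strrep(")", 10))
    expect_true(isStemLoop(call(bulged(2))))
    f3 <- call(bulged(3))
    expect_false(isStemLoop(f3))
    expect_equal(failureReasons(f3), "bulge")
})

test_that("internal loop sides are limited individually or jointly", {
    db <- paste0(strrep("(", 10), ".", strrep("(", 9), "....",
                 strrep(")", 9), "..", strrep(")", 10))  # 1 x 2 loop
    s <- structureFor(db)
    expect_true(isStemLoop(classifyStructure(s, hairpinCriteria())))
    joint <- hairpinCriteria(NULL, minSpan = 35L, bulgeMax = 2L,
                             bulgeMode = "sum")
    expect_equal(failureReasons(classifyStructure(s, joint)), "bulge")
})

test_that("classification picks the best qualifying element", {
    # one qualifying hairpin plus one sub-span hairpin
    db <- paste0(hairpinDotBracket(16, 3), "..", hairpinDotBracket(5, 4))
    cl <- classifyStructure(structureFor(db))
    expect_true(isStemLoop(cl))
    expect_equal(bestElement(cl)@outerStart, 1L)
    expect_equal(elementSpan(bestElement(cl)), 35L)
    # fully unpaired
    cl2 <- classifyStructure(structureFor("............"))
    expect_equal(failureReasons(cl2), "no_hairpin")
    # branched structure whose arms are individually too short
    db3 <- paste0("((..", hairpinDotBracket(4, 4), "..",
                  hairpinDotBracket(4, 4), "..))")
    cl3 <- classifyStructure(structureFor(db3))
    expect_false(isStemLoop(cl3))
    expect_true("branched_only" %in% failureReasons(cl3))
    expect_true("span" %in% failureReasons(cl3))
})

test_that("enumeration agrees with the enclosure-count oracle", {
    set.seed(23)
    for (r in 1:80) {
        db <- randomNestedDotBracket(sample(20:100, 1L))
        s <- structureFor(db)
        got <- enumerateHairpins(s)
        want <- oracleHairpinElements(pairTable(s))
        expect_length(got, length(want))
        for (k in seq_along(got)) {
            expect_equal(unname(got[[k]]@helixPairs[, 1L]),
                         unname(want[[k]]$pairs[, 1L]), info = db)
            expect_equal(loopLength(got[[k]]), unname(want[[k]]$loopLength))
            oracleRuns <- want[[k]]$bulgeRuns
            expect_equal(nrow(got[[k]]@bulges), length(oracleRuns))
            if (length(oracleRuns)) {
                oracleLen <- as.integer(vapply(oracleRuns, `[[`, "",
                                               "length"))
                expect_equal(sort(got[[k]]@bulges$length), sort(oracleLen))
            }
        }
    }
})

test_that("element count equals the number of terminal loops", {
    set.seed(29)
    for (r in 1:40) {
        db <- randomNestedDotBracket(sample(15:100, 1L))
        pt <- pairsFromDotBracket(db)
        open <- which(!is.na(pt) & pt > seq_along(pt))
        nTerm <- sum(vapply(open, function(i)
            !any(open > i & open < pt[i]), logical(1)))
        expect_length(enumerateHairpins(structureFor(db)), nTerm)
    }
})

test_that("tightening any criterion never converts a fail into a pass", {
    set.seed(31)
    base <- hairpinCriteria()
    stricter <- list(
        hairpinCriteria(NULL, minSpan = 40L),
        hairpinCriteria(NULL, loopMin = 4L, loopMax = 8L),
        hairpinCriteria(NULL, bulgeMax = 1L))
    dbs <- replicate(60, randomNestedDotBracket(sample(40:90, 1L)))
    baseCalls <- vapply(dbs, function(db)
        isStemLoop(classifyStructure(structureFor(db), base)), logical(1))
    for (crit in stricter) {
        strictCalls <- vapply(dbs, function(db)
            isStemLoop(classifyStructure(structureFor(db), crit)),
            logical(1))
        expect_true(all(strictCalls <= baseCalls))
        expect_lte(sum(strictCalls), sum(baseCalls))
    }
})

test_that("classification is deterministic", {
    set.seed(37)
    db <- randomNestedDotBracket(80)
    s <- structureFor(db)
    c1 <- classifyStructure(s)
    c2 <- classifyStructure(s)
    expect_identical(isStemLoop(c1), isStemLoop(c2))
    expect_identical(failureReasons(c1), failureReasons(c2))
})
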