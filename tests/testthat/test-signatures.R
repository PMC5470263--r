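sig16 <- function(len = 40) {
    signatureTable(seq(2, 32, 2), rep(c("A", "G"), 8), rep(c("C", "T"), 8))
}

seqFromProfile <- function(sig, pick, len = 40) {
    tb <- asTable(sig)
    s <- rep("A", len)
    s[tb$column] <- ifelse(pick == "A", tb$variantA,
                    ifelse(pick == "B", tb$variantB, "-"))
    s
}

test_that("signature matching counts lineage variants per column", {
    sig <- sig16()
    pureA <- seqFromProfile(sig, rep("A", 16))
    pureB <- seqFromProfile(sig, rep("B", 16))
    gappy <- seqFromProfile(sig, rep("-", 16))
    aln <- familyAlignment(rbind(a = pureA, b = pureB, g = gappy))
    sm <- signatureMatches(aln, sig)
    expect_equal(sm$nA, c(16L, 0L, 0L))
    expect_equal(sm$nB, c(0L, 16L, 0L))
    expect_equal(sm$nGap, c(0L, 0L, 16L))
    expect_equal(sm$profile[1], strrep("A", 16))
})

test_that("signature counts equal the brute-force per-column tally", {
    set.seed(21)
    for (case in 1:100) {
        len <- sample(20:60, 1)
        aln <- randomAlignment(1, len, gapFrac = runif(1, 0, 0.3))
        k <- sample(3:12, 1)
        cols <- sort(sample(len, k))
        vA <- sample(DNA, k, replace = TRUE)
        vB <- vapply(vA, function(b) sample(setdiff(DNA, b), 1), "")
        sig <- signatureTable(cols, vA, vB)
        sm <- signatureMatches(aln, sig)
        oracle <- oracleSignatureCounts(alnMatrix(aln)[1, ], sig)
        expect_equal(c(nA = sm$nA, nB = sm$nB, nOther = sm$nOther,
                       nGap = sm$nGap), oracle)
    }
})

test_that("lineage calls follow the minority-threshold convention", {
    df <- data.frame(nA = c(16, 0, 8, 12, 13, 0),
                     nB = c(0, 16, 8, 4, 3, 0))
    calls <- callLineage(df)
    expect_equal(calls$label,
                 c("A", "B", "intermingled", "intermingled", "A",
                   "uninformative"))
    # 12/4: minority fraction exactly 0.25 -> intermingled (inclusive)
    expect_equal(calls$minorityFraction[4], 0.25)
    # 13/3: minority 0.1875 < 0.25 -> clean A call
    strict <- callLineage(df, minorityThreshold = 0.1)
    expect_equal(strict$label[5], "intermingled")
})

test_that("most-lineage-like picks maximize own-signature matches with deterministic ties", {
    sig <- sig16()
    mixed <- seqFromProfile(sig, c(rep("A", 10), rep("B", 6)))
    aln <- familyAlignment(rbind(pureA = seqFromProfile(sig, rep("A", 16)),
                                 pureB = seqFromProfile(sig, rep("B", 16)),
                                 mixed = mixed))
    expect_equal(mostLineageLike(aln, seqIds(aln), sig, "A"), "pureA")
    expect_equal(mostLineageLike(aln, seqIds(aln), sig, "B"), "pureB")
    expect_equal(mostLineageLike(aln, "mixed", sig, "A"), "mixed")

    # exact tie in nA and nB -> lexicographically smallest id
    tie <- familyAlignment(rbind(zz = mixed, aa = mixed,
                                 mm = seqFromProfile(sig, rep("B", 16))))
    expect_equal(mostLineageLike(tie, seqIds(tie), sig, "A"), "aa")
})

test_that("signature retention measures surviving divergence within groups", {
    sig <- sig16()
    pureA <- seqFromProfile(sig, rep("A", 16))
    pureB <- seqFromProfile(sig, rep("B", 16))
    halfB <- seqFromProfile(sig, c(rep("A", 6), rep("B", 10)))
    aln <- familyAlignment(rbind(a = pureA, b = pureB, h = halfB))

    expect_equal(signatureRetention(aln, "a", sig), 0L)          # singleton
    expect_equal(signatureRetention(aln, c("a", "b"), sig), 16L) # full
    # most-A-like = a, most-B-like = b even with h present
    expect_equal(signatureRetention(aln, c("a", "b", "h"), sig), 16L)
    # a vs h differ where h carries B variants
    expect_equal(signatureRetention(aln, c("a", "h"), sig), 10L)
})

test_that("intermingling reports are pure without conversion and mixed with it", {
    fam <- simulateFamily(simConfig(nSpecies = 8, seqLen = 150, kDiag = 10,
                                    subRate = 0, convRate = 0, seed = 31))
    rep0 <- interminglingReport(fam$alignment, fam$groups, fam$signature)
    expect_true(all(rep0$profile %in%
                    c(strrep("A", 10), strrep("B", 10))))
    expect_true(all(rep0$label %in% c("A", "B")))
    expect_equal(order(rep0$group, rep0$id), seq_len(nrow(rep0)))

    fam5 <- simulateFamily(simConfig(nSpecies = 12, seqLen = 150,
                                     kDiag = 10, convRate = 5,
                                     tractMean = 20, seed = 32))
    rep5 <- interminglingReport(fam5$alignment, fam5$groups, fam5$signature,
                                groupBy = "species")
    hasBoth <- grepl("A", rep5$profile) & grepl("B", rep5$profile)
    expect_true(any(hasBoth))

    expect_error(signatureTable(integer(0), character(0), character(0)),
                 "at least one row")
})

test_that("lineage calls recover the truth perfectly without erosion", {
    fam <- simulateFamily(simConfig(nSpecies = 10, seqLen = 200, kDiag = 12,
                                    subRate = 0, convRate = 0, seed = 8))
    calls <- callLineage(signatureMatches(fam$alignment, fam$signature))
    expect_equal(calls$label, unname(trueLineage(fam$truth)[calls$id]))
})

test_that("screen and truth compute the same retention on simulated data", {
    for (s in c(3, 9, 27)) {
        fam <- simulateFamily(simConfig(nSpecies = 10, seqLen = 200,
                                        kDiag = 12, convRate = 1,
                                        tractMean = 25, seed = s))
        truthRet <- signatureRetentionTruth(fam$alignment, fam$truth)
        ids <- seqIds(fam$alignment)
        sp <- sub("_[AB]$", "", ids)
        screenRet <- vapply(unique(sp), function(x)
            signatureRetention(fam$alignment, ids[sp == x], fam$signature),
            0L)
        expect_equal(screenRet[names(truthRet)], truthRet)
    }
})
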