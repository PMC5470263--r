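mkCactus <- function(mat, ids, cols = 1L) {
    dimnames(mat) <- list(ids, ids)
    new("Cactus", matrix = mat, columns = as.integer(cols))
}

mkSeg <- function(cactiList, nColsTotal) {
    cols <- sort(unlist(lapply(cactiList, function(k) k@columns)))
    path <- vapply(cols, function(cc)
        which(vapply(cactiList, function(k) cc %in% k@columns,
                     logical(1)))[1L], integer(1))
    new("Segmentation", cacti = cactiList,
        path = path, analyzedColumns = as.integer(cols),
        fullPath = rep(1L, nColsTotal),
        switchPenalty = 0, nIterations = 0L, totalCost = 0)
}

test_that("within-species extremes take the maximum conspecific distance", {
    ids <- c("sp1_A", "sp1_B", "sp2_A", "sp2_B")
    gm <- groupMap(ids, rep(c("sp1", "sp2"), each = 2), rep("g", 4))
    mat <- matrix(0, 4, 4)
    mat[1, 2] <- mat[2, 1] <- 0.8
    mat[3, 4] <- mat[4, 3] <- 0.2
    cac <- mkCactus(mat, ids)
    expect_equal(as.numeric(withinSpeciesExtreme(cac, gm, "sp1")), 0.8)
    expect_equal(as.numeric(withinSpeciesExtreme(cac, gm, "sp2")), 0.2)
    expect_equal(attr(withinSpeciesExtreme(cac, gm, "sp1"), "pair"),
                 c("sp1_A", "sp1_B"))
    expect_error(withinSpeciesExtreme(cac, groupMap("sp1_A", "x", "g"), "x"),
                 "fewer than 2")

    # 4 sequences in one species: equals brute-force max over 6 pairs
    set.seed(6)
    ids4 <- paste0("m", 1:4)
    gm4 <- groupMap(ids4, rep("m", 4), rep("g", 4))
    sym <- matrix(0, 4, 4)
    sym[upper.tri(sym)] <- runif(6)
    sym <- sym + t(sym)
    cac4 <- mkCactus(sym, ids4)
    expect_equal(as.numeric(withinSpeciesExtreme(cac4, gm4, "m")),
                 max(sym))
})

test_that("discrimination scores average species extremes and normalize by max", {
    ids <- c("sp1_A", "sp1_B", "sp2_A", "sp2_B")
    gm <- groupMap(ids, rep(c("sp1", "sp2"), each = 2), rep("g", 4))
    hot <- matrix(0, 4, 4)
    hot[1, 2] <- hot[2, 1] <- 0.8
    hot[3, 4] <- hot[4, 3] <- 0.4
    cold <- matrix(0, 4, 4)
    cold[1, 2] <- cold[2, 1] <- 0.1
    cold[3, 4] <- cold[4, 3] <- 0.3
    seg <- mkSeg(list(mkCactus(hot, ids, 1L), mkCactus(cold, ids, 2L)), 2L)
    sc <- discriminationScores(seg, gm)
    expect_equal(sc$raw, c((0.8 + 0.4) / 2, (0.1 + 0.3) / 2))
    expect_equal(sc$normalized, sc$raw / max(sc$raw))
    expect_equal(sc$nSpeciesUsed, c(2L, 2L))

    # single cactus with nonzero raw -> normalized exactly 1
    seg1 <- mkSeg(list(mkCactus(hot, ids, 1L)), 1L)
    expect_equal(discriminationScores(seg1, gm)$normalized, 1)

    # all-zero distances -> all normalized zero, not NaN
    segz <- mkSeg(list(mkCactus(matrix(0, 4, 4), ids, 1L)), 1L)
    expect_equal(discriminationScores(segz, gm)$normalized, 0)

    soloGm <- groupMap(ids, paste0("s", 1:4), rep("g", 4))
    expect_error(discriminationScores(seg, soloGm), "no species")
})

test_that("normalization is idempotent", {
    x <- c(0.2, 1, 0.6)
    expect_equal((x / max(x)) / max(x / max(x)), x / max(x))
    ids <- c("sp1_A", "sp1_B")
    gm <- groupMap(ids, c("sp1", "sp1"), c("g", "g"))
    m <- matrix(c(0, 0.5, 0.5, 0), 2)
    seg <- mkSeg(list(mkCactus(m, ids, 1L)), 1L)
    sc <- discriminationScores(seg, gm)
    expect_equal(sc$normalized / max(sc$normalized), sc$normalized)
})

test_that("cactus labels follow the inclusive threshold rule", {
    sc <- data.frame(cactus = 1:3, raw = c(0.8, 0.08, 0.4),
                     normalized = c(1, 0.1, 0.5))
    lab <- classifyCacti(sc)
    expect_equal(lab$label, c("duplication", "concerted", "duplication"))
    labz <- classifyCacti(data.frame(cactus = 1, raw = 0, normalized = 0))
    expect_equal(labz$label, "concerted")
    labk <- classifyCacti(sc, topK = 1)
    expect_equal(labk$label, c("duplication", "concerted", "concerted"))
})

test_that("diagnostic sites are the sorted union of duplication cacti columns", {
    ids <- c("sp1_A", "sp1_B")
    m <- matrix(c(0, 1, 1, 0), 2)
    seg <- mkSeg(list(mkCactus(m, ids, c(7L, 3L, 9L)),
                      mkCactus(m * 0, ids, c(1L, 2L))), 9L)
    lab <- data.frame(cactus = 1:2, label = c("duplication", "concerted"))
    expect_equal(diagnosticSites(seg, lab), c(3L, 7L, 9L))
    labNone <- data.frame(cactus = 1:2, label = rep("concerted", 2))
    expect_length(diagnosticSites(seg, labNone), 0L)
})

test_that("discovery isolates true diagnostic columns without erosion", {
    fam <- simulateFamily(simConfig(seed = 12))
    disc <- discoverDiagnosticSites(fam$alignment, fam$groups)
    trueCols <- sigColumns(fam$truth@diagnosticColumns)
    expect_true(all(trueCols %in% disc$sites))
    hits <- length(intersect(disc$sites, trueCols))
    expect_gte(hits / length(disc$sites), 0.8)
    # duplication-labeled cacti all outrank concerted ones on raw score
    sc <- disc$scores
    if (any(sc$label == "concerted") && any(sc$label == "duplication"))
        expect_gt(min(sc$raw[sc$label == "duplication"]),
                  max(sc$raw[sc$label == "concerted"]))
    # diagnostic sites are disjoint from concerted cacti columns
    conc <- unlist(lapply(cacti(disc$segmentation)[sc$label == "concerted"],
                          function(k) k@columns))
    expect_length(intersect(disc$sites, conc), 0L)
})
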