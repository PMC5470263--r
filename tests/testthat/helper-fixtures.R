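# Fixtures and independent oracles shared across the suite. All data
# are generated in code under fixed seeds; oracles are deliberately
# naive (double loops, exhaustive enumeration) and independent of the
# package's implementation paths.

DNA <- c("A", "C", "G", "T")

randomAlignment <- function(nSeq, nCol, gapFrac = 0) {
    m <- matrix(sample(DNA, nSeq * nCol, replace = TRUE), nSeq, nCol)
    if (gapFrac > 0) {
        idx <- sample(length(m), round(gapFrac * length(m)))
        m[idx] <- sample(c("-", "N"), length(idx), replace = TRUE)
    }
    rownames(m) <- sprintf("s%03d", seq_len(nSeq))
    familyAlignment(m)
}

# uncorrected p-distance by explicit per-site loop
oraclePDist <- function(m, i, j) {
    comp <- 0L
    diff <- 0L
    for (v in seq_len(ncol(m))) {
        a <- m[i, v]
        b <- m[j, v]
        if (a %in% DNA && b %in% DNA) {
            comp <- comp + 1L
            if (a != b) diff <- diff + 1L
        }
    }
    if (comp == 0L) NA_real_ else diff / comp
}

# per-column signature tally by explicit loop
oracleSignatureCounts <- function(seqRow, sig) {
    tb <- asTable(sig)
    nA <- nB <- nOther <- nGap <- 0L
    for (r in seq_len(nrow(tb))) {
        ch <- seqRow[tb$column[r]]
        if (!(ch %in% DNA)) nGap <- nGap + 1L
        else if (ch == tb$variantA[r]) nA <- nA + 1L
        else if (ch == tb$variantB[r]) nB <- nB + 1L
        else nOther <- nOther + 1L
    }
    c(nA = nA, nB = nB, nOther = nOther, nGap = nGap)
}

# minimum total cost over all K^V state paths by full enumeration
# (vectorized over the path table, but still brute force)
oracleViterbi <- function(costs, penalty) {
    V <- nrow(costs)
    K <- ncol(costs)
    paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(K)), V)))
    emis <- matrix(costs[cbind(rep(seq_len(V), each = nrow(paths)),
                               as.vector(paths))], nrow(paths), V)
    switches <- if (V > 1)
        rowSums(paths[, -1, drop = FALSE] != paths[, -V, drop = FALSE])
    else 0
    min(rowSums(emis) + penalty * switches)
}

# does an edge of the unrooted tree induce exactly (subset, complement)?
oracleBipartition <- function(tree, subset) {
    tree <- ape::unroot(tree)
    tips <- tree$tip.label
    splits <- ape::prop.part(tree)
    for (s in splits) {
        side <- tips[s]
        if (setequal(side, subset) || setequal(setdiff(tips, side), subset))
            return(TRUE)
    }
    # prop.part misses trivial splits (single tips)
    length(subset) %in% c(1L, length(tips) - 1L, length(tips))
}

# single-topology null: balanced tree, equal short branches
singleTopologyAlignment <- function(seed, nTaxa = 8, len = 200, rate = 0.6,
                                    bl = 0.02) {
    set.seed(seed)
    tr <- ape::stree(nTaxa, type = "balanced",
                     tip.label = sprintf("t%02d", seq_len(nTaxa)))
    tr <- ape::compute.brlen(tr, 1)
    tr$edge.length <- rep(bl, length(tr$edge.length))
    m <- toupper(as.character(phangorn::simSeq(tr, l = len, rate = rate)))
    familyAlignment(m)
}

# two 100-column blocks simulated on unrelated topologies over the
# same 12 taxa; divergence high enough that single columns are
# informative about their local topology
twoBlockAlignment <- function(seed, nTaxa = 12, rate = 3) {
    set.seed(seed)
    t1 <- ape::rcoal(nTaxa, tip.label = sprintf("t%02d", seq_len(nTaxa)))
    t2 <- ape::rcoal(nTaxa, tip.label = sample(sprintf("t%02d",
                                                       seq_len(nTaxa))))
    t1$edge.length <- t1$edge.length /
        max(ape::node.depth.edgelength(t1)) * 0.1
    t2$edge.length <- t2$edge.length /
        max(ape::node.depth.edgelength(t2)) * 0.1
    m1 <- toupper(as.character(phangorn::simSeq(t1, l = 100, rate = rate)))
    m2 <- toupper(as.character(phangorn::simSeq(t2, l = 100, rate = rate)))
    familyAlignment(cbind(m1, m2[rownames(m1), ]))
}

# changepoint along a state path: position maximizing the L1 distance
# between the state distributions left and right of the cut
pathChangepoint <- function(fp, margin = 20L) {
    n <- length(fp)
    sts <- sort(unique(fp))
    best <- -1
    at <- NA_integer_
    for (b in margin:(n - margin)) {
        L <- tabulate(factor(fp[1:b], levels = sts), length(sts)) / b
        R <- tabulate(factor(fp[(b + 1):n], levels = sts),
                      length(sts)) / (n - b)
        v <- sum(abs(L - R))
        if (v > best) {
            best <- v
            at <- b
        }
    }
    at
}

# additive distance matrix of a tree (path lengths between tips)
treeDistances <- function(tree) {
    ape::cophenetic.phylo(tree)
}
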