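#' Per-column difference matrix
#'
#' The elementary local-phylogeny signal of one alignment column: entry
#' (i, j) is 0 when sequences i and j carry the same base at the
#' column, 1 when they differ, and `NA` when either carries a gap/`N`
#' (such pairs get zero weight in emission costs).
#'
#' @param aln a [FamilyAlignment-class].
#' @param col 1-based column index.
#' @return A symmetric 0/1/`NA` matrix with sequence ids as dimnames.
#' @export
columnDiffMatrix <- function(aln, col) {
    stopifnot(is(aln, "FamilyAlignment"), col >= 1, col <= nCols(aln))
    x <- alnMatrix(aln)[, col]
    ok <- x %in% DNA_BASES
    d <- outer(x, x, "!=") * 1
    d[!ok, ] <- NA_real_
    d[, !ok] <- NA_real_
    diag(d) <- 0
    d
}

# Pair-pattern representation used throughout this module: for n
# sequences the n(n-1)/2 unordered pairs are laid out in column-major
# upper-triangle order, and every alignment column becomes a 0/1/NA
# vector over those pairs.
pairPatterns <- function(m, cols) {
    n <- nrow(m)
    ut <- upper.tri(matrix(0, n, n))
    vapply(cols, function(v) {
        x <- m[, v]
        ok <- x %in% DNA_BASES
        d <- outer(x, x, "!=") * 1
        d[!ok, ] <- NA_real_
        d[, !ok] <- NA_real_
        d[ut]
    }, numeric(sum(ut)))
}

# Cactus pair-vector from a set of column patterns: the mean of 0/1
# difference indicators is itself a distance in [0, 1], so the scale of
# within- vs between-lineage divergence is preserved (the
# discrimination statistic normalizes once, across cacti).
cactusVector <- function(D) {
    v <- rowMeans(D, na.rm = TRUE)
    v[is.nan(v)] <- 0
    v
}

pairVecToMatrix <- function(v, ids) {
    n <- length(ids)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- v
    m <- m + t(m)
    diag(m) <- 0
    m
}

# per-column cost under each cactus pair-vector: mean squared deviation
# over pairs comparable in that column
costMatrix <- function(D, cactusVecs) {
    vapply(cactusVecs, function(cv) {
        colMeans((D - cv)^2, na.rm = TRUE)
    }, numeric(ncol(D)))
}

#' Fit of an alignment column to a cactus
#'
#' Mean squared deviation between the column's difference matrix and
#' the cactus matrix, over pairs where the column is comparable
#' (non-gap in both sequences).
#'
#' @param aln a [FamilyAlignment-class].
#' @param col 1-based column index.
#' @param cactus a [Cactus-class].
#' @return Nonnegative cost.
#' @export
emissionCost <- function(aln, col, cactus) {
    stopifnot(is(cactus, "Cactus"))
    d <- columnDiffMatrix(aln, col)
    cm <- cactus@matrix[rownames(d), colnames(d)]
    ut <- upper.tri(d)
    dev <- (d[ut] - cm[ut])^2
    mean(dev, na.rm = TRUE)
}

#' Minimum-cost column-to-cactus assignment (Viterbi)
#'
#' Dynamic program over alignment columns: finds the state path
#' minimizing total emission cost plus `switchPenalty` per state
#' change. Deterministic; ties prefer staying in the current state and
#' then the lowest state index.
#'
#' @param costs numeric matrix, columns-by-states, of emission costs.
#' @param switchPenalty nonnegative cost per state change.
#' @return A list with `path` (integer state per column) and `total`
#'   (the minimal total cost).
#' @export
viterbiAssign <- function(costs, switchPenalty) {
    stopifnot(is.matrix(costs), switchPenalty >= 0)
    V <- nrow(costs)
    K <- ncol(costs)
    if (V == 0L || K == 0L) stop("empty cost table")
    f <- matrix(Inf, V, K)
    back <- matrix(0L, V, K)
    f[1L, ] <- costs[1L, ]
    if (V > 1L) for (v in 2:V) {
        prevBest <- which.min(f[v - 1L, ])  # lowest index on ties
        for (k in seq_len(K)) {
            stay <- f[v - 1L, k]
            jump <- f[v - 1L, prevBest] + switchPenalty
            if (stay <= jump) {             # prefer staying on ties
                f[v, k] <- stay + costs[v, k]
                back[v, k] <- k
            } else {
                f[v, k] <- jump + costs[v, k]
                back[v, k] <- prevBest
            }
        }
    }
    path <- integer(V)
    path[V] <- which.min(f[V, ])
    if (V > 1L) for (v in V:2) path[v - 1L] <- back[v, path[v]]
    list(path = path, total = min(f[V, ]))
}

#' Partition alignment columns into local phylogenetic classes
#'
#' Segments the variable columns of an alignment into cacti — local
#' phylogenetic classes summarized as mean pairwise difference
#' matrices — in two stages. Stage one extracts site classes: sets of
#' at least `minSegment` columns sharing the identical
#' pairwise-difference partition. Repetition of one exact partition is
#' the footprint of a common local history at individual scattered
#' sites (in a duplicated gene family, fixed inter-lineage differences
#' repeat the lineage bipartition at every diagnostic column), so these
#' columns are classified directly and pay no contiguity cost. Stage
#' two segments the remaining columns with a Viterbi assignment
#' penalizing each state switch, starting from a single cactus (their
#' mean difference pattern): each iteration proposes a new cactus from
#' the contiguous window of `minSegment` columns with the worst mean
#' emission cost along the current path, refines all assignments by
#' coordinate descent (reassign, recompute matrices, repeat while the
#' cost drops), and keeps the proposal only if the total path cost
#' decreases. Finally each cactus matrix is recomputed from its
#' assigned columns and empty cacti are dropped. Monomorphic columns
#' carry no signal; they are excluded from the fit and assigned the
#' state of the nearest analyzed column in the returned full path. The
#' procedure involves no randomness.
#'
#' @param aln a [FamilyAlignment-class] with >= 4 sequences.
#' @param nIterations number of segmental cactus proposals to attempt.
#' @param minSegment minimum segment length, and equally the minimum
#'   recurrence of an exact pattern to form a site class; default 10.
#' @param switchPenalty cost per state change in the segmental stage;
#'   default 2x the median per-column emission cost of the initial
#'   single-cactus fit.
#' @param acceptMargin minimum decrease in total cost for a proposal to
#'   be kept; default 0 (any decrease).
#' @return A [Segmentation-class].
#' @export
fitPartition <- function(aln, nIterations = 5L, minSegment = 10L,
                         switchPenalty = NULL, acceptMargin = NULL) {
    stopifnot(is(aln, "FamilyAlignment"))
    if (nSeqs(aln) < 4L) stop("segmentation needs >= 4 sequences")
    if (minSegment > nCols(aln))
        stop("minSegment (", minSegment, ") exceeds alignment length (",
             nCols(aln), ")")
    m <- alnMatrix(aln)
    variable <- which(vapply(seq_len(ncol(m)), function(v) {
        x <- m[, v]
        length(unique(x[x %in% DNA_BASES])) >= 2L
    }, logical(1)))
    if (!length(variable))
        stop("alignment has no variable columns; nothing to segment")
    D <- pairPatterns(m, variable)
    V <- length(variable)

    # Stage 1 — site classes: columns showing the identical
    # pairwise-difference partition at least minSegment times are the
    # sharpest evidence of a shared local history (in a gene family,
    # fixed inter-lineage differences repeat one partition exactly).
    # Such classes are scattered by nature, so they are extracted
    # before the segmental stage and do not pay switch costs.
    key <- apply(D, 2L, function(x) paste(ifelse(is.na(x), 2, x),
                                          collapse = ""))
    mult <- table(key)
    classKeys <- names(mult)[mult >= minSegment]
    classCols <- lapply(classKeys, function(k) which(key == k))
    inClass <- integer(V)                    # 0 = segmental stage
    for (k in seq_along(classCols)) inClass[classCols[[k]]] <- k

    # Stage 2 — segmental classes: HMM over the remaining columns with
    # a per-switch penalty, growing the cactus set by worst-window
    # proposals refined by coordinate descent.
    chain <- which(inClass == 0L)
    nIterations <- as.integer(nIterations)
    chainPath <- integer(0)
    chainVecs <- list()
    if (length(chain)) {
        Dc <- D[, chain, drop = FALSE]
        chainVecs <- list(cactusVector(Dc))
        costs <- costMatrix(Dc, chainVecs)
        if (is.null(switchPenalty))
            switchPenalty <- 2 * stats::median(costs[, 1L])
        if (is.null(acceptMargin)) acceptMargin <- 0
        vit <- viterbiAssign(costs, switchPenalty)
        chainPath <- vit$path
        total <- vit$total
        rejectedWins <- integer(0)
        # proposals are seeded from the worst-fitting window at two
        # scales: minSegment (local structure) and 3 x minSegment (a
        # wider window averages away per-column noise, so a long block
        # under one topology can be captured in a single proposal)
        widths <- unique(c(minSegment,
                           min(3L * minSegment, length(chain))))
        for (it in seq_len(nIterations)) {
            if (length(chain) < minSegment) break
            pathCost <- costs[cbind(seq_along(chain), chainPath)]
            cand <- NULL
            tried <- integer(0)
            for (w in widths) {
                starts <- rankedWindowStarts(pathCost, w)
                starts <- starts[!((starts + w * 1000L) %in%
                                   rejectedWins)][1L]
                if (is.na(starts)) next
                tried <- c(tried, starts + w * 1000L)
                win <- starts:(starts + w - 1L)
                cw <- refineAssignment(
                    Dc, c(chainVecs,
                          list(cactusVector(Dc[, win, drop = FALSE]))),
                    switchPenalty)
                if (is.null(cand) || cw$total < cand$total) cand <- cw
            }
            if (is.null(cand)) break
            if (cand$total < total - acceptMargin - 1e-12) {
                chainVecs <- cand$vecs
                costs <- cand$costs
                chainPath <- cand$path
                total <- cand$total
                rejectedWins <- integer(0)
            } else {
                rejectedWins <- c(rejectedWins, tried)
            }
        }
    }
    if (is.null(switchPenalty)) switchPenalty <- 0

    # combined state space: chain cacti first, then site classes
    usedChain <- sort(unique(chainPath))
    path <- integer(V)
    path[chain] <- match(chainPath, usedChain)
    path[inClass > 0L] <- length(usedChain) + inClass[inClass > 0L]

    # keep non-empty states, recompute matrices from assigned columns
    used <- sort(unique(path))
    path <- match(path, used)
    ids <- seqIds(aln)
    cactiList <- lapply(seq_along(used), function(k) {
        cols <- variable[path == k]
        v <- cactusVector(D[, match(cols, variable), drop = FALSE])
        new("Cactus", matrix = pairVecToMatrix(v, ids),
            columns = as.integer(cols))
    })
    finalVecs <- lapply(cactiList, function(k) k@matrix[upper.tri(k@matrix)])
    finalCosts <- costMatrix(D, finalVecs)
    finalTotal <- sum(finalCosts[cbind(seq_len(V), path)]) +
        switchPenalty * sum(diff(path[chain]) != 0)

    fullPath <- integer(ncol(m))
    nearest <- findInterval(seq_len(ncol(m)), variable)
    for (v in seq_len(ncol(m))) {
        if (v %in% variable) {
            fullPath[v] <- path[match(v, variable)]
        } else {
            left <- nearest[v]
            if (left == 0L) {
                fullPath[v] <- path[1L]
            } else {
                dl <- v - variable[left]
                dr <- if (left < V) variable[left + 1L] - v else Inf
                fullPath[v] <- if (dl <= dr) path[left] else path[left + 1L]
            }
        }
    }

    new("Segmentation", cacti = cactiList, path = as.integer(path),
        analyzedColumns = as.integer(variable),
        fullPath = as.integer(fullPath),
        switchPenalty = as.numeric(switchPenalty),
        nIterations = nIterations, totalCost = as.numeric(finalTotal))
}

# Coordinate descent: alternate Viterbi reassignment with recomputing
# each cactus vector from its assigned columns until the total cost
# stops decreasing. Both steps are individually cost-non-increasing, so
# this terminates; empty states are dropped as they arise. A state
# listed in `frozen` keeps its seed vector instead of being recomputed:
# used for exact-pattern seeds, whose centroid must not drift toward
# merely correlated columns while its class crystallizes.
refineAssignment <- function(D, vecs, switchPenalty, frozen = integer(0),
                             maxRounds = 25L) {
    costs <- costMatrix(D, vecs)
    vit <- viterbiAssign(costs, switchPenalty)
    best <- list(vecs = vecs, costs = costs, path = vit$path,
                 total = vit$total)
    for (r in seq_len(maxRounds)) {
        used <- sort(unique(best$path))
        path <- match(best$path, used)
        vecs <- lapply(seq_along(used), function(k) {
            if (used[k] %in% frozen) best$vecs[[used[k]]]
            else cactusVector(D[, path == k, drop = FALSE])
        })
        frozen <- match(intersect(frozen, used), used)
        costs <- costMatrix(D, vecs)
        vit <- viterbiAssign(costs, switchPenalty)
        cand <- list(vecs = vecs, costs = costs, path = vit$path,
                     total = vit$total)
        if (cand$total >= best$total - 1e-12) {
            if (cand$total <= best$total + 1e-12) best <- cand
            break
        }
        best <- cand
    }
    best
}

# window start positions ordered by decreasing window cost (fixed
# width); leftmost first among ties
rankedWindowStarts <- function(pathCost, width) {
    V <- length(pathCost)
    cs <- cumsum(c(0, pathCost))
    sums <- cs[(width + 1L):(V + 1L)] - cs[1:(V - width + 1L)]
    order(-sums)
}
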