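#' Simulate an ultrametric species tree
#'
#' Draws a random ultrametric tree under a pure-birth (Yule) process
#' and rescales all branch lengths so that the root-to-tip depth equals
#' `treeHeight`. A Yule tree spreads speciation events through time,
#' giving a radiation-like scaffold along which the two paralog
#' lineages evolve.
#'
#' @param nSpecies number of species (tips).
#' @param seed RNG seed; `NULL` uses the current RNG stream (as done
#'   inside [simulateFamily()], which owns one seeded stream).
#' @param treeHeight root-to-tip depth.
#' @return An ultrametric `ape::phylo` with tips `sp01`, `sp02`, ...
#' @export
simulateSpeciesTree <- function(nSpecies, seed = NULL, treeHeight = 1) {
    stopifnot(nSpecies >= 2)
    if (!is.null(seed)) set.seed(seed)
    tr <- if (nSpecies == 2L) {
        ape::read.tree(text = "(sp01:1,sp02:1);")
    } else {
        t <- ape::rphylo(nSpecies, birth = 1, death = 0)
        t$tip.label <- sprintf("sp%02d", seq_len(nSpecies))
        t
    }
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth * treeHeight
    tr
}

#' Copy a gene-conversion tract from donor to recipient
#'
#' Nonreciprocal transfer: the recipient becomes identical to the donor
#' over the tract and is unchanged elsewhere; the donor is unmodified.
#' Coordinates are 1-based inclusive.
#'
#' @param donor,recipient character vectors of equal length (one base
#'   per element).
#' @param start,end tract bounds, `1 <= start <= end <= length`.
#' @return The modified recipient.
#' @examples
#' applyConversion(strsplit("AAAA", "")[[1]], strsplit("CCCC", "")[[1]], 2, 3)
#' @export
applyConversion <- function(donor, recipient, start, end) {
    stopifnot(length(donor) == length(recipient),
              start >= 1, end >= start, end <= length(donor))
    recipient[start:end] <- donor[start:end]
    recipient
}

#' Simulate a two-lineage gene family under gene conversion
#'
#' Forward simulation of the birth of two paralog lineages at the root
#' of a species tree, followed by erosion of their distinctness by
#' intergenic gene conversion. At the root one ancestral sequence is
#' duplicated into lineages A and B; `kDiag` diagnostic columns receive
#' distinct fixed founder variants per lineage. Both copies then
#' co-descend every branch of the species tree, accumulating
#' `Pois(subRate * bl * seqLen)` Jukes–Cantor substitutions per copy and
#' `Pois(convRate * bl)` gene-conversion events per copy, each copying a
#' geometric tract (mean `tractMean`, clipped at the sequence ends)
#' between the two conspecific copies in a uniformly chosen direction.
#' Diagnostic columns are protected from substitution (rejected and
#' resampled) unless `erodeBySubstitution` is set, so that conversion is
#' the only force eroding the duplication footprint. Finally each
#' species loses one copy (A or B, equal odds) with probability
#' `dropoutP`.
#'
#' One seeded RNG stream drives everything, consumed in a fixed order
#' (tree, founders, then a pre-order pass over branches with
#' substitutions before conversions, then dropout), so a seed
#' reproduces the output byte for byte.
#'
#' @param cfg a [SimConfig-class].
#' @return A list with elements `alignment` ([FamilyAlignment-class]),
#'   `groups` ([GroupMap-class]; group labels are the two root clades),
#'   `signature` ([SignatureTable-class] of the true diagnostic columns
#'   with founder variants), and `truth` ([SimTruth-class]).
#' @examples
#' fam <- simulateFamily(simConfig(nSpecies = 4, seqLen = 60, kDiag = 6,
#'                                 seed = 7))
#' fam$alignment
#' @export
simulateFamily <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    set.seed(cfg@seed)
    tree <- simulateSpeciesTree(cfg@nSpecies, seed = NULL,
                                treeHeight = cfg@treeHeight)
    L <- cfg@seqLen
    anc <- sample(DNA_BASES, L, replace = TRUE)
    if (cfg@kDiag > 0L) {
        diagCols <- sort(sample.int(L, cfg@kDiag))
        varA <- anc[diagCols]
        varB <- vapply(varA,
                       function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    } else {
        diagCols <- integer(0)
        varA <- varB <- character(0)
    }
    founderA <- anc
    founderA[diagCols] <- varA
    founderB <- anc
    founderB[diagCols] <- varB

    res <- evolveAlongTree(tree, founderA, founderB, diagCols, cfg)
    states <- res$states
    events <- res$events

    # per-species lineage dropout, tips visited in label order
    tips <- sort(tree$tip.label)
    keep <- list()
    for (sp in tips) {
        copies <- c("A", "B")
        if (cfg@dropoutP > 0 && stats::runif(1) < cfg@dropoutP)
            copies <- setdiff(copies, sample(c("A", "B"), 1L))
        keep[[sp]] <- copies
    }

    ids <- character(0)
    rows <- list()
    lineage <- character(0)
    for (sp in tips) {
        node <- match(sp, tree$tip.label)
        for (cp in keep[[sp]]) {
            id <- paste0(sp, "_", cp)
            ids <- c(ids, id)
            rows[[id]] <- states[[node]][[cp]]
            lineage[id] <- cp
        }
    }
    m <- do.call(rbind, rows)
    rownames(m) <- ids
    aln <- new("FamilyAlignment", seqs = m)

    clade <- rootCladeOf(tree)
    gm <- groupMap(ids,
                   species = sub("_[AB]$", "", ids),
                   group = clade[sub("_[AB]$", "", ids)])
    sig <- if (cfg@kDiag > 0L) signatureTable(diagCols, varA, varB)
           else signatureTable(1L, "A", "C")  # placeholder never used
    if (cfg@kDiag == 0L)
        warning("kDiag = 0: returned signature table is empty of meaning")
    truth <- new("SimTruth", lineage = lineage, diagnosticColumns = sig,
                 events = events,
                 founder = list(A = founderA, B = founderB),
                 tree = tree, config = cfg)
    list(alignment = aln, groups = gm, signature = sig, truth = truth)
}

# Pre-order pass over branches; per branch and copy: substitutions first,
# then conversions. Returns per-node sequence states and the event log.
evolveAlongTree <- function(tree, founderA, founderB, diagCols, cfg) {
    tree <- stats::reorder(tree, "cladewise")   # parents before children
    L <- cfg@seqLen
    nNode <- max(tree$edge)
    root <- ape::Ntip(tree) + 1L
    states <- vector("list", nNode)
    states[[root]] <- list(A = founderA, B = founderB)
    protect <- !cfg@erodeBySubstitution && length(diagCols) > 0L
    free <- setdiff(seq_len(L), diagCols)       # substitution-eligible sites
    ev <- list()
    ne <- 0L
    logEv <- function(edge, copy, type, pos = NA_integer_,
                      base = NA_character_, start = NA_integer_,
                      end = NA_integer_, donor = NA_character_) {
        ne <<- ne + 1L
        ev[[ne]] <<- data.frame(edge = edge, copy = copy, type = type,
                                pos = pos, base = base, start = start,
                                end = end, donor = donor,
                                stringsAsFactors = FALSE)
    }
    for (e in seq_len(nrow(tree$edge))) {
        parent <- tree$edge[e, 1L]
        child <- tree$edge[e, 2L]
        bl <- tree$edge.length[e]
        st <- states[[parent]]
        for (cp in c("A", "B")) {
            nSub <- stats::rpois(1L, cfg@subRate * bl * L)
            for (k in seq_len(nSub)) {
                pos <- if (protect) {
                    if (!length(free)) break
                    free[sample.int(length(free), 1L)]
                } else sample.int(L, 1L)
                newBase <- sample(setdiff(DNA_BASES, st[[cp]][pos]), 1L)
                st[[cp]][pos] <- newBase
                logEv(child, cp, "sub", pos = pos, base = newBase)
            }
        }
        for (cp in c("A", "B")) {
            nConv <- stats::rpois(1L, cfg@convRate * bl)
            for (k in seq_len(nConv)) {
                donor <- sample(c("A", "B"), 1L)
                recip <- setdiff(c("A", "B"), donor)
                start <- sample.int(L, 1L)
                len <- 1L + stats::rgeom(1L, 1 / cfg@tractMean)
                end <- min(L, start + len - 1L)
                st[[recip]] <- applyConversion(st[[donor]], st[[recip]],
                                               start, end)
                logEv(child, cp, "conv", start = start, end = end,
                      donor = donor)
            }
        }
        states[[child]] <- st
    }
    events <- if (ne) do.call(rbind, ev) else
        data.frame(edge = integer(0), copy = character(0),
                   type = character(0), pos = integer(0),
                   base = character(0), start = integer(0),
                   end = integer(0), donor = character(0))
    list(states = states, events = events)
}

# species -> root-clade label ("cladeI"/"cladeII")
rootCladeOf <- function(tree) {
    root <- ape::Ntip(tree) + 1L
    kids <- tree$edge[tree$edge[, 1L] == root, 2L]
    lab <- stats::setNames(rep("cladeII", ape::Ntip(tree)), tree$tip.label)
    tipsUnder <- function(node) {
        if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
        ape::extract.clade(tree, node)$tip.label
    }
    lab[tipsUnder(kids[1L])] <- "cladeI"
    lab
}

#' Replay a simulation from its event log
#'
#' Re-applies the logged substitutions and conversion tracts to the
#' founder sequences along the recorded tree, reproducing the simulated
#' alignment exactly. Used to verify the integrity of the event log.
#'
#' @param truth a [SimTruth-class].
#' @return A [FamilyAlignment-class] identical to the simulated one.
#' @export
replaySimulation <- function(truth) {
    stopifnot(is(truth, "SimTruth"))
    tree <- stats::reorder(truth@tree, "cladewise")
    events <- truth@events
    nNode <- max(tree$edge)
    root <- ape::Ntip(tree) + 1L
    states <- vector("list", nNode)
    states[[root]] <- truth@founder
    for (e in seq_len(nrow(tree$edge))) {
        parent <- tree$edge[e, 1L]
        child <- tree$edge[e, 2L]
        st <- states[[parent]]
        sel <- events[events$edge == child, , drop = FALSE]
        for (k in seq_len(nrow(sel))) {
            r <- sel[k, ]
            if (r$type == "sub") {
                st[[r$copy]][r$pos] <- r$base
            } else {
                recip <- setdiff(c("A", "B"), r$donor)
                st[[recip]] <- applyConversion(st[[r$donor]], st[[recip]],
                                               r$start, r$end)
            }
        }
        states[[child]] <- st
    }
    ids <- names(truth@lineage)
    rows <- lapply(ids, function(id) {
        sp <- sub("_[AB]$", "", id)
        states[[match(sp, tree$tip.label)]][[truth@lineage[id]]]
    })
    m <- do.call(rbind, rows)
    rownames(m) <- ids
    new("FamilyAlignment", seqs = m)
}

#' True per-species signature retention
#'
#' For every species that retains both gene copies, the number of true
#' diagnostic columns at which its two copies still differ; species
#' with a single surviving copy score 0. Full retention equals the
#' number of diagnostic columns; complete homogenization gives 0.
#'
#' @param aln the simulated [FamilyAlignment-class].
#' @param truth the matching [SimTruth-class].
#' @return Named integer vector, one entry per species.
#' @export
signatureRetentionTruth <- function(aln, truth) {
    stopifnot(is(aln, "FamilyAlignment"), is(truth, "SimTruth"))
    ids <- seqIds(aln)
    sp <- sub("_[AB]$", "", ids)
    cols <- sigColumns(truth@diagnosticColumns)
    m <- alnMatrix(aln)
    out <- integer(0)
    for (s in unique(sp)) {
        mine <- ids[sp == s]
        out[s] <- if (length(mine) == 2L)
            sum(m[mine[1L], cols] != m[mine[2L], cols]) else 0L
    }
    out
}
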