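#' Distance between a species' two most distant sequences in a cactus
#'
#' The maximum cactus-matrix distance over all conspecific pairs of a
#' species. Using the extreme pair rather than the mean over all pairs
#' keeps the statistic unbiased by how many sequences happen to be
#' available per species. The reporting attribute `pair` names the
#' extreme pair (lexicographically smallest on ties).
#'
#' @param cactus a [Cactus-class].
#' @param groups a [GroupMap-class].
#' @param species a species label with >= 2 sequences.
#' @return The maximum within-species distance, with attribute `pair`.
#' @export
withinSpeciesExtreme <- function(cactus, groups, species) {
    stopifnot(is(cactus, "Cactus"), is(groups, "GroupMap"))
    ids <- seqIds(groups)[asTable(groups)$species == species]
    ids <- intersect(ids, rownames(cactus@matrix))
    if (length(ids) < 2L)
        stop("species '", species, "' has fewer than 2 sequences")
    sub <- cactus@matrix[ids, ids]
    best <- -Inf
    pair <- c(NA, NA)
    for (a in seq_len(length(ids) - 1L)) for (b in (a + 1L):length(ids)) {
        p <- sort(c(ids[a], ids[b]))
        v <- sub[ids[a], ids[b]]
        if (is.na(v)) next
        if (v > best || (v == best &&
                         paste(p, collapse = "\r") <
                         paste(pair, collapse = "\r"))) {
            best <- v
            pair <- p
        }
    }
    structure(best, pair = pair)
}

#' Per-cactus discrimination scores
#'
#' The statistic separating duplication-history cacti from
#' concerted-evolution cacti: for each cactus, the mean over species
#' (those with >= 2 sequences) of the distance between the species' two
#' most distant sequences, normalized across cacti by division by the
#' maximum so the top cactus scores 1. Under duplication history a
#' species' copies sit in different lineages and are far apart; under
#' concerted evolution they cluster together, giving low scores.
#'
#' @param seg a [Segmentation-class].
#' @param groups a [GroupMap-class].
#' @return A data.frame with columns `cactus`, `nColumns`, `raw`,
#'   `normalized`, `nSpeciesUsed`.
#' @export
discriminationScores <- function(seg, groups) {
    stopifnot(is(seg, "Segmentation"), is(groups, "GroupMap"))
    tab <- asTable(groups)
    multi <- names(which(table(tab$species) >= 2L))
    if (!length(multi))
        stop("no species with >= 2 sequences; the statistic is undefined")
    raw <- vapply(cacti(seg), function(k) {
        mean(vapply(multi,
                    function(sp) as.numeric(withinSpeciesExtreme(k, groups,
                                                                 sp)),
                    numeric(1)), na.rm = TRUE)
    }, numeric(1))
    mx <- max(raw)
    normalized <- if (mx > 0) raw / mx else raw * 0
    data.frame(cactus = seq_along(raw),
               nColumns = vapply(cacti(seg), function(k)
                   length(k@columns), integer(1)),
               raw = raw, normalized = normalized,
               nSpeciesUsed = length(multi))
}

#' Label cacti as duplication-history or concerted-evolution
#'
#' A cactus reflects duplication history when its normalized
#' discrimination score reaches `threshold` (inclusive); otherwise it
#' reflects concerted evolution. Alternatively `topK` labels the `k`
#' highest-scoring cacti as duplication-history regardless of the
#' threshold.
#'
#' @param scores data.frame from [discriminationScores()].
#' @param threshold fraction in `[0, 1]`; default 0.5.
#' @param topK if not `NULL`, label the `topK` highest-raw-score cacti
#'   instead of thresholding.
#' @return `scores` with an added `label` column in
#'   `{duplication, concerted}`.
#' @export
classifyCacti <- function(scores, threshold = 0.5, topK = NULL) {
    stopifnot(is.data.frame(scores), "normalized" %in% names(scores))
    if (is.null(topK)) {
        lab <- ifelse(scores$normalized >= threshold & scores$raw > 0,
                      "duplication", "concerted")
    } else {
        stopifnot(topK >= 1)
        ord <- order(-scores$raw, scores$cactus)
        lab <- rep("concerted", nrow(scores))
        lab[ord[seq_len(min(topK, nrow(scores)))]] <- "duplication"
    }
    scores$label <- lab
    scores
}

#' Columns reflecting duplication history
#'
#' The sorted union (1-based) of the column sets of all
#' duplication-labeled cacti — the candidate diagnostic sites.
#'
#' @param seg a [Segmentation-class].
#' @param labels data.frame from [classifyCacti()].
#' @return Sorted integer vector of 1-based alignment columns (empty
#'   when no cactus is duplication-labeled).
#' @export
diagnosticSites <- function(seg, labels) {
    stopifnot(is(seg, "Segmentation"), is.data.frame(labels),
              all(c("cactus", "label") %in% names(labels)))
    keep <- labels$cactus[labels$label == "duplication"]
    sort(unique(unlist(lapply(cacti(seg)[keep], function(k) k@columns))))
}

#' Discover duplication-history sites end to end
#'
#' Runs [fitPartition()], [discriminationScores()], [classifyCacti()]
#' and [diagnosticSites()] in one call.
#'
#' @param aln a [FamilyAlignment-class].
#' @param groups a [GroupMap-class].
#' @param nIterations,minSegment,switchPenalty passed to
#'   [fitPartition()].
#' @param threshold,topK passed to [classifyCacti()].
#' @return A list with `segmentation`, `scores` (labeled), and `sites`.
#' @export
discoverDiagnosticSites <- function(aln, groups, nIterations = 5L,
                                    minSegment = 10L, switchPenalty = NULL,
                                    threshold = 0.5, topK = NULL) {
    checkGroupsCoverAlignment(groups, aln)
    seg <- fitPartition(aln, nIterations = nIterations,
                        minSegment = minSegment,
                        switchPenalty = switchPenalty)
    scores <- classifyCacti(discriminationScores(seg, groups),
                            threshold = threshold, topK = topK)
    list(segmentation = seg, scores = scores,
         sites = diagnosticSites(seg, scores))
}
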