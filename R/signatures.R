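#' Match sequences against a lineage signature
#'
#' For each sequence, compares the characters at the diagnostic columns
#' with the two lineage-specific variants: `nA` columns match variant A,
#' `nB` match variant B, `nOther` match neither, and gap/`N` columns are
#' labelled `gap` and excluded from all counts. The per-column profile
#' is returned as a string over `{A,B,o,-}` in signature order.
#'
#' @param aln a [FamilyAlignment-class].
#' @param sig a [SignatureTable-class].
#' @param ids sequence ids to screen (default: all).
#' @return A data.frame with columns `id`, `nA`, `nB`, `nOther`, `nGap`,
#'   `profile`.
#' @export
signatureMatches <- function(aln, sig, ids = seqIds(aln)) {
    stopifnot(is(aln, "FamilyAlignment"), is(sig, "SignatureTable"))
    checkSignatureBounds(sig, aln)
    miss <- setdiff(ids, seqIds(aln))
    if (length(miss)) stop("unknown sequence id(s): ",
                           paste(miss, collapse = ", "))
    tb <- asTable(sig)
    m <- alnMatrix(aln)[ids, tb$column, drop = FALSE]
    out <- lapply(seq_along(ids), function(i) {
        x <- m[i, ]
        lab <- ifelse(!(x %in% DNA_BASES), "-",
               ifelse(x == tb$variantA, "A",
               ifelse(x == tb$variantB, "B", "o")))
        data.frame(id = ids[i],
                   nA = sum(lab == "A"), nB = sum(lab == "B"),
                   nOther = sum(lab == "o"), nGap = sum(lab == "-"),
                   profile = paste(lab, collapse = ""),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Call the lineage of screened sequences
#'
#' Classifies each [signatureMatches()] row: lineage `A` (resp. `B`) when
#' that lineage has the majority of matched diagnostic variants and the
#' minority fraction `min(nA, nB) / (nA + nB)` stays below
#' `minorityThreshold`; `intermingled` when the minority fraction
#' reaches the threshold or the counts tie (the footprint of gene
#' conversion mixing the two signatures in one sequence);
#' `uninformative` when no diagnostic column is matched at all.
#'
#' @param match data.frame from [signatureMatches()].
#' @param minorityThreshold fraction in `[0, 0.5]`; default 0.25. The
#'   threshold is inclusive: a minority fraction exactly at it is
#'   called intermingled.
#' @return `match` with added columns `minorityFraction` and `label`.
#' @export
callLineage <- function(match, minorityThreshold = 0.25) {
    stopifnot(is.data.frame(match), all(c("nA", "nB") %in% names(match)),
              minorityThreshold >= 0, minorityThreshold <= 0.5)
    tot <- match$nA + match$nB
    mf <- ifelse(tot > 0, pmin(match$nA, match$nB) / tot, NA_real_)
    label <- ifelse(tot == 0, "uninformative",
             ifelse(match$nA == match$nB | mf >= minorityThreshold,
                    "intermingled",
             ifelse(match$nA > match$nB, "A", "B")))
    match$minorityFraction <- mf
    match$label <- label
    match
}

#' Most lineage-like sequence of a group
#'
#' The group member carrying the most variants of the requested lineage
#' signature. Ties are broken by fewer opposite-lineage matches, then by
#' lexicographically smallest id.
#'
#' @param aln a [FamilyAlignment-class].
#' @param ids ids of the group members.
#' @param sig a [SignatureTable-class].
#' @param lineage `"A"` or `"B"`.
#' @return A single sequence id.
#' @export
mostLineageLike <- function(aln, ids, sig, lineage = c("A", "B")) {
    lineage <- match.arg(lineage)
    sm <- signatureMatches(aln, sig, ids)
    own <- if (lineage == "A") sm$nA else sm$nB
    opp <- if (lineage == "A") sm$nB else sm$nA
    ord <- order(-own, opp, sm$id)
    sm$id[ord[1L]]
}

#' Retained signature divergence within a group
#'
#' The number of signature columns at which the group's most-A-like and
#' most-B-like sequences still differ — the group-level footprint of
#' duplication history surviving concerted evolution. Columns where
#' either pick carries a gap/`N` are excluded. Groups with a single
#' sequence score 0 (both picks coincide).
#'
#' @inheritParams mostLineageLike
#' @return Integer count in `[0, length(sig)]`.
#' @export
signatureRetention <- function(aln, ids, sig) {
    stopifnot(length(ids) >= 1L)
    if (length(ids) == 1L) return(0L)
    a <- mostLineageLike(aln, ids, sig, "A")
    b <- mostLineageLike(aln, ids, sig, "B")
    if (a == b) return(0L)
    cols <- sigColumns(sig)
    m <- alnMatrix(aln)
    x <- m[a, cols]
    y <- m[b, cols]
    ok <- x %in% DNA_BASES & y %in% DNA_BASES
    sum(x[ok] != y[ok])
}

#' Per-sequence intermingling report
#'
#' Screens every sequence against the signature and tabulates, per
#' group, the per-column profile strings and lineage calls plus the
#' group's most-lineage-like picks and retained signature divergence.
#' This is the tabular analog of an alignment figure shading
#' lineage-specific variants.
#'
#' @param aln a [FamilyAlignment-class].
#' @param groups a [GroupMap-class].
#' @param sig a [SignatureTable-class].
#' @param groupBy group sequences by `"group"` (higher group, e.g.
#'   order) or `"species"`.
#' @param minorityThreshold passed to [callLineage()].
#' @return A data.frame sorted by group then id with columns `group`,
#'   `id`, `nA`, `nB`, `nOther`, `nGap`, `profile`, `minorityFraction`,
#'   `label`, `retention` (the group-level retention, repeated within a
#'   group).
#' @export
interminglingReport <- function(aln, groups, sig,
                                groupBy = c("group", "species"),
                                minorityThreshold = 0.25) {
    stopifnot(is(aln, "FamilyAlignment"), is(groups, "GroupMap"),
              is(sig, "SignatureTable"))
    groupBy <- match.arg(groupBy)
    checkGroupsCoverAlignment(groups, aln)
    lab <- if (groupBy == "group") groupOf(groups, seqIds(aln))
           else speciesOf(groups, seqIds(aln))
    calls <- callLineage(signatureMatches(aln, sig), minorityThreshold)
    calls$group <- unname(lab[calls$id])
    ret <- vapply(split(calls$id, calls$group),
                  function(ids) signatureRetention(aln, ids, sig), 0L)
    calls$retention <- ret[calls$group]
    calls <- calls[order(calls$group, calls$id),
                   c("group", "id", "nA", "nB", "nOther", "nGap", "profile",
                     "minorityFraction", "label", "retention")]
    rownames(calls) <- NULL
    calls
}
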