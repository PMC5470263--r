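#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among the columns where neither
#' sequence carries a gap or `N` (pairwise deletion). If no comparable
#' columns exist the distance is `NA`.
#'
#' @param aln a [FamilyAlignment-class].
#' @param i,j sequence ids.
#' @return A proportion in `[0, 1]`, or `NA` if the pair shares no
#'   comparable column.
#' @examples
#' aln <- familyAlignment(c(a = "ACGT", b = "AGGT"))
#' pDistance(aln, "a", "b")  # 0.25
#' @export
pDistance <- function(aln, i, j) {
    stopifnot(is(aln, "FamilyAlignment"))
    m <- alnMatrix(aln)
    miss <- setdiff(c(i, j), rownames(m))
    if (length(miss)) stop("unknown sequence id(s): ",
                           paste(miss, collapse = ", "))
    x <- m[i, ]
    y <- m[j, ]
    comparable <- x %in% DNA_BASES & y %in% DNA_BASES
    if (!any(comparable)) return(NA_real_)
    mean(x[comparable] != y[comparable])
}

#' Uncorrected p-distance matrix
#'
#' All pairwise [pDistance()] values, with pairwise deletion of gap/`N`
#' sites, as a labeled symmetric matrix with zero diagonal.
#'
#' @param aln a [FamilyAlignment-class].
#' @return A symmetric numeric matrix with sequence ids as dimnames;
#'   entries are `NA` for pairs with no comparable columns.
#' @export
pDistanceMatrix <- function(aln) {
    stopifnot(is(aln, "FamilyAlignment"))
    m <- alnMatrix(aln)
    n <- nrow(m)
    ids <- rownames(m)
    ok <- matrix(m %in% DNA_BASES, nrow = n)   # comparable site mask
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    if (n > 1L) for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
        comp <- ok[a, ] & ok[b, ]
        d[a, b] <- d[b, a] <-
            if (any(comp)) mean(m[a, comp] != m[b, comp]) else NA_real_
    }
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei neighbor joining via `ape::nj`, with negative
#' branch-length estimates clamped to zero. Pairs with missing
#' distances are an error; the caller must remove such sequences first.
#'
#' @param d symmetric numeric distance matrix with >= 3 labeled rows.
#' @return An unrooted `ape::phylo` tree whose tip set equals the
#'   matrix labels.
#' @export
neighborJoining <- function(d) {
    stopifnot(is.matrix(d))
    if (nrow(d) < 3L) stop("neighbor joining needs >= 3 sequences")
    if (anyNA(d))
        stop("distance matrix contains missing values; remove sequences ",
             "with no comparable sites before tree building")
    tr <- ape::nj(stats::as.dist(d))
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
}

#' Does a leaf subset form one side of a bipartition?
#'
#' On an unrooted tree, a subset is (reciprocally) monophyletic iff some
#' edge splits the leaves into exactly (subset, complement). Singleton
#' subsets and the full leaf set are trivially monophyletic.
#'
#' @param tree an `ape::phylo`.
#' @param leaves character vector of tip labels.
#' @return `TRUE` or `FALSE`.
#' @export
isMonophyletic <- function(tree, leaves) {
    stopifnot(inherits(tree, "phylo"))
    tips <- tree$tip.label
    miss <- setdiff(leaves, tips)
    if (length(miss)) stop("tips not in tree: ", paste(miss, collapse = ", "))
    leaves <- unique(leaves)
    if (length(leaves) == 0L) stop("empty leaf subset")
    if (length(leaves) %in% c(1L, length(tips) - 1L, length(tips)))
        return(TRUE)
    # bipartition semantics on the unrooted tree: root at a tip outside
    # the subset, then ask for a clade
    out <- setdiff(tips, leaves)[1L]
    rooted <- ape::root(ape::unroot(tree), outgroup = out,
                        resolve.root = TRUE)
    ape::is.monophyletic(rooted, leaves)
}
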