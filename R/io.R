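#' Read an aligned FASTA file
#'
#' Parses an aligned FASTA into a [FamilyAlignment-class]. Characters
#' are uppercased and `U` is mapped to `T`; ambiguity codes other than
#' `N` are rejected so that downstream signature matching can rely on
#' exact single-character comparison. All internal column arithmetic is
#' 0-based half-open; every file format and report uses 1-based
#' inclusive columns, converted only at this I/O boundary.
#'
#' @param path path to a FASTA file.
#' @return A validated [FamilyAlignment-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), f)
#' readAlignment(f)
#' @export
readAlignment <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ss <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("not a readable FASTA file: ",
                                            path, " (", conditionMessage(e),
                                            ")", call. = FALSE))
    if (length(ss) == 0L) stop("empty FASTA file: ", path)
    lens <- Biostrings::width(ss)
    if (length(unique(lens)) != 1L)
        stop("alignment rows differ in length (", paste(sort(unique(lens)),
             collapse = ", "), "): file is not a valid alignment")
    ids <- sub("\\s.*$", "", names(ss))
    familyAlignment(stats::setNames(as.character(ss), ids))
}

#' Write an alignment to FASTA
#'
#' @param aln a [FamilyAlignment-class].
#' @param path output path. Lines are wrapped at 70 characters so that
#'   output is bit-stable across runs.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
    stopifnot(is(aln, "FamilyAlignment"))
    seqs <- apply(alnMatrix(aln), 1L, paste, collapse = "")
    ss <- Biostrings::BStringSet(seqs)
    names(ss) <- seqIds(aln)
    Biostrings::writeXStringSet(ss, path, width = 70L)
    invisible(path)
}

#' Read a sequence-to-species/group mapping table
#'
#' Reads a TSV with header `seq_id`, `species`, `group` and
#' cross-validates it against an alignment: every alignment id must be
#' present exactly once and no extra ids are allowed.
#'
#' @param path path to the TSV file.
#' @param aln the [FamilyAlignment-class] the map refers to.
#' @return A validated [GroupMap-class].
#' @export
readGroups <- function(path, aln) {
    stopifnot(is(aln, "FamilyAlignment"))
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, colClasses = "character", comment.char = "#")
    need <- c("seq_id", "species", "group")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("group map is missing column(s): ", paste(miss, collapse = ", "))
    gm <- groupMap(df$seq_id, df$species, df$group)
    checkGroupsCoverAlignment(gm, aln)
    gm
}

checkGroupsCoverAlignment <- function(gm, aln) {
    absent <- setdiff(seqIds(aln), seqIds(gm))
    extra <- setdiff(seqIds(gm), seqIds(aln))
    if (length(absent) || length(extra))
        stop("group map does not match alignment ids",
             if (length(absent)) paste0("; missing: ",
                                        paste(absent, collapse = ", ")),
             if (length(extra)) paste0("; not in alignment: ",
                                       paste(extra, collapse = ", ")))
    invisible(TRUE)
}

#' Write a group map to TSV
#'
#' @param gm a [GroupMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroups <- function(gm, path) {
    stopifnot(is(gm, "GroupMap"))
    utils::write.table(asTable(gm), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a lineage-signature table
#'
#' Reads a TSV with header `column`, `variantA`, `variantB` listing
#' diagnostic alignment columns (1-based) and the two lineage-specific
#' variants, and validates it against the alignment bounds.
#'
#' @param path path to the TSV file.
#' @param aln the [FamilyAlignment-class] the columns refer to.
#' @return A validated [SignatureTable-class].
#' @export
readSignature <- function(path, aln) {
    stopifnot(is(aln, "FamilyAlignment"))
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, colClasses = "character", comment.char = "#")
    need <- c("column", "variantA", "variantB")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("signature table is missing column(s): ",
             paste(miss, collapse = ", "))
    col <- suppressWarnings(as.numeric(df$column))
    if (anyNA(col) || any(col != round(col)))
        stop("signature 'column' entries must be integers")
    sig <- signatureTable(as.integer(col), df$variantA, df$variantB)
    checkSignatureBounds(sig, aln)
    sig
}

checkSignatureBounds <- function(sig, aln) {
    bad <- sigColumns(sig)[sigColumns(sig) > nCols(aln)]
    if (length(bad))
        stop("signature column(s) beyond alignment end (",
             nCols(aln), " columns): ", paste(bad, collapse = ", "))
    invisible(TRUE)
}

#' @rdname readSignature
#' @param sig a [SignatureTable-class].
#' @export
writeSignature <- function(sig, path) {
    stopifnot(is(sig, "SignatureTable"))
    utils::write.table(asTable(sig), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Newick serialization of trees
#'
#' Thin wrappers around ape's newick reader/writer so that the whole
#' pipeline round-trips trees through text: topology, tip labels, and
#' branch lengths (to print precision) survive `readNewick(writeNewick(t))`.
#'
#' @param tree an `ape::phylo` tree.
#' @return `writeNewick` returns a single newick string; `readNewick`
#'   returns an `ape::phylo`.
#' @examples
#' t <- readNewick("(A:1,B:1);")
#' writeNewick(t)
#' @export
writeNewick <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    ape::write.tree(tree, digits = 10)
}

#' @rdname writeNewick
#' @param text a newick string (or path handled by `ape::read.tree` when
#'   `text` looks like a file path ending in `.nwk`/`.tree`/`.txt`).
#' @export
readNewick <- function(text) {
    tr <- if (length(text) == 1L && file.exists(text) &&
              !grepl("[();]", text)) {
        ape::read.tree(text)
    } else {
        ape::read.tree(text = text)
    }
    if (is.null(tr)) stop("malformed newick string")
    tr
}

#' Write a distance matrix as labeled square TSV
#'
#' @param d symmetric numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
    stopifnot(is.matrix(d), !is.null(rownames(d)))
    df <- data.frame(id = rownames(d), d, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a report TSV with a provenance header
#'
#' Reports carry a comment line naming the package version and the seed
#' used, then a plain TSV table.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed seed to record in the header (NA if the computation was
#'   deterministic).
#' @return `path`, invisibly.
#' @export
writeReport <- function(df, path, seed = NA) {
    ver <- as.character(utils::packageVersion("duphist"))
    writeLines(sprintf("# duphist %s seed=%s", ver, seed), path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    invisible(path)
}

#' Subset an alignment by sequence ids
#'
#' @param aln a [FamilyAlignment-class].
#' @param ids ids to keep, in the given order.
#' @return A [FamilyAlignment-class] restricted to `ids`.
#' @export
subsetAlignment <- function(aln, ids) {
    stopifnot(is(aln, "FamilyAlignment"))
    miss <- setdiff(ids, seqIds(aln))
    if (length(miss)) stop("ids not in alignment: ",
                           paste(miss, collapse = ", "))
    new("FamilyAlignment", seqs = alnMatrix(aln)[ids, , drop = FALSE])
}
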