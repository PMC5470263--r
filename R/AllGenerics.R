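#' Accessors for duphist classes
#'
#' @param x an object.
#' @name accessors
NULL

#' @describeIn accessors number of alignment columns.
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' @describeIn accessors number of sequences.
#' @export
setGeneric("nSeqs", function(x) standardGeneric("nSeqs"))

#' @describeIn accessors sequence identifiers, in alignment order.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @describeIn accessors alignment as a character matrix.
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))

#' @describeIn accessors group map / signature table as a data.frame.
#' @export
setGeneric("asTable", function(x) standardGeneric("asTable"))

#' @describeIn accessors species label per sequence id.
#' @param ids sequence ids to look up.
#' @export
setGeneric("speciesOf", function(x, ids) standardGeneric("speciesOf"))

#' @describeIn accessors higher-group label per sequence id.
#' @export
setGeneric("groupOf", function(x, ids) standardGeneric("groupOf"))

#' @describeIn accessors diagnostic columns of a signature (1-based).
#' @export
setGeneric("sigColumns", function(x) standardGeneric("sigColumns"))

#' @describeIn accessors the cacti of a segmentation (list of Cactus).
#' @export
setGeneric("cacti", function(x) standardGeneric("cacti"))

#' @describeIn accessors per-column cactus assignment over all columns.
#' @export
setGeneric("columnPath", function(x) standardGeneric("columnPath"))

#' @describeIn accessors true lineage labels of a simulation.
#' @export
setGeneric("trueLineage", function(x) standardGeneric("trueLineage"))

setMethod("nCols", "FamilyAlignment", function(x) ncol(x@seqs))
setMethod("nSeqs", "FamilyAlignment", function(x) nrow(x@seqs))
setMethod("seqIds", "FamilyAlignment", function(x) rownames(x@seqs))
setMethod("alnMatrix", "FamilyAlignment", function(x) x@seqs)

setMethod("asTable", "GroupMap", function(x) x@map)
setMethod("asTable", "SignatureTable", function(x) x@table)
setMethod("seqIds", "GroupMap", function(x) x@map$seq_id)

setMethod("speciesOf", "GroupMap", function(x, ids) {
    i <- match(ids, x@map$seq_id)
    if (anyNA(i))
        stop("ids not in group map: ", paste(ids[is.na(i)], collapse = ", "))
    stats::setNames(x@map$species[i], ids)
})

setMethod("groupOf", "GroupMap", function(x, ids) {
    i <- match(ids, x@map$seq_id)
    if (anyNA(i))
        stop("ids not in group map: ", paste(ids[is.na(i)], collapse = ", "))
    stats::setNames(x@map$group[i], ids)
})

setMethod("sigColumns", "SignatureTable", function(x) x@table$column)
setMethod("length", "SignatureTable", function(x) nrow(x@table))

setMethod("cacti", "Segmentation", function(x) x@cacti)
setMethod("columnPath", "Segmentation", function(x) x@fullPath)
setMethod("length", "Segmentation", function(x) length(x@cacti))

setMethod("trueLineage", "SimTruth", function(x) x@lineage)

setMethod("show", "FamilyAlignment", function(object) {
    cat("FamilyAlignment:", nSeqs(object), "sequences x",
        nCols(object), "columns\n")
    ids <- seqIds(object)
    k <- min(5L, length(ids))
    for (i in seq_len(k)) {
        s <- paste(object@seqs[i, seq_len(min(40L, nCols(object)))],
                   collapse = "")
        cat(sprintf("  %-15s %s%s\n", ids[i], s,
                    if (nCols(object) > 40L) "..." else ""))
    }
    if (length(ids) > k) cat("  ...", length(ids) - k, "more\n")
})

setMethod("show", "GroupMap", function(object) {
    cat("GroupMap:", nrow(object@map), "sequences,",
        length(unique(object@map$species)), "species,",
        length(unique(object@map$group)), "groups\n")
})

setMethod("show", "SignatureTable", function(object) {
    cat("SignatureTable:", nrow(object@table), "diagnostic columns (",
        paste(range(object@table$column), collapse = "-"), ")\n")
})

setMethod("show", "Cactus", function(object) {
    cat("Cactus:", length(object@columns), "columns,",
        nrow(object@matrix), "sequences; mean distance",
        format(mean(object@matrix[upper.tri(object@matrix)]), digits = 3), "\n")
})

setMethod("show", "Segmentation", function(object) {
    cat("Segmentation:", length(object@cacti), "cacti over",
        length(object@analyzedColumns), "variable columns (",
        length(object@fullPath), "total ); switch penalty",
        format(object@switchPenalty, digits = 3), "; total cost",
        format(object@totalCost, digits = 4), "\n")
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: %d species, %d columns, %d diagnostic;",
                       " subRate=%g convRate=%g tractMean=%g dropoutP=%g",
                       " treeHeight=%g seed=%d\n"),
                object@nSpecies, object@seqLen, object@kDiag, object@subRate,
                object@convRate, object@tractMean, object@dropoutP,
                object@treeHeight, object@seed))
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@lineage), "sequences,",
        nrow(object@diagnosticColumns@table), "diagnostic columns,",
        nrow(object@events), "logged events\n")
})
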