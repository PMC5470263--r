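#' @import methods
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")
DNA_BASES <- c("A", "C", "G", "T")

#' Multigene-family alignment
#'
#' A fixed-length multiple sequence alignment of gene-family members,
#' stored as a character matrix over the alphabet `A,C,G,T,-,N` with one
#' row per sequence. Rows are named by unique sequence identifiers.
#' Construct with [familyAlignment()] or read from FASTA with
#' [readAlignment()].
#'
#' @slot seqs character matrix, rows = sequences (rownames are the ids),
#'   columns = alignment columns.
#' @exportClass FamilyAlignment
setClass("FamilyAlignment", representation(seqs = "matrix"))

setValidity("FamilyAlignment", function(object) {
    m <- object@seqs
    if (!is.character(m)) return("'seqs' must be a character matrix")
    if (ncol(m) < 1L) return("alignment must have at least one column")
    if (nrow(m) < 1L) return("alignment must contain at least one sequence")
    ids <- rownames(m)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        return("all sequences must have non-empty ids")
    if (anyDuplicated(ids))
        return(paste0("duplicate sequence ids: ",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    bad <- setdiff(unique(as.vector(m)), ALN_ALPHABET)
    if (length(bad))
        return(paste0("invalid characters in alignment (only A,C,G,T,-,N ",
                      "are allowed): ", paste(bad, collapse = ", ")))
    TRUE
})

#' Construct a FamilyAlignment
#'
#' @param seqs named character vector of equal-length sequence strings, or
#'   a character matrix with one row per sequence (rownames = ids).
#' @return A [FamilyAlignment-class] object.
#' @examples
#' aln <- familyAlignment(c(s1 = "ACGT", s2 = "ACGA"))
#' nCols(aln)
#' @export
familyAlignment <- function(seqs) {
    if (is.matrix(seqs)) {
        m <- seqs
    } else {
        if (is.null(names(seqs)))
            stop("sequences must be named")
        lens <- nchar(seqs)
        if (length(unique(lens)) != 1L)
            stop("alignment rows differ in length: ",
                 paste(unique(lens), collapse = " vs "))
        m <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
        rownames(m) <- names(seqs)
    }
    m[] <- toupper(m)
    m[m == "U"] <- "T"
    new("FamilyAlignment", seqs = m)
}

#' Species / higher-group labels for alignment sequences
#'
#' Maps every sequence id of an alignment to a species label and a
#' higher-group label (e.g. taxonomic order). Read from TSV with
#' [readGroups()].
#'
#' @slot map data.frame with columns `seq_id`, `species`, `group`.
#' @exportClass GroupMap
setClass("GroupMap", representation(map = "data.frame"))

setValidity("GroupMap", function(object) {
    df <- object@map
    need <- c("seq_id", "species", "group")
    if (!all(need %in% names(df)))
        return(paste("group map must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(df$seq_id))
        return("duplicate seq_id entries in group map")
    if (any(!nzchar(df$seq_id)) || any(!nzchar(df$species)) ||
        any(!nzchar(df$group)) || anyNA(df))
        return("group map labels must be non-empty")
    TRUE
})

#' @rdname GroupMap-class
#' @param seq_id,species,group character vectors of equal length.
#' @return A [GroupMap-class] object.
#' @export
groupMap <- function(seq_id, species, group) {
    new("GroupMap", map = data.frame(seq_id = as.character(seq_id),
                                     species = as.character(species),
                                     group = as.character(group),
                                     stringsAsFactors = FALSE))
}

#' Table of lineage-diagnostic alignment columns
#'
#' An ordered set of diagnostic columns, each carrying the two
#' lineage-specific variants (the variant fixed in lineage A and the one
#' fixed in lineage B). This is the container for signature tables such
#' as a 16-site diagnostic signature of two anciently duplicated MHC
#' class IIB lineages. Columns are 1-based alignment coordinates.
#'
#' @slot table data.frame with columns `column` (integer, 1-based,
#'   strictly increasing), `variantA`, `variantB` (single bases, unequal
#'   within each row).
#' @exportClass SignatureTable
setClass("SignatureTable", representation(table = "data.frame"))

setValidity("SignatureTable", function(object) {
    df <- object@table
    need <- c("column", "variantA", "variantB")
    if (!all(need %in% names(df)))
        return(paste("signature table must have columns",
                     paste(need, collapse = ", ")))
    if (nrow(df) == 0L) return("signature table must have at least one row")
    if (any(df$column < 1L) || any(df$column != as.integer(df$column)))
        return("signature columns must be positive integers (1-based)")
    if (is.unsorted(df$column, strictly = TRUE))
        return("signature columns must be strictly increasing")
    ok <- function(x) is.character(x) & nchar(x) == 1L & x %in% DNA_BASES
    if (!all(ok(df$variantA)) || !all(ok(df$variantB)))
        return("signature variants must be single bases in {A,C,G,T}")
    if (any(df$variantA == df$variantB))
        return("variantA and variantB must differ at every signature row")
    TRUE
})

#' @rdname SignatureTable-class
#' @param column integer vector of 1-based alignment columns.
#' @param variantA,variantB single-base variants fixed in lineage A / B.
#' @return A [SignatureTable-class] object.
#' @export
signatureTable <- function(column, variantA, variantB) {
    new("SignatureTable",
        table = data.frame(column = as.integer(column),
                           variantA = toupper(as.character(variantA)),
                           variantB = toupper(as.character(variantB)),
                           stringsAsFactors = FALSE))
}

#' A local phylogenetic class ("cactus")
#'
#' A cactus summarizes the local phylogenetic relationships of a set of
#' alignment columns as the mean of their 0/1 pairwise difference
#' matrices over all sequences (itself a distance in `[0, 1]`),
#' together with the set of columns assigned to it.
#'
#' @slot matrix symmetric numeric matrix (zero diagonal) with sequence
#'   ids as dimnames; entries in `[0, 1]`.
#' @slot columns integer vector of 1-based alignment columns assigned to
#'   this cactus.
#' @exportClass Cactus
setClass("Cactus",
         representation(matrix = "matrix", columns = "integer"))

setValidity("Cactus", function(object) {
    m <- object@matrix
    if (!is.numeric(m) || nrow(m) != ncol(m))
        return("cactus matrix must be square numeric")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        return("cactus matrix must carry identical row/col sequence ids")
    if (any(abs(m - t(m)) > 1e-12, na.rm = TRUE))
        return("cactus matrix must be symmetric")
    if (any(abs(diag(m)) > 1e-12)) return("cactus matrix diagonal must be zero")
    TRUE
})

#' Segmentation of alignment columns into cacti
#'
#' Result of [fitPartition()]: a set of cacti, the per-column state path
#' over the analyzed (variable) columns, and the path extended to every
#' alignment column. Monomorphic columns carry no signal and are
#' assigned the state of the nearest analyzed column.
#'
#' @slot cacti list of [Cactus-class] objects.
#' @slot path integer vector: cactus index per analyzed column.
#' @slot analyzedColumns integer vector of 1-based variable columns.
#' @slot fullPath integer vector: cactus index per alignment column.
#' @slot switchPenalty numeric cost per state change used by the Viterbi
#'   assignment.
#' @slot nIterations integer, number of cactus proposals attempted.
#' @slot totalCost numeric, final total path cost.
#' @exportClass Segmentation
setClass("Segmentation",
         representation(cacti = "list", path = "integer",
                        analyzedColumns = "integer", fullPath = "integer",
                        switchPenalty = "numeric", nIterations = "integer",
                        totalCost = "numeric"))

setValidity("Segmentation", function(object) {
    if (length(object@path) != length(object@analyzedColumns))
        return("path length must equal the number of analyzed columns")
    if (!length(object@cacti)) return("segmentation must retain >= 1 cactus")
    if (!all(vapply(object@cacti, is, logical(1), "Cactus")))
        return("'cacti' must be a list of Cactus objects")
    cols <- sort(unlist(lapply(object@cacti, function(k) k@columns)))
    if (!identical(cols, sort(object@analyzedColumns)))
        return("cactus columns must partition the analyzed column set")
    TRUE
})

#' Simulation configuration
#'
#' Parameters of the forward simulator of a two-lineage gene family
#' evolving along a species tree under gene conversion (see
#' [simulateFamily()]). Rates are per unit branch length; the tree is
#' rescaled so the root-to-tip depth equals `treeHeight`.
#'
#' @slot nSpecies number of species (>= 2).
#' @slot seqLen number of alignment columns.
#' @slot kDiag number of lineage-diagnostic columns (<= seqLen).
#' @slot subRate substitutions per site per unit branch length.
#' @slot convRate expected gene-conversion events per gene copy per unit
#'   branch length.
#' @slot tractMean mean conversion tract length (geometric).
#' @slot dropoutP per-species probability of losing one lineage.
#' @slot treeHeight root-to-tip depth of the species tree.
#' @slot erodeBySubstitution if TRUE, diagnostic columns are not
#'   protected from substitution.
#' @slot seed RNG seed driving every stochastic step.
#' @exportClass SimConfig
setClass("SimConfig",
         representation(nSpecies = "integer", seqLen = "integer",
                        kDiag = "integer", subRate = "numeric",
                        convRate = "numeric", tractMean = "numeric",
                        dropoutP = "numeric", treeHeight = "numeric",
                        erodeBySubstitution = "logical", seed = "integer"))

setValidity("SimConfig", function(object) {
    if (object@nSpecies < 2L) return("nSpecies must be >= 2")
    if (object@seqLen < 1L) return("seqLen must be >= 1")
    if (object@kDiag < 0L || object@kDiag > object@seqLen)
        return("kDiag must lie in [0, seqLen]")
    if (object@subRate < 0 || object@convRate < 0)
        return("rates must be >= 0")
    if (object@tractMean < 1) return("tractMean must be >= 1")
    if (object@dropoutP < 0 || object@dropoutP > 1)
        return("dropoutP must lie in [0, 1]")
    if (object@treeHeight <= 0) return("treeHeight must be > 0")
    TRUE
})

#' @rdname SimConfig-class
#' @param nSpecies,seqLen,kDiag,subRate,convRate,tractMean,dropoutP,treeHeight,erodeBySubstitution,seed
#'   see the class slots.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSpecies = 6, seqLen = 120, kDiag = 8, seed = 1)
#' @export
simConfig <- function(nSpecies = 20L, seqLen = 300L, kDiag = 16L,
                      subRate = 0.025, convRate = 0, tractMean = 50,
                      dropoutP = 0, treeHeight = 1,
                      erodeBySubstitution = FALSE, seed = 1L) {
    new("SimConfig", nSpecies = as.integer(nSpecies),
        seqLen = as.integer(seqLen), kDiag = as.integer(kDiag),
        subRate = as.numeric(subRate), convRate = as.numeric(convRate),
        tractMean = as.numeric(tractMean), dropoutP = as.numeric(dropoutP),
        treeHeight = as.numeric(treeHeight),
        erodeBySubstitution = isTRUE(erodeBySubstitution),
        seed = as.integer(seed))
}

#' Ground truth of a simulated gene family
#'
#' Records what the simulator actually did: the true lineage (A or B) of
#' every surviving sequence, the true diagnostic columns with their
#' founder variants, the founder sequences at the root, and the full
#' event log (substitutions and conversion tracts per branch and copy),
#' sufficient to replay the simulation exactly.
#'
#' @slot lineage named character vector, `A`/`B` per sequence id.
#' @slot diagnosticColumns [SignatureTable-class] of the true diagnostic
#'   columns and founder variants.
#' @slot events data.frame log with columns `edge`, `copy`, `type`
#'   (`sub`/`conv`), `pos`, `base`, `start`, `end`, `donor` in
#'   application order.
#' @slot founder named list with elements `A` and `B`: the two root
#'   sequences as character vectors.
#' @slot tree the species tree (`ape::phylo`).
#' @slot config the [SimConfig-class] used.
#' @exportClass SimTruth
setClass("SimTruth",
         representation(lineage = "character",
                        diagnosticColumns = "SignatureTable",
                        events = "data.frame", founder = "list",
                        tree = "ANY", config = "SimConfig"))
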