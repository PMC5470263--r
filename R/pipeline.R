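#' Read a pipeline configuration (YAML or JSON)
#'
#' Keys may be given in snake_case (`n_species`, `conv_rate`, ...) or
#' camelCase; unknown keys are an error so typos cannot silently fall
#' back to defaults.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return A named list of configuration values.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                            simplifyVector = TRUE)
           else yaml::read_yaml(path)
    if (!is.list(cfg)) stop("config must be a mapping")
    names(cfg) <- snakeToCamel(names(cfg))
    known <- c("nSpecies", "seqLen", "kDiag", "subRate", "convRate",
               "tractMean", "dropoutP", "treeHeight",
               "erodeBySubstitution", "seed", "convRates", "nReps",
               "nIterations", "minSegment", "switchPenalty", "threshold",
               "minorityThreshold", "groupBy")
    bad <- setdiff(names(cfg), known)
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg
}

snakeToCamel <- function(x) {
    gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
}

simConfigFromList <- function(cfg) {
    keep <- intersect(names(cfg),
                      names(formals(simConfig)))
    do.call(simConfig, cfg[keep])
}

#' Erosion recovery experiment
#'
#' The quantitative restatement of "concerted evolution erodes the
#' footprints of duplication": for each replicate and each gene
#' conversion rate, simulate a family, then measure (i) precision and
#' recall of the discovered duplication-history sites against the true
#' diagnostic columns, (ii) median per-species signature retention,
#' (iii) lineage-call accuracy of the signature screen, (iv) reciprocal
#' monophyly of the two true lineages on a neighbor-joining tree of
#' uncorrected p-distances, and (v) the fraction of two-copy species
#' whose paralogs are mutual nearest neighbors (the concerted-evolution
#' topology class). Returns per-replicate rows plus per-rate medians.
#'
#' @param baseConfig a [SimConfig-class] providing all parameters other
#'   than the conversion rate and seed.
#' @param convRates conversion rates to sweep.
#' @param nReps replicates per rate (>= 1).
#' @param seed master seed; per-run seeds are drawn from it.
#' @param nIterations,minSegment,threshold passed to
#'   [discoverDiagnosticSites()].
#' @param outDir if not `NULL`, write `replicates.tsv`, `summary.tsv`
#'   and `resolved_config.yaml` there.
#' @return A list with data.frames `replicates` and `summary`.
#' @export
runRecoveryExperiment <- function(baseConfig = simConfig(),
                                  convRates = c(0, 0.2, 1, 5),
                                  nReps = 20L, seed = 1L,
                                  nIterations = 5L, minSegment = 10L,
                                  threshold = 0.5, outDir = NULL) {
    stopifnot(is(baseConfig, "SimConfig"))
    if (nReps < 1L) stop("nReps must be >= 1")
    set.seed(seed)
    runSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  length(convRates) * nReps),
                       nrow = nReps)
    rows <- list()
    for (ri in seq_along(convRates)) {
        for (rep in seq_len(nReps)) {
            cfg <- baseConfig
            cfg@convRate <- convRates[ri]
            cfg@seed <- runSeeds[rep, ri]
            rows[[length(rows) + 1L]] <-
                cbind(convRate = convRates[ri], rep = rep,
                      seed = cfg@seed,
                      recoveryMetrics(cfg, nIterations, minSegment,
                                      threshold))
        }
    }
    reps <- do.call(rbind, rows)
    med <- function(x) stats::median(x, na.rm = TRUE)
    summary <- do.call(rbind, lapply(split(reps, reps$convRate), function(d) {
        data.frame(convRate = d$convRate[1L],
                   nReps = nrow(d),
                   medianPrecision = med(d$precision),
                   medianRecall = med(d$recall),
                   medianRetention = med(d$retention),
                   medianCallAccuracy = med(d$callAccuracy),
                   monophylyRate = mean(d$reciprocalMonophyly),
                   medianParalogNN = med(d$paralogNearestNeighbor))
    }))
    summary <- summary[order(summary$convRate), ]
    rownames(summary) <- NULL
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeReport(reps, file.path(outDir, "replicates.tsv"), seed = seed)
        writeReport(summary, file.path(outDir, "summary.tsv"), seed = seed)
        yaml::write_yaml(list(nSpecies = baseConfig@nSpecies,
                              seqLen = baseConfig@seqLen,
                              kDiag = baseConfig@kDiag,
                              subRate = baseConfig@subRate,
                              tractMean = baseConfig@tractMean,
                              dropoutP = baseConfig@dropoutP,
                              treeHeight = baseConfig@treeHeight,
                              convRates = convRates, nReps = nReps,
                              seed = seed, nIterations = nIterations,
                              minSegment = minSegment,
                              threshold = threshold),
                         file.path(outDir, "resolved_config.yaml"))
    }
    list(replicates = reps, summary = summary)
}

# one simulate -> screen -> discover -> tree-check replicate
recoveryMetrics <- function(cfg, nIterations, minSegment, threshold) {
    fam <- simulateFamily(cfg)
    aln <- fam$alignment
    truth <- fam$truth
    trueCols <- sigColumns(truth@diagnosticColumns)

    ret <- stats::median(signatureRetentionTruth(aln, truth))

    calls <- callLineage(signatureMatches(aln, fam$signature))
    acc <- mean(calls$label == trueLineage(truth)[calls$id])

    disc <- discoverDiagnosticSites(aln, fam$groups,
                                    nIterations = nIterations,
                                    minSegment = minSegment,
                                    threshold = threshold)
    hits <- length(intersect(disc$sites, trueCols))
    precision <- if (length(disc$sites)) hits / length(disc$sites)
                 else NA_real_
    recall <- hits / length(trueCols)

    d <- pDistanceMatrix(aln)
    lin <- trueLineage(truth)
    idsA <- names(lin)[lin == "A"]
    idsB <- names(lin)[lin == "B"]
    mono <- if (nrow(d) >= 3L && length(idsA) >= 1L && length(idsB) >= 1L &&
                !anyNA(d)) {
        tr <- neighborJoining(d)
        isMonophyletic(tr, idsA) && isMonophyletic(tr, idsB)
    } else NA
    nn <- paralogNearestNeighborRate(d, seqIds(aln))

    data.frame(precision = precision, recall = recall, retention = ret,
               callAccuracy = acc, reciprocalMonophyly = mono,
               paralogNearestNeighbor = nn, nSites = length(disc$sites))
}

# fraction of two-copy species whose two paralogs are each other's
# nearest neighbor in the distance matrix; ties count (under strong
# homogenization many distances collapse to zero)
paralogNearestNeighborRate <- function(d, ids) {
    sp <- sub("_[AB]$", "", ids)
    two <- names(which(table(sp) == 2L))
    if (!length(two)) return(NA_real_)
    eps <- 1e-12
    hit <- vapply(two, function(s) {
        pair <- ids[sp == s]
        dd <- d
        diag(dd) <- Inf
        dd[pair[1L], pair[2L]] <= min(dd[pair[1L], ]) + eps &&
            dd[pair[2L], pair[1L]] <= min(dd[pair[2L], ]) + eps
    }, logical(1))
    mean(hit)
}
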