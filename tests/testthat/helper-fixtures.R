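# Small builders shared across the test files.

mkNet <- function(..., genes = NULL) {
    pairs <- list(...)
    if (!length(pairs)) return(geneNetwork(NULL, genes = genes))
    geneNetwork(do.call(rbind, pairs), genes = genes)
}

mkAnn <- function(..., universe = NULL) {
    annotationSet(list(...), universe = universe)
}

# Exhaustive oracle for average precision: walk the ranking, accumulate
# precision at every hit.  Independent of the package implementation.
apOracle <- function(ranking, positives) {
    hits <- 0
    total <- 0
    for (r in seq_along(ranking)) {
        if (ranking[r] %in% positives) {
            hits <- hits + 1
            total <- total + hits / r
        }
    }
    total / length(positives)
}

# MAP null distribution for an APTable's structure: mean over groups of
# independent fold-matched random-ranking APs (analytic combination of the
# per-group calibrations already carried by the table).
nullMapStats <- function(aptable) netcrit:::.nullMapStats(aptable)

# Row index of a critical edge in a scan's edge matrix.
crit_edge_index <- function(cm, crit) {
    which(cm@edges[, 1] == crit$gene_a[1] & cm@edges[, 2] == crit$gene_b[1])
}
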