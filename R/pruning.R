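#' Prune a network by node degree
#'
#' Edges touching high-degree genes (hubs) are preferentially free of
#' specific functional information, so pruning privileges connections of
#' low-degree genes.  Each edge gets a badness score from the degrees of its
#' endpoints \emph{in the original network} (static ordering: degrees are
#' not recomputed during removal); the highest-badness edges are removed
#' until \code{ceiling(keep_fraction * |E|)} remain.  Ties are broken by the
#' smaller endpoint degree, then lexicographically.  The node set is
#' unchanged.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param keep_fraction fraction of edges to keep, in (0, 1].
#' @param badness how endpoint degrees combine: \code{"max"} (default),
#'   \code{"min"} or \code{"sum"}.
#' @return the pruned \linkS4class{GeneNetwork}.
#' @export
pruneByDegree <- function(network, keep_fraction,
                          badness = c("max", "min", "sum")) {
    badness <- match.arg(badness)
    if (keep_fraction <= 0 || keep_fraction > 1)
        stop("keep_fraction must be in (0, 1]")
    m <- numEdges(network)
    if (m == 0L) return(network)
    deg <- nodeDegrees(network)
    da <- deg[network@edges[, 1]]
    db <- deg[network@edges[, 2]]
    bad <- switch(badness,
                  max = pmax(da, db),
                  min = pmin(da, db),
                  sum = da + db)
    n_keep <- as.integer(ceiling(keep_fraction * m))
    o <- order(bad, pmin(da, db), network@edges[, 1], network@edges[, 2],
               method = "radix")
    keep_rows <- sort.int(o[seq_len(n_keep)])
    new("GeneNetwork", genes = network@genes,
        edges = network@edges[keep_rows, , drop = FALSE],
        droppedSelfLoops = 0L)
}

#' Degree-distribution profile with a power-law diagnostic
#'
#' Reports per-gene degrees, the degree histogram and the mean degree,
#' together with a visualization-grade power-law fit: ordinary least squares
#' of \code{log(count)} on \code{log(degree)} over positive degrees with at
#' least one gene.  Networks whose degree distribution has a heavy tail show
#' a clearly negative slope with a reasonable fit; networks with a
#' characteristic scale do not.  The fit is flagged degenerate when fewer
#' than 3 distinct positive degrees are observed (e.g. k-regular graphs).
#' This is a qualitative diagnostic, not a maximum-likelihood tail estimate.
#'
#' @param network a nonempty \linkS4class{GeneNetwork}.
#' @return a \linkS4class{DegreeProfile}.
#' @export
degreeProfile <- function(network) {
    if (numGenes(network) == 0L) stop("empty network")
    deg <- nodeDegrees(network)
    tab <- table(deg)
    hist <- data.frame(degree = as.integer(names(tab)),
                       count = as.integer(tab))
    pos <- hist[hist$degree > 0, , drop = FALSE]
    degenerate <- nrow(pos) < 3
    slope <- r2 <- NA_real_
    if (!degenerate) {
        fit <- stats::lm(log(count) ~ log(degree), data = pos)
        slope <- unname(stats::coef(fit)[2])
        r2 <- summary(fit)$r.squared
    }
    new("DegreeProfile", degrees = deg, histogram = hist,
        slope = slope, r_squared = r2,
        mean_degree = mean(deg), degenerate = degenerate)
}

setMethod("show", "DegreeProfile", function(object) {
    cat(sprintf("DegreeProfile: %d genes, mean degree %.2f\n",
                length(object@degrees), object@mean_degree))
    if (object@degenerate) {
        cat("  power-law fit: degenerate (fewer than 3 distinct degrees)\n")
    } else {
        cat(sprintf("  log-log fit: slope %.2f (R^2 = %.2f)\n",
                    object@slope, object@r_squared))
    }
    invisible(NULL)
})

#' Concordance of gene predictions before and after pruning
#'
#' Compares the per-gene voting scores of two evaluations (typically the
#' full and the pruned network) on the same groups and universe: per-group
#' Spearman rank correlation, a pooled mean, and a decile summary of rank
#' displacement (genes are binned by their rank in the baseline; the mean
#' rank in the other evaluation is reported per bin).  Both APTables must
#' have been produced with \code{keep_scores = TRUE}.  Groups missing from
#' either table, or with constant scores, are skipped with a message.
#'
#' @param baseline,pruned \linkS4class{APTable} objects carrying score
#'   matrices over the same gene universe.
#' @return list with \code{per_group} (data.frame \code{group_id},
#'   \code{spearman}), \code{pooled} (mean Spearman over usable groups) and
#'   \code{deciles} (data.frame \code{decile}, \code{mean_baseline_rank},
#'   \code{mean_other_rank}, \code{mean_displacement}, averaged over
#'   groups; rank 1 = best).
#' @export
rankConcordance <- function(baseline, pruned) {
    sb <- baseline@scores
    sp <- pruned@scores
    if (!length(sb) || !length(sp))
        stop("both evaluations must be run with keep_scores = TRUE")
    if (!identical(rownames(sb), rownames(sp)))
        stop("evaluations use different gene universes")
    common <- intersect(colnames(sb), colnames(sp))
    missing <- setdiff(union(colnames(sb), colnames(sp)), common)
    if (length(missing))
        message("rankConcordance: skipping group(s) missing in one table: ",
                paste(missing, collapse = ", "))
    rho <- rep(NA_real_, length(common))
    n <- nrow(sb)
    dec_base <- matrix(NA_real_, length(common), 10)
    dec_other <- matrix(NA_real_, length(common), 10)
    for (i in seq_along(common)) {
        x <- sb[, common[i]]
        y <- sp[, common[i]]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        rx <- rank(-x, ties.method = "average")
        ry <- rank(-y, ties.method = "average")
        rho[i] <- stats::cor(rx, ry)
        dec <- ceiling(10 * rx / n)
        dec[dec < 1] <- 1
        dec_base[i, ] <- tapply(rx, factor(dec, levels = 1:10), mean)
        dec_other[i, ] <- tapply(ry, factor(dec, levels = 1:10), mean)
    }
    usable <- !is.na(rho)
    if (any(!usable))
        message(sprintf("rankConcordance: %d group(s) with constant scores skipped",
                        sum(!usable)))
    deciles <- data.frame(
        decile = 1:10,
        mean_baseline_rank = colMeans(dec_base[usable, , drop = FALSE],
                                      na.rm = TRUE),
        mean_other_rank = colMeans(dec_other[usable, , drop = FALSE],
                                   na.rm = TRUE))
    deciles$mean_displacement <- deciles$mean_other_rank -
        deciles$mean_baseline_rank
    list(per_group = data.frame(group_id = common, spearman = rho,
                                stringsAsFactors = FALSE),
         pooled = mean(rho[usable]),
         deciles = deciles)
}
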