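# Per-group null calibration shared by evaluateNetwork and edgeRemovalScan.
.groupNulls <- function(pr, cfg) {
    ng <- length(pr$scored)
    null_mean <- rep(NA_real_, ng)
    null_sd <- rep(NA_real_, ng)
    cache <- new.env(parent = emptyenv())
    sidx <- which(pr$scored)
    for (i in seq_along(sidx)) {
        sizes <- tabulate(pr$folds[[i]] + 1L, nbins = cfg@n_folds)
        sizes <- sizes[sizes > 0]
        aps0 <- .foldedNullCached(sizes, pr$n, cfg@null_reps, cfg@seed,
                                  cache)
        null_mean[sidx[i]] <- mean(aps0)
        null_sd[sidx[i]] <- stats::sd(aps0)
    }
    list(mean = null_mean, sd = null_sd)
}

#' Fractional effect of removing an edge
#'
#' The effect of an edge on a learnable group is the drop in AP caused by its
#' removal, as a fraction of the group's above-null performance:
#' \deqn{effect = (AP_{full} - AP_{removed}) / (AP_{full} - null)}
#' The raw effect exceeds 1 when removal drops performance below the level
#' expected by chance; the capped effect fixes the maximum at 100\%.
#'
#' @param ap_full baseline AP (must exceed \code{null_mean}: the group must
#'   be learnable for the fraction to be meaningful).
#' @param ap_removed AP of the network missing the edge (same folds and
#'   tie-break seed).
#' @param null_mean null mean AP for the matching (k, n) protocol.
#' @return list with \code{effect_raw} and \code{effect_capped}
#'   (\code{= min(effect_raw, 1)}); vectorized over \code{ap_removed}.
#' @export
edgeEffect <- function(ap_full, ap_removed, null_mean) {
    if (any(ap_full <= null_mean))
        stop("group not learnable (ap_full <= null_mean): no effect defined")
    raw <- (ap_full - ap_removed) / (ap_full - null_mean)
    list(effect_raw = raw, effect_capped = pmin(raw, 1))
}

#' Leave-one-edge-out criticality scan
#'
#' Recomputes the cross-validated AP of every annotation group for every
#' network that differs from \code{network} by one removed edge, under the
#' identical fold assignment and tie-break seed as the baseline (so effects
#' isolate the edge, not cross-validation noise).  A fast path skips
#' (edge, group) cells that provably cannot change (neither endpoint is a
#' member, receives votes for the group, or loses its last connection); the
#' skipped cells equal the naive full recomputation exactly.  Cells are
#' materialized sparsely: only where the removed-edge AP differs from the
#' baseline by more than \code{tol}.
#'
#' By default only learnable groups (AP - null mean >
#' \code{cfg@learnability_delta}) are scanned; fractional effects are
#' meaningless for unlearnable groups.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param ann an \linkS4class{AnnotationSet}.
#' @param cfg a \linkS4class{RunConfig}.
#' @param learnable_only scan only learnable groups (default TRUE).
#' @param tol absolute tolerance below which a cell counts as "no effect".
#' @return a \linkS4class{CriticalityMatrix}.
#' @seealso \code{\link{criticalEdges}}, \code{\link{exceptionalityScores}}
#' @export
edgeRemovalScan <- function(network, ann, cfg = runConfig(),
                            learnable_only = TRUE, tol = 1e-12) {
    stopifnot(is(network, "GeneNetwork"), is(ann, "AnnotationSet"),
              is(cfg, "RunConfig"))
    pr <- .protocol(network, ann, cfg)
    nulls <- .groupNulls(pr, cfg)
    ng <- length(ann@groups)

    # baseline APs come from the scan itself (identical code path)
    scan_mask_scored <- rep(TRUE, sum(pr$scored))
    res0 <- .cpp_eval_groups(pr$n, pr$u, pr$v, pr$groups_idx, pr$folds,
                             cfg@n_folds, pr$keys, FALSE)
    ap_full <- rep(NA_real_, ng)
    ap_full[pr$scored] <- res0$ap
    learnable <- !is.na(ap_full) &
        (ap_full - nulls$mean > cfg@learnability_delta)
    scanned <- if (learnable_only) learnable else pr$scored

    res <- .cpp_edge_scan(pr$n, pr$u, pr$v, pr$groups_idx, pr$folds,
                          cfg@n_folds, pr$keys,
                          scanned[pr$scored], tol)
    stopifnot(all(abs(res$ap_full - ap_full[pr$scored]) == 0))

    gmap <- which(pr$scored)   # scored index -> full group index
    cells <- data.frame(
        edge = res$edge,
        group = gmap[res$group],
        ap_removed = res$ap_removed)
    eff <- rep(NA_real_, nrow(cells))
    ok <- learnable[cells$group]
    if (any(ok)) {
        g <- cells$group[ok]
        eff[ok] <- (ap_full[g] - cells$ap_removed[ok]) /
            (ap_full[g] - nulls$mean[g])
    }
    cells$effect_raw <- eff
    cells$effect_capped <- pmin(eff, 1)

    new("CriticalityMatrix",
        edges = network@edges,
        group_ids = names(ann@groups),
        ap_full = ap_full,
        null_mean = nulls$mean,
        null_sd = nulls$sd,
        learnable = learnable,
        scanned = scanned,
        cells = cells,
        annotation = ann,
        seed = cfg@seed,
        n_folds = cfg@n_folds)
}

setMethod("show", "CriticalityMatrix", function(object) {
    cat(sprintf(
        "CriticalityMatrix: %d edges x %d groups (%d scanned, %d learnable)\n",
        nrow(object@edges), length(object@group_ids), sum(object@scanned),
        sum(object@learnable)))
    cat(sprintf("  %d materialized (edge, group) cells with nonzero effect\n",
                nrow(object@cells)))
    invisible(NULL)
})

#' Critical edges of a criticality scan
#'
#' An edge is critical when removing it reduces at least one learnable
#' group's above-null performance by at least \code{threshold} (capped
#' fractional effect).
#'
#' @param cmatrix a \linkS4class{CriticalityMatrix}.
#' @param threshold fraction in (0, 1]; default from the scan convention is
#'   0.10.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{n_groups}, \code{max_effect} and a list column \code{groups} of
#'   affected group ids, ordered by decreasing \code{max_effect}.
#' @export
criticalEdges <- function(cmatrix, threshold = 0.10) {
    cells <- cmatrix@cells
    sel <- !is.na(cells$effect_capped) &
        cmatrix@learnable[cells$group] &
        cells$effect_capped >= threshold
    cells <- cells[sel, , drop = FALSE]
    if (!nrow(cells)) {
        return(data.frame(gene_a = character(0), gene_b = character(0),
                          n_groups = integer(0), max_effect = numeric(0),
                          groups = I(list())))
    }
    sp <- split(cells, cells$edge)
    eidx <- as.integer(names(sp))
    out <- data.frame(
        gene_a = cmatrix@edges[eidx, 1],
        gene_b = cmatrix@edges[eidx, 2],
        n_groups = vapply(sp, nrow, integer(1)),
        max_effect = vapply(sp, function(d) max(d$effect_capped),
                            numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    out$groups <- I(lapply(sp, function(d) cmatrix@group_ids[d$group]))
    o <- order(-out$max_effect, out$gene_a, out$gene_b, method = "radix")
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-edge exceptionality scores
#'
#' An exceptional edge is critical for many groups.  Two aggregate scores
#' are computed per edge across the learnable groups: the mean capped effect
#' (primary ordering) and the fraction of learnable groups with a capped
#' effect of at least 10\%.  Edges absent from a group's materialized cells
#' contribute an effect of exactly 0 for that group.  Ordering is descending
#' by mean effect with deterministic lexicographic tie-breaking.
#'
#' @param cmatrix a \linkS4class{CriticalityMatrix}.
#' @param drop_threshold effect cutoff for the fraction score (default 0.10).
#' @return data.frame with columns \code{rank}, \code{gene_a}, \code{gene_b},
#'   \code{mean_effect}, \code{frac_critical}, \code{top_group} (most
#'   affected group, NA when no effect) and \code{top_group_role}
#'   ("internal"/"external").
#' @export
exceptionalityScores <- function(cmatrix, drop_threshold = 0.10) {
    m <- nrow(cmatrix@edges)
    nl <- sum(cmatrix@learnable)
    mean_eff <- numeric(m)
    frac <- numeric(m)
    top_group <- rep(NA_character_, m)
    cells <- cmatrix@cells
    sel <- !is.na(cells$effect_capped) & cmatrix@learnable[cells$group]
    cells <- cells[sel, , drop = FALSE]
    if (nrow(cells) && nl > 0) {
        agg_sum <- tapply(cells$effect_capped, cells$edge, sum)
        agg_frac <- tapply(cells$effect_capped >= drop_threshold,
                           cells$edge, sum)
        eidx <- as.integer(names(agg_sum))
        mean_eff[eidx] <- as.numeric(agg_sum) / nl
        frac[eidx] <- as.numeric(agg_frac) / nl
        sp <- split(cells, cells$edge)
        top <- vapply(sp, function(d) {
            as.integer(d$group[which.max(d$effect_capped)])
        }, integer(1))
        top_group[eidx] <- cmatrix@group_ids[top]
    }
    o <- order(-mean_eff, cmatrix@edges[, 1], cmatrix@edges[, 2],
               method = "radix")
    out <- data.frame(
        rank = seq_len(m),
        gene_a = cmatrix@edges[o, 1],
        gene_b = cmatrix@edges[o, 2],
        mean_effect = mean_eff[o],
        frac_critical = frac[o],
        top_group = top_group[o],
        row.names = NULL, stringsAsFactors = FALSE)
    out$top_group_role <- NA_character_
    has_top <- which(!is.na(out$top_group))
    if (length(has_top)) {
        out$top_group_role[has_top] <- vapply(has_top, function(i) {
            classifyEdgeRole(
                c(out$gene_a[i], out$gene_b[i]),
                cmatrix@annotation@groups[[out$top_group[i]]])
        }, character(1))
    }
    out
}

#' Classify an edge as internal or external to a group
#'
#' A critical edge is \emph{internal} when both endpoints are members of the
#' group it affects, \emph{external} otherwise.  External critical edges can
#' encode non-membership: an edge between two genes lacking the function can
#' keep a non-member from being spuriously top-ranked.
#'
#' @param edge character vector of the two endpoint genes.
#' @param group character vector of group members.
#' @return \code{"internal"} or \code{"external"}.
#' @export
classifyEdgeRole <- function(edge, group) {
    if (length(edge) != 2) stop("edge must have exactly two endpoints")
    if (all(edge %in% group)) "internal" else "external"
}

#' Evaluate an ablated or skeleton network
#'
#' Re-evaluates the annotation set on the network with the given edges
#' removed (or on the network restricted to the edges kept), under the same
#' protocol and seeds as the baseline, so APTables are directly comparable.
#' The gene set (hence the evaluation universe, tie keys and folds) is
#' unchanged.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param ann an \linkS4class{AnnotationSet}.
#' @param cfg a \linkS4class{RunConfig}.
#' @param edges_to_remove,edges_to_keep exactly one may be non-NULL: a
#'   two-column matrix/data.frame of gene pairs, all present in the network.
#'   \code{edges_to_keep = NULL} with \code{edges_to_remove = NULL} evaluates
#'   the unmodified network.
#' @param keep_scores passed to \code{\link{evaluateNetwork}}.
#' @return an \linkS4class{APTable}.
#' @export
ablateAndEvaluate <- function(network, ann, cfg = runConfig(),
                              edges_to_remove = NULL, edges_to_keep = NULL,
                              keep_scores = FALSE) {
    if (!is.null(edges_to_remove) && !is.null(edges_to_keep))
        stop("give either edges_to_remove or edges_to_keep, not both")
    net2 <- network
    if (!is.null(edges_to_remove)) {
        e <- as.matrix(edges_to_remove)
        if (nrow(e)) net2 <- .dropEdges(network, e[, 1], e[, 2])
    } else if (!is.null(edges_to_keep)) {
        e <- as.matrix(edges_to_keep)
        net2 <- if (nrow(e)) .keepEdges(network, e[, 1], e[, 2])
                else new("GeneNetwork", genes = network@genes,
                         edges = network@edges[0, , drop = FALSE],
                         droppedSelfLoops = 0L)
    }
    evaluateNetwork(net2, ann, cfg, keep_scores = keep_scores)
}
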