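# Uniform sample of edge slots among all C(n, 2) pairs; the hash sampler is
# much faster for sparse draws, the plain one covers dense/small cases.  The
# rule is deterministic so all callers produce identical draws per seed.
.randomEdgeIdx <- function(npairs, n_edges) {
    if (npairs > 2 * n_edges)
        sample.int(npairs, n_edges, useHash = TRUE)
    else
        sample.int(npairs, n_edges)
}

.defaultGeneNames <- function(n) {
    sprintf("g%0*d", nchar(as.character(n)), seq_len(n))
}

.defaultGroupNames <- function(n, prefix = "G") {
    sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

#' Generate a uniform random network
#'
#' Samples \code{n_edges} unordered gene pairs uniformly without replacement
#' from all C(n_genes, 2) non-self pairs.  The default simulation regime is
#' 1000 genes with 1000 edges (sparsity 0.002).  Bit-identical for a given
#' seed; isolated genes remain in the node set.
#'
#' @param n_genes number of genes (>= 2).
#' @param n_edges number of edges (<= C(n_genes, 2)).
#' @param seed integer seed.
#' @param gene_names optional explicit node names (length \code{n_genes}).
#' @return a \linkS4class{GeneNetwork}.
#' @export
generateRandomNetwork <- function(n_genes = 1000, n_edges = 1000, seed = 1L,
                                  gene_names = NULL) {
    if (n_genes < 2) stop("n_genes must be >= 2")
    npairs <- n_genes * (n_genes - 1) / 2
    if (n_edges > npairs)
        stop(sprintf("infeasible edge count: %d > C(%d, 2) = %g",
                     n_edges, n_genes, npairs))
    if (is.null(gene_names)) gene_names <- .defaultGeneNames(n_genes)
    stopifnot(length(gene_names) == n_genes)
    idx <- .withSeed(.deriveSeed(seed, "net"),
                     .randomEdgeIdx(npairs, n_edges))
    ij <- .linearToPair(as.numeric(idx), n_genes)
    geneNetwork(cbind(gene_names[ij[, 1]], gene_names[ij[, 2]]),
                genes = gene_names)
}

#' Generate random pseudo-annotation groups
#'
#' Each group is an independent uniform sample of \code{group_size} genes
#' without replacement (within the group); a gene may belong to several
#' groups.  These "pseudo-GO" groups stand in for real annotations in null
#' simulations; at the default 100 groups of 20 over 1000 genes the expected
#' number of groups per gene is 2.
#'
#' @param n_genes universe size.
#' @param n_groups number of groups.
#' @param group_size genes per group (<= n_genes).
#' @param seed integer seed.
#' @param gene_names optional explicit universe names.
#' @return an \linkS4class{AnnotationSet} whose universe is all
#'   \code{n_genes} genes.
#' @export
generatePseudoGroups <- function(n_genes = 1000, n_groups = 100,
                                 group_size = 20, seed = 1L,
                                 gene_names = NULL) {
    if (group_size > n_genes) stop("group_size must be <= n_genes")
    if (is.null(gene_names)) gene_names <- .defaultGeneNames(n_genes)
    grp <- .withSeed(.deriveSeed(seed, "groups"), {
        lapply(seq_len(n_groups), function(i) {
            gene_names[sample.int(n_genes, group_size)]
        })
    })
    names(grp) <- .defaultGroupNames(n_groups)
    annotationSet(grp, universe = gene_names)
}

#' Preferential-attachment network fixture
#'
#' Barabasi-Albert-style network with a heavy-tailed degree distribution,
#' used as a positive control for the power-law diagnostic of
#' \code{\link{degreeProfile}}.
#'
#' @param n_genes number of genes.
#' @param m_per_node edges added per new node.
#' @param seed integer seed.
#' @return a \linkS4class{GeneNetwork}.
#' @export
generatePreferentialAttachment <- function(n_genes = 500, m_per_node = 2,
                                           seed = 1L) {
    g <- .withSeed(.deriveSeed(seed, "pa"), {
        igraph::sample_pa(n_genes, m = m_per_node, directed = FALSE)
    })
    el <- igraph::as_edgelist(g, names = FALSE)
    nm <- .defaultGeneNames(n_genes)
    geneNetwork(cbind(nm[el[, 1]], nm[el[, 2]]), genes = nm)
}

#' Jaccard similarity of two genes' annotation sets
#'
#' \code{|groups(a) ∩ groups(b)| / |groups(a) ∪ groups(b)|}, defined as 0
#' when both genes are unannotated.  Vectorized over pairs.
#'
#' @param ann an \linkS4class{AnnotationSet}.
#' @param gene_a,gene_b character vectors of equal length.
#' @return numeric vector of Jaccard indices in [0, 1].
#' @export
annotationJaccard <- function(ann, gene_a, gene_b) {
    stopifnot(length(gene_a) == length(gene_b))
    g2g <- .geneToGroups(ann)
    vapply(seq_along(gene_a), function(i) {
        a <- g2g[[gene_a[i]]]
        b <- g2g[[gene_b[i]]]
        u <- length(a) + length(b) - length(intersect(a, b))
        if (u == 0) 0 else length(intersect(a, b)) / u
    }, numeric(1))
}

#' Expected annotation Jaccard of a random gene pair
#'
#' Monte-Carlo estimate of the mean \code{\link{annotationJaccard}} over
#' uniformly sampled distinct gene pairs; the background expectation against
#' which the recurrent-edge Jaccard is compared.  Under the default
#' pseudo-annotation scheme this is close to the combinatorial expectation
#' \code{n_groups * p^2 / E|union|} with \code{p = group_size / n_genes}
#' (about 0.01 at the defaults).
#'
#' @param ann an \linkS4class{AnnotationSet}.
#' @param n_pairs number of sampled pairs (>= 1000 recommended).
#' @param seed integer seed.
#' @return list with \code{mean}, \code{se} (standard error) and
#'   \code{n_pairs}.
#' @export
expectedPairJaccard <- function(ann, n_pairs = 100000L, seed = 1L) {
    n <- length(ann@universe)
    if (n < 2) stop("universe must have >= 2 genes")
    ij <- .withSeed(.deriveSeed(seed, "pairs"), {
        a <- sample.int(n, n_pairs, replace = TRUE)
        b <- sample.int(n - 1L, n_pairs, replace = TRUE)
        b <- ifelse(b >= a, b + 1L, b)
        cbind(a, b)
    })
    j <- annotationJaccard(ann, ann@universe[ij[, 1]], ann@universe[ij[, 2]])
    list(mean = mean(j), se = stats::sd(j) / sqrt(n_pairs),
         n_pairs = n_pairs)
}

#' Planted-critical-edge fixtures
#'
#' Generates a network and annotation set in which designated groups are
#' learnable through exactly one in-group edge, so that criticality scans
#' have a known ground truth.  Each planted group has \code{group_size}
#' members whose only in-group connectivity is one designated edge between
#' its first two members; every member is additionally wired to the group's
#' dedicated out-group hub gene (so the designated endpoints have degree 2,
#' not 1).  Each hub receives \code{4 * group_size} extra edges to
#' background genes, giving it degree \code{5 * group_size}: its vote
#' fraction for the planted group stays at most \code{(k-1)/(5k)} (about
#' 0.17), far below the 1/2 scored by a held-out designated endpoint, and
#' robustly so under any single edge removal.  Because the hubs are the
#' highest-degree genes and carry no in-group edges, degree pruning removes
#' their connections wholesale while keeping the function-carrying planted
#' edges -- the empirical pattern the pruning analysis relies on.
#' Background edges are sampled uniformly among background genes only, and
#' edges inside background groups are removed, so that no background group
#' is learnable and only the planted edges carry function.  With
#' \code{n_planted = 0} the generator reduces exactly to
#' \code{\link{generateRandomNetwork}} plus
#' \code{\link{generatePseudoGroups}}.
#'
#' Planted fixtures are designed to be evaluated with leave-one-out folds
#' (\code{n_folds = group_size}) so that the two designated endpoints are
#' never held out together.
#'
#' @param n_genes total genes (default 300).
#' @param n_edges background edges sampled before stripping (default 500).
#' @param n_groups background groups (default 8).
#' @param group_size size of every group, background and planted
#'   (default 6).
#' @param n_planted number of planted groups (default 1).
#' @param seed integer seed.
#' @return list with \code{network} (\linkS4class{GeneNetwork}),
#'   \code{annotations} (\linkS4class{AnnotationSet}; background groups
#'   first, then planted groups named \code{P1}, \code{P2}, ...), and
#'   \code{manifest}: a data.frame (\code{group_id}, \code{gene_a},
#'   \code{gene_b}) of the planted edges.
#' @export
generatePlanted <- function(n_genes = 300, n_edges = 500, n_groups = 8,
                            group_size = 6, n_planted = 1, seed = 1L) {
    if (n_planted == 0) {
        return(list(
            network = generateRandomNetwork(n_genes, n_edges, seed),
            annotations = generatePseudoGroups(n_genes, n_groups,
                                               group_size, seed),
            manifest = data.frame(group_id = character(0),
                                  gene_a = character(0),
                                  gene_b = character(0))))
    }
    if (group_size < 2) stop("planted groups need group_size >= 2")
    hub_extra <- 4L * group_size
    need <- n_planted * (group_size + 1L)
    if (need + hub_extra + group_size > n_genes)
        stop("n_genes too small for the requested planted structure")
    nm <- .defaultGeneNames(n_genes)

    .withSeed(.deriveSeed(seed, "planted"), {
        reserved <- sample.int(n_genes, need)
        background <- setdiff(seq_len(n_genes), reserved)
        nb <- length(background)

        # planted groups, each with one dedicated out-group hub
        planted_groups <- vector("list", n_planted)
        manifest <- data.frame(group_id = character(0),
                               gene_a = character(0),
                               gene_b = character(0))
        extra_a <- integer(0); extra_b <- integer(0)
        for (p in seq_len(n_planted)) {
            block <- reserved[((p - 1) * (group_size + 1L) + 1):
                              (p * (group_size + 1L))]
            members <- block[seq_len(group_size)]
            hub <- block[group_size + 1L]
            planted_groups[[p]] <- nm[members]
            # designated in-group edge between the first two members
            extra_a <- c(extra_a, members[1])
            extra_b <- c(extra_b, members[2])
            manifest <- rbind(manifest, data.frame(
                group_id = paste0("P", p),
                gene_a = min(nm[members[1]], nm[members[2]]),
                gene_b = max(nm[members[1]], nm[members[2]]),
                stringsAsFactors = FALSE))
            # every member wired to the hub; the hub padded with background
            # edges up to degree 5 * group_size
            extra_a <- c(extra_a, members)
            extra_b <- c(extra_b, rep.int(hub, group_size))
            tg <- background[sample.int(nb, hub_extra)]
            extra_a <- c(extra_a, rep.int(hub, hub_extra))
            extra_b <- c(extra_b, tg)
        }
        names(planted_groups) <- paste0("P", seq_len(n_planted))
        if (anyDuplicated(paste(pmin(extra_a, extra_b),
                                pmax(extra_a, extra_b))))
            stop("conflicting planted specification: duplicate edge")

        # background groups over background genes only
        bg_groups <- lapply(seq_len(n_groups), function(i) {
            nm[background[sample.int(nb, min(group_size, nb))]]
        })
        names(bg_groups) <- .defaultGroupNames(n_groups)

        # background edges among background genes, stripped of any edge
        # inside a background group
        npairs_bg <- nb * (nb - 1) / 2
        idx <- .randomEdgeIdx(npairs_bg, min(n_edges, npairs_bg))
        ij <- .linearToPair(as.numeric(idx), nb)
        ea <- background[ij[, 1]]
        eb <- background[ij[, 2]]
        in_same_group <- rep(FALSE, length(ea))
        for (g in bg_groups) {
            gi <- match(g, nm)
            in_same_group <- in_same_group |
                ((ea %in% gi) & (eb %in% gi))
        }
        ea <- ea[!in_same_group]
        eb <- eb[!in_same_group]

        edges <- cbind(nm[c(ea, extra_a)], nm[c(eb, extra_b)])
        net <- geneNetwork(edges, genes = nm)
        ann <- annotationSet(c(bg_groups, planted_groups), universe = nm)
        list(network = net, annotations = ann, manifest = manifest)
    })
}

#' Random-network null screen
#'
#' Phase 1 draws one fixed pseudo-annotation set, evaluates
#' \code{calib_reps} uniform random networks by cross-validated neighbor
#' voting, and sets a MAP threshold at \code{mean + sd_multiplier * SD} of
#' the calibration distribution (whose normality is checked with a
#' Kolmogorov-Smirnov statistic against a normal with the sample moments --
#' a Lilliefors-style caveat, since the moments are estimated).  Phase 2
#' evaluates \code{screen_reps} fresh random networks under the same fixed
#' annotation set and fold assignments and retains those whose MAP exceeds
#' the threshold; edge occurrences are tallied across the retained networks.
#'
#' Replicate \code{i} uses a sub-seed derived deterministically from the
#' master seed, with edges drawn exactly as
#' \code{generateRandomNetwork(n_genes, n_edges, seed = sub_seed)} and fresh
#' tie-break keys per replicate; fold assignments are fixed once from the
#' master seed.  The entire result is a pure function of the parameters.
#'
#' @param n_genes,n_edges random-network size (defaults 1000 and 1000:
#'   sparsity 0.002).
#' @param n_groups,group_size pseudo-annotation scheme (defaults 100 and
#'   20).
#' @param calib_reps calibration replicates (default 1000).
#' @param screen_reps screening replicates (default 100000).
#' @param sd_multiplier threshold multiplier (default 3); \code{Inf} selects
#'   nothing, \code{-Inf} selects everything.
#' @param n_folds cross-validation folds (default 3).
#' @param seed master seed.
#' @param verbose print progress messages.
#' @return a \linkS4class{NullScreenResult}.
#' @seealso \code{\link{recurrentEdgeAnalysis}}
#' @export
nullScreen <- function(n_genes = 1000, n_edges = 1000, n_groups = 100,
                       group_size = 20, calib_reps = 1000L,
                       screen_reps = 100000L, sd_multiplier = 3,
                       n_folds = 3L, seed = 1L, verbose = FALSE) {
    ann <- generatePseudoGroups(n_genes, n_groups, group_size,
                                seed = .deriveSeed(seed, "ann"))
    stopifnot(identical(ann@universe, .defaultGeneNames(n_genes)))
    groups_idx <- lapply(ann@groups,
                         function(g) match(g, ann@universe) - 1L)
    templates <- .foldTemplates(ann, n_folds)
    npairs <- n_genes * (n_genes - 1) / 2

    # Each replicate is a complete, independent evaluation: its network,
    # fold assignment and tie keys all derive from the replicate sub-seed,
    # so it equals evaluateNetwork(generateRandomNetwork(., sub_seed), ann,
    # runConfig(seed = sub_seed, .)) exactly.
    eval_one <- function(rep_seed) {
        set.seed(.deriveSeed(rep_seed, "net"))
        idx <- .randomEdgeIdx(npairs, n_edges)
        ij <- .linearToPair(as.numeric(idx), n_genes)
        folds <- .makeFoldsFast(templates, rep_seed)
        set.seed(.deriveSeed(rep_seed, "tiekey"))
        keys <- runif(n_genes)
        res <- .cpp_eval_groups(n_genes, ij[, 1] - 1L, ij[, 2] - 1L,
                                groups_idx, folds, n_folds, keys, FALSE)
        list(map = mean(res$ap), idx = idx)
    }

    calib <- numeric(calib_reps)
    for (i in seq_len(calib_reps)) {
        calib[i] <- eval_one(.deriveSeed(seed, paste0("rep:", i)))$map
        if (verbose && i %% 200 == 0)
            message(sprintf("calibration %d/%d", i, calib_reps))
    }
    mu <- mean(calib)
    sigma <- stats::sd(calib)
    ks <- suppressWarnings(stats::ks.test(calib, "pnorm", mu, sigma))
    threshold <- mu + sd_multiplier * sigma

    selected_idx <- list()
    selected_maps <- numeric(0)
    for (j in seq_len(screen_reps)) {
        r <- eval_one(.deriveSeed(seed, paste0("rep:", calib_reps + j)))
        if (r$map > threshold) {
            selected_idx[[length(selected_idx) + 1L]] <- r$idx
            selected_maps <- c(selected_maps, r$map)
        }
        if (verbose && j %% 5000 == 0)
            message(sprintf("screen %d/%d (%d selected)", j, screen_reps,
                            length(selected_idx)))
    }
    if (!length(selected_idx))
        warning("null screen retained zero networks")

    tally <- if (length(selected_idx)) {
        counts <- tabulate(unlist(selected_idx), nbins = npairs)
        nz <- which(counts > 0)
        ij <- .linearToPair(as.numeric(nz), n_genes)
        data.frame(gene_a = ann@universe[ij[, 1]],
                   gene_b = ann@universe[ij[, 2]],
                   count = counts[nz], stringsAsFactors = FALSE)
    } else {
        data.frame(gene_a = character(0), gene_b = character(0),
                   count = integer(0))
    }
    new("NullScreenResult",
        calibration = calib, calib_mean = mu, calib_sd = sigma,
        ks_p = ks$p.value, threshold = threshold,
        sd_multiplier = as.numeric(sd_multiplier),
        screen_reps = as.integer(screen_reps),
        selected_count = length(selected_maps),
        selected_maps = selected_maps,
        edge_tally = tally, annotations = ann,
        params = list(n_genes = n_genes, n_edges = n_edges,
                      n_groups = n_groups, group_size = group_size,
                      calib_reps = calib_reps, screen_reps = screen_reps,
                      sd_multiplier = sd_multiplier, n_folds = n_folds,
                      seed = seed))
}

#' @describeIn nullScreen the per-edge occurrence tally across retained
#'   networks.
#' @param x a \linkS4class{NullScreenResult}.
#' @export
setMethod("edgeTally", "NullScreenResult", function(x) x@edge_tally)

#' @describeIn nullScreen the number of retained networks.
#' @export
setMethod("selectedCount", "NullScreenResult", function(x) {
    x@selected_count
})

#' @describeIn nullScreen calibration moments, KS normality p-value and
#'   threshold.
#' @export
setMethod("calibrationStats", "NullScreenResult", function(x) {
    list(mean = x@calib_mean, sd = x@calib_sd, ks_p = x@ks_p,
         threshold = x@threshold)
})

setMethod("show", "NullScreenResult", function(object) {
    cat(sprintf("NullScreenResult: %d calibration + %d screen replicates\n",
                length(object@calibration), object@screen_reps))
    cat(sprintf("  calibration MAP: %.5f +/- %.5f (KS normality p = %.3f)\n",
                object@calib_mean, object@calib_sd, object@ks_p))
    cat(sprintf("  threshold (mean + %g SD): %.5f\n",
                object@sd_multiplier, object@threshold))
    cat(sprintf("  retained networks: %d; distinct edges tallied: %d\n",
                object@selected_count, nrow(object@edge_tally)))
    invisible(NULL)
})

#' Recurrent-edge analysis of a null screen
#'
#' Takes the \code{top_m} edges occurring most frequently across the
#' retained networks (ties broken lexicographically), builds the skeleton
#' network containing only those edges over the full universe, evaluates its
#' MAP under the screen's fixed annotations and fold assignments, and
#' reports the z-score relative to the calibration distribution together
#' with the mean annotation Jaccard of the edges' endpoint pairs.
#'
#' @param result a \linkS4class{NullScreenResult} with a nonempty tally.
#' @param top_m number of recurrent edges (default 24); when fewer edges
#'   were tallied, all are used with a warning.
#' @return list with \code{edges} (data.frame \code{gene_a}, \code{gene_b},
#'   \code{count}, \code{jaccard}), \code{skeleton}
#'   (\linkS4class{GeneNetwork}), \code{map}, \code{z} and
#'   \code{mean_jaccard}.
#' @export
recurrentEdgeAnalysis <- function(result, top_m = 24L) {
    tally <- result@edge_tally
    if (!nrow(tally)) stop("empty edge tally: no retained networks")
    if (top_m > nrow(tally)) {
        warning(sprintf("only %d tallied edges available (top_m = %d)",
                        nrow(tally), top_m))
        top_m <- nrow(tally)
    }
    o <- order(-tally$count, tally$gene_a, tally$gene_b, method = "radix")
    top <- tally[o[seq_len(top_m)], , drop = FALSE]
    ann <- result@annotations
    top$jaccard <- annotationJaccard(ann, top$gene_a, top$gene_b)
    rownames(top) <- NULL

    p <- result@params
    skeleton <- geneNetwork(cbind(top$gene_a, top$gene_b),
                            genes = ann@universe)
    groups_idx <- lapply(ann@groups,
                         function(g) match(g, ann@universe) - 1L)
    folds <- .makeFolds(ann, p$n_folds, p$seed)
    pr <- .networkIndex(skeleton)
    keys <- .withSeed(.deriveSeed(p$seed, "skeleton"),
                      runif(length(ann@universe)))
    res <- .cpp_eval_groups(length(ann@universe), pr$u - 1L, pr$v - 1L,
                            groups_idx, folds, p$n_folds, keys, FALSE)
    map <- mean(res$ap)
    list(edges = top, skeleton = skeleton, map = map,
         z = (map - result@calib_mean) / result@calib_sd,
         mean_jaccard = mean(top$jaccard))
}
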