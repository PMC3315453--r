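test_that("edge effects follow the above-null fraction with capping", {
    e <- edgeEffect(0.5, 0.5, 0.1)
    expect_equal(e$effect_raw, 0)
    e <- edgeEffect(0.5, 0.1, 0.1)  # drop to the null mean
    expect_equal(e$effect_raw, 1)
    expect_equal(e$effect_capped, 1)
    e <- edgeEffect(0.5, 0.02, 0.1)  # below chance: raw > 1, capped at 1
    expect_gt(e$effect_raw, 1)
    expect_equal(e$effect_capped, 1)
    expect_error(edgeEffect(0.05, 0.01, 0.1), "not learnable")
    # vectorized over removals
    e <- edgeEffect(0.5, c(0.5, 0.3, 0.1), 0.1)
    expect_equal(e$effect_raw, c(0, 0.5, 1))
})

test_that("edge roles are internal only when both endpoints are members", {
    grp <- c("a", "b", "c")
    expect_equal(classifyEdgeRole(c("a", "b"), grp), "internal")
    expect_equal(classifyEdgeRole(c("a", "x"), grp), "external")
    expect_equal(classifyEdgeRole(c("x", "y"), grp), "external")
    expect_error(classifyEdgeRole("a", grp), "two endpoints")
})

test_that("scan baseline equals the standard evaluation and skips are exact", {
    net <- generateRandomNetwork(35, 50, seed = 21)
    ann <- generatePseudoGroups(35, 6, 5, seed = 22)
    cfg <- runConfig(seed = 23, null_reps = 200)
    cm <- edgeRemovalScan(net, ann, cfg, learnable_only = FALSE)
    tab <- apScores(evaluateNetwork(net, ann, cfg))
    expect_identical(cm@ap_full, tab$ap)
    # naive oracle: rebuild each one-edge-removed network and re-evaluate
    e <- edges(net)
    for (i in seq_len(nrow(e))) {
        naive <- apScores(ablateAndEvaluate(
            net, ann, cfg, edges_to_remove = e[i, , drop = FALSE]))$ap
        for (g in seq_along(naive)) {
            cell <- cm@cells[cm@cells$edge == i & cm@cells$group == g, ]
            expected <- if (nrow(cell)) cell$ap_removed else cm@ap_full[g]
            expect_equal(naive[g], expected, tolerance = 1e-12)
        }
    }
})

test_that("a far-away edge has exactly zero effect", {
    # two components: a clique group and a disjoint pair; removing the
    # disjoint pair's edge cannot move the clique group's AP
    cl <- sprintf("c%d", 1:6)
    pairs <- t(utils::combn(cl, 2))
    net <- geneNetwork(rbind(pairs, c("z1", "z2")),
                       genes = c(cl, "z1", "z2", sprintf("f%02d", 1:20)))
    ann <- annotationSet(list(CL = cl), universe = genes(net))
    cfg <- runConfig(seed = 2, null_reps = 200)
    cm <- edgeRemovalScan(net, ann, cfg)
    far <- which(cm@edges[, 1] == "z1" & cm@edges[, 2] == "z2")
    expect_false(far %in% cm@cells$edge)
})

test_that("the planted edge is found by the scan with full effect", {
    fx <- generatePlanted(n_genes = 250, n_edges = 400, n_groups = 6,
                          group_size = 6, n_planted = 1, seed = 31)
    cfg <- runConfig(seed = 32, n_folds = 6, null_reps = 400)
    cm <- edgeRemovalScan(fx$network, fx$annotations, cfg)
    crit <- criticalEdges(cm, 0.10)
    expect_equal(nrow(crit), 1L)
    expect_equal(crit$gene_a, fx$manifest$gene_a)
    expect_equal(crit$gene_b, fx$manifest$gene_b)
    expect_gte(crit$max_effect, 0.9)  # removal erases the learnable signal
    # Fig 1 Case 1 semantics: removal turns the held-out hit into a miss,
    # dropping the group's AP to the vicinity of the null mean
    pl <- which(cm@group_ids == fx$manifest$group_id)
    cell <- cm@cells[cm@cells$edge == crit_edge_index(cm, crit) &
                     cm@cells$group == pl, ]
    expect_lt(cell$ap_removed, cm@null_mean[pl] + 3 * cm@null_sd[pl])
    # exceptionality ranks the planted edge first; ordering is invariant to
    # group permutation by construction (aggregates over groups)
    exc <- exceptionalityScores(cm)
    expect_equal(exc$gene_a[1], crit$gene_a)
    expect_equal(exc$top_group[1], fx$manifest$group_id)
    expect_equal(exc$top_group_role[1], "internal")
    # edges with no materialized effect score exactly zero
    expect_true(all(exc$mean_effect[-1] < exc$mean_effect[1]))
    zero <- exc[exc$mean_effect == 0, ]
    expect_true(all(zero$frac_critical == 0))
})

test_that("criticalEdges thresholds behave at the extremes", {
    fx <- generatePlanted(n_genes = 250, n_edges = 400, n_groups = 6,
                          group_size = 6, n_planted = 2, seed = 41)
    cfg <- runConfig(seed = 42, n_folds = 6, null_reps = 400)
    cm <- edgeRemovalScan(fx$network, fx$annotations, cfg)
    # threshold 1: only edges erasing a group's entire above-null signal
    c1 <- criticalEdges(cm, 1.0)
    key1 <- paste(c1$gene_a, c1$gene_b)
    keyp <- paste(fx$manifest$gene_a, fx$manifest$gene_b)
    expect_true(all(key1 %in% keyp))
    # threshold near 0: every materialized positive effect on a learnable
    # group is included
    c0 <- criticalEdges(cm, 1e-9)
    cells <- cm@cells
    pos <- cells[!is.na(cells$effect_capped) & cells$effect_capped > 0, ]
    expect_equal(nrow(c0), length(unique(pos$edge)))
})

test_that("ablation reproduces the baseline and the empty-network null", {
    net <- generateRandomNetwork(300, 300, seed = 51)
    ann <- generatePseudoGroups(300, 20, 10, seed = 52)
    cfg <- runConfig(seed = 53, null_reps = 500)
    base <- evaluateNetwork(net, ann, cfg)
    keep_all <- ablateAndEvaluate(net, ann, cfg,
                                  edges_to_keep = edges(net))
    expect_identical(apScores(keep_all), apScores(base))
    # keep zero edges: prevalence-only scores, MAP within 3 null SDs
    empty <- ablateAndEvaluate(net, ann, cfg,
                               edges_to_keep = edges(net)[0, , drop = FALSE])
    nm <- nullMapStats(empty)
    expect_lt(abs(mapScore(empty) - nm$mean), 3 * nm$sd)
    expect_error(ablateAndEvaluate(net, ann, cfg,
                                   edges_to_remove = cbind("nope", "nah")),
                 "not present")
    expect_error(ablateAndEvaluate(net, ann, cfg,
                                   edges_to_remove = edges(net)[1, , drop = FALSE],
                                   edges_to_keep = edges(net)),
                 "not both")
})

test_that("removing planted edges drops MAP by their design effect", {
    fx <- generatePlanted(n_genes = 250, n_edges = 400, n_groups = 6,
                          group_size = 6, n_planted = 2, seed = 61)
    cfg <- runConfig(seed = 62, n_folds = 6, null_reps = 400)
    base <- evaluateNetwork(fx$network, fx$annotations, cfg)
    abl <- ablateAndEvaluate(fx$network, fx$annotations, cfg,
                             edges_to_remove = cbind(fx$manifest$gene_a,
                                                     fx$manifest$gene_b))
    t0 <- apScores(base); t1 <- apScores(abl)
    pl <- fx$manifest$group_id
    # each planted group falls from learnable to the null vicinity
    for (g in pl) {
        i <- which(t0$group_id == g)
        expect_gt(t0$ap[i] - t0$null_mean[i], 0.2)
        expect_lt(t1$ap[i] - t1$null_mean[i], 3 * t1$null_sd[i])
    }
    # and MAP drops by at least the sum of their above-null margins, give
    # or take the null jitter of the other groups
    margin <- sum(t0$ap[t0$group_id %in% pl] -
                  t0$null_mean[t0$group_id %in% pl])
    nm <- nullMapStats(base)
    G <- nrow(t0)
    expect_gt(mapScore(base) - mapScore(abl),
              margin / G - 2 * nm$sd)
})
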