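test_that("random networks have the requested size and are seed-stable", {
    net <- generateRandomNetwork(1000, 1000, seed = 4)
    expect_equal(numEdges(net), 1000L)
    expect_equal(numGenes(net), 1000L)
    expect_equal(numEdges(net) / choose(1000, 2), 0.002, tolerance = 0.01)
    # the unique maximal graph on 3 genes
    tri <- generateRandomNetwork(3, 3, seed = 1)
    expect_equal(numEdges(tri), 3L)
    expect_setequal(paste(edges(tri)[, 1], edges(tri)[, 2]),
                    c("g1 g2", "g1 g3", "g2 g3"))
    expect_identical(edges(generateRandomNetwork(100, 200, seed = 9)),
                     edges(generateRandomNetwork(100, 200, seed = 9)))
    expect_false(identical(edges(generateRandomNetwork(100, 200, seed = 9)),
                           edges(generateRandomNetwork(100, 200, seed = 10))))
    expect_error(generateRandomNetwork(4, 10), "infeasible")
})

test_that("pair <-> linear index mapping is a bijection", {
    for (n in c(5, 37, 1000)) {
        npairs <- n * (n - 1) / 2
        L <- if (npairs <= 300) seq_len(npairs)
             else sort(sample.int(npairs, 300))
        ij <- netcrit:::.linearToPair(as.numeric(L), n)
        expect_true(all(ij[, 1] < ij[, 2]))
        back <- netcrit:::.pairToLinear(ij[, 1], ij[, 2], n)
        expect_equal(back, as.numeric(L))
    }
})

test_that("pseudo groups have exact sizes and the expected multifunctionality", {
    ann <- generatePseudoGroups(1000, 100, 20, seed = 2)
    expect_equal(length(groups(ann)), 100L)
    expect_true(all(groupSizes(ann) == 20L))
    # E[groups per gene] = 100 * 20 / 1000 = 2; check across seeds
    mf <- vapply(1:5, function(s) {
        mean(multifunctionality(generatePseudoGroups(1000, 100, 20,
                                                     seed = s)))
    }, numeric(1))
    se <- sqrt(2 / 1000 / 5)  # binomial-ish scale across 5 draws
    expect_lt(abs(mean(mf) - 2), 3 * max(se, 0.01))
    # group_size = n_genes: every group is the whole universe
    small <- generatePseudoGroups(10, 3, 10, seed = 1)
    expect_true(all(vapply(groups(small), function(g) {
        setequal(g, universe(small))
    }, logical(1))))
})

test_that("annotation Jaccard handles identity, disjointness and background", {
    ann <- annotationSet(list(A = c("x", "y"), B = c("x", "y"),
                              C = c("p"), D = c("q")),
                         universe = c("x", "y", "p", "q", "zz"))
    expect_equal(annotationJaccard(ann, "x", "y"), 1)
    expect_equal(annotationJaccard(ann, "p", "q"), 0)
    expect_equal(annotationJaccard(ann, "zz", "zz"), 0)  # both unannotated
    expect_equal(annotationJaccard(ann, "x", "p"), 0)
    # background expectation is consistent with the first-order closed form
    # E|shared| / E|union| (a ratio-of-expectations approximation, so only
    # agreement to ~20% is expected)
    ann2 <- generatePseudoGroups(1000, 100, 20, seed = 6)
    est <- expectedPairJaccard(ann2, n_pairs = 60000, seed = 7)
    p <- 20 / 1000
    closed <- 100 * p^2 / (2 * 100 * p - 100 * p^2)
    expect_lt(abs(est$mean - closed), 0.2 * closed)
})

test_that("planted generator reduces to the plain generators when empty", {
    fx <- generatePlanted(n_genes = 120, n_edges = 150, n_groups = 5,
                          group_size = 6, n_planted = 0, seed = 8)
    expect_identical(edges(fx$network),
                     edges(generateRandomNetwork(120, 150, seed = 8)))
    expect_identical(groups(fx$annotations),
                     groups(generatePseudoGroups(120, 5, 6, seed = 8)))
    expect_equal(nrow(fx$manifest), 0L)
})

test_that("planted fixtures isolate the designated edge", {
    fx <- generatePlanted(n_genes = 250, n_edges = 400, n_groups = 6,
                          group_size = 6, n_planted = 2, seed = 9)
    ann <- fx$annotations
    net <- fx$network
    key_net <- paste(edges(net)[, 1], edges(net)[, 2])
    for (i in seq_len(nrow(fx$manifest))) {
        g <- groups(ann)[[fx$manifest$group_id[i]]]
        # the designated edge is present and is the only in-group edge
        d <- groupDensity(net, g)
        expect_equal(d$in_edges, 1)
        expect_true(paste(fx$manifest$gene_a[i],
                          fx$manifest$gene_b[i]) %in% key_net)
        # designated endpoints have degree 2 (planted edge + anchor)
        deg <- nodeDegrees(net)
        expect_equal(unname(deg[fx$manifest$gene_a[i]]), 2L)
        expect_equal(unname(deg[fx$manifest$gene_b[i]]), 2L)
        # every member is wired out-of-group
        expect_true(all(deg[g] >= 1))
    }
    # background groups carry no in-group edges
    bg <- setdiff(names(groups(ann)), fx$manifest$group_id)
    for (b in bg)
        expect_equal(groupDensity(net, groups(ann)[[b]])$in_edges, 0)
})

test_that("null screen is reproducible and honors threshold extremes", {
    r1 <- nullScreen(n_genes = 200, n_edges = 200, n_groups = 10,
                     group_size = 8, calib_reps = 60L, screen_reps = 150L,
                     seed = 11)
    r2 <- nullScreen(n_genes = 200, n_edges = 200, n_groups = 10,
                     group_size = 8, calib_reps = 60L, screen_reps = 150L,
                     seed = 11)
    expect_identical(r1@calibration, r2@calibration)
    expect_identical(edgeTally(r1), edgeTally(r2))
    expect_identical(r1@threshold, r2@threshold)
    # infinite multiplier: nothing selected
    expect_warning(
        r_inf <- nullScreen(n_genes = 200, n_edges = 200, n_groups = 10,
                            group_size = 8, calib_reps = 60L,
                            screen_reps = 100L, sd_multiplier = Inf,
                            seed = 11),
        "zero networks")
    expect_equal(selectedCount(r_inf), 0L)
    # minus-infinite multiplier: everything selected, tally sums to E * reps
    r_all <- nullScreen(n_genes = 200, n_edges = 200, n_groups = 10,
                        group_size = 8, calib_reps = 60L,
                        screen_reps = 100L, sd_multiplier = -Inf,
                        seed = 11)
    expect_equal(selectedCount(r_all), 100L)
    expect_equal(sum(edgeTally(r_all)$count), 100L * 200L)
})

test_that("screen replicates equal the public evaluation protocol", {
    res <- suppressWarnings(
        nullScreen(n_genes = 300, n_edges = 300, n_groups = 15,
                   group_size = 10, calib_reps = 10L, screen_reps = 0L,
                   seed = 21))
    ann <- res@annotations
    for (i in c(2L, 7L)) {
        rep_seed <- netcrit:::.deriveSeed(21, paste0("rep:", i))
        net <- generateRandomNetwork(300, 300, seed = rep_seed)
        tab <- evaluateNetwork(net, ann,
                               runConfig(seed = rep_seed, null_reps = 100))
        expect_identical(mapScore(tab), res@calibration[i])
    }
})

test_that("recurrent-edge analysis reports skeleton and endpoint overlap", {
    res <- nullScreen(n_genes = 200, n_edges = 200, n_groups = 10,
                      group_size = 8, calib_reps = 80L, screen_reps = 400L,
                      sd_multiplier = 1.5, seed = 31)
    expect_gt(selectedCount(res), 0)
    expect_warning(rec <- recurrentEdgeAnalysis(res, top_m = 10^6),
                   "available")
    rec <- recurrentEdgeAnalysis(res, top_m = min(24, nrow(edgeTally(res))))
    expect_equal(numEdges(rec$skeleton), nrow(rec$edges))
    expect_true(all(diff(rec$edges$count) <= 0))
    expect_equal(rec$mean_jaccard, mean(rec$edges$jaccard))
    expect_equal(rec$z, (rec$map - res@calib_mean) / res@calib_sd)
    # tally concentrated on one edge -> one-edge skeleton
    fake <- res
    fake@edge_tally <- data.frame(gene_a = "g001", gene_b = "g002",
                                  count = 5L)
    rec1 <- suppressWarnings(recurrentEdgeAnalysis(fake, top_m = 1))
    expect_equal(numEdges(rec1$skeleton), 1L)
})

test_that("calibration MAPs look normal and the screen tail is heavy", {
    # scaled-down screen: the KS check should not reject normality, and the
    # selected fraction at 3 SD should far exceed the Gaussian tail 0.00135
    res <- nullScreen(calib_reps = 150L, screen_reps = 0L,
                      seed = 41) |> suppressWarnings()
    expect_gt(res@ks_p, 0.01)
})
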