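test_that("neighbor voting scores follow the vote-fraction definition", {
    # path a - b - c, training {a}: b has neighbors {a, c} -> 1/2; c -> 0
    net <- mkNet(c("a", "b"), c("b", "c"))
    s <- neighborVotingScores(net, "a", "b")
    expect_equal(s[["b"]], 1 / 2)
    expect_equal(s[["c"]], 0)
    # all neighbors in training -> 1
    net2 <- mkNet(c("a", "g"), c("b", "g"))
    expect_equal(neighborVotingScores(net2, c("a", "b"))[["g"]], 1)
    # isolated gene among 1000 genes with 10 positives -> prevalence 0.01
    u <- sprintf("u%04d", 1:1000)
    net3 <- geneNetwork(NULL, genes = u)
    s3 <- neighborVotingScores(net3, u[1:10], universe = u)
    expect_true(all(s3 == 0.01))
    expect_error(neighborVotingScores(net, character(0)), "empty training")
    expect_error(neighborVotingScores(net, "a", "a"), "disjoint")
})

test_that("adding an edge to a training positive never lowers a score", {
    for (s in 1:10) {
        net <- generateRandomNetwork(25, 40, seed = s)
        g <- genes(net)
        train <- g[1:5]
        cand <- g[10]
        s0 <- neighborVotingScores(net, train)[[cand]]
        if (paste(min(cand, train[1]), max(cand, train[1])) %in%
            paste(edges(net)[, 1], edges(net)[, 2])) next
        net2 <- geneNetwork(rbind(edges(net), c(cand, train[1])), genes = g)
        s1 <- neighborVotingScores(net2, train)[[cand]]
        expect_gte(s1, s0)
        expect_true(all(neighborVotingScores(net2, train) >= 0))
        expect_true(all(neighborVotingScores(net2, train) <= 1))
    }
})

test_that("average precision matches hand-derived values and errors", {
    expect_equal(averagePrecision(letters[1:6], c("a", "b", "c")), 1)
    expect_equal(averagePrecision(c("x", "y", "p", "z"), "p"), 1 / 3)
    expect_equal(averagePrecision(c("a", "x", "b", "y"), c("a", "b")),
                 (1 + 2 / 3) / 2)
    expect_error(averagePrecision(c("a", "b"), "q"), "absent")
    expect_error(averagePrecision(c("a", "b"), character(0)), "nonempty")
})

test_that("average precision equals the exhaustive oracle on small rankings", {
    for (n in 2:6) {
        ranking <- paste0("g", seq_len(n))
        for (k in 1:min(4, n)) {
            sets <- utils::combn(ranking, k)
            for (j in seq_len(ncol(sets))) {
                pos <- sets[, j]
                expect_equal(averagePrecision(ranking, pos),
                             apOracle(ranking, pos))
            }
        }
    }
})

test_that("a clique group disjoint from the rest is perfectly learnable", {
    # clique of 6 plus unrelated background genes
    cl <- sprintf("c%d", 1:6)
    pairs <- utils::combn(cl, 2)
    net <- geneNetwork(t(pairs), genes = c(cl, sprintf("b%02d", 1:30)))
    ann <- annotationSet(list(CL = cl), universe = genes(net))
    for (s in 1:3) {
        tab <- evaluateNetwork(net, ann, runConfig(seed = s,
                                                   null_reps = 200))
        expect_equal(apScores(tab)$ap[1], 1)
    }
})

test_that("cross-validated AP pools folds and matches the C++ evaluator", {
    net <- generateRandomNetwork(60, 90, seed = 3)
    ann <- generatePseudoGroups(60, 6, 6, seed = 4)
    cfg <- runConfig(seed = 5, null_reps = 200)
    tab <- apScores(evaluateNetwork(net, ann, cfg))
    U <- sort(unique(c(genes(net), universe(ann))), method = "radix")
    for (g in names(groups(ann))) {
        ref <- crossValidatedAP(net, groups(ann)[[g]], cfg, group_id = g,
                                universe = U)
        expect_equal(ref$ap, tab$ap[tab$group_id == g], tolerance = 1e-12)
        # fold sizes differ by at most one
        sizes <- table(ref$fold_assignment)
        expect_lte(max(sizes) - min(sizes), 1)
    }
})

test_that("evaluation is deterministic in the seed and skips tiny groups", {
    net <- generateRandomNetwork(50, 80, seed = 1)
    ann <- annotationSet(list(ok = genes(net)[1:6], tiny = genes(net)[7:8]),
                        universe = genes(net))
    cfg <- runConfig(seed = 9, null_reps = 150)
    t1 <- suppressMessages(evaluateNetwork(net, ann, cfg))
    t2 <- suppressMessages(evaluateNetwork(net, ann, cfg))
    expect_identical(apScores(t1), apScores(t2))
    expect_true(apScores(t1)$skipped[2])
    expect_true(is.na(apScores(t1)$ap[2]))
    expect_error(crossValidatedAP(net, genes(net)[1:2], cfg), "skipped")
})

test_that("a group with no connectivity scores near the fold-matched null", {
    # no edges anywhere: every gene falls back to the prevalence score, the
    # ranking is a pure tie-break permutation, and AP matches the
    # fold-matched random-ranking null.  (With other genes connected, the
    # prevalence fallback deliberately places isolated genes above the
    # zero-score block, so an isolated group in a connected network sits
    # above this null; see the methods vignette.)
    net <- geneNetwork(NULL, genes = sprintf("n%03d", 1:300))
    ann <- generatePseudoGroups(300, 20, 12, seed = 44,
                                gene_names = genes(net))
    for (s in 1:3) {
        tab <- evaluateNetwork(net, ann, runConfig(seed = s,
                                                   null_reps = 1000))
        t <- apScores(tab)
        # single-group APs are skewed, so individual draws are compared via
        # their empirical p; the MAP is compared against the null moments
        expect_true(all(t$empirical_p > 0.001))
        nm <- nullMapStats(tab)
        expect_lt(abs(mapScore(tab) - nm$mean), 3 * nm$sd)
    }
})

test_that("on dense fixtures the AP moves less than a null SD across seeds", {
    # a group with strong in-group connectivity: evaluation noise (folds and
    # tie keys) must not move its AP materially
    set.seed(3)
    mem <- sprintf("d%02d", 1:10)
    in_edges <- t(utils::combn(mem, 2))[sample(45, 30), ]
    bg <- generateRandomNetwork(60, 80, seed = 4)
    net <- geneNetwork(rbind(in_edges, edges(bg)),
                       genes = c(mem, genes(bg)))
    ann <- annotationSet(list(D = mem), universe = genes(net))
    aps <- vapply(1:6, function(s) {
        apScores(evaluateNetwork(net, ann, runConfig(seed = s,
                                                     null_reps = 300)))$ap
    }, numeric(1))
    tab <- apScores(evaluateNetwork(net, ann, runConfig(seed = 1,
                                                        null_reps = 300)))
    expect_lt(max(aps) - min(aps), tab$null_sd[1])
})

test_that("MAP is the arithmetic mean over included groups and is order-invariant", {
    net <- generateRandomNetwork(40, 60, seed = 6)
    ann <- generatePseudoGroups(40, 5, 5, seed = 7)
    tab <- evaluateNetwork(net, ann, runConfig(seed = 8, null_reps = 150))
    t <- apScores(tab)
    expect_equal(mapScore(tab), mean(t$ap))
    expect_equal(mapAcrossGroups(tab), mapScore(tab))
    expect_equal(mapAcrossGroups(tab, include = c("G2", "G4")),
                 mean(t$ap[t$group_id %in% c("G2", "G4")]))
    expect_equal(mapAcrossGroups(tab, include = rev(t$group_id)),
                 mapScore(tab))
    expect_equal(mapAcrossGroups(tab, include = "G3"),
                 t$ap[t$group_id == "G3"])
})

test_that("random-ranking null matches exact enumeration and a brute force", {
    # k = 1, n = 2: AP is 1 or 1/2 with equal probability -> mean 0.75
    rn <- randomRankingNull(1, 2, reps = 4000, seed = 1)
    expect_lt(abs(rn$mean - 0.75), 3 * rn$sd / sqrt(4000))
    # k = n - 1 = 1 symmetric case
    rn2 <- randomRankingNull(1, 2, reps = 4000, seed = 2)
    expect_lt(abs(rn2$mean - 0.75), 0.02)
    # k = 3, n = 6: exhaustive enumeration over all C(6, 3) placements
    sets <- utils::combn(6, 3)
    exact <- mean(apply(sets, 2, function(r) mean(seq_len(3) / sort(r))))
    rn3 <- randomRankingNull(3, 6, reps = 6000, seed = 3)
    expect_lt(abs(rn3$mean - exact), 3 * rn3$sd / sqrt(6000))
    # k = 20, n = 1000 against a brute force with a different generator
    brute <- vapply(1:3000, function(i) {
        r <- sort(sample(1000, 20))  # plain sample(), not sample.int
        mean(seq_len(20) / r)
    }, numeric(1))
    rn4 <- randomRankingNull(20, 1000, reps = 3000, seed = 4)
    se <- sqrt(rn4$sd^2 / 3000 + stats::var(brute) / 3000)
    expect_lt(abs(rn4$mean - mean(brute)), 3 * se)
    expect_error(randomRankingNull(5, 5), "k must be <")
    # determinism
    expect_identical(randomRankingNull(2, 10, 200, seed = 9)$aps,
                     randomRankingNull(2, 10, 200, seed = 9)$aps)
})

test_that("learnable groups use a strict margin over the null mean", {
    tab <- new("APTable",
               table = data.frame(
                   group_id = c("A", "B", "C"),
                   k = c(10L, 10L, 10L),
                   ap = c(0.05, 0.061, 0.2),
                   null_mean = c(0.05, 0.05, 0.05),
                   null_sd = c(0.01, 0.01, 0.01),
                   empirical_p = c(0.5, 0.1, 0.001),
                   learnable = c(FALSE, TRUE, TRUE),
                   skipped = c(FALSE, FALSE, FALSE)),
               map = 0.1, n_folds = 3L, seed = 1L,
               scores = matrix(numeric(0), 0, 0))
    expect_identical(learnableGroups(tab, 0.01), c("B", "C"))
    expect_identical(learnableGroups(tab, 0), c("B", "C"))
    expect_identical(learnableGroups(tab, 0.15), "C")
})

test_that("group density reports in-group and outgoing connectivity", {
    cl <- sprintf("k%d", 1:4)
    net <- geneNetwork(t(utils::combn(cl, 2)))
    d <- groupDensity(net, cl)
    expect_equal(d$in_edges, 6)
    expect_equal(d$density, 1)
    expect_equal(d$out_edges, 0)
    # edgeless group
    net2 <- generateRandomNetwork(30, 30, seed = 5)
    iso_ann <- c("zz1", "zz2", "zz3")
    net3 <- geneNetwork(edges(net2), genes = c(genes(net2), iso_ann))
    expect_equal(groupDensity(net3, iso_ann)$density, 0)
})

test_that("a clique-like complex group reproduces its density signature", {
    # synthetic clone of a complex-like group: k members with 27 in-group
    # interactions and > 1200 outgoing connections
    k <- 12
    mem <- sprintf("m%02d", 1:k)
    out <- sprintf("o%04d", 1:1300)
    in_pairs <- t(utils::combn(mem, 2))[1:27, ]
    set.seed(13)
    out_pairs <- cbind(sample(mem, 1250, replace = TRUE), out[1:1250])
    net <- geneNetwork(rbind(in_pairs, out_pairs))
    d <- groupDensity(net, mem)
    expect_equal(d$in_edges, 27)
    expect_equal(d$density, 27 / (k * (k - 1) / 2))
    expect_gt(d$out_edges, 1200)
})

test_that("fold assignment is deterministic and balanced per group", {
    f1 <- netcrit:::.groupFolds("G7", 20, 3, 11)
    f2 <- netcrit:::.groupFolds("G7", 20, 3, 11)
    expect_identical(f1, f2)
    expect_lte(diff(range(table(f1))), 1)
    f3 <- netcrit:::.groupFolds("G8", 20, 3, 11)
    expect_false(identical(f1, f3))
})
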