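# ---- seeded randomness ------------------------------------------------------

# Derive a deterministic 31-bit sub-seed from (seed, salt).  Salts are short
# strings; arithmetic stays exact in doubles.
.deriveSeed <- function(seed, salt) {
    M <- 2147483647
    h <- 0
    for (ch in utf8ToInt(as.character(salt))) h <- (h * 131 + ch) %% M
    s <- ((abs(as.numeric(seed)) %% M) * 48271 + h) %% M
    as.integer(s)
}

# Evaluate expr under a temporary RNG state.
.withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    expr
}

# Balanced fold assignment for one group: a permutation of
# rep(0:(F-1), length.out = k).  Deterministic given (group id, F, seed) and
# independent of any other group.
.groupFolds <- function(group_id, k, n_folds, seed) {
    labels <- rep(seq_len(n_folds) - 1L, length.out = k)
    .withSeed(.deriveSeed(seed, paste0("fold:", group_id)),
              sample(labels))
}

.makeFolds <- function(ann, n_folds, seed) {
    ks <- vapply(ann@groups, length, integer(1))
    mapply(.groupFolds, names(ann@groups), ks,
           MoreArgs = list(n_folds = n_folds, seed = seed),
           SIMPLIFY = FALSE)
}

# Hot-loop variant of .makeFolds with identical output: the per-group salt
# hashes and fold-label templates are precomputed once, and the caller is
# responsible for RNG state (no per-group save/restore).
.saltHash <- function(salt) {
    M <- 2147483647
    h <- 0
    for (ch in utf8ToInt(salt)) h <- (h * 131 + ch) %% M
    h
}

.foldTemplates <- function(ann, n_folds) {
    ks <- vapply(ann@groups, length, integer(1))
    list(hashes = vapply(paste0("fold:", names(ann@groups)), .saltHash,
                         numeric(1)),
         labels = lapply(ks, function(k) {
             rep(seq_len(n_folds) - 1L, length.out = k)
         }))
}

.makeFoldsFast <- function(templates, seed) {
    M <- 2147483647
    s <- (abs(as.numeric(seed)) %% M) * 48271
    hashes <- templates$hashes
    labels <- templates$labels
    out <- vector("list", length(hashes))
    for (i in seq_along(hashes)) {
        set.seed(as.integer((s + hashes[i]) %% M))
        out[[i]] <- sample(labels[[i]])
    }
    out
}

# One tie-break key per gene, drawn once per evaluation.
.makeTieKeys <- function(n, seed) {
    .withSeed(.deriveSeed(seed, "tiekey"), runif(n))
}

# ---- protocol assembly ------------------------------------------------------

# The evaluation universe is the union of network genes and the annotation
# universe; every universe gene is a ranking candidate (closed world).
.evalUniverse <- function(net, ann) {
    sort(unique(c(net@genes, ann@universe)), method = "radix")
}

# Index-aligned protocol pieces shared by evaluateNetwork and the edge scan.
.protocol <- function(net, ann, cfg) {
    U <- .evalUniverse(net, ann)
    n <- length(U)
    u <- match(net@edges[, 1], U) - 1L
    v <- match(net@edges[, 2], U) - 1L
    ks <- vapply(ann@groups, length, integer(1))
    scored <- ks >= cfg@n_folds
    groups_idx <- lapply(ann@groups[scored],
                         function(g) match(g, U) - 1L)
    folds <- .makeFolds(ann, cfg@n_folds, cfg@seed)[scored]
    keys <- .makeTieKeys(n, cfg@seed)
    list(U = U, n = n, u = u, v = v, ks = ks, scored = scored,
         groups_idx = groups_idx, folds = folds, keys = keys)
}

# ---- null calibration -------------------------------------------------------

#' Null distribution of average precision for random rankings
#'
#' Monte-Carlo distribution of AP when \code{k} positives are placed by a
#' uniformly random permutation of \code{n} genes (one single ranking, no
#' cross-validation structure).
#'
#' @param k number of positives (1 <= k < n).
#' @param n ranking length.
#' @param reps Monte-Carlo replicates (>= 100).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return list with \code{mean}, \code{sd}, \code{quantiles} (1\%, 5\%,
#'   50\%, 95\%, 99\%) and the vector of sampled \code{aps}.
#' @examples
#' # k = 1, n = 2: ranks 1 and 2 are equally likely, so E[AP] = 0.75
#' randomRankingNull(1, 2, reps = 2000, seed = 1)$mean
#' @export
randomRankingNull <- function(k, n, reps = 1000L, seed = 1L) {
    if (k >= n) stop("k must be < n")
    if (k < 1) stop("k must be >= 1")
    if (reps < 100) stop("reps must be >= 100")
    aps <- .withSeed(seed, vapply(seq_len(reps), function(i) {
        r <- sort.int(sample.int(n, k))
        mean(seq_len(k) / r)
    }, numeric(1)))
    list(mean = mean(aps), sd = stats::sd(aps),
         quantiles = stats::quantile(aps, c(.01, .05, .5, .95, .99)),
         aps = aps)
}

# Fold-matched random-ranking null for the pooled cross-validated AP: per
# fold, k_f positives are placed uniformly among the n - (k - k_f)
# candidates (training positives are not candidates); contributions pool
# exactly as in the real protocol.  This is the calibration used for
# learnability: an uninformative network is centred on it.
.foldedNullAps <- function(fold_sizes, n, reps, seed) {
    k <- sum(fold_sizes)
    .withSeed(seed, vapply(seq_len(reps), function(i) {
        tot <- 0
        for (kf in fold_sizes) {
            ncand <- n - (k - kf)
            r <- sort.int(sample.int(ncand, kf))
            tot <- tot + sum(seq_len(kf) / r)
        }
        tot / k
    }, numeric(1)))
}

# Cache of folded-null draws keyed by (fold sizes, n); seeds derive from the
# cache key so results are reproducible and shared across identical groups.
.foldedNullCached <- function(fold_sizes, n, reps, seed, cache) {
    sizes <- sort(fold_sizes)
    key <- paste(c(n, reps, sizes), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    aps <- .foldedNullAps(sizes, n, reps,
                          .deriveSeed(seed, paste0("null:", key)))
    cache[[key]] <- aps
    aps
}

# ---- core operations --------------------------------------------------------

#' Neighbor-voting scores against a training set
#'
#' For each gene outside the training set, the score is the fraction of its
#' network neighbors that are training positives; genes with no network
#' connections fall back to the training prevalence
#' \code{|training| / |universe|} so that an empty network reproduces the
#' random-ranking null in expectation.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param training_positives character vector of training genes (nonempty).
#' @param holdout character vector of held-out positives (disjoint from
#'   training); checked, and included among the scored genes.
#' @param universe optional evaluation universe; defaults to the union of
#'   network genes, training and holdout.
#' @return named numeric vector of scores in [0, 1] for every universe gene
#'   not in the training set.
#' @examples
#' net <- geneNetwork(rbind(c("a", "b"), c("b", "c")))
#' neighborVotingScores(net, "a", "b")[c("b", "c")]  # 1/2, 0
#' @export
neighborVotingScores <- function(network, training_positives, holdout =
                                 character(0), universe = NULL) {
    if (!length(training_positives))
        stop("empty training set: no vote possible")
    if (length(intersect(training_positives, holdout)))
        stop("training and holdout sets must be disjoint")
    if (is.null(universe))
        universe <- sort(unique(c(network@genes, training_positives,
                                  holdout)), method = "radix")
    if (!all(c(training_positives, holdout) %in% universe))
        stop("training and holdout genes must be in the universe")
    deg <- nodeDegrees(network)
    deg_full <- setNames(integer(length(universe)), universe)
    deg_full[names(deg)] <- deg
    votes <- setNames(numeric(length(universe)), universe)
    e <- network@edges
    in_train_a <- e[, 1] %in% training_positives
    in_train_b <- e[, 2] %in% training_positives
    if (any(in_train_a)) {
        tb <- table(e[in_train_a, 2])
        votes[names(tb)] <- votes[names(tb)] + as.integer(tb)
    }
    if (any(in_train_b)) {
        ta <- table(e[in_train_b, 1])
        votes[names(ta)] <- votes[names(ta)] + as.integer(ta)
    }
    prev <- length(training_positives) / length(universe)
    score <- ifelse(deg_full > 0, votes / pmax(deg_full, 1L), prev)
    score[setdiff(universe, training_positives)]
}

#' Rank genes by score with seeded random tie-breaking
#'
#' Binary-vote scores are heavily tied; ties are broken by a random key drawn
#' once per call (deterministic given \code{seed}), matching the assumptions
#' of the random-ranking null.
#'
#' @param scores named numeric vector.
#' @param seed integer seed for the tie-break key.
#' @param tie_key optional explicit key (same length as \code{scores});
#'   overrides \code{seed}.
#' @return character vector of gene names, best first (positions 1..n).
#' @export
rankGenes <- function(scores, seed = 1L, tie_key = NULL) {
    if (is.null(tie_key))
        tie_key <- .withSeed(.deriveSeed(seed, "tiekey"),
                             runif(length(scores)))
    names(scores)[order(-scores, tie_key)]
}

#' Average precision of a ranking
#'
#' \deqn{AP = (1/k) \sum_{i=1..k} i / r_i}{AP = (1/k) sum_i i/r_i}
#' where \eqn{r_1 < ... < r_k} are the ranks of the \eqn{k} positives: the
#' mean of the precision at each positive's rank (the discrete area under
#' the precision-recall curve).  AP is 1 exactly when the positives occupy
#' ranks 1..k.
#'
#' @param ranking character vector of genes, best first (tie-free positions).
#' @param positives nonempty character vector, all present in the ranking.
#' @return AP in [0, 1].
#' @examples
#' averagePrecision(c("a", "x", "b", "y"), c("a", "b"))  # (1 + 2/3)/2
#' @export
averagePrecision <- function(ranking, positives) {
    if (!length(positives)) stop("positives must be nonempty")
    r <- match(positives, ranking)
    if (anyNA(r))
        stop("positive gene(s) absent from ranking: ",
             paste(positives[is.na(r)], collapse = ", "))
    r <- sort.int(r)
    mean(seq_along(r) / r)
}

#' Cross-validated average precision for a single gene group
#'
#' Pure-R implementation of the pooled cross-validation protocol: the
#' positives are split into balanced folds; per fold, the held-out positives
#' are scored by \code{\link{neighborVotingScores}} against the remaining
#' training positives with all non-group universe genes as candidates, and
#' the precision contributions of true positives are pooled across folds
#' into one AP.  Fold assignment and tie-breaking are deterministic given
#' (\code{group_id}, \code{cfg@n_folds}, \code{cfg@seed}) and match
#' \code{\link{evaluateNetwork}} exactly.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param group character vector of positives (size >= \code{cfg@n_folds}).
#' @param cfg a \linkS4class{RunConfig}.
#' @param group_id identifier used to derive the fold assignment.
#' @param universe optional evaluation universe (defaults to the union of
#'   network genes and the group).
#' @return list with \code{ap}, \code{fold_assignment} (0-based fold per
#'   group member) and \code{fold_rankings} (per fold, the ranked candidate
#'   genes, best first).
#' @export
crossValidatedAP <- function(network, group, cfg = runConfig(),
                             group_id = "group", universe = NULL) {
    if (is.null(universe))
        universe <- sort(unique(c(network@genes, group)), method = "radix")
    group <- as.character(group)
    k <- length(group)
    if (k < cfg@n_folds)
        stop(sprintf("group '%s' has %d members but n_folds = %d; skipped",
                     group_id, k, cfg@n_folds))
    folds <- .groupFolds(group_id, k, cfg@n_folds, cfg@seed)
    keys <- setNames(.makeTieKeys(length(universe), cfg@seed), universe)
    apsum <- 0
    fold_rankings <- vector("list", cfg@n_folds)
    for (f in seq_len(cfg@n_folds) - 1L) {
        hold <- group[folds == f]
        train <- group[folds != f]
        if (!length(hold)) next
        sc <- neighborVotingScores(network, train, hold, universe = universe)
        ranking <- names(sc)[order(-sc, keys[names(sc)])]
        fold_rankings[[f + 1L]] <- ranking
        r <- sort.int(match(hold, ranking))
        apsum <- apsum + sum(seq_along(r) / r)
    }
    list(ap = apsum / k, fold_assignment = folds,
         fold_rankings = fold_rankings)
}

#' Evaluate a network against an annotation set
#'
#' Runs the pooled cross-validated neighbor-voting protocol for every
#' annotation group, calibrates each AP against a fold-matched random-ranking
#' null, and aggregates to the MAP.  Groups smaller than \code{cfg@n_folds}
#' are skipped (NA rows).  The evaluation universe is the union of network
#' genes and the annotation universe.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param ann an \linkS4class{AnnotationSet}.
#' @param cfg a \linkS4class{RunConfig}; \code{cfg@seed} fixes fold
#'   assignment and tie-breaking, \code{cfg@null_reps} the null calibration.
#' @param keep_scores logical; when TRUE the per-gene voting scores (mean
#'   over folds for non-members, holdout-fold score for members) are kept for
#'   \code{\link{rankConcordance}}.
#' @return an \linkS4class{APTable}.
#' @examples
#' net <- generateRandomNetwork(50, 60, seed = 1)
#' ann <- generatePseudoGroups(50, 5, 6, seed = 2)
#' tab <- evaluateNetwork(net, ann, runConfig(seed = 3, null_reps = 200))
#' mapScore(tab)
#' @export
evaluateNetwork <- function(network, ann, cfg = runConfig(),
                            keep_scores = FALSE) {
    stopifnot(is(network, "GeneNetwork"), is(ann, "AnnotationSet"),
              is(cfg, "RunConfig"))
    pr <- .protocol(network, ann, cfg)
    ng <- length(ann@groups)
    ap <- rep(NA_real_, ng)
    res <- .cpp_eval_groups(pr$n, pr$u, pr$v, pr$groups_idx, pr$folds,
                            cfg@n_folds, pr$keys, isTRUE(keep_scores))
    ap[pr$scored] <- res$ap
    if (any(!pr$scored))
        message(sprintf(
            "evaluateNetwork: skipped %d group(s) smaller than n_folds = %d",
            sum(!pr$scored), cfg@n_folds))

    null_mean <- rep(NA_real_, ng)
    null_sd <- rep(NA_real_, ng)
    emp_p <- rep(NA_real_, ng)
    cache <- new.env(parent = emptyenv())
    sidx <- which(pr$scored)
    for (i in seq_along(sidx)) {
        g <- sidx[i]
        sizes <- tabulate(pr$folds[[i]] + 1L, nbins = cfg@n_folds)
        sizes <- sizes[sizes > 0]
        aps0 <- .foldedNullCached(sizes, pr$n, cfg@null_reps, cfg@seed,
                                  cache)
        null_mean[g] <- mean(aps0)
        null_sd[g] <- stats::sd(aps0)
        emp_p[g] <- (1 + sum(aps0 >= ap[g])) / (length(aps0) + 1)
    }
    learnable <- ap - null_mean > cfg@learnability_delta
    tab <- data.frame(
        group_id = names(ann@groups),
        k = unname(pr$ks),
        ap = ap,
        null_mean = null_mean,
        null_sd = null_sd,
        empirical_p = emp_p,
        learnable = learnable,
        skipped = !pr$scored,
        row.names = NULL, stringsAsFactors = FALSE)
    scores <- if (isTRUE(keep_scores)) {
        m <- res$scores
        dimnames(m) <- list(pr$U, names(ann@groups)[pr$scored])
        m
    } else {
        matrix(numeric(0), 0, 0)
    }
    new("APTable", table = tab, map = mean(ap[pr$scored]),
        n_folds = cfg@n_folds, seed = cfg@seed, scores = scores)
}

#' @describeIn evaluateNetwork the per-group result table.
#' @param x an \linkS4class{APTable}.
#' @export
setMethod("apScores", "APTable", function(x) x@table)

#' @describeIn evaluateNetwork the global MAP (mean AP over scored groups).
#' @export
setMethod("mapScore", "APTable", function(x) x@map)

#' @describeIn evaluateNetwork the per-gene score matrix (empty unless
#'   \code{keep_scores = TRUE}).
#' @export
setMethod("geneScores", "APTable", function(x) x@scores)

setMethod("show", "APTable", function(object) {
    t <- object@table
    scored <- !t$skipped
    cat(sprintf("APTable: %d groups (%d scored), %d-fold CV, seed %d\n",
                nrow(t), sum(scored), object@n_folds, object@seed))
    cat(sprintf("  MAP = %.4f\n", object@map))
    if (any(scored, na.rm = TRUE))
        cat(sprintf("  learnable groups: %d\n",
                    sum(t$learnable[scored], na.rm = TRUE)))
    invisible(NULL)
})

#' Mean average precision across groups
#'
#' Arithmetic mean of per-group APs over the included groups; invariant to
#' group order.
#'
#' @param aptable an \linkS4class{APTable}.
#' @param include optional character vector of group ids (or logical/integer
#'   index) selecting the groups to average; defaults to all scored groups.
#' @return MAP as a single number.
#' @export
mapAcrossGroups <- function(aptable, include = NULL) {
    t <- aptable@table
    if (is.null(include)) {
        sel <- !t$skipped
    } else if (is.character(include)) {
        sel <- t$group_id %in% include
    } else {
        sel <- include
    }
    sel <- sel & !t$skipped
    if (!any(sel)) stop("no scored groups included")
    mean(t$ap[sel])
}

#' Learnable groups
#'
#' Groups whose cross-validated AP exceeds the null mean by strictly more
#' than \code{delta}.
#'
#' @param aptable an \linkS4class{APTable}.
#' @param delta margin in AP units (default 0.01).
#' @return character vector of group ids.
#' @export
learnableGroups <- function(aptable, delta = 0.01) {
    t <- aptable@table
    sel <- !t$skipped & (t$ap - t$null_mean > delta)
    t$group_id[sel]
}

#' In-group connectivity of an annotation group
#'
#' Clique-like groups (e.g. protein complexes) have high in-group density;
#' most functional groups have very sparse in-group connectivity.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param group character vector of member genes (>= 2).
#' @return list with \code{in_edges} (edges with both endpoints in the
#'   group), \code{density} (in-group edges / C(k, 2) over in-universe
#'   members) and \code{out_edges} (edges with exactly one endpoint in the
#'   group).
#' @export
groupDensity <- function(network, group) {
    group <- unique(as.character(group))
    k <- length(group)
    if (k < 2) stop("group must have >= 2 genes")
    e <- network@edges
    a_in <- e[, 1] %in% group
    b_in <- e[, 2] %in% group
    in_edges <- sum(a_in & b_in)
    out_edges <- sum(xor(a_in, b_in))
    list(in_edges = in_edges,
         density = in_edges / (k * (k - 1) / 2),
         out_edges = out_edges)
}

# Null distribution summary for the MAP of an APTable: groups are
# independent under the random-ranking null, so the MAP null has mean equal
# to the mean of the per-group null means and SD sqrt(sum sd_g^2)/G.
.nullMapStats <- function(aptable) {
    t <- aptable@table
    sel <- !t$skipped
    G <- sum(sel)
    list(mean = mean(t$null_mean[sel]),
         sd = sqrt(sum(t$null_sd[sel]^2)) / G)
}
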