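#' Predict exceptional edges from annotation overlap alone
#'
#' Greedy selection of gene pairs by weighted shared-annotation count, with
#' no network input: the score of a pair is the sum over its shared groups of
#' \code{1 / (1 + usage)^weight_exponent}, where \code{usage} counts how many
#' previously selected pairs used that group.  The maximal-scoring unselected
#' pair is taken (ties broken lexicographically), the usage of its shared
#' groups is incremented, and the loop repeats until \code{m} pairs are
#' selected or no pair with positive score remains (then the truncated list
#' is returned with a warning).  The \code{1/(1+usage)} form makes the first
#' use of a group weigh 1 and down-weights reuse; candidate pairs are
#' enumerated only among genes sharing at least one group (all other pairs
#' score 0).
#'
#' @param ann an \linkS4class{AnnotationSet} with at least 2 annotated genes.
#' @param m number of pairs to select (>= 1).
#' @param weight_exponent exponent on the usage down-weighting (default 1).
#' @return a \linkS4class{PredictedEdgeList}.
#' @export
predictExceptionalEdges <- function(ann, m, weight_exponent = 1) {
    stopifnot(is(ann, "AnnotationSet"))
    if (m < 1) stop("m must be >= 1")
    n_ann <- sum(multifunctionality(ann) > 0)
    if (n_ann < 2) stop("need at least 2 annotated genes")

    # candidate pairs: all within-group pairs, deduplicated
    ng <- length(ann@groups)
    pa <- character(0); pb <- character(0); pg <- integer(0)
    for (gi in seq_len(ng)) {
        mem <- sort(ann@groups[[gi]], method = "radix")
        if (length(mem) < 2) next
        cmb <- utils::combn(mem, 2)
        pa <- c(pa, cmb[1, ]); pb <- c(pb, cmb[2, ])
        pg <- c(pg, rep.int(gi, ncol(cmb)))
    }
    if (!length(pa)) stop("no gene pair shares a group")
    key <- paste(pa, pb, sep = "\r")
    ukey <- sort(unique(key), method = "radix")
    pid <- match(key, ukey)
    npairs <- length(ukey)
    S <- Matrix::sparseMatrix(i = pid, j = pg, x = 1,
                              dims = c(npairs, ng))
    shared_n <- as.integer(Matrix::rowSums(S))
    first_tab <- match(ukey, key)
    pair_a <- pa[first_tab]
    pair_b <- pb[first_tab]

    usage <- integer(ng)
    selected <- integer(0)
    sel_score <- numeric(0)
    available <- rep(TRUE, npairs)
    for (it in seq_len(m)) {
        w <- (1 + usage)^(-weight_exponent)
        sc <- as.numeric(S %*% w)
        sc[!available] <- -Inf
        best <- max(sc)
        if (!is.finite(best) || best <= 0) {
            warning(sprintf(
                "only %d pair(s) with positive score; requested %d",
                length(selected), m))
            break
        }
        cand <- which(sc == best)
        pick <- cand[1L]  # ukey is radix-sorted, so cand[1] is lexic. least
        selected <- c(selected, pick)
        sel_score <- c(sel_score, best)
        available[pick] <- FALSE
        used <- pg[pid == pick]
        usage[used] <- usage[used] + 1L
    }
    names(usage) <- names(ann@groups)
    pairs <- data.frame(
        rank = seq_along(selected),
        gene_a = pair_a[selected],
        gene_b = pair_b[selected],
        score = sel_score,
        shared_groups = shared_n[selected],
        row.names = NULL, stringsAsFactors = FALSE)
    new("PredictedEdgeList", pairs = pairs, usage = usage)
}

#' @describeIn predictExceptionalEdges the ordered pair table.
#' @param x a \linkS4class{PredictedEdgeList}.
#' @export
setMethod("predictedPairs", "PredictedEdgeList", function(x) x@pairs)

setMethod("show", "PredictedEdgeList", function(object) {
    cat(sprintf("PredictedEdgeList with %d pairs\n", nrow(object@pairs)))
    print(head(object@pairs, 5))
    if (nrow(object@pairs) > 5) cat("  ...\n")
    invisible(NULL)
})

#' Overlap between predicted pairs and a network
#'
#' @param predicted a \linkS4class{PredictedEdgeList}.
#' @param network a \linkS4class{GeneNetwork}.
#' @return list with \code{count} (predicted pairs present as network edges)
#'   and \code{fraction} (count / number of predicted pairs).
#' @export
networkOverlap <- function(predicted, network) {
    p <- predicted@pairs
    if (!nrow(p)) return(list(count = 0L, fraction = NaN))
    canon <- .canonicalizeEdges(p$gene_a, p$gene_b)
    key_p <- paste(canon$edges[, 1], canon$edges[, 2], sep = "\r")
    key_n <- paste(network@edges[, 1], network@edges[, 2], sep = "\r")
    count <- sum(key_p %in% key_n)
    list(count = count, fraction = count / nrow(p))
}

#' Skeleton network from predicted pairs
#'
#' A tiny network consisting of only the first \code{top_m} predicted pairs.
#' Its gene set is their endpoints plus the supplied universe, so that
#' evaluation ranks the full gene list.
#'
#' @param predicted a \linkS4class{PredictedEdgeList}.
#' @param top_m number of leading pairs to keep (<= number predicted).
#' @param universe optional additional gene set (e.g. the annotation
#'   universe).
#' @return a \linkS4class{GeneNetwork} with exactly \code{top_m} edges over
#'   at most \code{2 * top_m} connected genes.
#' @export
skeletonNetwork <- function(predicted, top_m, universe = NULL) {
    p <- predicted@pairs
    if (top_m > nrow(p))
        stop("top_m exceeds the number of predicted pairs")
    p <- p[seq_len(top_m), , drop = FALSE]
    g <- sort(unique(c(p$gene_a, p$gene_b, universe)), method = "radix")
    geneNetwork(cbind(p$gene_a, p$gene_b), genes = g)
}
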