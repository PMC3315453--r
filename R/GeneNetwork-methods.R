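# Byte-wise (locale-independent) string comparison helpers; canonical edge
# storage must not depend on the session locale.
.cstring_lt <- function(a, b) {
    u <- sort(unique(c(a, b)), method = "radix")
    match(a, u) < match(b, u)
}

.radix_order <- function(...) order(..., method = "radix")

# Canonicalize a two-column character matrix of edges: swap so gene_a <
# gene_b bytewise, drop self loops and duplicates, sort rows.
.canonicalizeEdges <- function(a, b) {
    self <- a == b
    n_self <- sum(self)
    a2 <- a[!self]
    b2 <- b[!self]
    swap <- !.cstring_lt(a2, b2)
    if (any(swap)) {
        tmp <- a2[swap]
        a2[swap] <- b2[swap]
        b2[swap] <- tmp
    }
    key <- paste(a2, b2, sep = "\r")
    keep <- !duplicated(key)
    a2 <- a2[keep]
    b2 <- b2[keep]
    o <- .radix_order(a2, b2)
    list(edges = cbind(gene_a = a2[o], gene_b = b2[o]),
         dropped_self_loops = n_self)
}

#' Construct a GeneNetwork
#'
#' Builds a canonical \linkS4class{GeneNetwork} from an edge list.  Reversed
#' duplicates collapse to a single edge; self loops are dropped (their count
#' is retained in the object).
#'
#' @param edges a two-column character matrix or data.frame of gene pairs;
#'   may be empty.
#' @param genes optional character vector of node identifiers; defaults to
#'   the genes appearing in \code{edges}.  Must contain all edge endpoints.
#' @return a \linkS4class{GeneNetwork}.
#' @examples
#' net <- geneNetwork(rbind(c("a", "b"), c("b", "a"), c("a", "c")))
#' numEdges(net)  # 2
#' @export
geneNetwork <- function(edges = NULL, genes = NULL) {
    if (is.null(edges)) {
        em <- matrix(character(0), ncol = 2)
        canon <- list(edges = em, dropped_self_loops = 0L)
    } else {
        edges <- as.matrix(edges)
        if (ncol(edges) < 2)
            stop("'edges' must have at least two columns")
        storage.mode(edges) <- "character"
        canon <- .canonicalizeEdges(edges[, 1], edges[, 2])
    }
    e <- canon$edges
    colnames(e) <- c("gene_a", "gene_b")
    if (is.null(genes)) {
        genes <- sort(unique(as.vector(e)), method = "radix")
    } else {
        genes <- as.character(genes)
        if (!all(as.vector(e) %in% genes))
            stop("all edge endpoints must be in 'genes'")
    }
    new("GeneNetwork", genes = genes, edges = e,
        droppedSelfLoops = as.integer(canon$dropped_self_loops))
}

#' @describeIn geneNetwork node identifiers.
#' @param x a \linkS4class{GeneNetwork}.
#' @export
setMethod("genes", "GeneNetwork", function(x, ...) x@genes)

#' @describeIn geneNetwork canonical edge matrix (columns \code{gene_a},
#'   \code{gene_b}).
#' @export
setMethod("edges", "GeneNetwork", function(x, ...) x@edges)

#' @describeIn geneNetwork number of nodes.
#' @export
setMethod("numGenes", "GeneNetwork", function(x) length(x@genes))

#' @describeIn geneNetwork number of edges.
#' @export
setMethod("numEdges", "GeneNetwork", function(x) nrow(x@edges))

#' @describeIn geneNetwork named integer vector of node degrees (number of
#'   incident edges; 0 for isolated genes).
#' @export
setMethod("nodeDegrees", "GeneNetwork", function(x, ...) {
    d <- integer(length(x@genes))
    names(d) <- x@genes
    if (nrow(x@edges)) {
        t1 <- table(factor(x@edges[, 1], levels = x@genes))
        t2 <- table(factor(x@edges[, 2], levels = x@genes))
        d <- setNames(as.integer(t1 + t2), x@genes)
    }
    d
})

setMethod("show", "GeneNetwork", function(object) {
    cat(sprintf("GeneNetwork with %d genes and %d edges\n",
                numGenes(object), numEdges(object)))
    if (object@droppedSelfLoops > 0L)
        cat(sprintf("  (%d self-loop record(s) dropped on input)\n",
                    object@droppedSelfLoops))
    if (numEdges(object)) {
        n <- min(5L, numEdges(object))
        apply(object@edges[seq_len(n), , drop = FALSE], 1L, function(r) {
            cat("  ", r[1], "--", r[2], "\n")
        })
        if (numEdges(object) > n) cat("  ...\n")
    }
    invisible(NULL)
})

# ---- internal index representation -----------------------------------------

# Integer view of a network: genes indexed 1..n, edges as index pairs.
.networkIndex <- function(net) {
    g <- net@genes
    e <- net@edges
    u <- match(e[, 1], g)
    v <- match(e[, 2], g)
    deg <- integer(length(g))
    if (length(u)) {
        tab <- tabulate(c(u, v), nbins = length(g))
        deg <- tab
    }
    list(genes = g, n = length(g), u = u, v = v, deg = deg)
}

# Linear index of a canonical pair (i < j, 1-based) among all C(n, 2) pairs,
# and its inverse.  Used for tallying edges compactly; exact in doubles for
# C(n, 2) < 2^53.
.pairToLinear <- function(i, j, n) {
    (i - 1) * n - (i - 1) * i / 2 + (j - i)
}

.linearToPair <- function(L, n) {
    # invert L = (i-1)*n - (i-1)*i/2 + (j-i); guard float error with a fixup
    i <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * L)) / 2) + 1
    i <- pmax(1, pmin(i, n - 1))
    base <- (i - 1) * n - (i - 1) * i / 2
    too_high <- base >= L
    while (any(too_high)) {
        i[too_high] <- i[too_high] - 1
        base <- (i - 1) * n - (i - 1) * i / 2
        too_high <- base >= L
    }
    nxt <- i * n - i * (i + 1) / 2
    too_low <- nxt < L
    while (any(too_low)) {
        i[too_low] <- i[too_low] + 1
        base <- (i - 1) * n - (i - 1) * i / 2
        nxt <- i * n - i * (i + 1) / 2
        too_low <- nxt < L
    }
    base <- (i - 1) * n - (i - 1) * i / 2
    j <- L - base + i
    cbind(i = as.integer(i), j = as.integer(j))
}

# Remove one edge (by endpoints) from a GeneNetwork, keeping the gene set.
.dropEdges <- function(net, drop_a, drop_b) {
    canon <- .canonicalizeEdges(drop_a, drop_b)
    key_all <- paste(net@edges[, 1], net@edges[, 2], sep = "\r")
    key_drop <- paste(canon$edges[, 1], canon$edges[, 2], sep = "\r")
    if (!all(key_drop %in% key_all))
        stop("edge(s) to remove are not present in the network")
    keep <- !(key_all %in% key_drop)
    new("GeneNetwork", genes = net@genes,
        edges = net@edges[keep, , drop = FALSE],
        droppedSelfLoops = 0L)
}

# Keep only the given edges (must be present).
.keepEdges <- function(net, keep_a, keep_b) {
    canon <- .canonicalizeEdges(keep_a, keep_b)
    key_all <- paste(net@edges[, 1], net@edges[, 2], sep = "\r")
    key_keep <- paste(canon$edges[, 1], canon$edges[, 2], sep = "\r")
    if (!all(key_keep %in% key_all))
        stop("edge(s) to keep are not present in the network")
    keep <- key_all %in% key_keep
    new("GeneNetwork", genes = net@genes,
        edges = net@edges[keep, , drop = FALSE],
        droppedSelfLoops = 0L)
}
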