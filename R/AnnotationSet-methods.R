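#' Construct an AnnotationSet
#'
#' @param groups named list of character vectors (group id -> member genes).
#'   Duplicate genes within a group are collapsed.
#' @param universe character vector of assessable genes; defaults to the
#'   union of all group members.
#' @return an \linkS4class{AnnotationSet}.
#' @examples
#' ann <- annotationSet(list(G1 = c("a", "b"), G2 = c("b", "c")))
#' groupSizes(ann)
#' multifunctionality(ann)["b"]  # 2
#' @export
annotationSet <- function(groups, universe = NULL) {
    if (length(groups) && (is.null(names(groups)) || any(names(groups) == "")))
        stop("groups must be named")
    groups <- lapply(groups, function(g) unique(as.character(g)))
    if (is.null(universe))
        universe <- sort(unique(unlist(groups, use.names = FALSE)),
                         method = "radix")
    new("AnnotationSet", groups = groups,
        universe = as.character(universe))
}

#' @describeIn annotationSet the named list of groups.
#' @param x an \linkS4class{AnnotationSet}.
#' @export
setMethod("groups", "AnnotationSet", function(x, ...) x@groups)

#' @describeIn annotationSet the gene universe.
#' @export
setMethod("universe", "AnnotationSet", function(x) x@universe)

#' @describeIn annotationSet named integer vector of group sizes.
#' @export
setMethod("groupSizes", "AnnotationSet", function(x) {
    vapply(x@groups, length, integer(1))
})

#' @describeIn annotationSet per-gene annotation count over the universe
#'   (0 for unannotated genes).
#' @export
setMethod("multifunctionality", "AnnotationSet", function(x) {
    m <- integer(length(x@universe))
    names(m) <- x@universe
    if (length(x@groups)) {
        tab <- table(factor(unlist(x@groups, use.names = FALSE),
                            levels = x@universe))
        m <- setNames(as.integer(tab), x@universe)
    }
    m
})

setMethod("show", "AnnotationSet", function(object) {
    ks <- groupSizes(object)
    cat(sprintf("AnnotationSet with %d groups over %d genes\n",
                length(object@groups), length(object@universe)))
    if (length(ks))
        cat(sprintf("  group sizes: min %d, median %s, max %d\n",
                    min(ks), format(stats::median(ks)), max(ks)))
    invisible(NULL)
})

# Reverse index: gene -> integer ids of containing groups.
.geneToGroups <- function(ann) {
    out <- vector("list", length(ann@universe))
    names(out) <- ann@universe
    for (gi in seq_along(ann@groups)) {
        for (g in ann@groups[[gi]]) out[[g]] <- c(out[[g]], gi)
    }
    out
}
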