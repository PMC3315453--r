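#' Read an undirected network from a two-column edge list
#'
#' The dialect is a lowest-common-denominator interchange format: one edge
#' per line, at least two whitespace- or tab-separated tokens (gene A,
#' gene B); further columns are ignored; lines starting with the comment
#' prefix are skipped.  Duplicate lines and reversed duplicates collapse to a
#' single canonical edge; self-loop lines are dropped (their count is kept in
#' the returned object and reported via \code{message}).
#'
#' @param path path to the edge-list file.
#' @param comment_prefix lines starting with this string are skipped.
#' @return a \linkS4class{GeneNetwork}.
#' @seealso \code{\link{writeEdgeList}}
#' @export
readEdgeList <- function(path, comment_prefix = "#") {
    if (!file.exists(path)) stop("edge-list file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- !startsWith(trimws(lines, "left"), comment_prefix) &
        nzchar(trimws(lines))
    lines <- lines[keep]
    if (!length(lines))
        stop("empty edge list: no network records in ", path)
    toks <- strsplit(trimws(lines), "[ \t]+")
    nt <- lengths(toks)
    if (any(nt < 2)) {
        bad <- which(keep)[which(nt < 2)[1]]
        stop(sprintf("malformed edge line %d in %s: need >= 2 fields",
                     bad, path))
    }
    a <- vapply(toks, `[[`, character(1), 1L)
    b <- vapply(toks, `[[`, character(1), 2L)
    net <- geneNetwork(cbind(a, b))
    if (net@droppedSelfLoops > 0L)
        message(sprintf("readEdgeList: dropped %d self-loop line(s)",
                        net@droppedSelfLoops))
    if (numEdges(net) == 0L)
        stop("empty network: all records were self loops in ", path)
    net
}

#' Write a GeneNetwork as a two-column TSV edge list
#'
#' Output is deterministic (canonical lexicographic edge order) and
#' round-trips through \code{\link{readEdgeList}} to an identical network.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(network, path) {
    stopifnot(is(network, "GeneNetwork"))
    validObject(network)
    con <- tryCatch(file(path, open = "wt"),
                    error = function(e) stop("cannot write to ", path,
                                             ": ", conditionMessage(e)))
    on.exit(close(con))
    writeLines("# gene_a\tgene_b", con)
    if (numEdges(network)) {
        writeLines(paste(network@edges[, 1], network@edges[, 2],
                         sep = "\t"), con)
    }
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one group per line, tab-separated fields
#' \code{name<TAB>description<TAB>member1<TAB>member2...}.  Duplicate member
#' entries within a line collapse; duplicate group identifiers across lines
#' are an error.
#'
#' @param path path to the GMT file.
#' @param universe optional explicit gene universe; defaults to the union of
#'   all members.
#' @return an \linkS4class{AnnotationSet}.
#' @export
readGMT <- function(path, universe = NULL) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    toks <- strsplit(lines, "\t", fixed = TRUE)
    nt <- lengths(toks)
    if (any(nt < 3))
        stop(sprintf("malformed GMT line %d in %s: need >= 3 tab-separated fields",
                     which(nt < 3)[1], path))
    ids <- vapply(toks, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicate group identifier in GMT: ",
             ids[duplicated(ids)][1])
    grp <- lapply(toks, function(t) unique(t[-c(1L, 2L)]))
    names(grp) <- ids
    if (!is.null(universe)) {
        members <- unique(unlist(grp, use.names = FALSE))
        extra <- setdiff(members, universe)
        if (length(extra))
            grp <- lapply(grp, intersect, y = universe)
        return(annotationSet(grp, universe = universe))
    }
    annotationSet(grp)
}

#' Write an AnnotationSet as a GMT file
#'
#' @param ann an \linkS4class{AnnotationSet}.
#' @param path output file path.
#' @param descriptions optional character vector of per-group descriptions
#'   (defaults to \code{"na"}).
#' @return invisibly, \code{path}.
#' @export
writeGMT <- function(ann, path, descriptions = NULL) {
    stopifnot(is(ann, "AnnotationSet"))
    if (is.null(descriptions)) descriptions <- rep("na", length(ann@groups))
    lines <- mapply(function(id, desc, members) {
        paste(c(id, desc, members), collapse = "\t")
    }, names(ann@groups), descriptions, ann@groups)
    writeLines(unname(lines), path)
    invisible(path)
}

#' Filter annotation groups by in-universe size
#'
#' Group membership is first intersected with the supplied universe, then
#' groups whose in-universe size falls outside \code{[min_size, max_size]}
#' are removed.  The returned universe is the supplied one.  The operation is
#' idempotent.
#'
#' @param ann an \linkS4class{AnnotationSet}.
#' @param min_size,max_size inclusive size bounds (the conventional
#'   assessment window is 10--300 genes).
#' @param universe gene universe to assess against; defaults to the
#'   annotation's own universe.
#' @return a filtered \linkS4class{AnnotationSet}.
#' @export
filterAnnotations <- function(ann, min_size = 10L, max_size = 300L,
                              universe = NULL) {
    stopifnot(is(ann, "AnnotationSet"))
    if (min_size < 1L) stop("min_size must be >= 1")
    if (is.null(universe)) universe <- ann@universe
    universe <- as.character(universe)
    if (!length(universe)) stop("empty universe")
    grp <- lapply(ann@groups, function(g) g[g %in% universe])
    sizes <- vapply(grp, length, integer(1))
    keep <- sizes >= min_size & sizes <= max_size
    annotationSet(grp[keep], universe = universe)
}
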