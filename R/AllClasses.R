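#' GeneNetwork: an undirected, unweighted gene network
#'
#' Stores a simple undirected graph over opaque, case-sensitive gene
#' identifiers.  Edges are canonical unordered pairs: each edge is stored once
#' with \code{gene_a < gene_b} (lexicographic, C locale) and rows sorted, so
#' \code{(a, b)} and \code{(b, a)} map to the same stored edge.  Self loops
#' are disallowed.
#'
#' @slot genes character vector of gene identifiers (the node set, ordered).
#' @slot edges two-column character matrix of canonical edges
#'   (columns \code{gene_a}, \code{gene_b}).
#' @slot droppedSelfLoops integer; number of self-loop records dropped when
#'   the object was constructed from external input.
#'
#' @seealso \code{\link{geneNetwork}}, \code{\link{readEdgeList}}
#' @exportClass GeneNetwork
setClass("GeneNetwork",
    representation(
        genes = "character",
        edges = "matrix",
        droppedSelfLoops = "integer"
    ),
    prototype(
        genes = character(0),
        edges = matrix(character(0), ncol = 2,
                       dimnames = list(NULL, c("gene_a", "gene_b"))),
        droppedSelfLoops = 0L
    )
)

setValidity("GeneNetwork", function(object) {
    e <- object@edges
    if (!is.character(e) || ncol(e) != 2)
        return("'edges' must be a two-column character matrix")
    if (anyDuplicated(object@genes))
        return("duplicated gene identifiers")
    if (nrow(e)) {
        if (any(e[, 1] == e[, 2]))
            return("self loops are not allowed")
        if (!all(e %in% object@genes))
            return("edge endpoints must be in the gene set")
        cmp <- .cstring_lt(e[, 1], e[, 2])
        if (!all(cmp))
            return("edges are not stored canonically (gene_a < gene_b)")
        key <- paste(e[, 1], e[, 2], sep = "\r")
        if (anyDuplicated(key))
            return("duplicate edges")
        if (is.unsorted(key))
            return("edge rows must be sorted")
    }
    TRUE
})

#' AnnotationSet: flat gene-function annotations
#'
#' A named collection of gene groups (e.g. GO-term gene sets, with no
#' ontology structure) over a fixed universe of assessable genes.  Groups may
#' overlap; the number of groups a gene belongs to is its
#' \emph{multifunctionality}.
#'
#' @slot groups named list; each element a character vector of member genes.
#' @slot universe character vector of all assessable genes.
#'
#' @seealso \code{\link{annotationSet}}, \code{\link{readGMT}},
#'   \code{\link{filterAnnotations}}
#' @exportClass AnnotationSet
setClass("AnnotationSet",
    representation(groups = "list", universe = "character"),
    prototype(groups = structure(list(), names = character(0)),
              universe = character(0))
)

setValidity("AnnotationSet", function(object) {
    g <- object@groups
    if (length(g)) {
        if (is.null(names(g)) || any(names(g) == "") ||
            anyDuplicated(names(g)))
            return("groups must be uniquely named")
        if (!all(vapply(g, is.character, logical(1))))
            return("each group must be a character vector")
        if (any(vapply(g, anyDuplicated, integer(1)) > 0))
            return("duplicate genes within a group")
        if (!all(unlist(g, use.names = FALSE) %in% object@universe))
            return("every annotated gene must be in the universe")
    }
    if (anyDuplicated(object@universe))
        return("duplicated genes in universe")
    TRUE
})

#' RunConfig: evaluation protocol parameters
#'
#' Bundles the tunable parameters of the cross-validation protocol and the
#' downstream criticality analysis.
#'
#' @slot n_folds integer (>= 2), number of cross-validation folds.
#' @slot seed integer master seed for fold assignment and tie-breaking.
#' @slot min_size,max_size group-size bounds used by
#'   \code{\link{filterAnnotations}}.
#' @slot criticality_threshold fraction in (0, 1]; an edge is critical for a
#'   group when its capped fractional effect is at least this value.
#' @slot learnability_delta AP units; a group is learnable when its AP
#'   exceeds the null mean by more than this margin.
#' @slot null_reps integer; Monte-Carlo replicates for null calibration.
#'
#' @seealso \code{\link{runConfig}}
#' @exportClass RunConfig
setClass("RunConfig",
    representation(
        n_folds = "integer",
        seed = "integer",
        min_size = "integer",
        max_size = "integer",
        criticality_threshold = "numeric",
        learnability_delta = "numeric",
        null_reps = "integer"
    )
)

setValidity("RunConfig", function(object) {
    if (object@n_folds < 2L) return("n_folds must be >= 2")
    if (object@min_size < 1L) return("min_size must be >= 1")
    if (object@min_size > object@max_size)
        return("min_size must be <= max_size")
    if (object@criticality_threshold <= 0 ||
        object@criticality_threshold > 1)
        return("criticality_threshold must be in (0, 1]")
    if (object@null_reps < 1L) return("null_reps must be >= 1")
    TRUE
})

#' APTable: cross-validated average precision per group
#'
#' Result of \code{\link{evaluateNetwork}} / \code{\link{ablateAndEvaluate}}:
#' one row per annotation group with the pooled cross-validated average
#' precision (AP), the matching random-ranking null calibration, an empirical
#' p-value and the learnability flag; plus the global MAP (mean AP over
#' scored groups).
#'
#' @slot table data.frame with columns \code{group_id}, \code{k}, \code{ap},
#'   \code{null_mean}, \code{null_sd}, \code{empirical_p}, \code{learnable},
#'   \code{skipped}.
#' @slot map numeric(1), mean AP over scored (non-skipped) groups.
#' @slot n_folds,seed protocol echo.
#' @slot scores optional genes x groups matrix of per-gene voting scores
#'   (mean over folds for non-members; holdout-fold score for members), or a
#'   0 x 0 matrix when not requested.
#'
#' @exportClass APTable
setClass("APTable",
    representation(
        table = "data.frame",
        map = "numeric",
        n_folds = "integer",
        seed = "integer",
        scores = "matrix"
    )
)

#' CriticalityMatrix: leave-one-edge-out effects
#'
#' Sparse result of \code{\link{edgeRemovalScan}}.  Rows of \code{cells} are
#' the (edge, group) pairs whose AP after removing the edge differs from the
#' baseline AP by more than an absolute tolerance of 1e-12; all other cells
#' have exactly the baseline AP.
#'
#' @slot edges two-column character matrix of the scanned edges (canonical).
#' @slot group_ids character vector of group identifiers.
#' @slot ap_full baseline AP per group (same folds and tie-break seed as the
#'   scan).
#' @slot null_mean,null_sd per-group null calibration.
#' @slot learnable logical per group; effects are computed for learnable
#'   groups (and for all groups when the scan was run with
#'   \code{learnable_only = FALSE}).
#' @slot scanned logical per group: whether the group was scanned.
#' @slot cells data.frame with columns \code{edge}, \code{group} (integer
#'   indices), \code{ap_removed}, \code{effect_raw}, \code{effect_capped}.
#' @slot annotation the \linkS4class{AnnotationSet} that was scanned (kept
#'   for internal/external edge classification).
#' @slot seed,n_folds protocol echo (must match the baseline evaluation).
#'
#' @exportClass CriticalityMatrix
setClass("CriticalityMatrix",
    representation(
        edges = "matrix",
        group_ids = "character",
        ap_full = "numeric",
        null_mean = "numeric",
        null_sd = "numeric",
        learnable = "logical",
        scanned = "logical",
        cells = "data.frame",
        annotation = "AnnotationSet",
        seed = "integer",
        n_folds = "integer"
    )
)

#' PredictedEdgeList: greedily predicted exceptional edges
#'
#' Ordered gene pairs selected by weighted annotation overlap
#' (\code{\link{predictExceptionalEdges}}).
#'
#' @slot pairs data.frame with columns \code{rank}, \code{gene_a},
#'   \code{gene_b}, \code{score} (selection-time weighted overlap) and
#'   \code{shared_groups} (raw shared-group count).
#' @slot usage named integer: how many selected pairs used each group.
#'
#' @exportClass PredictedEdgeList
setClass("PredictedEdgeList",
    representation(pairs = "data.frame", usage = "integer")
)

#' DegreeProfile: node-degree diagnostics
#'
#' Degree distribution of a network with a visualization-grade power-law fit
#' (least squares on log(count) vs log(degree) over positive degrees).
#'
#' @slot degrees named integer, per-gene degree.
#' @slot histogram data.frame with columns \code{degree}, \code{count}
#'   (all observed degrees, including 0).
#' @slot slope,r_squared log-log least-squares fit (NA when degenerate).
#' @slot mean_degree numeric(1).
#' @slot degenerate logical; TRUE when fewer than 3 distinct positive
#'   degrees are observed and the fit is meaningless.
#'
#' @exportClass DegreeProfile
setClass("DegreeProfile",
    representation(
        degrees = "integer",
        histogram = "data.frame",
        slope = "numeric",
        r_squared = "numeric",
        mean_degree = "numeric",
        degenerate = "logical"
    )
)

#' NullScreenResult: random-network null screen
#'
#' Result of \code{\link{nullScreen}}: the calibration MAP distribution and
#' threshold, the retained (above-threshold) networks of the screening phase
#' and the per-edge occurrence tally across them.
#'
#' @slot calibration numeric vector of calibration MAPs.
#' @slot calib_mean,calib_sd moments of the calibration distribution.
#' @slot ks_p Kolmogorov-Smirnov p-value against a normal with the sample
#'   moments (Lilliefors-style caveat: moments are estimated).
#' @slot threshold MAP threshold (= mean + sd_multiplier * SD).
#' @slot sd_multiplier the multiplier used.
#' @slot screen_reps number of screening replicates.
#' @slot selected_count number of retained networks.
#' @slot selected_maps MAPs of retained networks.
#' @slot edge_tally data.frame \code{gene_a}, \code{gene_b}, \code{count}:
#'   occurrences of each edge across retained networks (only edges seen at
#'   least once).
#' @slot annotations the fixed \linkS4class{AnnotationSet} shared by all
#'   replicates.
#' @slot params named list echoing the simulation parameters (n_genes,
#'   n_edges, n_groups, group_size, calib_reps, screen_reps, sd_multiplier,
#'   n_folds, seed).
#'
#' @exportClass NullScreenResult
setClass("NullScreenResult",
    representation(
        calibration = "numeric",
        calib_mean = "numeric",
        calib_sd = "numeric",
        ks_p = "numeric",
        threshold = "numeric",
        sd_multiplier = "numeric",
        screen_reps = "integer",
        selected_count = "integer",
        selected_maps = "numeric",
        edge_tally = "data.frame",
        annotations = "AnnotationSet",
        params = "list"
    )
)

setValidity("NullScreenResult", function(object) {
    if (object@selected_count > object@screen_reps)
        return("selected_count cannot exceed screen_reps")
    if (length(object@selected_maps) != object@selected_count)
        return("selected_maps length must equal selected_count")
    TRUE
})
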