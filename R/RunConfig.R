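#' Construct a RunConfig
#'
#' Defaults follow the package's standard protocol: 3-fold cross-validation
#' (the regime used for criticality detection; 8-fold is common for large
#' mammalian data and available here by argument), a 10\% criticality
#' threshold, a 0.01 learnability margin over the null mean, and group-size
#' bounds of 10--300 genes for annotation filtering.
#'
#' @param n_folds number of cross-validation folds (>= 2).
#' @param seed integer master seed for fold assignment and tie-breaking.
#' @param min_size,max_size group-size bounds for annotation filtering.
#' @param criticality_threshold fraction in (0, 1].
#' @param learnability_delta margin (AP units) above the null mean.
#' @param null_reps Monte-Carlo replicates for null calibration.
#' @return a \linkS4class{RunConfig}.
#' @examples
#' cfg <- runConfig(seed = 7)
#' cfg
#' @export
runConfig <- function(n_folds = 3L, seed = 1L, min_size = 10L,
                      max_size = 300L, criticality_threshold = 0.10,
                      learnability_delta = 0.01, null_reps = 1000L) {
    new("RunConfig",
        n_folds = as.integer(n_folds),
        seed = as.integer(seed),
        min_size = as.integer(min_size),
        max_size = as.integer(max_size),
        criticality_threshold = as.numeric(criticality_threshold),
        learnability_delta = as.numeric(learnability_delta),
        null_reps = as.integer(null_reps))
}

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig\n")
    cat(sprintf("  n_folds: %d   seed: %d   null_reps: %d\n",
                object@n_folds, object@seed, object@null_reps))
    cat(sprintf("  group sizes: [%d, %d]\n", object@min_size,
                object@max_size))
    cat(sprintf("  criticality_threshold: %g   learnability_delta: %g\n",
                object@criticality_threshold, object@learnability_delta))
    invisible(NULL)
})

#' Read a RunConfig from a flat key-value file
#'
#' The file is YAML with flat scalar keys mirroring the
#' \linkS4class{RunConfig} fields (\code{n_folds}, \code{seed},
#' \code{min_size}, \code{max_size}, \code{criticality_threshold},
#' \code{learnability_delta}, \code{null_reps}).  Missing keys take the
#' \code{\link{runConfig}} defaults; unknown keys are an error.
#'
#' @param path path to the config file.
#' @return a \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    known <- names(formals(runConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    do.call(runConfig, vals)
}
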