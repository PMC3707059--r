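#' Principal-coordinate ordination of an IBS matrix
#'
#' Classical (metric) principal coordinates analysis of the genetic
#' distance `1 - IBS`, via Gower double-centering and eigendecomposition,
#' with coordinates ordered by eigenvalue; optionally refined by Kruskal
#' non-metric multidimensional scaling (stress minimization initialized at
#' the metric solution).
#'
#' @param ibs A [PairwiseMatrix-class] from [ibsMatrix()] (or a symmetric
#'   similarity matrix in `[0, 1]`).
#' @param dims Number of dimensions (default 2).
#' @param method `"metric"` (default) or `"nonmetric"`.
#' @return A list: `points` (samples x dims), `eig` (all eigenvalues),
#'   `explained` (shares of the positive eigenvalues for the returned
#'   dimensions), `stress` (`NA` for metric; final stress in percent for
#'   non-metric), `method`.
#' @export
pcoaIBS <- function(ibs, dims = 2L, method = c("metric", "nonmetric")) {
    method <- match.arg(method)
    v <- if (methods::is(ibs, "PairwiseMatrix")) pairValues(ibs) else ibs
    if (anyNA(v))
        stop("IBS matrix has undefined pairs; impute them or drop the ",
             "samples involved before ordination")
    D <- 1 - v
    cmd <- stats::cmdscale(D, k = dims, eig = TRUE)
    pts <- cmd$points
    colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
    pos <- cmd$eig[cmd$eig > 1e-12]
    explained <- cmd$eig[seq_len(dims)] / sum(pos)
    stress <- NA_real_
    if (method == "nonmetric") {
        fit <- MASS::isoMDS(stats::as.dist(D), y = pts, k = dims,
                            trace = FALSE)
        pts <- fit$points
        colnames(pts) <- paste0("NMDS", seq_len(ncol(pts)))
        stress <- fit$stress
    }
    list(points = pts, eig = cmd$eig, explained = explained,
         stress = stress, method = method)
}
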