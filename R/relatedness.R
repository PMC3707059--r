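#' Pairwise identity-by-state matrix
#'
#' For each sample pair, over jointly non-missing sites, the per-site share
#' is 1 for identical diploid genotypes, 0.5 when exactly one allele is
#' shared (a heterozygote against either homozygote) and 0 for opposite
#' homozygotes; IBS is the mean per-site share (PLINK "distance"
#' semantics). For an inbred panel this is nearly equivalent to haploid
#' matching. Pairs with no jointly called site are `NA`.
#'
#' @param panel A [GenotypePanel-class] with at least two samples.
#' @return A [PairwiseMatrix-class] (`statistic = "IBS"`), with the per-pair
#'   jointly non-missing site counts in `pairCounts()`.
#' @export
ibsMatrix <- function(panel) {
    gt <- genotypes(panel)
    if (ncol(gt) < 2L) stop("need at least two samples")
    M <- (!is.na(gt)) * 1
    X <- gt; X[is.na(X)] <- 0L
    X <- X * 1  # numeric for crossprod
    X2 <- X * X
    # sum over joint sites of (g_i - g_j)^2
    D2 <- crossprod(X2, M) + crossprod(M, X2) - 2 * crossprod(X)
    A0 <- (gt == 0L) & !is.na(gt); A2 <- (gt == 2L) & !is.na(gt)
    A0 <- A0 * 1; A2 <- A2 * 1
    Nopp <- crossprod(A0, A2) + crossprod(A2, A0)
    # |g_i - g_j| = (g_i - g_j)^2 except opposite homozygotes (4 -> 2)
    Sabs <- D2 - 2 * Nopp
    Njoint <- crossprod(M)
    ibs <- 1 - Sabs / (2 * Njoint)
    ibs[Njoint == 0] <- NA_real_
    diag(ibs) <- 1
    ibs <- (ibs + t(ibs)) / 2
    .PairwiseMatrix(ibs, matrix(as.integer(Njoint), nrow(Njoint),
                                dimnames = dimnames(Njoint)), "IBS")
}

#' Method-of-moments IBD estimate (pi-hat)
#'
#' Estimates the IBD sharing coefficient pi-hat = P(Z=1)/2 + P(Z=2) for
#' every sample pair from observed IBS0/IBS1/IBS2 site counts, by the
#' three-state method of moments: P(Z=0) is read off the opposite-homozygote
#' count, P(Z=1) off the one-shared-allele count after removing the Z=0
#' contribution, and P(Z=2) is the remainder. Expected IBS-state
#' probabilities for unrelated pairs are computed per site from the sample's
#' observed genotype frequencies (`freq_model = "genotype"`, the default),
#' which keeps the estimator consistent for inbred panels where
#' Hardy-Weinberg genotype products would badly overstate P(Z=0);
#' `freq_model = "hwe"` gives the classical allele-frequency products.
#' Estimates are computed on the (LD-pruned) sites supplied, since the
#' moment conditions assume independent markers.
#'
#' @param panel A [GenotypePanel-class].
#' @param sites Optional site subset (indices, names or logical), typically
#'   the survivors of [ldPrune()].
#' @param freq_model `"genotype"` (observed genotype frequencies; robust to
#'   inbreeding) or `"hwe"` (allele-frequency products).
#' @return A [PairwiseMatrix-class] (`statistic = "IBD pi-hat"`) of clamped
#'   pi-hat values; the unclamped estimates are kept in the `raw` slot.
#' @export
ibdEstimate <- function(panel, sites = NULL,
                        freq_model = c("genotype", "hwe")) {
    freq_model <- match.arg(freq_model)
    if (!is.null(sites)) panel <- panel[sites, ]
    gt <- genotypes(panel)
    if (ncol(gt) < 2L) stop("need at least two samples")
    called <- !is.na(gt)
    n <- rowSums(called)
    P0 <- rowSums(gt == 0L, na.rm = TRUE) / n
    P1 <- rowSums(gt == 1L, na.rm = TRUE) / n
    P2 <- rowSums(gt == 2L, na.rm = TRUE) / n
    p <- P0 + P1 / 2
    q <- 1 - p
    poly <- !is.na(p) & p > 0 & p < 1
    if (!any(poly)) stop("no polymorphic sites; cannot estimate IBD")
    if (freq_model == "genotype") {
        e0 <- 2 * P0 * P2
        e10 <- 2 * P1 * (P0 + P2)
    } else {
        e0 <- 2 * p^2 * q^2
        e10 <- 4 * p^3 * q + 4 * p * q^3
    }
    e11 <- 2 * p * q
    M <- called * 1
    A0 <- ((gt == 0L) & called) * 1
    A1 <- ((gt == 1L) & called) * 1
    A2 <- ((gt == 2L) & called) * 1
    N0 <- crossprod(A0, A2) + crossprod(A2, A0)
    Ahom <- A0 + A2
    N1 <- crossprod(A1, Ahom) + crossprod(Ahom, A1)
    E0 <- crossprod(M * e0, M)
    E10 <- crossprod(M * e10, M)
    E11 <- crossprod(M * e11, M)
    z0 <- ifelse(E0 > 0, N0 / E0, 0)
    z1 <- ifelse(E11 > 0, (N1 - z0 * E10) / E11, 0)
    z2_raw <- 1 - z0 - z1
    pihat_raw <- z2_raw + z1 / 2
    z0c <- pmin(pmax(z0, 0), 1)
    z1c <- pmin(pmax(z1, 0), 1 - z0c)
    z2c <- 1 - z0c - z1c
    pihat <- pmin(pmax(z2c + z1c / 2, 0), 1)
    Njoint <- crossprod(M)
    pihat[Njoint == 0] <- NA_real_
    diag(pihat) <- 1
    pihat <- (pihat + t(pihat)) / 2
    .PairwiseMatrix(pihat,
                    matrix(as.integer(Njoint), nrow(Njoint),
                           dimnames = dimnames(Njoint)),
                    "IBD pi-hat", raw = pihat_raw)
}

#' Nearest-neighbor report by IBS
#'
#' The `k` most similar samples for each sample, sorted by decreasing IBS
#' with ties broken lexicographically by neighbor id. When the panel holds
#' fewer than `k + 1` samples all others are listed.
#'
#' @param ibs A [PairwiseMatrix-class] from [ibsMatrix()] (or a plain
#'   symmetric matrix).
#' @param k Number of neighbors (default 10).
#' @return A `data.frame` with columns `sample`, `rank`, `neighbor`, `ibs`.
#' @export
nearestNeighbors <- function(ibs, k = 10L) {
    v <- if (methods::is(ibs, "PairwiseMatrix")) pairValues(ibs) else ibs
    ids <- colnames(v)
    out <- lapply(ids, function(s) {
        others <- setdiff(ids, s)
        val <- v[s, others]
        o <- order(-val, others)
        kk <- min(k, length(others))
        data.frame(sample = s, rank = seq_len(kk),
                   neighbor = others[o][seq_len(kk)],
                   ibs = unname(val[o][seq_len(kk)]))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Detect and merge duplicated samples
#'
#' Single-linkage clusters over pairs whose IBS meets the merge threshold
#' (0.99 by default, a conservative value given typical GBS error rates;
#' residual differences within a cluster are attributed to residual
#' heterozygosity and sequencing error). Each cluster is collapsed to a
#' consensus line: per site, the unanimous non-missing call, missing on
#' conflict, or the sole non-missing call — so the consensus call rate is
#' at least the best member's.
#'
#' @param panel A [GenotypePanel-class].
#' @param ibs The [ibsMatrix()] of the same panel.
#' @param threshold Minimum IBS for two samples to be considered the same
#'   accession (inclusive; default 0.99).
#' @return A list: `groups`, a `data.frame` (`member`, `consensus`,
#'   `group_size`, `min_ibs` within group), and `panel`, the merged
#'   [GenotypePanel-class] with one consensus column per cluster (named
#'   after the lexicographically first member).
#' @export
mergeDuplicates <- function(panel, ibs, threshold = 0.99) {
    v <- if (methods::is(ibs, "PairwiseMatrix")) pairValues(ibs) else ibs
    ids <- colnames(v)
    stopifnot(identical(ids, colnames(panel)))
    adj <- !is.na(v) & v >= threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    gt <- genotypes(panel)
    cl <- lapply(split(ids, comp), unname)
    cl <- cl[order(vapply(cl, min, ""))]
    cons <- matrix(NA_integer_, nrow(gt), length(cl))
    colnames(cons) <- unname(vapply(cl, min, ""))
    groups <- vector("list", length(cl))
    for (i in seq_along(cl)) {
        members <- cl[[i]]
        sub <- gt[, members, drop = FALSE]
        if (length(members) == 1L) {
            cons[, i] <- sub[, 1]
            min_ibs <- NA_real_
        } else {
            lo <- suppressWarnings(apply(sub, 1L, min, na.rm = TRUE))
            hi <- suppressWarnings(apply(sub, 1L, max, na.rm = TRUE))
            agree <- is.finite(lo) & lo == hi
            cons[agree, i] <- as.integer(lo[agree])
            vv <- v[members, members]
            min_ibs <- min(vv[upper.tri(vv)])
        }
        groups[[i]] <- data.frame(member = members,
                                  consensus = colnames(cons)[i],
                                  group_size = length(members),
                                  min_ibs = min_ibs)
    }
    rr <- SummarizedExperiment::rowRanges(panel)
    merged <- GenotypePanel(cons, .siteChrom(panel), .sitePos(panel),
                            S4Vectors::mcols(rr)$ref,
                            S4Vectors::mcols(rr)$alt)
    list(groups = do.call(rbind, groups), panel = merged)
}

#' Relationship-network edge list
#'
#' All sample pairs with IBS strictly above a threshold, as a deterministic
#' edge list suitable for import into graph tools.
#'
#' @param ibs A [PairwiseMatrix-class] or symmetric matrix.
#' @param threshold Strict lower bound on IBS.
#' @return A `data.frame` with columns `sample1`, `sample2`, `ibs`, ordered
#'   by sample position (`sample1` earlier than `sample2`).
#' @export
networkEdges <- function(ibs, threshold) {
    v <- if (methods::is(ibs, "PairwiseMatrix")) pairValues(ibs) else ibs
    ids <- colnames(v)
    sel <- which(upper.tri(v) & !is.na(v) & v > threshold, arr.ind = TRUE)
    sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
    data.frame(sample1 = ids[sel[, 1]], sample2 = ids[sel[, 2]],
               ibs = v[sel])
}

#' Concordance between two call sets
#'
#' Compares two panels over their shared (sample, site) grid: the
#' discrepancy rate is the fraction of jointly non-missing calls that
#' differ; the heterozygote-excluded variant drops cells heterozygous in
#' either set.
#'
#' @param panelA,panelB Two [GenotypePanel-class] objects sharing samples
#'   (by id) and sites (by chromosome and position).
#' @return A list: `all_calls`, `het_excluded`, `n_joint`,
#'   `n_joint_het_excluded`, `n_shared_samples`, `n_shared_sites`. Rates are
#'   `NA` (flagged) when there are no joint calls.
#' @export
concordance <- function(panelA, panelB) {
    sA <- rownames(genotypes(panelA)); sB <- rownames(genotypes(panelB))
    sites <- intersect(sA, sB)
    samples <- intersect(colnames(panelA), colnames(panelB))
    if (!length(sites) || !length(samples))
        stop("panels share no (sample, site) grid")
    a <- genotypes(panelA)[sites, samples, drop = FALSE]
    b <- genotypes(panelB)[sites, samples, drop = FALSE]
    joint <- !is.na(a) & !is.na(b)
    n_joint <- sum(joint)
    nohet <- joint & a != 1L & b != 1L
    list(all_calls = if (n_joint) mean(a[joint] != b[joint]) else NA_real_,
         het_excluded = if (sum(nohet))
             mean(a[nohet] != b[nohet]) else NA_real_,
         n_joint = n_joint,
         n_joint_het_excluded = sum(nohet),
         n_shared_samples = length(samples),
         n_shared_sites = length(sites))
}
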