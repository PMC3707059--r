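# Linkage-disequilibrium utilities: window pruning and decay curves.
# r2 is always the squared Pearson correlation of haploidized allele
# dosages on pairwise-complete samples.

#' LD pruning by sliding SNP windows
#'
#' Greedy pairwise pruning: within a window of `window` adjacent SNPs, for
#' every surviving pair with r2 strictly above the threshold the later site
#' is removed; the window then slides by `step` SNPs to the chromosome end.
#' The surviving set contains no within-window pair above the threshold.
#' Defaults (window 100, step 25, r2 0.2) are the standard pre-IBD pruning
#' parameters.
#'
#' @param panel A [GenotypePanel-class] (sites ordered).
#' @param window Window size in adjacent SNPs.
#' @param step Window step in SNPs.
#' @param r2_threshold Strict r2 bound above which one of a pair is
#'   removed.
#' @return A named logical vector, `TRUE` for surviving sites.
#' @export
ldPrune <- function(panel, window = 100L, step = 25L, r2_threshold = 0.2) {
    d <- .hapDosage(panel)
    keep <- rep(TRUE, nrow(d))
    for (chr_idx in .chromIndices(panel)) {
        n <- length(chr_idx)
        starts <- seq(1L, n, by = step)
        for (s in starts) {
            win <- chr_idx[s:min(s + window - 1L, n)]
            alive <- win[keep[win]]
            if (length(alive) < 2L) next
            r2 <- suppressWarnings(stats::cor(
                d[alive, , drop = FALSE] |> t(),
                use = "pairwise.complete.obs"))^2
            for (i in seq_len(length(alive) - 1L)) {
                if (!keep[alive[i]]) next
                for (j in seq((i + 1L), length(alive))) {
                    if (!keep[alive[j]]) next
                    if (!is.na(r2[i, j]) && r2[i, j] > r2_threshold)
                        keep[alive[j]] <- FALSE
                }
            }
        }
    }
    stats::setNames(keep, rownames(genotypes(panel)))
}

#' Genome-wide LD decay curve
#'
#' Computes pairwise r2 against inter-SNP distance within chromosomes.
#' Sites with more than `max_missing` missing data or minor allele
#' frequency below `min_maf` (within the analyzed group) are filtered
#' first, and at most `subsample` lines are drawn at random so groups of
#' different sizes are comparable. Pairs are binned by distance
#' (log-spaced by default, since decay is fastest at short range) and
#' summarized as the mean, median, and central 50% and 90% ranges per bin.
#'
#' @param panel A [GenotypePanel-class].
#' @param group Group label or sample ids (default: all samples).
#' @param max_missing Maximum per-site missing fraction within the group
#'   (default 0.25).
#' @param min_maf Minimum within-group minor allele frequency (default
#'   0.05).
#' @param subsample Number of lines drawn when the group is larger
#'   (default 180); smaller groups are used whole, with a warning.
#' @param max_distance Maximum pair distance in bp.
#' @param bins Number of distance bins, or an explicit vector of bin edges
#'   in bp.
#' @param log_spaced Use log-spaced bin edges (default) or linear.
#' @param seed Optional integer seed for the subsample.
#' @return A list: `bins`, a `data.frame` with `dist_lo`, `dist_hi`,
#'   `n_pairs`, `mean_r2`, `median_r2`, `q25`, `q75`, `q05`, `q95`;
#'   `n_sites_used`; `samples_used`.
#' @export
ldDecay <- function(panel, group = NULL, max_missing = 0.25,
                    min_maf = 0.05, subsample = 180L, max_distance = 1e6,
                    bins = 15L, log_spaced = TRUE, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    ids <- .groupSamples(panel, group)
    if (length(ids) > subsample) {
        ids <- sample(ids, subsample)
    } else if (length(ids) < subsample) {
        warning("group smaller than 'subsample' (", length(ids),
                " < ", subsample, "); using all lines")
    }
    d <- .hapDosage(panel)[, sort(ids), drop = FALSE]
    n <- ncol(d)
    call_rate <- rowMeans(!is.na(d))
    f <- rowMeans(d, na.rm = TRUE)
    maf <- pmin(f, 1 - f)
    use <- call_rate >= 1 - max_missing & !is.na(maf) & maf >= min_maf
    if (!any(use)) stop("no SNPs pass the missingness/MAF filters")
    pos <- .sitePos(panel)
    pairs <- list(); k <- 0L
    for (chr_idx in .chromIndices(panel)) {
        idx <- chr_idx[use[chr_idx]]
        if (length(idx) < 2L) next
        r2 <- suppressWarnings(stats::cor(t(d[idx, , drop = FALSE]),
                                          use = "pairwise.complete.obs"))^2
        dd <- abs(outer(pos[idx], pos[idx], "-"))
        ut <- upper.tri(r2)
        ok <- ut & dd <= max_distance & !is.na(r2)
        if (!any(ok)) next
        k <- k + 1L
        pairs[[k]] <- data.frame(dist = dd[ok], r2 = r2[ok])
    }
    if (!k) stop("no SNP pairs within 'max_distance'")
    pairs <- do.call(rbind, pairs)
    if (length(bins) == 1L) {
        lo <- max(1, min(pairs$dist)); hi <- max(pairs$dist)
        edges <- if (log_spaced)
            exp(seq(log(lo), log(hi), length.out = bins + 1L))
        else seq(lo, hi, length.out = bins + 1L)
        edges[1] <- lo - 1e-9; edges[length(edges)] <- hi + 1e-9
    } else edges <- bins
    bin <- cut(pairs$dist, edges, include.lowest = TRUE)
    agg <- lapply(split(pairs$r2, bin), function(x) {
        if (!length(x)) return(NULL)
        q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95),
                             names = FALSE)
        data.frame(n_pairs = length(x), mean_r2 = mean(x),
                   median_r2 = q[3], q25 = q[2], q75 = q[4],
                   q05 = q[1], q95 = q[5])
    })
    keep <- !vapply(agg, is.null, TRUE)
    lohi <- cbind(utils::head(edges, -1), utils::tail(edges, -1))[keep, ,
                                                                  drop = FALSE]
    out <- cbind(data.frame(dist_lo = lohi[, 1], dist_hi = lohi[, 2]),
                 do.call(rbind, agg[keep]))
    rownames(out) <- NULL
    list(bins = out, n_sites_used = sum(use), samples_used = sort(ids))
}
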