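# Allele-frequency spectra, allele sharing, and windowed differentiation
# statistics for germplasm groups.

# Window index per site for fixed-width bp tiling (1-based windows starting
# at position 1).
.bpWindows <- function(panel, window_bp) {
    chrom <- .siteChrom(panel)
    pos <- .sitePos(panel)
    win <- (pos - 1L) %/% window_bp
    data.frame(chrom = chrom, win = win,
               start = win * window_bp + 1,
               end = (win + 1) * window_bp,
               key = paste(chrom, win, sep = ":"))
}

#' Minor-allele-frequency spectrum within a group
#'
#' Per-site MAF among the group's non-missing haploidized calls, binned
#' into a site-frequency-spectrum histogram. Sites monomorphic within the
#' group are reported separately and excluded from the spectrum; the
#' rare-allele fraction is the share of polymorphic sites with MAF below
#' 0.05.
#'
#' @param panel A [GenotypePanel-class].
#' @param group Group label or sample ids (default: all samples).
#' @param bin_edges MAF histogram bin edges (default steps of 0.05 over
#'   `[0, 0.5]`; bins are left-closed).
#' @return A list: `counts` (named per bin), `maf` (per polymorphic site),
#'   `rare_fraction` (MAF < 0.05 among polymorphic sites),
#'   `n_polymorphic`, `n_monomorphic`, `n_undefined` (no calls in group).
#' @export
mafSpectrum <- function(panel, group = NULL,
                        bin_edges = seq(0, 0.5, by = 0.05)) {
    ids <- .groupSamples(panel, group)
    d <- .hapDosage(panel)[, ids, drop = FALSE]
    n <- rowSums(!is.na(d))
    f <- rowMeans(d, na.rm = TRUE)
    maf <- pmin(f, 1 - f)
    undefined <- n == 0L
    mono <- !undefined & maf == 0
    poly <- !undefined & maf > 0
    cuts <- cut(maf[poly], bin_edges, include.lowest = FALSE, right = FALSE)
    # right-closed top bin so MAF = 0.5 is counted
    cuts[is.na(cuts) & maf[poly] == max(bin_edges)] <-
        levels(cuts)[length(levels(cuts))]
    counts <- table(cuts)
    list(counts = counts, maf = maf[poly],
         rare_fraction = if (any(poly)) mean(maf[poly] < 0.05) else NA_real_,
         n_polymorphic = sum(poly), n_monomorphic = sum(mono),
         n_undefined = sum(undefined))
}

#' Allele presence and sharing across groups
#'
#' An allele is considered present in a group only when it is carried by at
#' least `min_carriers` distinct samples (a heterozygote carries both
#' alleles), which removes singleton sequencing artifacts. Sharing
#' percentages are computed over the union of alleles present in any group.
#'
#' @param panel A [GenotypePanel-class].
#' @param groups Named list of sample-id vectors, or `NULL` to use the
#'   panel's `group` labels.
#' @param min_carriers Minimum distinct carriers (default 2).
#' @return A list: `present`, a list of two logical site x group matrices
#'   (`ref`, `alt`); `group_pct`, percent of the allele union present per
#'   group; `shared_pct`, percent of the union present in every group;
#'   `n_union`, number of (site, allele) pairs in the union.
#' @export
allelePresence <- function(panel, groups = NULL, min_carriers = 2L) {
    if (is.null(groups)) {
        grp <- sampleGroups(panel)
        if (all(is.na(grp))) stop("no group labels available")
        groups <- split(names(grp)[!is.na(grp)], grp[!is.na(grp)])
    }
    gt <- genotypes(panel)
    ng <- length(groups)
    pres_ref <- matrix(FALSE, nrow(gt), ng,
                       dimnames = list(rownames(gt), names(groups)))
    pres_alt <- pres_ref
    for (k in seq_len(ng)) {
        sub <- gt[, groups[[k]], drop = FALSE]
        carr_ref <- rowSums(sub == 0L | sub == 1L, na.rm = TRUE)
        carr_alt <- rowSums(sub == 2L | sub == 1L, na.rm = TRUE)
        pres_ref[, k] <- carr_ref >= min_carriers
        pres_alt[, k] <- carr_alt >= min_carriers
    }
    union_ref <- rowSums(pres_ref) > 0L
    union_alt <- rowSums(pres_alt) > 0L
    n_union <- sum(union_ref) + sum(union_alt)
    group_pct <- vapply(seq_len(ng), function(k)
        100 * (sum(pres_ref[union_ref, k]) + sum(pres_alt[union_alt, k])) /
            n_union, 0)
    names(group_pct) <- names(groups)
    shared <- sum(rowSums(pres_ref[union_ref, , drop = FALSE]) == ng) +
        sum(rowSums(pres_alt[union_alt, , drop = FALSE]) == ng)
    list(present = list(ref = pres_ref, alt = pres_alt),
         group_pct = group_pct,
         shared_pct = 100 * shared / n_union,
         n_union = n_union)
}

#' Weir-Cockerham fixation index between two groups
#'
#' Per-SNP Weir-Cockerham theta from the variance-components (ANOVA)
#' estimator applied to haploidized calls — each inbred line contributes a
#' single allele, so the within-individual (heterozygosity) components
#' vanish and theta = (MSP - MSG) / (MSP + (n_c - 1) MSG), where MSP and
#' MSG are the among- and within-population mean squares of allele
#' frequency and n_c the variance-effective sample size. Window averages
#' (unweighted mean of per-site theta per bp window) and the genome-wide
#' ratio-of-sums estimate (sum of numerator components over sum of
#' denominator components, the standard multi-locus weighting) are both
#' reported.
#'
#' @param panel A [GenotypePanel-class].
#' @param groupA,groupB Group labels or sample-id vectors.
#' @param window_bp Window width for per-window averages (default 1 Mb).
#' @param min_samples Minimum called haploid samples per group at a site
#'   (default 2; sites below are skipped).
#' @return A list: `per_site` ([S4Vectors::DataFrame] with `chrom`, `pos`,
#'   `theta`, `a` numerator and `d` denominator components, `used`);
#'   `windows` (`data.frame` with per-window mean and ratio-of-sums theta
#'   and site counts); `overall` (list with `ratio_of_sums`, `mean_theta`,
#'   `n_sites`).
#' @export
weirCockerhamFst <- function(panel, groupA, groupB, window_bp = 1e6,
                             min_samples = 2L) {
    idsA <- .groupSamples(panel, groupA)
    idsB <- .groupSamples(panel, groupB)
    d <- .hapDosage(panel)
    comp <- .wcComponents(d[, idsA, drop = FALSE],
                          d[, idsB, drop = FALSE], min_samples)
    theta <- ifelse(comp$used & comp$d != 0, comp$a / comp$d, NA_real_)
    wins <- .bpWindows(panel, window_bp)
    per_site <- S4Vectors::DataFrame(chrom = wins$chrom,
                                     pos = .sitePos(panel),
                                     theta = theta, a = comp$a, d = comp$d,
                                     used = comp$used,
                                     row.names = rownames(d))
    sp <- split(seq_len(nrow(per_site)), wins$key)
    wtab <- lapply(names(sp), function(k) {
        idx <- sp[[k]]
        th <- theta[idx]
        n_used <- sum(!is.na(th))
        if (!n_used) return(NULL)
        data.frame(chrom = wins$chrom[idx[1]], start = wins$start[idx[1]],
                   end = wins$end[idx[1]], n_sites = n_used,
                   theta_mean = mean(th, na.rm = TRUE),
                   theta_ratio = sum(comp$a[idx], na.rm = TRUE) /
                       sum(comp$d[idx], na.rm = TRUE))
    })
    wtab <- do.call(rbind, wtab[!vapply(wtab, is.null, TRUE)])
    wtab <- wtab[order(factor(wtab$chrom, levels = unique(wins$chrom)),
                       wtab$start), , drop = FALSE]
    rownames(wtab) <- NULL
    list(per_site = per_site, windows = wtab,
         overall = list(
             ratio_of_sums = sum(comp$a, na.rm = TRUE) /
                 sum(comp$d, na.rm = TRUE),
             mean_theta = mean(theta, na.rm = TRUE),
             n_sites = sum(comp$used)))
}

# Per-site variance components for the haploid two-population theta.
.wcComponents <- function(dA, dB, min_samples) {
    nA <- unname(rowSums(!is.na(dA))); nB <- unname(rowSums(!is.na(dB)))
    pA <- unname(rowMeans(dA, na.rm = TRUE))
    pB <- unname(rowMeans(dB, na.rm = TRUE))
    used <- nA >= min_samples & nB >= min_samples
    N <- nA + nB
    pbar <- (nA * pA + nB * pB) / N
    r <- 2L
    MSP <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / (r - 1)
    MSG <- (nA * pA * (1 - pA) + nB * pB * (1 - pB)) / (N - r)
    nc <- (N - (nA^2 + nB^2) / N) / (r - 1)
    a <- MSP - MSG
    dd <- MSP + (nc - 1) * MSG
    a[!used] <- NA_real_; dd[!used] <- NA_real_
    list(a = a, d = dd, used = used)
}

#' Bootstrap confidence interval for the genome-wide fixation index
#'
#' Percentile bootstrap over sites of the ratio-of-sums Weir-Cockerham
#' estimate.
#'
#' @param fit Result of [weirCockerhamFst()].
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return A list: `estimate`, `lower`, `upper`, `n_sites`.
#' @export
fstBootstrapCI <- function(fit, n_boot = 200L, conf = 0.95, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    a <- fit$per_site$a; dd <- fit$per_site$d
    use <- !is.na(a) & !is.na(dd)
    a <- a[use]; dd <- dd[use]
    n <- length(a)
    boot <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        sum(a[idx]) / sum(dd[idx])
    }, 0)
    alpha <- (1 - conf) / 2
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
    list(estimate = sum(a) / sum(dd), lower = ci[1], upper = ci[2],
         n_sites = n)
}

#' Windowed nucleotide divergence between two groups
#'
#' After haploidization, the pairwise identity-by-state of every
#' cross-group sample pair is computed per bp window, and the window's
#' average nucleotide difference is 1 minus the average IBS. Pair-windows
#' supported by fewer than `min_joint` jointly called sites are excluded.
#'
#' @param panel A [GenotypePanel-class].
#' @param groupA,groupB Group labels or sample-id vectors.
#' @param window_bp Window width (default 1 Mb).
#' @param min_joint Minimum jointly non-missing sites per pair-window
#'   (default 10).
#' @return A list: `windows`, a `data.frame` (`chrom`, `start`, `end`,
#'   `n_sites`, `n_pairs`, `divergence`), and `overall`, the mean of the
#'   window divergences.
#' @export
nucleotideDivergence <- function(panel, groupA, groupB, window_bp = 1e6,
                                 min_joint = 10L) {
    idsA <- .groupSamples(panel, groupA)
    idsB <- .groupSamples(panel, groupB)
    d <- .hapDosage(panel)
    wins <- .bpWindows(panel, window_bp)
    sp <- split(seq_len(nrow(d)), wins$key)
    out <- lapply(names(sp), function(k) {
        idx <- sp[[k]]
        dA <- d[idx, idsA, drop = FALSE]; dB <- d[idx, idsB, drop = FALSE]
        MA <- (!is.na(dA)) * 1; MB <- (!is.na(dB)) * 1
        A0 <- (dA == 0); A0[is.na(A0)] <- FALSE
        B0 <- (dB == 0); B0[is.na(B0)] <- FALSE
        A1 <- (dA == 1); A1[is.na(A1)] <- FALSE
        B1 <- (dB == 1); B1[is.na(B1)] <- FALSE
        match <- crossprod(A0 * 1, B0 * 1) + crossprod(A1 * 1, B1 * 1)
        joint <- crossprod(MA, MB)
        ok <- joint >= min_joint
        if (!any(ok)) return(NULL)
        ibs <- match[ok] / joint[ok]
        data.frame(chrom = wins$chrom[idx[1]], start = wins$start[idx[1]],
                   end = wins$end[idx[1]], n_sites = length(idx),
                   n_pairs = sum(ok), divergence = 1 - mean(ibs))
    })
    out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    if (is.null(out)) stop("no pair-window reaches 'min_joint' sites")
    out <- out[order(factor(out$chrom, levels = unique(wins$chrom)),
                     out$start), , drop = FALSE]
    rownames(out) <- NULL
    list(windows = out, overall = mean(out$divergence))
}

#' Spearman rank correlation between two window statistics
#'
#' Rank correlation (ties mid-ranked) across genome windows, reported both
#' as rho and rho squared (the coefficient of determination of the ranks).
#'
#' @param statsA,statsB Numeric vectors of per-window statistics, matched
#'   by position.
#' @return A list: `rho`, `rho_squared`, `n` (complete pairs). `NA` with a
#'   warning when fewer than 3 complete pairs exist.
#' @export
windowRankCorrelation <- function(statsA, statsB) {
    if (length(statsA) != length(statsB))
        stop("'statsA' and 'statsB' must have equal length")
    ok <- !is.na(statsA) & !is.na(statsB)
    if (sum(ok) < 3L) {
        warning("fewer than 3 complete window pairs; correlation undefined")
        return(list(rho = NA_real_, rho_squared = NA_real_, n = sum(ok)))
    }
    rho <- stats::cor(statsA[ok], statsB[ok], method = "spearman")
    list(rho = rho, rho_squared = rho^2, n = sum(ok))
}
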