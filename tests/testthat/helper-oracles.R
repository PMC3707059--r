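# Brute-force oracles and small panel builders shared across tests.
# Oracles are deliberately written as plain loops over the definitions,
# independent of the implementation paths they check.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
})

# Build a panel from a raw code matrix on a single chromosome (or a vector
# of chromosome labels), with evenly spaced positions by default.
makePanel <- function(geno, chrom = "1", pos = NULL, group = NULL,
                      family = NULL) {
    geno <- as.matrix(geno)
    n <- nrow(geno)
    if (length(chrom) == 1L) chrom <- rep(chrom, n)
    if (is.null(pos)) {
        pos <- integer(n)
        for (cc in unique(chrom))
            pos[chrom == cc] <- seq_len(sum(chrom == cc)) * 100L
    }
    GenotypePanel(geno, chrom, pos, ref = rep("A", n), alt = rep("G", n),
                  group = group, family = family)
}

# Random genotype matrix with missingness and hets.
randomGeno <- function(n_sites, n_samples, p_missing = 0.2, p_het = 0.1) {
    codes <- sample(c(0L, 1L, 2L, NA), n_sites * n_samples, replace = TRUE,
                    prob = c((1 - p_missing - p_het) / 2, p_het,
                             (1 - p_missing - p_het) / 2, p_missing))
    m <- matrix(codes, n_sites, n_samples)
    colnames(m) <- sprintf("S%02d", seq_len(n_samples))
    m
}

# IBS by the allele-sharing definition, one pair at a time.
bruteIBS <- function(gt) {
    share <- function(a, b) {
        if (a == b) return(1)
        if (a == 1L || b == 1L) return(0.5)  # het vs either hom
        0  # opposite homozygotes
    }
    n <- ncol(gt)
    out <- matrix(NA_real_, n, n, dimnames = list(colnames(gt),
                                                  colnames(gt)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        joint <- which(!is.na(gt[, i]) & !is.na(gt[, j]))
        if (length(joint))
            out[i, j] <- mean(vapply(joint, function(s)
                share(gt[s, i], gt[s, j]), 0))
    }
    diag(out) <- 1
    out
}

# Exhaustive nearest-donor search on haploidized dosage.
bruteNearestDonor <- function(d, window, target, donors, min_overlap) {
    donors <- sort(setdiff(donors, target))
    best <- NULL
    for (dn in donors) {
        joint <- which(!is.na(d[window, target]) & !is.na(d[window, dn]))
        if (length(joint) < min_overlap) next
        mm <- mean(d[window[joint], target] != d[window[joint], dn])
        cand <- list(donor = dn, mismatch = mm, overlap = length(joint))
        if (is.null(best) ||
            mm < best$mismatch ||
            (mm == best$mismatch && cand$overlap > best$overlap) ||
            (mm == best$mismatch && cand$overlap == best$overlap &&
             dn < best$donor))
            best <- cand
    }
    best
}

# Maximal shared interval around a focal site (no forgiveness), by direct
# enumeration on jointly non-missing haploid calls of one chromosome.
enumSharedInterval <- function(x, y, focal) {
    joint <- which(!is.na(x) & !is.na(y))
    j <- match(focal, joint)
    if (is.na(j)) return(NULL)
    m <- x[joint] == y[joint]
    if (!m[j]) return(list(length_sites = 1L, lo = focal, hi = focal))
    lo <- j
    while (lo > 1L && m[lo - 1L]) lo <- lo - 1L
    hi <- j
    while (hi < length(m) && m[hi + 1L]) hi <- hi + 1L
    list(length_sites = hi - lo + 1L, lo = joint[lo], hi = joint[hi])
}

# Single-linkage clusters over pairs meeting a threshold, by union-find.
bruteSingleLinkage <- function(v, threshold) {
    ids <- colnames(v)
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
        if (i < j && !is.na(v[i, j]) && v[i, j] >= threshold) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
        }
    }
    roots <- vapply(seq_along(ids), find, 0L)
    unname(lapply(split(ids, roots), sort))
}

# Per-site Weir-Cockerham theta for two haploid samples of alleles,
# straight from the mean-square definitions.
bruteThetaHaploid <- function(p1, n1, p2, n2) {
    N <- n1 + n2
    pbar <- (n1 * p1 + n2 * p2) / N
    MSP <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
    MSG <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - 2)
    nc <- (N - (n1^2 + n2^2) / N)
    (MSP - MSG) / (MSP + (nc - 1) * MSG)
}
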