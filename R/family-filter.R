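# Biparental error-correction filter: a SNP that appears polymorphic inside
# a family where it cannot truly segregate is evidence of error or paralog
# collapse, and a SNP segregating in families should show local LD there.

.checkFamilies <- function(panel, families) {
    if (!all(c("family_id", "sample_id") %in% colnames(families)))
        stop("'families' needs columns 'family_id' and 'sample_id'")
    miss <- setdiff(families$sample_id, colnames(panel))
    if (length(miss))
        stop("family members absent from panel: ",
             paste(utils::head(miss, 5), collapse = ", "))
    if (anyDuplicated(families$sample_id))
        stop("samples may belong to at most one family")
    sizes <- table(families$family_id)
    if (any(sizes < 2L))
        stop("each family needs >= 2 members")
    split(families$sample_id, families$family_id)
}

#' Apparent within-family minor allele frequency
#'
#' For each site and biparental family, computes the minor allele frequency
#' among the family's haploidized calls. A family is classified as
#' segregating at the site iff its within-family MAF is at least `seg_maf`
#' (inclusive); in families where the SNP is not actually segregating, any
#' nonzero apparent MAF measures genotyping error. The site-level apparent
#' error rate is the maximum apparent MAF across non-segregating families
#' (a conservative aggregation). Families with fewer than `min_members`
#' haploid calls at a site are not assessed there.
#'
#' @param panel A [GenotypePanel-class].
#' @param families A `data.frame` with columns `family_id` and `sample_id`.
#' @param seg_maf Within-family MAF at or above which the family counts as
#'   segregating (default 0.15).
#' @param min_members Minimum genotyped members for a family to be assessed
#'   at a site (default 10).
#' @return A list with `site`, a [S4Vectors::DataFrame] (`apparent_error`,
#'   `n_assessed`, `n_segregating`; `apparent_error` is `NA` where no
#'   non-segregating family could be assessed), and `family_maf` /
#'   `segregating`, site x family matrices.
#' @export
apparentFamilyMAF <- function(panel, families, seg_maf = 0.15,
                              min_members = 10L) {
    fam <- .checkFamilies(panel, families)
    d <- .hapDosage(panel)
    nf <- length(fam)
    maf <- matrix(NA_real_, nrow(d), nf,
                  dimnames = list(rownames(d), names(fam)))
    seg <- matrix(NA, nrow(d), nf, dimnames = dimnames(maf))
    for (k in seq_len(nf)) {
        sub <- d[, fam[[k]], drop = FALSE]
        n <- rowSums(!is.na(sub))
        n1 <- rowSums(sub, na.rm = TRUE)
        f <- pmin(n1, n - n1) / n
        f[n < min_members] <- NA_real_
        maf[, k] <- f
        seg[, k] <- f >= seg_maf
    }
    nonseg_maf <- maf
    nonseg_maf[is.na(seg) | seg] <- NA_real_
    apparent <- suppressWarnings(apply(nonseg_maf, 1L, max, na.rm = TRUE))
    apparent[!is.finite(apparent)] <- NA_real_
    site <- S4Vectors::DataFrame(
        apparent_error = apparent,
        n_assessed = rowSums(!is.na(maf)),
        n_segregating = rowSums(seg, na.rm = TRUE),
        row.names = rownames(d))
    list(site = site, family_maf = maf, segregating = seg)
}

# The w window SNPs nearest to the focal site by index on its chromosome
# (focal excluded; ties broken toward the lower index; truncated windows
# extend into the available side).
.ldWindowIndices <- function(chr_idx, focal, w) {
    local <- setdiff(chr_idx, focal)
    if (!length(local) || w < 1L) return(integer(0))
    o <- order(abs(local - focal), local)
    sort(local[o][seq_len(min(w, length(local)))])
}

#' Local family LD around a focal SNP
#'
#' For each family in which the focal SNP segregates, computes the squared
#' Pearson correlation between the focal SNP and each SNP of a local window
#' (on haploidized dosage, pairwise-complete family members), takes the
#' within-family median, then the median across families. The window holds
#' one-twentieth of the chromosome's SNPs, centered on the focal SNP by
#' index; SNPs within `exclusion_bp` (100 Kb) of the focal position are
#' excluded, guarding against local assembly-order errors. A chromosome with
#' fewer than 20 SNPs uses all its SNPs minus the exclusion zone.
#'
#' @param panel A [GenotypePanel-class].
#' @param families Family table (see [apparentFamilyMAF()]).
#' @param site Site row index (or site name) of the focal SNP.
#' @param r2_min Median-r2 pass threshold (default 0.5, inclusive).
#' @param exclusion_bp Physical exclusion radius around the focal SNP.
#' @param seg_maf,min_members Passed to the segregation classification.
#' @param afm Optional precomputed result of [apparentFamilyMAF()] to avoid
#'   recomputation when scanning many sites.
#' @return A list: `median_r2` (NA when no family segregates), `pass`
#'   (`NA` = test skipped by vacuity), `per_family` named vector of family
#'   medians, and `window` (site indices used).
#' @export
localFamilyLD <- function(panel, families, site, r2_min = 0.5,
                          exclusion_bp = 1e5, seg_maf = 0.15,
                          min_members = 10L, afm = NULL) {
    fam <- .checkFamilies(panel, families)
    if (is.character(site)) site <- match(site, rownames(genotypes(panel)))
    if (is.na(site) || site < 1L || site > nrow(panel))
        stop("unknown focal site")
    if (is.null(afm))
        afm <- apparentFamilyMAF(panel, families, seg_maf, min_members)
    chrom <- .siteChrom(panel); pos <- .sitePos(panel)
    chr_idx <- which(chrom == chrom[site])
    w <- max(1L, floor(length(chr_idx) / 20))
    win <- .ldWindowIndices(chr_idx, site, w)
    win <- win[abs(pos[win] - pos[site]) > exclusion_bp]
    seg_here <- afm$segregating[site, ]
    seg_fams <- names(fam)[!is.na(seg_here) & seg_here]
    if (!length(seg_fams))
        return(list(median_r2 = NA_real_, pass = NA,
                    per_family = stats::setNames(numeric(0), character(0)),
                    window = win))
    d <- .hapDosage(panel)
    per_family <- vapply(seg_fams, function(k) {
        sub <- d[, fam[[k]], drop = FALSE]
        if (!length(win)) return(NA_real_)
        r2 <- .r2With(sub[site, ], t(sub[win, , drop = FALSE]))
        stats::median(r2, na.rm = TRUE)
    }, 0)
    med <- stats::median(per_family, na.rm = TRUE)
    list(median_r2 = med,
         pass = if (is.na(med)) NA else med >= r2_min,
         per_family = per_family, window = win)
}

#' Biparental error-correction filter
#'
#' Keeps a site iff (a) its apparent error rate — the maximum apparent MAF
#' across biparental families where the SNP is not segregating — is at most
#' `max_error`, and (b) the across-family median of within-family median
#' local r2 is at least `min_median_r2` in the families where it does
#' segregate. Either test is skipped (passes by vacuity) when no family can
#' be assessed for it; set `vacuous_ld_pass = FALSE` to fail sites that
#' segregate in no family instead.
#'
#' @param panel A [GenotypePanel-class].
#' @param families Family table (see [apparentFamilyMAF()]).
#' @param max_error Maximum tolerated apparent family MAF (default 0.01).
#' @param min_median_r2 Minimum median local r2 (default 0.5).
#' @param seg_maf,min_members,exclusion_bp See [apparentFamilyMAF()] and
#'   [localFamilyLD()].
#' @param vacuous_ld_pass Whether sites segregating in no family pass the
#'   LD component.
#' @return A list with `keep` (named logical) and `audit`, a
#'   [S4Vectors::DataFrame] of the per-site evidence (`apparent_error`,
#'   `median_r2`, `error_pass`, `ld_pass`).
#' @export
errorCorrectionFilter <- function(panel, families, max_error = 0.01,
                                  min_median_r2 = 0.5, seg_maf = 0.15,
                                  min_members = 10L, exclusion_bp = 1e5,
                                  vacuous_ld_pass = TRUE) {
    afm <- apparentFamilyMAF(panel, families, seg_maf, min_members)
    n <- nrow(panel)
    med_r2 <- rep(NA_real_, n)
    ld_pass <- rep(NA, n)
    has_seg <- afm$site$n_segregating > 0L
    for (i in which(has_seg)) {
        res <- localFamilyLD(panel, families, i, min_median_r2,
                             exclusion_bp, seg_maf, min_members, afm = afm)
        med_r2[i] <- res$median_r2
        ld_pass[i] <- res$pass
    }
    err <- afm$site$apparent_error
    error_pass <- is.na(err) | err <= max_error
    ld_ok <- ifelse(is.na(ld_pass), vacuous_ld_pass, ld_pass)
    keep <- stats::setNames(error_pass & ld_ok, rownames(genotypes(panel)))
    audit <- S4Vectors::DataFrame(apparent_error = err,
                                  median_r2 = med_r2,
                                  error_pass = error_pass,
                                  ld_pass = ld_pass,
                                  keep = unname(keep),
                                  row.names = names(keep))
    list(keep = keep, audit = audit)
}
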