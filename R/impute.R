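#' Partition sites into imputation windows
#'
#' Consecutive, non-overlapping blocks of `window_size` sites in panel
#' order. Windows never span a chromosome boundary; the final window of each
#' chromosome may be shorter.
#'
#' @param panel A [GenotypePanel-class].
#' @param window_size Sites per window (default 1024).
#' @return A list of integer site-index vectors.
#' @export
partitionWindows <- function(panel, window_size = 1024L) {
    window_size <- .checkCount(window_size, "window_size", min = 2L)
    out <- lapply(.chromIndices(panel), function(idx)
        unname(split(idx, ceiling(seq_along(idx) / window_size))))
    unlist(out, recursive = FALSE, use.names = FALSE)
}

# Deterministic donor choice from mismatch / overlap vectors: minimal
# mismatch fraction, ties by larger overlap, then lexicographic donor id.
.pickDonor <- function(frac, joint, donors, min_overlap) {
    ok <- !is.na(frac) & joint >= min_overlap
    if (!any(ok)) return(NULL)
    cand <- donors[ok]
    f <- frac[ok]; jn <- joint[ok]
    o <- order(f, -jn, cand)
    list(donor = unname(cand[o[1]]), mismatch = unname(f[o[1]]),
         overlap = unname(jn[o[1]]))
}

#' Find the most similar donor line in a window
#'
#' Among the donors, finds the line minimizing the mismatch fraction with
#' the target over jointly non-missing haploidized calls inside the window.
#' Donors sharing fewer than `min_overlap` jointly called sites are not
#' considered (guards against spurious zero-mismatch matches on tiny
#' overlaps); ties are broken by larger overlap, then by lexicographic donor
#' id, so runs are reproducible.
#'
#' @param panel A [GenotypePanel-class].
#' @param window Integer vector of site indices (one element of
#'   [partitionWindows()]).
#' @param target Target sample id.
#' @param donors Candidate donor ids (default: all other samples).
#' @param max_mismatch Acceptance threshold on the mismatch fraction
#'   (default 0.05): above it the donor is vetoed.
#' @param min_overlap Minimum jointly non-missing calls (default 32).
#' @return A list `donor`, `mismatch`, `overlap`, `accepted`; `donor` is
#'   `NA` when no candidate meets `min_overlap`.
#' @export
nearestDonor <- function(panel, window, target, donors = NULL,
                         max_mismatch = 0.05, min_overlap = 32L) {
    d <- .hapDosage(panel)[window, , drop = FALSE]
    if (is.null(donors)) donors <- colnames(d)
    donors <- sort(setdiff(donors, target))
    x <- d[, target]
    sub <- d[, donors, drop = FALSE]
    joint <- colSums(!is.na(x) & !is.na(sub))
    mm <- colSums(x != sub, na.rm = TRUE)
    frac <- ifelse(joint > 0, mm / joint, NA_real_)
    pick <- .pickDonor(frac, joint, donors, min_overlap)
    if (is.null(pick))
        return(list(donor = NA_character_, mismatch = NA_real_,
                    overlap = NA_integer_, accepted = FALSE))
    c(pick, list(accepted = pick$mismatch <= max_mismatch))
}

#' Window-based nearest-neighbor imputation
#'
#' Splits the panel into windows of `window_size` consecutive SNPs and, for
#' every (sample, window) with missing calls, copies the missing calls from
#' the most similar donor line in that window — exploiting the short
#' identical-by-descent segments shared across an inbred collection. A
#' donor differing from the target by more than `max_mismatch` (default 5%)
#' of jointly called haploidized sites is vetoed and the window is left
#' unimputed. Observed calls are never altered, and cells missing in the
#' chosen donor stay missing.
#'
#' @param panel A [GenotypePanel-class].
#' @param window_size Sites per window (default 1024).
#' @param max_mismatch Donor veto threshold (default 0.05).
#' @param min_overlap Minimum jointly non-missing calls per window for a
#'   donor to be considered (default 32).
#' @param donors Donor sample ids (default: the panel itself; the target is
#'   always excluded from its own donor search).
#' @return A list with `panel` (imputed), and `report`: `fraction_imputed`
#'   and `fraction_left_missing` over originally-missing calls (they sum to
#'   1), `n_missing_before`, plus `choices`, a `data.frame` of per
#'   (window, sample) donor decisions.
#' @export
imputePanel <- function(panel, window_size = 1024L, max_mismatch = 0.05,
                        min_overlap = 32L, donors = NULL) {
    gt <- genotypes(panel)
    d <- .hapDosage(gt)
    samples <- colnames(gt)
    if (is.null(donors)) donors <- samples
    donors <- sort(donors)
    windows <- partitionWindows(panel, window_size)
    n_missing <- sum(is.na(gt))
    n_imputed <- 0L
    choices <- vector("list", length(windows))
    for (w in seq_along(windows)) {
        idx <- windows[[w]]
        dw <- d[idx, , drop = FALSE]
        gw <- gt[idx, , drop = FALSE]
        need <- which(colSums(is.na(gw)) > 0L)
        if (!length(need)) next
        # pairwise mismatch counts / overlaps between all samples and donors
        M <- !is.na(dw)
        A0 <- (dw == 0) & M; A1 <- (dw == 1) & M
        A0[is.na(A0)] <- FALSE; A1[is.na(A1)] <- FALSE
        mmat <- crossprod(A0[, donors, drop = FALSE] * 1,
                          A1 * 1)  # donors x samples
        mmat <- mmat + crossprod(A1[, donors, drop = FALSE] * 1, A0 * 1)
        jmat <- crossprod(M[, donors, drop = FALSE] * 1, M * 1)
        rec <- vector("list", length(need))
        for (t in seq_along(need)) {
            j <- need[t]
            tid <- samples[j]
            cand <- setdiff(donors, tid)
            frac <- ifelse(jmat[cand, j] > 0,
                           mmat[cand, j] / jmat[cand, j], NA_real_)
            pick <- .pickDonor(frac, jmat[cand, j], cand, min_overlap)
            accepted <- !is.null(pick) && pick$mismatch <= max_mismatch
            filled <- 0L
            if (accepted) {
                fill <- is.na(gw[, j]) & !is.na(gw[, pick$donor])
                if (any(fill)) {
                    gt[idx[fill], j] <- gw[fill, pick$donor]
                    filled <- sum(fill)
                    n_imputed <- n_imputed + filled
                }
            }
            rec[[t]] <- data.frame(
                window = w, sample = tid,
                donor = if (is.null(pick)) NA_character_ else pick$donor,
                mismatch = if (is.null(pick)) NA_real_ else pick$mismatch,
                overlap = if (is.null(pick)) NA_integer_ else pick$overlap,
                accepted = accepted, n_filled = filled)
        }
        choices[[w]] <- do.call(rbind, rec)
    }
    choices <- do.call(rbind, choices[!vapply(choices, is.null, TRUE)])
    SummarizedExperiment::assay(panel, "GT") <- gt
    list(panel = panel,
         report = list(
             fraction_imputed = if (n_missing) n_imputed / n_missing else 0,
             fraction_left_missing =
                 if (n_missing) 1 - n_imputed / n_missing else 0,
             n_missing_before = n_missing,
             choices = choices))
}

#' Score imputation against masked ground truth
#'
#' Compares imputed calls at deliberately masked cells with the hidden
#' truth. The error rate is the fraction of imputed cells whose call
#' differs from the truth; the heterozygote-excluded variant drops cells
#' heterozygous in either the truth or the imputation (heterozygote calls
#' are inherently noisy in low-pass GBS data).
#'
#' @param truth The original (pre-masking) [GenotypePanel-class].
#' @param mask Mask record from [maskGenotypes()].
#' @param imputed The imputed [GenotypePanel-class].
#' @return A list: `all_calls_error`, `het_excluded_error`,
#'   `fraction_imputed`, `fraction_unimputed`, `n_masked`, `n_imputed`.
#'   Rates are `NA` when the mask is empty.
#' @export
evaluateImputation <- function(truth, mask, imputed) {
    if (!nrow(mask))
        return(list(all_calls_error = NA_real_,
                    het_excluded_error = NA_real_,
                    fraction_imputed = NA_real_,
                    fraction_unimputed = NA_real_,
                    n_masked = 0L, n_imputed = 0L))
    gt_t <- genotypes(truth)
    gt_i <- genotypes(imputed)
    j <- match(mask$sample, colnames(gt_t))
    cells <- cbind(mask$site, j)
    tv <- gt_t[cells]
    iv <- gt_i[cells]
    imput <- !is.na(iv)
    wrong <- imput & iv != tv
    keep_het <- imput & !(tv == 1L | iv == 1L)
    list(all_calls_error = if (any(imput)) mean(wrong[imput]) else NA_real_,
         het_excluded_error = if (any(keep_het))
             mean(iv[keep_het] != tv[keep_het]) else NA_real_,
         fraction_imputed = mean(imput),
         fraction_unimputed = mean(!imput),
         n_masked = nrow(mask), n_imputed = sum(imput))
}
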