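#' Per-site quality summaries
#'
#' Computes, for every site, the quantities driving the discovery filters:
#' call rate, first-allele frequency `p` (a heterozygote contributes one
#' copy of each allele), minor allele frequency, observed heterozygosity
#' `H_O` (heterozygous calls / non-missing calls), expected heterozygosity
#' `H_E = 2 p (1 - p)`, and the coefficient of panmixia `1 - H_O / H_E` (the
#' site-level inbreeding coefficient used to reject collapsed paralogs: near
#' 1 for true SNPs in an inbred panel, low when apparent heterozygosity is
#' excessive). A monomorphic site (`H_E = 0`, `H_O = 0`) is fully consistent
#' with inbreeding and its panmixia is defined as 1; the stored `panmixia`
#' is clamped to `[0, 1]` with the unclamped value kept in `panmixia_raw`.
#'
#' @param panel A [GenotypePanel-class].
#' @return A [S4Vectors::DataFrame] with one row per site: `n_called`,
#'   `call_rate`, `p_ref`, `maf`, `obs_het`, `exp_het`, `panmixia`,
#'   `panmixia_raw` and `defined` (`FALSE` for all-missing sites, whose
#'   statistics are `NA` and which are excluded from filtering decisions).
#' @examples
#' gp <- GenotypePanel(cbind(a = c(0L, 0L), b = c(0L, 0L), c = c(2L, NA)),
#'                     chrom = c("1", "1"), pos = 1:2,
#'                     ref = c("A", "A"), alt = c("G", "G"))
#' siteSummary(gp)  # site 1: p = 2/3, H_E = 4/9, panmixia = 1
#' @export
siteSummary <- function(panel) {
    gt <- genotypes(panel)
    called <- !is.na(gt)
    n_called <- unname(rowSums(called))
    n0 <- unname(rowSums(gt == 0L, na.rm = TRUE))
    n1 <- unname(rowSums(gt == 1L, na.rm = TRUE))
    p <- (2 * n0 + n1) / (2 * n_called)
    ho <- n1 / n_called
    he <- 2 * p * (1 - p)
    pan_raw <- ifelse(he == 0, ifelse(ho == 0, 1, -Inf), 1 - ho / he)
    undef <- n_called == 0L
    res <- S4Vectors::DataFrame(
        n_called = n_called,
        call_rate = n_called / ncol(gt),
        p_ref = p,
        maf = pmin(p, 1 - p),
        obs_het = ho,
        exp_het = he,
        panmixia = pmax(0, pmin(1, pan_raw)),
        panmixia_raw = pan_raw,
        defined = !undef,
        row.names = rownames(gt))
    res[undef, c("p_ref", "maf", "obs_het", "exp_het",
                 "panmixia", "panmixia_raw")] <- NA_real_
    res
}

#' SNP discovery filter
#'
#' Keeps a site iff it meets all three pipeline discovery thresholds
#' (inclusive comparisons): minimum call rate 10%, minimum coefficient of
#' panmixia 0.8, and minimum minor allele frequency 0.2%. All-missing
#' (undefined) sites are dropped.
#'
#' @param table The [siteSummary()] of the matrix being filtered.
#' @param min_call_rate,min_panmixia,min_maf Thresholds (defaults are the
#'   GBS discovery-pipeline values).
#' @return A named logical vector, `TRUE` for kept sites.
#' @export
discoveryFilter <- function(table, min_call_rate = 0.10,
                            min_panmixia = 0.8, min_maf = 0.002) {
    keep <- table$defined &
        table$call_rate >= min_call_rate &
        table$panmixia >= min_panmixia &
        table$maf >= min_maf
    keep[is.na(keep)] <- FALSE
    stats::setNames(keep, rownames(table))
}
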