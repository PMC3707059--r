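#' Mask genotype calls to emulate GBS missingness
#'
#' Hides calls so that each sample's realized call rate matches a target
#' drawn uniformly from `[callrate_low, callrate_high]` (the per-sample
#' coverage range of low-pass GBS data). With `genotype_bias > 0` the target
#' rate of each sample is additionally multiplied by
#' `1 - genotype_bias * d`, where `d` is the sample's haploid mismatch
#' fraction to a designated `reference` sample: lines distant from the
#' reference lineage lose more calls, emulating the reference-alignment and
#' presence/absence-variation effect of reduced-representation sequencing
#' against a single reference genome.
#'
#' Masking is non-destructive: the returned `mask` record lists every hidden
#' call with its original code, and [unmaskGenotypes()] restores the input
#' exactly.
#'
#' @param panel A [GenotypePanel-class].
#' @param callrate_low,callrate_high Per-sample call-rate range in `[0, 1]`.
#' @param genotype_bias Non-negative multiplier strength of the
#'   reference-distance effect (0 disables it).
#' @param reference Sample id of the reference-proximal lineage (required
#'   when `genotype_bias > 0`).
#' @param seed Optional integer seed.
#' @return A list with `panel` (masked) and `mask`, a `data.frame` with
#'   columns `site` (row index), `sample` (sample id) and `call` (original
#'   code).
#' @export
maskGenotypes <- function(panel, callrate_low = 0.02, callrate_high = 0.75,
                          genotype_bias = 0, reference = NULL, seed = NULL) {
    .checkProb(callrate_low, "callrate_low")
    .checkProb(callrate_high, "callrate_high")
    if (callrate_low > callrate_high)
        stop("'callrate_low' must not exceed 'callrate_high'")
    if (genotype_bias < 0)
        stop("'genotype_bias' must be non-negative")
    if (genotype_bias > 0 && is.null(reference))
        stop("'reference' sample is required when 'genotype_bias' > 0")
    if (!is.null(seed)) set.seed(seed)
    gt <- genotypes(panel)
    target <- stats::runif(ncol(gt), callrate_low, callrate_high)
    if (genotype_bias > 0) {
        d <- .hapDosage(gt)
        dref <- d[, reference]
        mism <- vapply(seq_len(ncol(d)), function(j) {
            joint <- !is.na(dref) & !is.na(d[, j])
            if (!any(joint)) return(0)
            mean(dref[joint] != d[joint, j])
        }, 0)
        target <- pmax(0, pmin(1, target * (1 - genotype_bias * mism)))
    }
    recs <- vector("list", ncol(gt))
    for (j in seq_len(ncol(gt))) {
        called <- which(!is.na(gt[, j]))
        keep_n <- round(target[j] * length(called))
        hide <- if (length(called))
            sample(called, length(called) - keep_n) else integer(0)
        if (length(hide)) {
            recs[[j]] <- data.frame(site = hide,
                                    sample = colnames(gt)[j],
                                    call = gt[hide, j])
            gt[hide, j] <- NA_integer_
        }
    }
    mask <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
    if (is.null(mask))
        mask <- data.frame(site = integer(0), sample = character(0),
                           call = integer(0))
    rownames(mask) <- NULL
    SummarizedExperiment::assay(panel, "GT") <- gt
    list(panel = panel, mask = mask)
}

#' Restore masked genotype calls
#'
#' @param panel A masked [GenotypePanel-class].
#' @param mask The mask record returned by [maskGenotypes()].
#' @return The panel with every masked call restored.
#' @export
unmaskGenotypes <- function(panel, mask) {
    gt <- genotypes(panel)
    if (nrow(mask)) {
        j <- match(mask$sample, colnames(gt))
        gt[cbind(mask$site, j)] <- as.integer(mask$call)
    }
    SummarizedExperiment::assay(panel, "GT") <- gt
    panel
}

#' Inject base-call errors into a panel
#'
#' Alters each non-missing call independently with probability
#' `error_rate`. An erroneous homozygous call becomes the opposite
#' homozygote (a miscalled base on an effectively haploid GBS call); an
#' erroneous heterozygous call collapses to a random homozygote. The default
#' rate matches the repeated-sample base-call error rate typical of GBS
#' (~0.18%).
#'
#' @param panel A [GenotypePanel-class].
#' @param error_rate Per-call error probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A list with `panel` (perturbed) and `errors`, a `data.frame` of
#'   altered cells (`site`, `sample`, `original`, `observed`).
#' @export
injectErrors <- function(panel, error_rate = 0.0018, seed = NULL) {
    .checkProb(error_rate, "error_rate")
    if (!is.null(seed)) set.seed(seed)
    gt <- genotypes(panel)
    errors <- data.frame(site = integer(0), sample = character(0),
                         original = integer(0), observed = integer(0))
    if (error_rate > 0) {
        called <- which(!is.na(gt))
        hit <- called[stats::runif(length(called)) < error_rate]
        if (length(hit)) {
            old <- gt[hit]
            new <- ifelse(old == 0L, 2L,
                   ifelse(old == 2L, 0L,
                          2L * stats::rbinom(length(old), 1L, 0.5)))
            gt[hit] <- as.integer(new)
            errors <- data.frame(site = ((hit - 1L) %% nrow(gt)) + 1L,
                                 sample = colnames(gt)[((hit - 1L) %/%
                                                        nrow(gt)) + 1L],
                                 original = old, observed = as.integer(new))
        }
    }
    SummarizedExperiment::assay(panel, "GT") <- gt
    list(panel = panel, errors = errors)
}
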