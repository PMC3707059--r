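#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn GenotypePanel genotype call matrix (sites x samples).
#' @param x A `GenotypePanel`.
#' @export
setMethod("genotypes", "GenotypePanel", function(x)
    SummarizedExperiment::assay(x, "GT"))

#' @describeIn GenotypePanel heterozygous calls set to `NA`.
#' @export
setMethod("haploidize", "GenotypePanel", function(x) {
    gt <- SummarizedExperiment::assay(x, "GT")
    gt[!is.na(gt) & gt == 1L] <- NA_integer_
    SummarizedExperiment::assay(x, "GT") <- gt
    x
})

#' @describeIn GenotypePanel per-sample group labels (NA when unassigned).
#' @export
setMethod("sampleGroups", "GenotypePanel", function(x) {
    cd <- SummarizedExperiment::colData(x)
    g <- if ("group" %in% colnames(cd)) cd$group else
        rep(NA_character_, ncol(x))
    stats::setNames(as.character(g), colnames(x))
})

#' @describeIn GenotypePanel assign group labels (unnamed, in column order,
#'   or named by sample id).
#' @param value replacement group labels.
#' @export
setMethod("sampleGroups<-", "GenotypePanel", function(x, value) {
    if (!is.null(names(value))) {
        g <- stats::setNames(rep(NA_character_, ncol(x)), colnames(x))
        miss <- setdiff(names(value), colnames(x))
        if (length(miss))
            stop("unknown sample id(s): ", paste(miss, collapse = ", "))
        g[names(value)] <- as.character(value)
        value <- g
    } else if (length(value) != ncol(x)) {
        stop("'value' must have one label per sample or be named")
    }
    SummarizedExperiment::colData(x)$group <- as.character(value)
    x
})

setMethod("show", "GenotypePanel", function(object) {
    gt <- SummarizedExperiment::assay(object, "GT")
    chr <- unique(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(object))))
    cr <- if (length(gt)) mean(!is.na(gt)) else NA_real_
    cat(sprintf("GenotypePanel: %d sites x %d samples on %d chromosome(s)\n",
                nrow(object), ncol(object), length(chr)))
    cat(sprintf("  call rate: %.1f%%; het rate among calls: %.2f%%\n",
                100 * cr,
                100 * mean(gt[!is.na(gt)] == 1L)))
    g <- SummarizedExperiment::colData(object)$group
    if (!is.null(g))
        cat("  groups: ",
            paste(utils::head(names(table(g)), 6), collapse = ", "), "\n",
            sep = "")
    invisible(NULL)
})

#' @describeIn PairwiseMatrix numeric value matrix.
#' @param x A `PairwiseMatrix`.
#' @export
setMethod("pairValues", "PairwiseMatrix", function(x) x@values)

#' @describeIn PairwiseMatrix supporting-site counts.
#' @export
setMethod("pairCounts", "PairwiseMatrix", function(x) x@counts)

setMethod("show", "PairwiseMatrix", function(object) {
    v <- object@values
    off <- v[upper.tri(v)]
    cat(sprintf("PairwiseMatrix (%s): %d samples\n",
                object@statistic, nrow(v)))
    if (length(off))
        cat(sprintf("  off-diagonal range: [%.4f, %.4f] (%d NA pairs)\n",
                    suppressWarnings(min(off, na.rm = TRUE)),
                    suppressWarnings(max(off, na.rm = TRUE)),
                    sum(is.na(off))))
    invisible(NULL)
})
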