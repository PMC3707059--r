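#' GenotypePanel: diploid SNP calls for a panel of samples
#'
#' The central container of the package. A `GenotypePanel` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] with a single `"GT"`
#' assay holding one diploid call per (site, sample): `0L` homozygous for the
#' first (reference-like) allele, `1L` heterozygous, `2L` homozygous for the
#' second allele, `NA` missing. Rows are SNP sites carried as a
#' [GenomicRanges::GRanges] (1-based positions, width 1) with `ref` and `alt`
#' single-nucleotide metadata columns; columns are samples, optionally
#' annotated with a `group` (germplasm group) and a `family` (biparental
#' family) label in `colData`.
#'
#' Sites are always sorted by (chromosome, position) and duplicated
#' (chromosome, position) pairs are rejected. Minor allele frequency and
#' allele dosage are never stored; they are recomputed by each analysis from
#' the calls at hand.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @seealso [GenotypePanel()] for construction, [readVCF()], [readHapMap()].
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

.validGenotypePanel <- function(object) {
    msg <- NULL
    if (!("GT" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'GT' is required")
    gt <- SummarizedExperiment::assay(object, "GT")
    if (!is.integer(gt) && !all(is.na(gt)))
        msg <- c(msg, "'GT' assay must be an integer matrix")
    bad <- gt[!is.na(gt)]
    if (length(bad) && !all(bad %in% 0:2))
        msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr)) {
        mc <- S4Vectors::mcols(rr)
        if (!all(c("ref", "alt") %in% colnames(mc)))
            msg <- c(msg, "site metadata must contain 'ref' and 'alt'")
        else if (any(!is.na(mc$ref) & !is.na(mc$alt) & mc$ref == mc$alt))
            msg <- c(msg, "'ref' and 'alt' alleles must be distinct")
        if (any(GenomicRanges::start(rr) < 1L))
            msg <- c(msg, "positions must be >= 1")
        chr <- as.character(GenomicRanges::seqnames(rr))
        pos <- GenomicRanges::start(rr)
        o <- order(factor(chr, levels = unique(chr)), pos)
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "sites must be sorted by (chromosome, position)")
        if (anyDuplicated(paste(chr, pos)))
            msg <- c(msg, "duplicate (chromosome, position) pairs")
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (is.null(msg)) TRUE else msg
}

setValidity("GenotypePanel", .validGenotypePanel)

#' Construct a GenotypePanel
#'
#' @param geno Integer matrix of genotype codes, sites in rows and samples in
#'   columns (`0` hom first allele, `1` het, `2` hom second allele, `NA`
#'   missing). Column names are sample ids; row names are ignored and
#'   regenerated as `chrom_pos`.
#' @param chrom Character vector of chromosome labels, one per site.
#' @param pos Integer vector of 1-based positions, one per site.
#' @param ref,alt Single-nucleotide first and second alleles per site.
#' @param group Optional character vector of per-sample group labels.
#' @param family Optional character vector of per-sample biparental family
#'   labels.
#' @param metadata Optional list stored in `metadata()` (used by the
#'   simulators to carry ground truth).
#' @return A [GenotypePanel-class] with sites sorted by (chromosome,
#'   position).
#' @examples
#' gp <- GenotypePanel(matrix(c(0L, 2L, 1L, NA), 2, 2,
#'                            dimnames = list(NULL, c("L1", "L2"))),
#'                     chrom = c("1", "1"), pos = c(100L, 200L),
#'                     ref = c("A", "C"), alt = c("G", "T"))
#' gp
#' @export
GenotypePanel <- function(geno, chrom, pos, ref, alt,
                          group = NULL, family = NULL, metadata = list()) {
    geno <- as.matrix(geno)
    storage.mode(geno) <- "integer"
    if (is.null(colnames(geno)))
        colnames(geno) <- sprintf("S%03d", seq_len(ncol(geno)))
    stopifnot(length(chrom) == nrow(geno), length(pos) == nrow(geno),
              length(ref) == nrow(geno), length(alt) == nrow(geno))
    chrom <- as.character(chrom)
    lv <- unique(chrom)
    num <- suppressWarnings(as.numeric(lv))
    lv <- lv[order(is.na(num), num, lv)]  # natural chromosome order
    o <- order(factor(chrom, levels = lv), pos)
    geno <- geno[o, , drop = FALSE]
    chrom <- chrom[o]; pos <- as.integer(pos[o])
    ref <- as.character(ref)[o]; alt <- as.character(alt)[o]
    rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                                 ref = ref, alt = alt)
    names(rr) <- paste(chrom, pos, sep = "_")
    rownames(geno) <- names(rr)
    cd <- S4Vectors::DataFrame(row.names = colnames(geno))
    if (!is.null(group)) cd$group <- as.character(group)
    if (!is.null(family)) cd$family <- as.character(family)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(GT = geno), rowRanges = rr, colData = cd,
        metadata = metadata)
    methods::new("GenotypePanel", se)
}

#' PairwiseMatrix: a symmetric sample-by-sample statistic
#'
#' Holds pairwise identity-by-state, identity-by-descent or distance values
#' together with the number of jointly non-missing sites supporting each
#' pair. Values lie in `[0, 1]` with a unit diagonal; pairs with no
#' supporting sites are `NA`. For clamped estimators (IBD pi-hat) the
#' unclamped values are retained in the `raw` slot for auditing.
#'
#' @slot values symmetric numeric matrix in `[0, 1]`, diagonal 1.
#' @slot counts integer matrix of supporting jointly non-missing site counts.
#' @slot statistic single string naming the statistic (e.g. `"IBS"`).
#' @slot raw optional unclamped value matrix (may be 0x0 when not relevant).
#' @aliases PairwiseMatrix-class
#' @exportClass PairwiseMatrix
setClass("PairwiseMatrix",
         representation(values = "matrix", counts = "matrix",
                        statistic = "character", raw = "matrix"))

.validPairwiseMatrix <- function(object) {
    v <- object@values
    msg <- NULL
    if (nrow(v) != ncol(v)) msg <- c(msg, "'values' must be square")
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-10)))
        msg <- c(msg, "'values' must be symmetric")
    ok <- v[!is.na(v)]
    if (length(ok) && (min(ok) < -1e-10 || max(ok) > 1 + 1e-10))
        msg <- c(msg, "'values' must lie in [0, 1]")
    if (!all(dim(object@counts) == dim(v)))
        msg <- c(msg, "'counts' dimensions must match 'values'")
    if (is.null(msg)) TRUE else msg
}

setValidity("PairwiseMatrix", .validPairwiseMatrix)

.PairwiseMatrix <- function(values, counts, statistic, raw = NULL) {
    if (is.null(raw)) raw <- matrix(numeric(0), 0, 0)
    methods::new("PairwiseMatrix", values = values,
                 counts = counts, statistic = statistic, raw = raw)
}
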