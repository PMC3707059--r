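#' @include AllClasses.R
NULL

#' Extract the genotype call matrix
#'
#' @param x A [GenotypePanel-class] object.
#' @return An integer matrix (sites x samples) with values `0` (homozygous
#'   first/reference allele), `1` (heterozygous), `2` (homozygous second
#'   allele) and `NA` (missing).
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Set heterozygous calls to missing
#'
#' Inbred-panel analyses treat each line as a random sample of a single
#' haplotype, so residual heterozygous calls carry no usable phase
#' information and are set to missing before relatedness and diversity
#' computations.
#'
#' @param x A [GenotypePanel-class] object.
#' @return An object of the same class with every heterozygous call replaced
#'   by `NA`; all other calls are unchanged.
#' @export
setGeneric("haploidize", function(x) standardGeneric("haploidize"))

#' Get or set per-sample group labels
#'
#' @param x A [GenotypePanel-class] object.
#' @param value A character vector of group labels, either unnamed (length
#'   equal to the number of samples) or named by sample id.
#' @return `sampleGroups` returns a character vector named by sample id
#'   (possibly `NA` for unassigned samples).
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setGeneric("sampleGroups<-", function(x, value) standardGeneric("sampleGroups<-"))

#' Extract the numeric values of a pairwise sample matrix
#'
#' @param x A [PairwiseMatrix-class] object.
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
setGeneric("pairValues", function(x) standardGeneric("pairValues"))

#' @describeIn pairValues The per-pair count of jointly non-missing sites
#'   supporting each value.
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))
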