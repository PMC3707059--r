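# Internal helpers shared across modules.

# Haploidized allele dosage: 0 for hom first allele, 1 for hom second allele,
# NA for het or missing. Accepts a GenotypePanel or a raw code matrix.
.hapDosage <- function(x) {
    gt <- if (methods::is(x, "GenotypePanel")) genotypes(x) else x
    d <- gt
    d[!is.na(d) & d == 1L] <- NA_integer_
    d / 2
}

.siteChrom <- function(panel)
    as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(panel)))

.sitePos <- function(panel)
    GenomicRanges::start(SummarizedExperiment::rowRanges(panel))

# Resolve a group specification to sample ids: NULL -> all samples; a single
# string matching a colData group label -> members of that group; otherwise a
# vector of sample ids.
.groupSamples <- function(panel, group) {
    ids <- colnames(panel)
    if (is.null(group)) return(ids)
    grp <- sampleGroups(panel)
    if (length(group) == 1L && group %in% grp)
        return(ids[!is.na(grp) & grp == group])
    miss <- setdiff(group, ids)
    if (length(miss))
        stop("unknown sample id(s) or group label: ",
             paste(miss, collapse = ", "))
    group
}

# Per-chromosome site index runs, in panel order.
.chromIndices <- function(panel) {
    chr <- .siteChrom(panel)
    split(seq_along(chr), factor(chr, levels = unique(chr)))
}

# Squared Pearson correlation between one site and a set of sites on
# pairwise-complete haploidized dosages.
.r2With <- function(x, Y) {
    r <- suppressWarnings(stats::cor(x, Y, use = "pairwise.complete.obs"))
    as.vector(r)^2
}

.checkProb <- function(value, field) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
        value < 0 || value > 1)
        stop("'", field, "' must be a probability in [0, 1]")
    value
}

.checkCount <- function(value, field, min = 1L) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
        value < min || value != round(value))
        stop("'", field, "' must be an integer count >= ", min)
    as.integer(value)
}

# Draw random ref/alt allele pairs.
.randomAlleles <- function(n) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    list(ref = ref, alt = unname(alt))
}
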