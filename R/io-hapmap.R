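# TASSEL HapMap text: 11 metadata columns, then one single-letter IUPAC
# diploid code per sample. Heterozygotes use the two-base ambiguity codes.

.IUPAC_HET <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

.hetCode <- function(a, b) {
    key <- paste0(pmin(a, b), pmax(a, b))
    code <- .IUPAC_HET[key]
    if (anyNA(code))
        stop("no IUPAC code for allele pair(s): ",
             paste(unique(key[is.na(code)]), collapse = ", "))
    unname(code)
}

#' Read a TASSEL HapMap text genotype file
#'
#' Reads the tab-separated HapMap dialect used by TASSEL 3 (11 standard
#' header columns — `rs#`, `alleles`, `chrom`, `pos`, `strand`, `assembly#`,
#' `center`, `protLSID`, `assayLSID`, `panelLSID`, `QCcode` — followed by
#' one column per sample). Homozygotes are plain bases, heterozygotes the
#' two-base IUPAC ambiguity codes (R, Y, S, W, K, M), missing is `N`.
#'
#' @param path Path to a `.hmp.txt` file (plain or gzipped).
#' @return A [GenotypePanel-class].
#' @seealso [writeHapMap()]
#' @export
readHapMap <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", data.table = FALSE)
    if (ncol(dt) < 12L)
        stop("HapMap file must have 11 metadata columns plus >= 1 sample: ",
             path)
    alleles <- strsplit(dt[[2L]], "/", fixed = TRUE)
    if (any(lengths(alleles) != 2L))
        stop("malformed 'alleles' column at row ",
             which(lengths(alleles) != 2L)[1], " in ", path)
    ref <- vapply(alleles, `[`, "", 1L)
    alt <- vapply(alleles, `[`, "", 2L)
    het <- .hetCode(ref, alt)
    samples <- colnames(dt)[-(1:11)]
    geno <- matrix(NA_integer_, nrow(dt), length(samples))
    for (j in seq_along(samples)) {
        g <- dt[[11L + j]]
        out <- rep(NA_integer_, length(g))
        out[g == ref] <- 0L
        out[g == alt] <- 2L
        out[g == het] <- 1L
        unknown <- is.na(out) & g != "N"
        if (any(unknown)) {
            i <- which(unknown)[1]
            stop("unknown genotype code '", g[i], "' at row ", i,
                 " (site ", dt[[1L]][i], "), sample '", samples[j],
                 "' in ", path)
        }
        geno[, j] <- out
    }
    colnames(geno) <- samples
    GenotypePanel(geno, dt[[3L]], as.integer(dt[[4L]]), ref, alt)
}

#' Write a GenotypePanel as TASSEL HapMap text
#'
#' @param panel A [GenotypePanel-class].
#' @param path Output path (conventionally `*.hmp.txt`).
#' @return `path`, invisibly.
#' @seealso [readHapMap()]
#' @export
writeHapMap <- function(panel, path) {
    gt <- genotypes(panel)
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(panel))
    ref <- mc$ref; alt <- mc$alt
    het <- .hetCode(ref, alt)
    cells <- matrix("N", nrow(gt), ncol(gt))
    cells[!is.na(gt) & gt == 0L] <- matrix(ref, nrow(gt),
                                           ncol(gt))[!is.na(gt) & gt == 0L]
    cells[!is.na(gt) & gt == 2L] <- matrix(alt, nrow(gt),
                                           ncol(gt))[!is.na(gt) & gt == 2L]
    cells[!is.na(gt) & gt == 1L] <- matrix(het, nrow(gt),
                                           ncol(gt))[!is.na(gt) & gt == 1L]
    meta <- data.frame(`rs#` = rownames(gt),
                       alleles = paste(ref, alt, sep = "/"),
                       chrom = .siteChrom(panel),
                       pos = .sitePos(panel),
                       strand = "+", `assembly#` = "NA", center = "NA",
                       protLSID = "NA", assayLSID = "NA", panelLSID = "NA",
                       QCcode = "NA", check.names = FALSE)
    out <- cbind(meta, as.data.frame(cells,
                                     col.names = colnames(gt)))
    colnames(out)[-(1:11)] <- colnames(gt)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
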