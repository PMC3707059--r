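#' Read a VCF file into a GenotypePanel
#'
#' Parses a (plain or gzipped) VCF 4.x file of biallelic SNP records via
#' \pkg{vcfR} and maps diploid `GT` fields onto the canonical call codes:
#' `0/0` (or `0|0`, or haploid `0`) to homozygous reference, `0/1`/`1/0` to
#' heterozygous, `1/1` to homozygous alternate and `./.` to missing.
#' Multi-allelic records are rejected by default, the behavior of a GBS SNP
#' pipeline that emits biallelic sites. With `split_multiallelic = TRUE` a
#' multi-allelic record is reduced to a biallelic one for the most frequent
#' alternate allele (the container keeps a single record per position), and
#' calls involving any other alternate become missing.
#'
#' @param path Path to a VCF file.
#' @param split_multiallelic Reduce multi-allelic records to their major
#'   alternate instead of rejecting the file.
#' @return A [GenotypePanel-class].
#' @seealso [writeVCF()]
#' @export
readVCF <- function(path, split_multiallelic = FALSE) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix
    gtf <- v@gt
    if (is.null(gtf) || ncol(gtf) < 2L)
        stop("VCF has no sample genotype columns: ", path)
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi) && !split_multiallelic)
        stop(sum(multi), " multi-allelic record(s) in ", path,
             " (first at ", fix[which(multi)[1], "CHROM"], ":",
             fix[which(multi)[1], "POS"],
             "); use split_multiallelic = TRUE to reduce them")
    gt_field <- gtf[, -1L, drop = FALSE]
    gt_field[] <- gsub("|", "/", sub(":.*$", "", gt_field), fixed = TRUE)
    gt_field[is.na(gt_field)] <- "./."
    bad <- matrix(!grepl("^[0-9.]+(/[0-9.]+)?$", gt_field),
                  nrow(gt_field))
    if (any(bad)) {
        idx <- which(bad, arr.ind = TRUE)[1L, ]
        stop("malformed GT '", gt_field[bad][1], "' at record ", idx[1],
             ", sample '", colnames(gtf)[-1L][idx[2]], "' in ", path)
    }
    parseRow <- function(i, alt_idx) {
        g <- gt_field[i, ]
        out <- rep(NA_integer_, length(g))
        a <- as.character(alt_idx)
        out[g == "0/0" | g == "0"] <- 0L
        out[g == paste0("0/", a) | g == paste0(a, "/0")] <- 1L
        out[g == paste0(a, "/", a) | g == a] <- 2L
        out
    }
    alt <- fix[, "ALT"]
    geno <- matrix(NA_integer_, nrow(fix), ncol(gtf) - 1L)
    alt_used <- character(nrow(fix))
    for (i in seq_len(nrow(fix))) {
        alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
        k <- 1L
        if (length(alts) > 1L) {
            counts <- vapply(seq_along(alts), function(kk) {
                a <- as.character(kk)
                sum(vapply(strsplit(gt_field[i, ], "/", fixed = TRUE),
                           function(al) sum(al == a), 0L))
            }, 0L)
            k <- which.max(counts)
        }
        geno[i, ] <- parseRow(i, k)
        alt_used[i] <- alts[k]
    }
    colnames(geno) <- colnames(gtf)[-1L]
    GenotypePanel(geno, fix[, "CHROM"], as.integer(fix[, "POS"]),
                  fix[, "REF"], alt_used)
}

#' Write a GenotypePanel as a minimal VCF 4.2 file
#'
#' Emits a deterministic, minimal plain-text VCF: one `##contig` line per
#' chromosome, a single `GT` FORMAT field, sites in panel order.
#'
#' @param panel A [GenotypePanel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [readVCF()]
#' @export
writeVCF <- function(panel, path) {
    gt <- genotypes(panel)
    chrom <- .siteChrom(panel); pos <- .sitePos(panel)
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(panel))
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    cells <- matrix("./.", nrow(gt), ncol(gt))
    ok <- !is.na(gt)
    cells[ok] <- code[as.character(gt[ok])]
    body <- paste(chrom, pos, rownames(gt), mc$ref, mc$alt, ".", ".", ".",
                  "GT", apply(cells, 1L, paste, collapse = "\t"),
                  sep = "\t")
    header <- c("##fileformat=VCFv4.2",
                "##source=gbspanel",
                sprintf("##contig=<ID=%s>", unique(chrom)),
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(gt)),
                      collapse = "\t"))
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c(header, body), con)
    invisible(path)
}

#' Write per-sample annotations as a TSV sidecar
#'
#' @param panel A [GenotypePanel-class].
#' @param path Output path for a tab-separated table with columns
#'   `sample_id` plus any `colData` columns (e.g. `group`, `family`).
#' @return `path`, invisibly.
#' @export
writeSampleInfo <- function(panel, path) {
    cd <- as.data.frame(SummarizedExperiment::colData(panel))
    out <- cbind(sample_id = colnames(panel), cd)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a per-sample annotation TSV sidecar
#'
#' @param path A tab-separated file with a `sample_id` column.
#' @return A `data.frame` keyed by `sample_id`.
#' @export
readSampleInfo <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(df))
        stop("sample info file must have a 'sample_id' column: ", path)
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in ", path)
    df
}
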