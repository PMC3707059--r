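# Shared-haplotype length sampling: how far two random lines from a group
# stay identical around a random focal SNP.

# Extend from position j of the match vector m in one direction, allowing
# `forgive` mismatched sites to be skipped (not counted) before the side
# ends. Returns the count of matching sites and the index of the last
# matching site encountered (j when none).
.extendSide <- function(m, j, dir, forgive) {
    n <- length(m)
    cnt <- 0L
    last <- j
    i <- j + dir
    while (i >= 1L && i <= n) {
        if (m[i]) {
            cnt <- cnt + 1L
            last <- i
        } else {
            if (forgive <= 0L) break
            forgive <- forgive - 1L
        }
        i <- i + dir
    }
    list(count = cnt, last = last)
}

#' Sample shared-haplotype lengths between random line pairs
#'
#' Repeats the following draw: choose a random focal SNP across the genome
#' and two random lines from the group; compare their haploidized genotypes
#' at the focal SNP and extend outward in both directions until the
#' genotypes differ. To allow for sequencing error, `forgiveness` mismatches
#' (one by default) are permitted on each side before the haplotype end is
#' assigned; sites missing in either line are skipped — they count neither
#' as match nor mismatch. No allele-frequency filtering is applied. The
#' extension never crosses a chromosome end.
#'
#' Conventions (pinned by an exact-enumeration oracle in the tests):
#' `length_sites` counts compared-and-matching sites, including the focal
#' site; forgiven mismatches are not counted. When the two lines differ at
#' the focal site itself, that mismatch consumes the forgiveness of both
#' sides and the draw is recorded with the matching neighbors found (floor
#' 1). `length_bp` is the span between the terminal matching sites and
#' `median_site` the median position of the matching sites, the position
#' used to assign the draw to a genome interval.
#'
#' @param panel A [GenotypePanel-class].
#' @param group Group label or >= 2 sample ids (default: all samples).
#' @param n_draws Number of draws (default 1000).
#' @param forgiveness Mismatches forgiven per side (default 1; 0 gives the
#'   exact maximal shared interval).
#' @param seed Optional integer seed.
#' @return A `data.frame` with one row per draw: `chrom`, `focal_pos`,
#'   `sample1`, `sample2`, `length_sites`, `length_bp`, `median_site`,
#'   `focal_match`. Draws whose focal site could not be jointly called in
#'   25 pair attempts are dropped.
#' @seealso [haplotypeLengthByWindow()] for per-interval averages.
#' @export
haplotypeLengthSample <- function(panel, group = NULL, n_draws = 1000L,
                                  forgiveness = 1L, seed = NULL) {
    ids <- .groupSamples(panel, group)
    if (length(ids) < 2L) stop("group must contain at least 2 lines")
    n_draws <- .checkCount(n_draws, "n_draws")
    forgiveness <- .checkCount(forgiveness, "forgiveness", min = 0L)
    if (!is.null(seed)) set.seed(seed)
    d <- .hapDosage(panel)[, ids, drop = FALSE]
    chrom <- .siteChrom(panel); pos <- .sitePos(panel)
    chr_of <- factor(chrom, levels = unique(chrom))
    out <- vector("list", n_draws)
    for (k in seq_len(n_draws)) {
        rec <- NULL
        for (try in 1:25) {
            focal <- sample.int(nrow(d), 1L)
            pair <- sample(ids, 2L)
            x <- d[, pair[1]]; y <- d[, pair[2]]
            if (is.na(x[focal]) || is.na(y[focal])) next
            cidx <- which(chr_of == chr_of[focal])
            joint <- cidx[!is.na(x[cidx]) & !is.na(y[cidx])]
            m <- x[joint] == y[joint]
            j <- match(focal, joint)
            if (m[j]) {
                L <- .extendSide(m, j, -1L, forgiveness)
                R <- .extendSide(m, j, +1L, forgiveness)
                len <- 1L + L$count + R$count
                span_idx <- joint[L$last]:joint[R$last]
            } else if (forgiveness >= 1L) {
                # focal mismatch consumes the forgiveness of both sides
                L <- .extendSide(m, j, -1L, forgiveness - 1L)
                R <- .extendSide(m, j, +1L, forgiveness - 1L)
                len <- max(1L, L$count + R$count)
                span_idx <- joint[L$last]:joint[R$last]
            } else {
                # nothing to forgive: the draw ends at the focal site
                L <- R <- list(count = 0L, last = j)
                len <- 1L
                span_idx <- focal
            }
            match_sites <- joint[joint >= min(span_idx) &
                                 joint <= max(span_idx)]
            match_sites <- match_sites[m[match(match_sites, joint)]]
            med <- if (length(match_sites))
                stats::median(pos[match_sites]) else pos[focal]
            rec <- data.frame(chrom = chrom[focal], focal_pos = pos[focal],
                              sample1 = pair[1], sample2 = pair[2],
                              length_sites = len,
                              length_bp = pos[joint[R$last]] -
                                  pos[joint[L$last]],
                              median_site = med,
                              focal_match = m[j])
            break
        }
        out[[k]] <- rec
    }
    res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    rownames(res) <- NULL
    res
}

#' Average shared-haplotype length per genome interval
#'
#' Assigns each draw to a fixed-width bp interval by its median site
#' (draws are sorted by median site, the convention used to build
#' per-interval distributions) and averages lengths per interval.
#'
#' @param draws Result of [haplotypeLengthSample()].
#' @param window_bp Interval width in bp (default 1 Mb).
#' @return A `data.frame`: `chrom`, `start`, `end`, `n_draws`,
#'   `mean_sites`, `mean_bp`, ordered by chromosome and interval.
#' @export
haplotypeLengthByWindow <- function(draws, window_bp = 1e6) {
    draws <- draws[order(draws$chrom, draws$median_site), , drop = FALSE]
    win <- (draws$median_site - 1) %/% window_bp
    key <- paste(draws$chrom, win, sep = ":")
    sp <- split(seq_len(nrow(draws)), factor(key, levels = unique(key)))
    out <- lapply(sp, function(idx)
        data.frame(chrom = draws$chrom[idx[1]],
                   start = win[idx[1]] * window_bp + 1,
                   end = (win[idx[1]] + 1) * window_bp,
                   n_draws = length(idx),
                   mean_sites = mean(draws$length_sites[idx]),
                   mean_bp = mean(draws$length_bp[idx])))
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
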