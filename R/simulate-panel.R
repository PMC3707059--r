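#' Simulate a structured inbred GBS panel with known ground truth
#'
#' Generates a panel of inbred lines from several subpopulations under a
#' Balding-Nichols drift model: ancestral allele frequencies are drawn
#' uniformly, each subpopulation's frequency is a Beta draw around the
#' ancestral value with drift parameter equal to `fst_target`, and each line
#' samples a single haplotype (inbreds are homozygous apart from residual
#' heterozygosity). The closed-form link between the Beta parameterization
#' and the Weir-Cockerham expectation makes the target fixation index
#' directly recoverable by [weirCockerhamFst()].
#'
#' Defaults emulate the statistical structure of a large maize inbred GBS
#' panel at desk scale: three major subpopulations with moderate
#' differentiation (fixation index 0.06), ten chromosomes, a ~0.2% base-call
#' error rate and a small residual heterozygosity.
#'
#' @param n_groups Number of subpopulations.
#' @param samples_per_group Inbred lines per subpopulation.
#' @param n_chromosomes,sites_per_chromosome,chromosome_length Genome layout;
#'   site positions are drawn uniformly along each chromosome (bp).
#' @param fst_target Drift parameter in `[0, 0.99]`; `0` means all
#'   subpopulations share the ancestral frequencies exactly.
#' @param residual_het_rate Probability that a call is rendered heterozygous
#'   (residual heterozygosity of incompletely fixed lines).
#' @param error_rate Base-call error rate applied via [injectErrors()].
#' @param maf_range Range of ancestral allele frequencies (uniform draw).
#' @param seed Optional integer seed.
#' @return A [GenotypePanel-class] with per-sample `group` labels and
#'   `metadata()` fields `ancestral_freq` (per site), `group_freq` (site x
#'   group matrix of realized subpopulation frequencies), `fst_target` and
#'   `error_record`.
#' @examples
#' p <- simulateStructuredPanel(n_groups = 2, samples_per_group = 5,
#'                              n_chromosomes = 1,
#'                              sites_per_chromosome = 100, seed = 1)
#' table(sampleGroups(p))
#' @export
simulateStructuredPanel <- function(n_groups = 3L, samples_per_group = 60L,
                                    n_chromosomes = 10L,
                                    sites_per_chromosome = 500L,
                                    chromosome_length = 2e8,
                                    fst_target = 0.06,
                                    residual_het_rate = 0.005,
                                    error_rate = 0.0018,
                                    maf_range = c(0.05, 0.95),
                                    seed = NULL) {
    n_groups <- .checkCount(n_groups, "n_groups")
    samples_per_group <- .checkCount(samples_per_group, "samples_per_group")
    n_chromosomes <- .checkCount(n_chromosomes, "n_chromosomes")
    sites_per_chromosome <- .checkCount(sites_per_chromosome,
                                        "sites_per_chromosome")
    if (!is.numeric(chromosome_length) || chromosome_length < sites_per_chromosome)
        stop("'chromosome_length' must be at least 'sites_per_chromosome' bp")
    if (!is.numeric(fst_target) || fst_target < 0 || fst_target > 0.99)
        stop("'fst_target' must lie in [0, 0.99]")
    .checkProb(residual_het_rate, "residual_het_rate")
    .checkProb(error_rate, "error_rate")
    if (!is.null(seed)) set.seed(seed)

    n_sites <- n_chromosomes * sites_per_chromosome
    chrom <- rep(as.character(seq_len(n_chromosomes)),
                 each = sites_per_chromosome)
    pos <- as.vector(vapply(seq_len(n_chromosomes), function(i)
        sort(sample.int(chromosome_length, sites_per_chromosome)),
        integer(sites_per_chromosome)))
    anc <- stats::runif(n_sites, maf_range[1], maf_range[2])

    if (fst_target > 0) {
        a <- anc * (1 - fst_target) / fst_target
        b <- (1 - anc) * (1 - fst_target) / fst_target
        pg <- vapply(seq_len(n_groups),
                     function(g) stats::rbeta(n_sites, a, b),
                     numeric(n_sites))
    } else {
        pg <- matrix(anc, n_sites, n_groups)
    }
    colnames(pg) <- paste0("G", seq_len(n_groups))

    n_samples <- n_groups * samples_per_group
    geno <- matrix(NA_integer_, n_sites, n_samples)
    grp <- rep(colnames(pg), each = samples_per_group)
    for (j in seq_len(n_samples)) {
        allele <- stats::rbinom(n_sites, 1L, pg[, grp[j]])
        geno[, j] <- 2L * allele
    }
    if (residual_het_rate > 0) {
        het <- matrix(stats::runif(length(geno)) < residual_het_rate,
                      n_sites, n_samples)
        geno[het] <- 1L
    }
    colnames(geno) <- sprintf("%s_L%03d", grp,
                              sequence(rep(samples_per_group, n_groups)))
    al <- .randomAlleles(n_sites)
    panel <- GenotypePanel(geno, chrom, pos, al$ref, al$alt, group = grp,
                           metadata = list(ancestral_freq = anc,
                                           group_freq = pg,
                                           fst_target = fst_target))
    if (error_rate > 0) {
        pe <- injectErrors(panel, error_rate)
        panel <- pe$panel
        S4Vectors::metadata(panel)$error_record <- pe$errors
    }
    panel
}

# One meiosis: recombine a pair of haplotypes (with their origin labels)
# into a gamete, with a Poisson number of crossovers placed uniformly in bp
# per chromosome and a random starting phase.
.gamete <- function(hap1, hap2, org1, org2, chrom, pos, xo_rate) {
    pick1 <- logical(length(hap1))
    for (idx in split(seq_along(chrom),
                      factor(chrom, levels = unique(chrom)))) {
        k <- stats::rpois(1L, xo_rate)
        phase <- stats::runif(1) < 0.5
        if (k > 0) {
            br <- sort(stats::runif(k, min(pos[idx]), max(pos[idx])))
            seg <- findInterval(pos[idx], br)
            pick1[idx] <- xor(phase, seg %% 2L == 1L)
        } else {
            pick1[idx] <- phase
        }
    }
    list(hap = ifelse(pick1, hap1, hap2),
         org = ifelse(pick1, org1, org2))
}

#' Expected recurrent-parent genome fraction after backcrossing
#'
#' After `b` backcrosses to a recurrent parent (followed by selfing to
#' fixation), the expected fraction of the derived inbred genome inherited
#' from the recurrent parent is `1 - (1/2)^(b + 1)`; four backcrosses give
#' 0.96875, the ~97% identity expected between a parental inbred and its
#' BC4-derived progeny.
#'
#' @param n_backcrosses Number of backcross generations (`>= 0`).
#' @return Expected recurrent-parent fraction.
#' @examples
#' backcrossExpectedFraction(4)  # 0.96875
#' @export
backcrossExpectedFraction <- function(n_backcrosses) {
    n_backcrosses <- .checkCount(n_backcrosses, "n_backcrosses", min = 0L)
    1 - 0.5^(n_backcrosses + 1)
}

#' Simulate an inbred line derived by backcrossing
#'
#' Crosses a donor line into a recurrent parent, backcrosses to the
#' recurrent parent `n_backcrosses` times (each meiosis places a Poisson
#' number of crossovers uniformly per chromosome), optionally selfs, and
#' fixes the line by doubling a final gamete. The realized recurrent-parent
#' fraction is tracked per site through every meiosis.
#'
#' @param panel A [GenotypePanel-class] holding both parents.
#' @param recurrent,donor Sample ids of the recurrent and donor parents;
#'   heterozygous or missing parent calls are resolved to a random allele.
#' @param n_backcrosses Backcross generations (`>= 0`; `0` is a selfed F1).
#' @param n_self_generations Selfing meioses applied after the last
#'   backcross, before the final fixation step.
#' @param crossovers_per_chromosome Expected crossovers per chromosome per
#'   meiosis.
#' @param seed Optional integer seed.
#' @return A list with `genotype` (integer code vector over the panel's
#'   sites), `recurrent_fraction` (realized fraction of sites inherited from
#'   the recurrent parent), `expected_fraction`, and `origin` (logical,
#'   `TRUE` where the site came from the recurrent parent).
#' @export
simulateBackcrossLine <- function(panel, recurrent, donor,
                                  n_backcrosses = 4L,
                                  n_self_generations = 0L,
                                  crossovers_per_chromosome = 2,
                                  seed = NULL) {
    n_backcrosses <- .checkCount(n_backcrosses, "n_backcrosses", min = 0L)
    n_self_generations <- .checkCount(n_self_generations,
                                      "n_self_generations", min = 0L)
    if (!is.null(seed)) set.seed(seed)
    gt <- genotypes(panel)
    chrom <- .siteChrom(panel); pos <- .sitePos(panel)
    hapOf <- function(id) {
        g <- gt[, id]
        a <- g / 2
        unres <- is.na(g) | g == 1L
        a[unres] <- stats::rbinom(sum(unres), 1L, 0.5)
        a
    }
    hr <- hapOf(recurrent); hd <- hapOf(donor)
    if (all(hr == hd))
        warning("recurrent and donor parents are identical; ",
                "realized fraction is reported as 1.0")
    # F1
    cur <- list(h1 = hr, o1 = rep(TRUE, length(hr)),
                h2 = hd, o2 = rep(FALSE, length(hd)))
    for (b in seq_len(n_backcrosses)) {
        g <- .gamete(cur$h1, cur$h2, cur$o1, cur$o2, chrom, pos,
                     crossovers_per_chromosome)
        cur <- list(h1 = g$hap, o1 = g$org,
                    h2 = hr, o2 = rep(TRUE, length(hr)))
    }
    for (s in seq_len(n_self_generations)) {
        g1 <- .gamete(cur$h1, cur$h2, cur$o1, cur$o2, chrom, pos,
                      crossovers_per_chromosome)
        g2 <- .gamete(cur$h1, cur$h2, cur$o1, cur$o2, chrom, pos,
                      crossovers_per_chromosome)
        cur <- list(h1 = g1$hap, o1 = g1$org, h2 = g2$hap, o2 = g2$org)
    }
    fin <- .gamete(cur$h1, cur$h2, cur$o1, cur$o2, chrom, pos,
                   crossovers_per_chromosome)
    frac <- if (all(hr == hd)) 1.0 else mean(fin$org)
    list(genotype = as.integer(2L * fin$hap),
         recurrent_fraction = frac,
         expected_fraction = backcrossExpectedFraction(n_backcrosses),
         origin = fin$org)
}

#' Simulate a biparental family
#'
#' Crosses two (resolved-to-haploid) parents and selfs the F1 independently
#' `generations_of_selfing` times per progeny, recombining with a Poisson
#' number of crossovers per chromosome at each meiosis. At sites where the
#' parents carry the same allele all progeny match the parents; at
#' segregating sites progeny allele frequencies are ~0.5/0.5.
#'
#' @param panel A [GenotypePanel-class] holding both parents (fully
#'   genotyped at the sites of interest).
#' @param parentA,parentB Parent sample ids.
#' @param n_progeny Number of progeny (`>= 2`).
#' @param generations_of_selfing Selfing generations after the F1.
#' @param crossovers_per_chromosome Expected crossovers per chromosome.
#' @param family_id Label stored in the progeny `colData$family`.
#' @param seed Optional integer seed.
#' @return A [GenotypePanel-class] of the progeny on the same sites, with
#'   `family` labels set.
#' @export
simulateBiparentalFamily <- function(panel, parentA, parentB,
                                     n_progeny = 50L,
                                     generations_of_selfing = 3L,
                                     crossovers_per_chromosome = 2,
                                     family_id = "F1", seed = NULL) {
    n_progeny <- .checkCount(n_progeny, "n_progeny", min = 2L)
    generations_of_selfing <- .checkCount(generations_of_selfing,
                                          "generations_of_selfing", min = 0L)
    if (!is.null(seed)) set.seed(seed)
    gt <- genotypes(panel)
    if (anyNA(gt[, c(parentA, parentB)]))
        stop("parents must be fully genotyped")
    chrom <- .siteChrom(panel); pos <- .sitePos(panel)
    ha <- gt[, parentA] / 2; hb <- gt[, parentB] / 2
    ha[gt[, parentA] == 1L] <- stats::rbinom(sum(gt[, parentA] == 1L), 1, 0.5)
    hb[gt[, parentB] == 1L] <- stats::rbinom(sum(gt[, parentB] == 1L), 1, 0.5)
    org <- rep(FALSE, length(ha))
    prog <- matrix(NA_integer_, nrow(gt), n_progeny)
    for (j in seq_len(n_progeny)) {
        ind <- list(h1 = ha, h2 = hb)
        for (s in seq_len(generations_of_selfing)) {
            g1 <- .gamete(ind$h1, ind$h2, org, org, chrom, pos,
                          crossovers_per_chromosome)
            g2 <- .gamete(ind$h1, ind$h2, org, org, chrom, pos,
                          crossovers_per_chromosome)
            ind <- list(h1 = g1$hap, h2 = g2$hap)
        }
        prog[, j] <- as.integer(ind$h1 + ind$h2)
    }
    colnames(prog) <- sprintf("%s_P%03d", family_id, seq_len(n_progeny))
    rr <- SummarizedExperiment::rowRanges(panel)
    GenotypePanel(prog, chrom, pos,
                  S4Vectors::mcols(rr)$ref, S4Vectors::mcols(rr)$alt,
                  family = rep(family_id, n_progeny),
                  metadata = list(parents = c(parentA, parentB),
                                  segregating = ha != hb))
}

#' Construct a two-line panel with planted shared haplotype blocks
#'
#' Builds a pair of fully genotyped inbred lines whose genomes agree in
#' blocks of exactly `block_sites` consecutive SNPs and disagree at every
#' site of the `gap_sites`-SNP spacers between blocks. Because the gaps are
#' fully discordant, the shared-haplotype extent around any focal site inside
#' a block is exactly the block, giving an exact ground truth for
#' [haplotypeLengthSample()].
#'
#' @param n_blocks Number of shared blocks.
#' @param block_sites Sites per shared block.
#' @param gap_sites Sites per discordant spacer (the pattern is
#'   gap, block, gap, ..., block, gap).
#' @param spacing_bp Distance between adjacent sites (bp).
#' @param chrom Chromosome label.
#' @param seed Optional integer seed.
#' @return A [GenotypePanel-class] with samples `"A"` and `"B"` in one group
#'   `"pair"`; `metadata()` carries `block_sites`, `block_bp` (bp span of a
#'   block) and the logical site vector `in_block`.
#' @export
simulateHaplotypeBlockPair <- function(n_blocks = 20L, block_sites = 50L,
                                       gap_sites = 10L, spacing_bp = 1000L,
                                       chrom = "1", seed = NULL) {
    n_blocks <- .checkCount(n_blocks, "n_blocks")
    block_sites <- .checkCount(block_sites, "block_sites")
    gap_sites <- .checkCount(gap_sites, "gap_sites", min = 2L)
    if (!is.null(seed)) set.seed(seed)
    in_block <- c(rep(FALSE, gap_sites),
                  rep(rep(c(TRUE, FALSE), n_blocks),
                      times = rep(c(block_sites, gap_sites), n_blocks)))
    n <- length(in_block)
    base <- 2L * stats::rbinom(n, 1L, 0.5)
    other <- base
    other[!in_block] <- 2L - base[!in_block]
    geno <- cbind(A = base, B = other)
    pos <- seq_len(n) * as.integer(spacing_bp)
    al <- .randomAlleles(n)
    GenotypePanel(geno, rep(chrom, n), pos, al$ref, al$alt,
                  group = c("pair", "pair"),
                  metadata = list(block_sites = block_sites,
                                  block_bp = (block_sites - 1L) * spacing_bp,
                                  in_block = in_block))
}

#' Simulate a group of founder-mosaic inbred lines
#'
#' Each line is a mosaic of a small founder set: walking along each
#' chromosome, the line switches to a different random founder with
#' probability `switch_prob` between adjacent sites, so shared haplotype
#' segments and linkage disequilibrium decay approximately geometrically
#' with site distance. Passing a per-gap vector for `switch_prob` creates
#' regions of suppressed recombination (longer shared haplotypes, slower LD
#' decay), mimicking pericentromeric behavior.
#'
#' @param n_lines Number of inbred lines.
#' @param n_founders Number of founder haplotypes.
#' @param n_sites Sites on the single simulated chromosome.
#' @param switch_prob Founder-switch probability per inter-site gap; scalar
#'   or vector of length `n_sites - 1`.
#' @param spacing_bp Distance between adjacent sites (bp).
#' @param chrom Chromosome label.
#' @param group Group label for all lines.
#' @param seed Optional integer seed.
#' @return A [GenotypePanel-class]; `metadata()` carries the founder
#'   haplotype matrix, the per-line founder-index paths, and `switch_prob`.
#' @export
simulateFounderMosaicPanel <- function(n_lines = 30L, n_founders = 8L,
                                       n_sites = 2000L, switch_prob = 0.01,
                                       spacing_bp = 1000L, chrom = "1",
                                       group = "mosaic", seed = NULL) {
    n_lines <- .checkCount(n_lines, "n_lines", min = 2L)
    n_founders <- .checkCount(n_founders, "n_founders", min = 2L)
    n_sites <- .checkCount(n_sites, "n_sites", min = 2L)
    if (length(switch_prob) == 1L)
        switch_prob <- rep(switch_prob, n_sites - 1L)
    if (length(switch_prob) != n_sites - 1L)
        stop("'switch_prob' must be scalar or length n_sites - 1")
    if (!is.null(seed)) set.seed(seed)
    founders <- matrix(stats::rbinom(n_sites * n_founders, 1L, 0.5),
                       n_sites, n_founders)
    paths <- matrix(NA_integer_, n_sites, n_lines)
    geno <- matrix(NA_integer_, n_sites, n_lines)
    for (j in seq_len(n_lines)) {
        f <- integer(n_sites)
        f[1] <- sample.int(n_founders, 1L)
        sw <- stats::runif(n_sites - 1L) < switch_prob
        for (i in seq_len(n_sites - 1L)) {
            f[i + 1L] <- if (sw[i]) {
                cand <- sample.int(n_founders - 1L, 1L)
                if (cand >= f[i]) cand + 1L else cand
            } else f[i]
        }
        paths[, j] <- f
        geno[, j] <- 2L * founders[cbind(seq_len(n_sites), f)]
    }
    colnames(geno) <- sprintf("M%03d", seq_len(n_lines))
    pos <- seq_len(n_sites) * as.integer(spacing_bp)
    al <- .randomAlleles(n_sites)
    GenotypePanel(geno, rep(chrom, n_sites), pos, al$ref, al$alt,
                  group = rep(group, n_lines),
                  metadata = list(founders = founders, paths = paths,
                                  switch_prob = switch_prob))
}
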