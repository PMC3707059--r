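test_that("MAF spectrum matches brute-force binning", {
    # identical lines: everything monomorphic, empty spectrum
    same <- makePanel(matrix(rep(c(0L, 2L), 20), 40, 6))
    sfs <- mafSpectrum(same)
    expect_identical(sfs$n_polymorphic, 0L)
    expect_identical(sum(sfs$counts), 0L)

    # one minor homozygote among 20 lines: MAF 0.05
    m <- matrix(0L, 1, 20); m[1, 3] <- 2L
    one <- mafSpectrum(makePanel(m))
    expect_equal(unname(one$maf), 0.05)

    set.seed(50)
    p <- simulateStructuredPanel(1, 30, 1, 800, fst_target = 0, seed = 51)
    sfs2 <- mafSpectrum(p)
    d <- gbspanel:::.hapDosage(p)
    f <- rowMeans(d, na.rm = TRUE)
    maf <- pmin(f, 1 - f)
    maf <- maf[maf > 0]
    edges <- seq(0, 0.5, 0.05)
    want <- vapply(seq_len(10), function(k) {
        if (k < 10) sum(maf >= edges[k] & maf < edges[k + 1])
        else sum(maf >= edges[10] & maf <= 0.5)
    }, 0L)
    expect_identical(unname(as.integer(sfs2$counts)), want)
    expect_equal(sfs2$rare_fraction, mean(maf < 0.05))
})

test_that("allele presence needs two carriers and recovers engineered sharing", {
    # an allele carried once is absent; carried twice (or one het + one
    # hom) is present
    m <- matrix(0L, 3, 12)
    m[1, 1] <- 2L               # singleton alt
    m[2, c(2, 3)] <- 2L         # two alt carriers
    m[3, 4] <- 1L; m[3, 5] <- 2L  # het counts as carrying
    gp <- makePanel(m, group = rep("g1", 12))
    ap <- allelePresence(gp, groups = list(g1 = colnames(genotypes(gp))))
    expect_identical(unname(ap$present$alt[, "g1"]), c(FALSE, TRUE, TRUE))
    expect_identical(unname(ap$present$ref[, "g1"]), c(TRUE, TRUE, TRUE))

    # engineered private and shared alleles across three groups
    g <- matrix(0L, 3, 30)
    g[1, 1:10] <- 2L            # alt private to group A
    g[2, ] <- rep(c(0L, 2L), 15)  # alt everywhere
    g[3, 11:14] <- 2L           # alt private to group B
    gp2 <- makePanel(g, group = rep(c("A", "B", "C"), each = 10))
    ap2 <- allelePresence(gp2)
    expect_identical(unname(ap2$present$alt["1_100", ]),
                     c(TRUE, FALSE, FALSE))
    expect_identical(unname(ap2$present$alt["1_300", ]),
                     c(FALSE, TRUE, FALSE))
    # union: 3 ref + 3 alt = 6; shared by all: ref at sites 2 and 3 (group
    # A has no ref carrier at site 1) plus alt at site 2 = 3
    expect_identical(ap2$n_union, 6L)
    expect_equal(ap2$shared_pct, 100 * 3 / 6)
    expect_equal(unname(ap2$group_pct["C"]), 100 * 4 / 6)
})

test_that("Weir-Cockerham theta equals hand computation and hits its limits", {
    # worked frequency table: p1 = 0.8 (n 30), p2 = 0.3 (n 50)
    m <- cbind(matrix(rep(c(rep(2L, 24), rep(0L, 6))), 1, 30),
               matrix(rep(c(rep(2L, 15), rep(0L, 35))), 1, 50))
    gp <- makePanel(m, group = rep(c("A", "B"), c(30, 50)))
    fit <- weirCockerhamFst(gp, "A", "B")
    expect_equal(fit$per_site$theta, bruteThetaHaploid(0.2, 30, 0.7, 50))

    # groups fixed for opposite alleles: theta = 1
    fx <- makePanel(matrix(rep(c(0L, 2L), each = 10), 1, 20),
                    group = rep(c("A", "B"), each = 10))
    expect_equal(weirCockerhamFst(fx, "A", "B")$per_site$theta, 1)

    # identical frequencies, many sites: mean theta near 0 (can be
    # slightly negative per site)
    p0 <- simulateStructuredPanel(2, 30, 1, 10000, fst_target = 0,
                                  residual_het_rate = 0, error_rate = 0,
                                  seed = 52)
    null_fit <- weirCockerhamFst(p0, "G1", "G2")
    expect_lt(abs(null_fit$overall$mean_theta), 0.005)
    expect_lt(abs(null_fit$overall$ratio_of_sums), 0.005)
})

test_that("nucleotide divergence matches a brute-force pair computation", {
    idA <- paste0("a", 1:4); idB <- paste0("b", 1:4)
    same <- makePanel(matrix(rep(c(0L, 2L), 20), 40, 8,
                             dimnames = list(NULL, c(idA, idB))),
                      group = rep(c("A", "B"), each = 4))
    expect_equal(nucleotideDivergence(same, "A", "B",
                                      min_joint = 5)$overall, 0)

    opp <- makePanel(cbind(matrix(0L, 40, 4), matrix(2L, 40, 4)) |>
                     `colnames<-`(c(idA, idB)),
                     group = rep(c("A", "B"), each = 4))
    expect_equal(nucleotideDivergence(opp, "A", "B",
                                      min_joint = 5)$overall, 1)

    set.seed(53)
    m <- randomGeno(30, 8, p_missing = 0.2, p_het = 0.1)
    colnames(m) <- c(idA, idB)
    gp <- makePanel(m, group = rep(c("A", "B"), each = 4))
    got <- nucleotideDivergence(gp, "A", "B", window_bp = 1e7,
                                min_joint = 3)
    d <- gbspanel:::.hapDosage(m)
    ibs <- c()
    for (i in idA) for (j in idB) {
        joint <- !is.na(d[, i]) & !is.na(d[, j])
        if (sum(joint) >= 3)
            ibs <- c(ibs, mean(d[joint, i] == d[joint, j]))
    }
    expect_equal(got$overall, 1 - mean(ibs))
})

test_that("haplotype sampler equals exact enumeration and honors forgiveness", {
    # two identical lines: the haplotype spans the whole chromosome
    x <- sample(c(0L, 2L), 60, replace = TRUE)
    twin <- makePanel(cbind(A = x, B = x), group = c("p", "p"))
    dr <- haplotypeLengthSample(twin, "p", n_draws = 5, seed = 54)
    expect_true(all(dr$length_sites == 60))

    # alternating mismatch pattern: forgiveness rule governs short lengths
    y <- x; y[seq(2, 60, by = 2)] <- 2L - y[seq(2, 60, by = 2)]
    alt <- makePanel(cbind(A = x, B = y), group = c("p", "p"))
    dr2 <- haplotypeLengthSample(alt, "p", n_draws = 40, seed = 55)
    # matching at odd sites only; one forgiven mismatch each side lets the
    # extension reach the two flanking odd sites: length 3 (edges less)
    expect_true(all(dr2$length_sites[dr2$focal_match] <= 3))
    expect_true(any(dr2$length_sites[dr2$focal_match] == 3))

    # with forgiveness disabled the sampler equals the exact maximal
    # shared interval on small chromosomes
    set.seed(56)
    for (rep in 1:8) {
        m <- randomGeno(20, 2, p_missing = 0.15, p_het = 0.1)
        colnames(m) <- c("A", "B")
        gp <- makePanel(m, group = c("p", "p"))
        dr3 <- haplotypeLengthSample(gp, "p", n_draws = 15,
                                     forgiveness = 0, seed = 56 + rep)
        if (is.null(dr3) || !nrow(dr3)) next
        d <- gbspanel:::.hapDosage(m)
        for (r in seq_len(nrow(dr3))) {
            focal <- which(gbspanel:::.sitePos(gp) == dr3$focal_pos[r])
            want <- enumSharedInterval(d[, "A"], d[, "B"], focal)
            if (dr3$focal_match[r]) {
                expect_identical(dr3$length_sites[r], want$length_sites)
            } else {
                expect_identical(dr3$length_sites[r], 1L)
            }
        }
    }
})

test_that("planted founder blocks are recovered at their exact length", {
    bp <- simulateHaplotypeBlockPair(n_blocks = 25, block_sites = 50,
                                     gap_sites = 10, seed = 57)
    dr <- haplotypeLengthSample(bp, "pair", n_draws = 400, seed = 58)
    shared <- dr[dr$focal_match, ]
    expect_lt(abs(mean(shared$length_sites) - 50) / 50, 0.1)
    # bp lengths follow at the site spacing
    expect_equal(mean(shared$length_bp),
                 mean(shared$length_sites - 1) * 1000)
})

test_that("suppressed-recombination regions lengthen haplotypes", {
    n_sites <- 1500
    sw <- rep(0.04, n_sites - 1)
    sw[500:999] <- 0.002  # middle third: recombination suppressed
    mos <- simulateFounderMosaicPanel(n_lines = 25, n_founders = 6,
                                      n_sites = n_sites, switch_prob = sw,
                                      seed = 59)
    dr <- haplotypeLengthSample(mos, "mosaic", n_draws = 600, seed = 60)
    agg <- haplotypeLengthByWindow(dr, window_bp = 1e5)  # 100 sites/window
    mid <- agg$start > 5e5 & agg$end <= 1e6
    expect_gt(mean(agg$mean_sites[mid]), 1.5 * mean(agg$mean_sites[!mid]))
    # window correlation with the local switch (recombination) rate is
    # negative
    win_rate <- vapply(seq_len(nrow(agg)), function(i) {
        lo <- max(1, (agg$start[i] - 1) / 1000)
        hi <- min(n_sites - 1, agg$end[i] / 1000)
        mean(sw[lo:hi])
    }, 0)
    rc <- windowRankCorrelation(agg$mean_sites, win_rate)
    expect_lt(rc$rho, 0)
})

test_that("LD decay hits exact, null and monotone regimes", {
    # a duplicated SNP pair isolated at a known distance: r2 = 1 there
    set.seed(61)
    m <- vapply(1:10, function(i) sample(c(0L, 2L), 40, replace = TRUE),
                integer(40))
    m <- t(m); m[4, ] <- m[3, ]  # duplicate at 100 bp from its template
    pos <- c(1000L, 30000L, 60000L, 60100L, 90000L, 120000L, 150000L,
             180000L, 210000L, 240000L)
    gp <- makePanel(m, pos = pos)
    suppressWarnings(
        ld <- ldDecay(gp, subsample = 40, min_maf = 0.05,
                      max_distance = 1000, bins = c(0, 150, 1000)))
    expect_equal(ld$bins$mean_r2[1], 1)

    # independent sites: mean r2 at the 1/(n-1) sampling-bias level
    p0 <- simulateStructuredPanel(1, 60, 1, 600, fst_target = 0,
                                  residual_het_rate = 0, error_rate = 0,
                                  seed = 62)
    suppressWarnings(
        ld0 <- ldDecay(p0, subsample = 60, max_distance = 1e8, bins = 4,
                       seed = 63))
    overall <- sum(ld0$bins$mean_r2 * ld0$bins$n_pairs) /
        sum(ld0$bins$n_pairs)
    expect_gt(overall, 0.5 / 59)
    expect_lt(overall, 2.5 / 59)

    # founder mosaic: monotone decay, seed-reproducible, order-invariant
    mos <- simulateFounderMosaicPanel(n_lines = 40, n_founders = 6,
                                      n_sites = 700, switch_prob = 0.02,
                                      seed = 64)
    suppressWarnings({
        a <- ldDecay(mos, subsample = 40, max_distance = 2e5, bins = 6,
                     seed = 65)
        b <- ldDecay(mos, subsample = 40, max_distance = 2e5, bins = 6,
                     seed = 65)
        shuf <- mos[, sample(ncol(mos))]
        c_ <- ldDecay(shuf, subsample = 40, max_distance = 2e5, bins = 6,
                      seed = 65)
    })
    expect_identical(a$bins, b$bins)
    expect_identical(a$bins, c_$bins)
    expect_gt(a$bins$mean_r2[1], a$bins$mean_r2[nrow(a$bins)])
    expect_lt(windowRankCorrelation(a$bins$mean_r2,
                                    seq_len(nrow(a$bins)))$rho, 0)
})

test_that("window rank correlations mirror a rank-based oracle", {
    expect_equal(windowRankCorrelation(1:10, 1:10)$rho_squared, 1)
    neg <- windowRankCorrelation(1:10, -(1:10))
    expect_equal(neg$rho, -1)
    expect_equal(neg$rho_squared, 1)

    set.seed(66)
    x <- rnorm(50); y <- x + rnorm(50)
    got <- windowRankCorrelation(x, y)
    expect_equal(got$rho, cor(rank(x), rank(y)))

    expect_warning(r <- windowRankCorrelation(c(1, 2), c(3, 4)),
                   "fewer than 3")
    expect_true(is.na(r$rho))
})
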