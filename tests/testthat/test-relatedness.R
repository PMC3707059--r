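test_that("IBS identities and oracle equivalence hold", {
    # allele-sharing definition on constructed pairs
    gp <- makePanel(cbind(A = rep(0L, 10), B = rep(2L, 10),
                          C = rep(1L, 10)))
    v <- pairValues(ibsMatrix(gp))
    expect_equal(unname(diag(v)), rep(1, 3))
    expect_equal(v["A", "B"], 0)    # AA vs GG at every site
    expect_equal(v["A", "C"], 0.5)  # AA vs AG at every site
    expect_equal(v["B", "C"], 0.5)

    set.seed(40)
    m <- randomGeno(120, 10)
    got <- pairValues(ibsMatrix(makePanel(m)))
    want <- bruteIBS(m)
    expect_equal(got, want)
    expect_equal(got, t(got))

    # a sample against its differently-masked copy is IBS 1 on joint sites
    x <- m[, 1]
    x2 <- x; x2[sample(120, 40)] <- NA
    both <- makePanel(cbind(one = x, two = x2))
    expect_equal(pairValues(ibsMatrix(both))["one", "two"], 1)
})

test_that("LD pruning leaves no within-window pair above threshold", {
    set.seed(41)
    # a site duplicated 5x within a window: exactly one copy survives
    base <- sample(c(0L, 2L), 40, replace = TRUE)
    m <- sapply(1:30, function(i) sample(c(0L, 2L), 40, replace = TRUE))
    m[, 10:14] <- base
    gp <- makePanel(t(m))
    keep <- ldPrune(gp, window = 30, step = 10, r2_threshold = 0.2)
    expect_identical(sum(keep[10:14]), 1L)

    # exhaustive verification on 200-site instances
    for (rep in 1:2) {
        mos <- simulateFounderMosaicPanel(n_lines = 30, n_founders = 4,
                                          n_sites = 200,
                                          switch_prob = 0.05,
                                          seed = 41 + rep)
        keep <- ldPrune(mos, window = 50, step = 12, r2_threshold = 0.3)
        d <- gbspanel:::.hapDosage(mos)
        # exhaustively: no window instance retains a pair above threshold
        for (s in seq(1, 200, by = 12)) {
            alive <- intersect(s:min(s + 49, 200), which(keep))
            if (length(alive) < 2) next
            r2 <- suppressWarnings(cor(t(d[alive, ]),
                                       use = "pairwise.complete.obs"))^2
            expect_false(any(r2[upper.tri(r2)] > 0.3, na.rm = TRUE))
        }
    }
})

test_that("IBD pi-hat recovers duplicates, unrelated pairs and BC4 lines", {
    p <- simulateStructuredPanel(1, 40, 5, 400, fst_target = 0,
                                 residual_het_rate = 0, error_rate = 0,
                                 seed = 42)
    g <- genotypes(p)
    g <- cbind(g, DUP = g[, 1])
    # 30 BC4 derivatives of line 1 in one batch
    set.seed(43)
    bcs <- sapply(1:30, function(i)
        simulateBackcrossLine(p, "G1_L001", "G1_L002")$genotype)
    colnames(bcs) <- sprintf("BC_%02d", 1:30)
    gp <- makePanel(cbind(g, bcs),
                    chrom = as.character(seqnames(rowRanges(p))),
                    pos = start(rowRanges(p)))
    keep <- ldPrune(gp)
    ibd <- ibdEstimate(gp, sites = keep)
    v <- pairValues(ibd)
    expect_gt(v["DUP", "G1_L001"], 0.99)
    # unrelated founders: pi-hat near 0
    unrel <- v["G1_L010", sprintf("G1_L%03d", 11:40)]
    expect_lt(mean(abs(unrel)), 0.05)
    # BC4 relatives: mean pi-hat near the pedigree expectation 0.96875
    bc_v <- v[colnames(bcs), "G1_L001"]
    mc_se <- sd(bc_v) / sqrt(length(bc_v))
    expect_lt(abs(mean(bc_v) - 0.96875), 4 * mc_se + 0.005)
    expect_error(ibdEstimate(makePanel(matrix(0L, 10, 3))), "polymorphic")
})

test_that("nearest neighbors equal a brute-force sort", {
    set.seed(44)
    m <- randomGeno(100, 8, p_missing = 0.1)
    m <- cbind(m, S09 = m[, "S02"])  # duplicated pair
    ibs <- ibsMatrix(makePanel(m))
    nn <- nearestNeighbors(ibs, k = 3)
    top1 <- nn[nn$sample == "S02" & nn$rank == 1, ]
    expect_identical(top1$neighbor, "S09")

    v <- pairValues(ibs)
    for (s in colnames(m)) {
        others <- setdiff(colnames(m), s)
        o <- order(-v[s, others], others)
        expect_identical(nn$neighbor[nn$sample == s], others[o][1:3])
    }

    # k beyond the panel size lists all other samples
    all_nn <- nearestNeighbors(ibs, k = 50)
    expect_true(all(table(all_nn$sample) == ncol(m) - 1))
})

test_that("duplicate merging forms single-linkage groups and consensus calls", {
    x <- rep(c(0L, 2L), 30)
    a <- x; a[1:20] <- NA          # complementary missingness
    b <- x; b[41:60] <- NA
    c_ <- x; c_[5] <- 2L - x[5]    # one conflicting homozygote
    other <- rep(c(2L, 0L), 30)
    gp <- makePanel(cbind(a = a, b = b, c = c_, z = other))
    ibs <- ibsMatrix(gp)
    res <- mergeDuplicates(gp, ibs, threshold = 0.95)
    grp <- res$groups
    expect_identical(sort(grp$member[grp$consensus == "a"]),
                     c("a", "b", "c"))
    cons <- genotypes(res$panel)
    # union coverage from complementary missingness
    expect_false(anyNA(cons[-5, "a"]))
    expect_identical(unname(cons[2, "a"]), x[2])
    # conflicting homozygotes leave the consensus missing
    expect_true(is.na(cons[5, "a"]))
    # the unrelated line remains its own group
    expect_true("z" %in% grp$consensus)

    # cluster membership equals brute-force single linkage on random panels
    set.seed(45)
    m <- randomGeno(80, 10, p_missing = 0.3)
    ibs2 <- ibsMatrix(makePanel(m))
    got <- mergeDuplicates(makePanel(m), ibs2, threshold = 0.8)$groups
    want <- bruteSingleLinkage(pairValues(ibs2), 0.8)
    got_cl <- unname(lapply(split(got$member, got$consensus), sort))
    expect_identical(sort(vapply(got_cl, paste, "", collapse = ",")),
                     sort(vapply(want, paste, "", collapse = ",")))

    # idempotence: merging the merged panel changes nothing
    again <- mergeDuplicates(res$panel, ibsMatrix(res$panel), 0.95)
    expect_identical(dim(genotypes(again$panel)),
                     dim(genotypes(res$panel)))
})

test_that("network edges use a strict threshold and deterministic order", {
    x <- rep(c(0L, 2L), 20)
    gp <- makePanel(cbind(a = x, b = x, c = rep(0L, 40)))
    ibs <- ibsMatrix(gp)
    ed <- networkEdges(ibs, 1.0)
    expect_identical(nrow(ed), 0L)  # strict: IBS 1.0 pairs excluded at 1.0
    ed2 <- networkEdges(ibs, 0.99)
    expect_identical(ed2$sample1, "a")
    expect_identical(ed2$sample2, "b")

    set.seed(46)
    m <- randomGeno(60, 9)
    v <- pairValues(ibsMatrix(makePanel(m)))
    ed3 <- networkEdges(ibsMatrix(makePanel(m)), 0.5)
    brute <- sum(v[upper.tri(v)] > 0.5, na.rm = TRUE)
    expect_identical(nrow(ed3), brute)
})

test_that("PCoA separates known structure and satisfies the Gower identity", {
    # two clusters of mutual IBS 1, cross IBS 0.5: PCo1 separates exactly
    v <- matrix(0.5, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
    v[1:3, 1:3] <- 1; v[4:6, 4:6] <- 1
    counts <- matrix(100L, 6, 6, dimnames = dimnames(v))
    pm <- new("PairwiseMatrix", values = v, counts = counts,
              statistic = "IBS", raw = matrix(numeric(0), 0, 0))
    pc <- pcoaIBS(pm, dims = 2)
    expect_lt(max(abs(pc$points[1:3, 1] - pc$points[1, 1])), 1e-8)
    expect_lt(max(abs(pc$points[4:6, 1] - pc$points[4, 1])), 1e-8)
    expect_gt(abs(pc$points[1, 1] - pc$points[4, 1]), 0.1)

    # distances reconstructed from full-rank coordinates match the input
    set.seed(47)
    pts <- matrix(rnorm(8 * 3), 8, 3)
    D <- as.matrix(dist(pts))
    sim <- 1 - D / max(D) / 2
    dimnames(sim) <- list(paste0("s", 1:8), paste0("s", 1:8))
    pm2 <- new("PairwiseMatrix", values = sim,
               counts = matrix(1L, 8, 8, dimnames = dimnames(sim)),
               statistic = "IBS", raw = matrix(numeric(0), 0, 0))
    pc2 <- suppressWarnings(pcoaIBS(pm2, dims = 7))
    recon <- as.matrix(dist(pc2$points))
    expect_equal(recon, 1 - sim, tolerance = 1e-6,
                 ignore_attr = TRUE)

    # synthetic 3-group panel: coordinates cluster by true group
    p <- simulateStructuredPanel(3, 15, 1, 1500, fst_target = 0.15,
                                 error_rate = 0, seed = 48)
    pc3 <- pcoaIBS(ibsMatrix(p), dims = 2)
    grp <- sampleGroups(p)
    co <- pc3$points
    sil <- vapply(seq_len(nrow(co)), function(i) {
        dd <- sqrt(colSums((t(co) - co[i, ])^2))
        a <- mean(dd[grp == grp[i]][-which(names(dd[grp == grp[i]]) ==
                                           rownames(co)[i])])
        b <- min(vapply(setdiff(unique(grp), grp[i]), function(g)
            mean(dd[grp == g]), 0))
        (b - a) / max(a, b)
    }, 0)
    expect_gt(mean(sil), 0)

    # undefined pairs are refused with advice
    v_na <- v; v_na[1, 6] <- v_na[6, 1] <- NA
    pm3 <- new("PairwiseMatrix", values = v_na, counts = counts,
               statistic = "IBS", raw = matrix(numeric(0), 0, 0))
    expect_error(pcoaIBS(pm3), "undefined pairs")

    # non-metric refinement runs and reports stress
    nm <- pcoaIBS(pm2, dims = 2, method = "nonmetric")
    expect_false(is.na(nm$stress))
})

test_that("concordance rates match hand counts", {
    a <- makePanel(matrix(c(0L, 2L), 50, 2,
                          dimnames = list(NULL, c("x", "y"))))
    expect_equal(concordance(a, a)$all_calls, 0)

    g <- genotypes(a); g[3, 1] <- 2L
    b <- makePanel(g)
    cc <- concordance(a, b)
    expect_equal(cc$all_calls, 1 / 100)

    # toy grid with hets and missing: hand-counted rates
    ga <- makePanel(cbind(x = c(0L, 1L, 2L, NA, 0L),
                          y = c(2L, 0L, 1L, 0L, 0L)))
    gb <- makePanel(cbind(x = c(0L, 0L, 2L, 0L, 2L),
                          y = c(2L, 0L, 1L, NA, 0L)))
    cc2 <- concordance(ga, gb)
    # joint cells: 8; differing: (2,x) het vs hom, (5,x) -> 2
    expect_identical(cc2$n_joint, 8L)
    expect_equal(cc2$all_calls, 2 / 8)
    # het-excluded: drop (2,x) and (3,y) -> 6 cells, 1 differs
    expect_equal(cc2$het_excluded, 1 / 6)
})
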