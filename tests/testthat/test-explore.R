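test_that("PCA separates a constructed two-cluster design on PC1", {
    ## two duplicated sample groups offset by a constant on half the genes
    base <- matrix(rnorm(100 * 1, 5, 0.0), 100, 1)
    x <- cbind(a1 = base[, 1], a2 = base[, 1], a3 = base[, 1],
               b1 = base[, 1], b2 = base[, 1], b3 = base[, 1])
    x[1:50, 4:6] <- x[1:50, 4:6] + 4
    rownames(x) <- sprintf("g%d", 1:100)
    pca <- pcaSamples(x, 2)
    expect_gt(pca$varianceFraction[1], 0.999)
    pc1 <- pca$coordinates[, "PC1"]
    expect_true(all(sign(pc1[1:3]) != sign(pc1[4:6])))

    ## identical samples: zero variance everywhere
    same <- matrix(3, 10, 4, dimnames = list(sprintf("g%d", 1:10),
                                             sprintf("s%d", 1:4)))
    pca0 <- pcaSamples(same, 2)
    expect_equal(pca0$varianceFraction, c(0, 0))
    expect_error(pcaSamples(x[, 1, drop = FALSE]), "2 samples")
})

test_that("PCA coordinates match a hand eigendecomposition and gene order", {
    ## 3 samples, 2 genes: SVD of the centered sample matrix by hand
    x <- rbind(g1 = c(1, 2, 3), g2 = c(2, 2, 5))
    colnames(x) <- c("s1", "s2", "s3")
    pca <- pcaSamples(x, 2)
    cx <- t(x - rowMeans(x))
    ev <- eigen(cx %*% t(cx))
    handCoord1 <- ev$vectors[, 1] * sqrt(ev$values[1])
    expect_equal(abs(unname(pca$coordinates[, 1])), abs(handCoord1),
                 tolerance = 1e-10)
    expect_equal(pca$varianceFraction,
                 ev$values[1:2] / sum(ev$values), tolerance = 1e-10)
    ## orthogonality and variance-fraction budget
    expect_lt(abs(sum(pca$coordinates[, 1] * pca$coordinates[, 2])), 1e-8)
    expect_lte(sum(pca$varianceFraction), 1 + 1e-10)

    ## gene reordering leaves coordinates unchanged up to sign
    set.seed(6)
    y <- matrix(rnorm(60), 12, 5,
                dimnames = list(sprintf("g%d", 1:12), sprintf("s%d", 1:5)))
    p1 <- pcaSamples(y, 2)
    p2 <- pcaSamples(y[sample(12), ], 2)
    for (k in 1:2)
        expect_equal(abs(unname(p1$coordinates[, k])),
                     abs(unname(p2$coordinates[, k])), tolerance = 1e-9)
})

test_that("Pearson clustering hits exact heights and the brute-force merge order", {
    ## perfectly correlated items merge at 0; anti-correlated at 2
    x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
    rownames(x) <- sprintf("g%d", 1:4)
    hc <- pearsonCluster(x, axis = "samples")
    expect_equal(min(hc$height), 0, tolerance = 1e-12)
    expect_equal(max(hc$height), 2, tolerance = 1e-12)
    expect_true(all(diff(hc$height) >= -1e-12))  # non-decreasing merges

    ## 4-item fixture equals brute-force average-linkage enumeration
    set.seed(13)
    y <- matrix(rnorm(4 * 20), 20, 4,
                dimnames = list(NULL, c("w", "x", "y", "z")))
    hc2 <- pearsonCluster(y, axis = "samples")
    d <- 1 - cor(y[, sort(colnames(y))])
    oracle <- oracleAverageLinkage(as.dist(d))
    expect_equal(hc2$height, oracle$heights, tolerance = 1e-10)
    expect_identical(hclustMembers(hc2), oracle$members)

    ## zero-variance item is named in the error
    y2 <- cbind(y, flat = rep(1, 20))
    expect_error(pearsonCluster(y2), "flat")
})

test_that("Pearson clustering is invariant to positive affine per-item rescaling", {
    set.seed(14)
    y <- matrix(rnorm(5 * 30), 30, 5,
                dimnames = list(NULL, sprintf("s%d", 1:5)))
    hc1 <- pearsonCluster(y)
    y2 <- sweep(sweep(y, 2, runif(5, 0.2, 4), "*"), 2, rnorm(5, 0, 7), "+")
    hc2 <- pearsonCluster(y2)
    expect_equal(hc1$height, hc2$height, tolerance = 1e-10)
    expect_identical(hc1$merge, hc2$merge)
})

test_that("volcano classification gates on inclusive boundaries", {
    dge <- data.frame(gene_id = c("a", "b", "c", "d"),
                      p_adj = c(0.04, 0.04, 0.04, 0.2),
                      log2fc = c(0.6, 0.3, -0.5, 3))
    v <- volcanoClassify(dge, 0.05, 0.5)
    expect_identical(as.character(v$class), c("up", "ns", "down", "ns"))
    expect_equal(v$nUp + v$nDown + v$nNs, v$nTotal)

    empty <- volcanoClassify(dge[0, ], 0.05, 0.5)
    expect_equal(unlist(empty[c("nTotal", "nUp", "nDown", "nNs")]),
                 c(nTotal = 0L, nUp = 0L, nDown = 0L, nNs = 0L))
    expect_error(volcanoClassify(dge, 1.2, 0.5), "alpha")
    expect_error(volcanoClassify(dge, 0.05, 0), "lfcCut")
})

test_that("volcano counts are monotone in alpha and the fold-change cut", {
    set.seed(15)
    dge <- data.frame(gene_id = sprintf("g%d", 1:300),
                      p_adj = runif(300), log2fc = rnorm(300))
    alphas <- c(0.01, 0.05, 0.2)
    cuts <- c(0.25, 0.5, 1)
    for (cut in cuts) {
        ups <- vapply(alphas, function(a)
            volcanoClassify(dge, a, cut)$nUp, numeric(1))
        expect_true(all(diff(ups) >= 0))  # non-decreasing in alpha
    }
    for (a in alphas) {
        ups <- vapply(cuts, function(cut)
            volcanoClassify(dge, a, cut)$nUp, numeric(1))
        expect_true(all(diff(ups) <= 0))  # non-increasing in the cut
    }
})
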