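mkNorm <- function(nGenes, nSamples, seed = 1) {
    set.seed(seed)
    matrix(rnorm(nGenes * nSamples, 6, 2), nGenes, nSamples,
           dimnames = list(sprintf("g%d", seq_len(nGenes)),
                           sprintf("s%d", seq_len(nSamples))))
}

test_that("gene z-scores standardize each transcript across animals", {
    x <- rbind(g1 = c(1, 2, 3))
    colnames(x) <- c("s1", "s2", "s3")
    zm <- geneZScores(x, "g1")
    expect_equal(unname(zMatrix(zm)[1, ]), c(-1, 0, 1), tolerance = 1e-12)

    ## every retained row: mean 0, sd 1 within 1e-10 (also the class validity)
    y <- mkNorm(40, 12)
    zm2 <- geneZScores(y, rownames(y))
    z <- zMatrix(zm2)
    expect_true(all(abs(rowMeans(z)) < 1e-10))
    expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-10))

    ## exclusions with reasons; all-excluded is an error
    y2 <- rbind(y, flat = rep(5, 12))
    zm3 <- geneZScores(y2, c("g1", "flat", "ghost"))
    ex <- excludedGenes(zm3)
    expect_setequal(ex$gene_id, c("flat", "ghost"))
    expect_identical(ex$reason[ex$gene_id == "flat"], "zero variance")
    expect_identical(ex$reason[ex$gene_id == "ghost"], "missing")
    expect_error(geneZScores(y2, c("flat", "ghost")), "empty-signature")
})

test_that("z-scores are invariant to per-gene positive affine transforms", {
    set.seed(22)
    for (i in 1:50) {
        y <- mkNorm(10, 8, seed = i)
        a <- runif(10, 0.1, 5)
        b <- rnorm(10, 0, 10)
        z1 <- zMatrix(geneZScores(y, rownames(y)))
        z2 <- zMatrix(geneZScores(y * a + b, rownames(y)))
        expect_equal(z1, z2, tolerance = 1e-9)
    }
})

test_that("the Control-referenced z variant centers Controls only", {
    y <- mkNorm(5, 6, seed = 3)
    tr <- rep(c("Control", "Ethanol"), each = 3)
    zm <- geneZScores(y, rownames(y), zReference = "control", treatment = tr)
    z <- zMatrix(zm)
    expect_true(all(abs(rowMeans(z[, 1:3])) < 1e-10))
    expect_true(all(abs(apply(z[, 1:3], 1, sd) - 1) < 1e-10))
})

test_that("signature scores are the per-animal mean of gene z rows", {
    y <- mkNorm(20, 10, seed = 5)
    zm <- geneZScores(y, rownames(y))
    sc <- signatureScore(zm)
    ## brute force: loop the mean over genes per animal
    for (s in seq_len(ncol(y))) {
        acc <- 0
        for (g in rownames(y)) acc <- acc + zMatrix(zm)[g, s]
        expect_equal(unname(sc[s]), acc / nrow(y), tolerance = 1e-12)
    }
    ## single gene: scores equal that z row; r and -r cancel
    zm1 <- geneZScores(y[1, , drop = FALSE], "g1")
    expect_equal(signatureScore(zm1), zMatrix(zm1)[1, ], tolerance = 1e-12)
    r <- zMatrix(zm1)[1, ]
    mirrored <- new("ZScoreMatrix",
                    z = rbind(a = r, b = -r),
                    excluded = data.frame(gene_id = character(),
                                          reason = character(),
                                          stringsAsFactors = FALSE))
    expect_equal(unname(signatureScore(mirrored)), rep(0, 10),
                 tolerance = 1e-12)
})

test_that("compareGroups reproduces the worked two-sample statistic", {
    tr <- rep(c("Control", "Ethanol"), each = 3)
    cmp <- compareGroups(c(-1, 0, 1, 1, 2, 3), tr)
    expect_equal(cmp$tStat, 2 / sqrt(2 / 3), tolerance = 1e-12)
    expect_equal(round(cmp$tStat, 4), 2.4495)
    expect_equal(cmp$df, 4L)
    expect_equal(cmp$pValue, 2 * pt(-2 / sqrt(2 / 3), df = 4),
                 tolerance = 1e-12)
    expect_equal(cmp$pValue, 0.0705, tolerance = 1e-3)
    expect_identical(cmp$direction, "none")  # p > 0.05

    ## identical groups; swapped labels negate t and keep p
    same <- compareGroups(rep(c(1, 2, 3), 2), tr)
    expect_equal(same$tStat, 0)
    expect_equal(same$pValue, 1)
    swap <- compareGroups(c(1, 2, 3, -1, 0, 1), tr)
    expect_equal(swap$tStat, -cmp$tStat, tolerance = 1e-12)
    expect_equal(swap$pValue, cmp$pValue, tolerance = 1e-12)

    ## zero pooled variance with nonzero difference: flagged infinite t
    inf <- compareGroups(c(0, 0, 0, 1, 1, 1), tr)
    expect_true(inf$infinite)
    expect_identical(inf$tStat, Inf)
    expect_gt(inf$pValue, 0)
    expect_error(compareGroups(c(1, 2, 3), c("Control", "Control",
                                             "Ethanol")), ">= 2")
})

test_that("compareGroups equals the textbook implementation on random inputs", {
    set.seed(41)
    for (i in 1:200) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        xC <- rnorm(n1); xE <- rnorm(n2, 0.5)
        cmp <- compareGroups(c(xC, xE),
                             c(rep("Control", n1), rep("Ethanol", n2)))
        oracle <- oracleStudentT(xC, xE)
        expect_equal(cmp$tStat, oracle$t, tolerance = 1e-10)
        expect_equal(cmp$pValue, oracle$p, tolerance = 1e-10)
    }
})

test_that("scoreAllSignatures chains gate, z, mean and t per signature", {
    nG <- 500
    genes <- geneUniverse(nG)
    catalog <- GeneSetCatalog(list(
        GeneSet("hit", genes[1:30], "microglia", "neurodegenerative"),
        GeneSet("empty", genes[481:500], "oligodendrocyte", "NFOL")))
    cfg <- simulationConfig(nGenes = nG, seed = 33, baselineLogMean = 4.5,
                            effects = c(hit = 1.5))
    se <- generateCounts(cfg, generateDesign(6, 3, "P5", 33), catalog)
    sef <- filterLowExpression(se)
    norm <- log2CPM(sef, tmmFactors(sef), priorCount = 0.5)
    dge <- runDGE(se)
    ss <- scoreAllSignatures(norm, catalog, dge, alpha = 0.05)
    rep <- as.data.frame(signatureReport(ss))
    rownames(rep) <- rep$signature

    ## the empty intersection is reported, not dropped, with no statistic
    expect_equal(rep["empty", "n_genes_tested"], 0L)
    expect_true(is.na(rep["empty", "t_stat"]))
    expect_identical(rep["empty", "direction"], "none")

    ## the injected signature is testable and called up in Ethanol
    expect_gt(rep["hit", "n_genes_tested"], 0L)
    expect_identical(rep["hit", "direction"], "up_in_ethanol")
    expect_identical(rep["hit", "stars"] %in% c("*", "**", "***"), TRUE)

    ## its statistic equals recomputing the chain by hand
    hit <- intersectWithDEG(catalog[["hit"]], dge, 0.05)
    sc <- signatureScore(geneZScores(norm, geneIds(hit$geneSet)))
    cmp <- compareGroups(sc, SummarizedExperiment::colData(norm)$treatment)
    expect_equal(rep["hit", "t_stat"], cmp$tStat, tolerance = 1e-12)
    expect_equal(rep["hit", "p_value"], cmp$pValue, tolerance = 1e-12)
    expect_equal(unname(animalScores(ss)["hit", ]), unname(sc),
                 tolerance = 1e-12)

    ## deterministic: identical inputs, identical outputs (no RNG anywhere)
    ss2 <- scoreAllSignatures(norm, catalog, dge, alpha = 0.05)
    expect_identical(as.data.frame(signatureReport(ss2)), as.data.frame(signatureReport(ss)))
})
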