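treat6 <- rep(c("Control", "Ethanol"), each = 3)

test_that("per-gene OLS equals hand arithmetic and brute-force group means", {
    x <- rbind(g1 = c(1, 1, 1, 3, 3, 3), g2 = c(0, 1, 2, 2, 3, 4))
    colnames(x) <- sprintf("s%d", 1:6)
    ols <- fitGeneModels(x, treat6)
    expect_equal(unname(ols$coef), c(2, 2), tolerance = 1e-12)
    expect_equal(unname(ols$sSq), c(0, 1), tolerance = 1e-12)
    expect_equal(unname(ols$dfResidual), c(4L, 4L))

    set.seed(4)
    y <- matrix(rnorm(50 * 8), 50, 8,
                dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:8)))
    tr <- rep(c("Control", "Ethanol"), each = 4)
    ols2 <- fitGeneModels(y, tr)
    for (g in 1:50)
        expect_equal(unname(ols2$coef[g]),
                     mean(y[g, tr == "Ethanol"]) - mean(y[g, tr == "Control"]),
                     tolerance = 1e-12)
    expect_error(fitGeneModels(y, c(rep("Control", 7), "Ethanol")),
                 "design error")
})

test_that("moderation recovers the prior from chi-square simulated variances", {
    ## identical variances: zero spread means infinite shrinkage, and the
    ## prior variance is the bias-corrected log-scale moment exp(mean(e))
    fitC <- estimateModeration(rep(2, 10), 4)
    expect_identical(fitC$d0, Inf)
    expect_equal(fitC$s0Sq, exp(log(2) - digamma(2) + log(2)),
                 tolerance = 1e-9)

    ## s_g^2 ~ s0^2 * chisq_d0 / d0 scaled by chisq_dg sampling noise:
    ## draw true variances from the prior, then observed ones given dg
    set.seed(77)
    d0 <- 4; s0Sq <- 1.5; dg <- 4; nG <- 10000
    trueVar <- s0Sq * d0 / rchisq(nG, df = d0)  # scaled inverse chi-square
    sSq <- trueVar * rchisq(nG, df = dg) / dg
    fit <- estimateModeration(sSq, dg)
    expect_lt(abs(fit$d0 - d0) / d0, 0.2)
    expect_lt(abs(fit$s0Sq - s0Sq) / s0Sq, 0.2)

    ## two genes, closed-form moment equations evaluated independently
    sSq2 <- c(1, exp(2))
    e <- log(sSq2) - digamma(dg / 2) + log(dg / 2)
    evar <- var(e) - trigamma(dg / 2)
    fit2 <- estimateModeration(sSq2, dg)
    if (evar > 0) {
        expect_true(is.finite(fit2$d0))
        expect_equal(trigamma(fit2$d0 / 2), evar, tolerance = 1e-8)
        expect_equal(fit2$s0Sq,
                     exp(mean(e) + digamma(fit2$d0 / 2) - log(fit2$d0 / 2)),
                     tolerance = 1e-10)
    } else {
        expect_identical(fit2$d0, Inf)
    }
    expect_error(estimateModeration(c(0, 0), 4), "degenerate-variance")
})

test_that("moderation and moderated t match the reference limma implementation", {
    skip_if_not_installed("limma")
    set.seed(9)
    x <- matrix(rnorm(500 * 6, sd = rep(sqrt(0.5 + rexp(500)), 6)), 500, 6,
                dimnames = list(sprintf("g%d", 1:500), sprintf("s%d", 1:6)))
    ols <- fitGeneModels(x, treat6)
    fit <- estimateModeration(ols$sSq, ols$dfResidual)
    mt <- moderatedT(ols$coef, ols$sSq, ols$dfResidual, fit, 3, 3)
    lf <- limma::eBayes(limma::lmFit(x, cbind(1, treat6 == "Ethanol")))
    expect_equal(fit$d0, lf$df.prior, tolerance = 1e-6)
    expect_equal(fit$s0Sq, lf$s2.prior, tolerance = 1e-8)
    expect_equal(mt$tMod, unname(lf$t[, 2]), tolerance = 1e-10)
    expect_equal(mt$pRaw, unname(lf$p.value[, 2]), tolerance = 1e-10)
})

test_that("moderated t follows its closed form and classical limits", {
    ## worked fixture: coef 2, s_g^2 = 1, d_g = 4, d0 = 4, s0^2 = 1, 3+3
    mt <- moderatedT(2, 1, 4, list(d0 = 4, s0Sq = 1), 3, 3)
    expect_equal(mt$tMod, 2 / sqrt(2 / 3), tolerance = 1e-12)
    expect_equal(mt$dfTotal, 8)
    expect_equal(mt$pRaw, 2 * pt(-2 / sqrt(2 / 3), df = 8),
                 tolerance = 1e-12)

    ## d0 = 0: exactly the classical pooled two-sample t
    set.seed(12)
    for (i in 1:25) {
        xC <- rnorm(4); xE <- rnorm(4, 1)
        ols <- fitGeneModels(rbind(g = c(xC, xE)),
                             rep(c("Control", "Ethanol"), each = 4))
        mt0 <- moderatedT(ols$coef, ols$sSq, ols$dfResidual,
                          list(d0 = 0, s0Sq = 1), 4, 4)
        oracle <- oracleStudentT(xC, xE)
        expect_equal(unname(mt0$tMod), oracle$t, tolerance = 1e-10)
        expect_equal(unname(mt0$pRaw), oracle$p, tolerance = 1e-10)
    }

    ## coef 0 -> t 0, p 1; zero variance with nonzero coef is undefined
    mtz <- moderatedT(c(0, 1), c(0, 0), 4, list(d0 = 0, s0Sq = 0), 3, 3)
    expect_equal(mtz$tMod[1], 0)
    expect_equal(mtz$pRaw[1], 1)
    expect_true(mtz$undefined[2])

    ## moderated t interpolates monotonically in d0 between classical and
    ## pooled-prior forms for fixed data
    sg <- 2; s0 <- 0.5
    ts <- vapply(c(0, 1, 4, 16, 64, 1e6),
                 function(d0) moderatedT(1, sg, 4,
                                         list(d0 = d0, s0Sq = s0), 3, 3)$tMod,
                 numeric(1))
    expect_true(all(diff(ts) > 0))  # shrinking a large s_g^2 downward
})

test_that("BH adjustment equals the literal step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03),
                 tolerance = 1e-12)
    expect_equal(bhAdjust(0.42), 0.42)
    set.seed(31)
    for (i in 1:20) {
        p <- runif(sample(5:100, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, oracleBH(p), tolerance = 1e-12)
        expect_true(all(adj >= p & adj <= 1))
        ## invariant under permutation of input order
        perm <- sample(length(p))
        expect_equal(bhAdjust(p[perm]), adj[perm], tolerance = 1e-12)
    }
    expect_error(bhAdjust(c(0.5, 0)), "validation")
    expect_error(bhAdjust(c(0.5, 1.2)), "validation")
})

test_that("runDGE recovers injected effects and is deterministic", {
    catalog <- GeneSetCatalog(list(GeneSet("s1", geneUniverse(2000)[1:50],
                                           "microglia", "neurodegenerative")))
    cfg <- simulationConfig(nGenes = 2000, seed = 19, baselineLogMean = 4,
                            effects = c(s1 = 1))
    se <- generateCounts(cfg, generateDesign(6, 3, "P5", 19), catalog)
    tab1 <- runDGE(se)
    tab2 <- runDGE(se)
    expect_identical(as.data.frame(tab1), as.data.frame(tab2))

    inj <- tab1$gene_id %in% geneUniverse(2000)[1:50]
    expect_lt(abs(mean(tab1$log2fc[inj]) - 1), 0.2)
    expect_true(all(tab1$p_adj >= tab1$p_raw))
    ## p_adj monotone non-decreasing in p_raw rank order
    o <- order(tab1$p_raw)
    expect_true(all(diff(tab1$p_adj[o]) >= -1e-15))
    expect_error(runDGE(se[, 1:6]), "both treatments")
})
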