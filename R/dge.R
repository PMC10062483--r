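#' Per-gene two-group ordinary least squares
#'
#' Fits, for each gene, the model log2-CPM ~ intercept + treatment with the
#' Ethanol - Control contrast, by closed-form OLS (group means). Sexes are
#' pooled with no covariate and litter is not modelled.
#'
#' @param norm log2-CPM matrix (genes x samples) or SE with a `logCPM`
#'   assay.
#' @param treatment character/factor of `"Control"`/`"Ethanol"` per sample
#'   (taken from `colData(norm)$treatment` when omitted).
#' @return list with numeric vectors `coef` (Ethanol - Control), `sSq`
#'   (residual variance), `dfResidual` (n - 2), and `meanExpr`.
#' @examples
#' x <- rbind(g1 = c(1, 1, 1, 3, 3, 3))
#' colnames(x) <- sprintf("s%d", 1:6)
#' fitGeneModels(x, rep(c("Control", "Ethanol"), each = 3))$coef
#' @export
fitGeneModels <- function(norm, treatment = NULL) {
    if (is(norm, "SummarizedExperiment")) {
        if (is.null(treatment)) treatment <- colData(norm)$treatment
        norm <- assay(norm, "logCPM")
    }
    stopIf(is.null(treatment), "treatment labels are required")
    stopIf(!all(treatment %in% c("Control", "Ethanol")),
           "treatment must be Control or Ethanol")
    isE <- treatment == "Ethanol"
    n1 <- sum(!isE)
    n2 <- sum(isE)
    stopIf(n1 < 2L || n2 < 2L, "design error: each group needs >= 2 samples")
    mC <- rowMeans(norm[, !isE, drop = FALSE])
    mE <- rowMeans(norm[, isE, drop = FALSE])
    rss <- rowSums((norm[, !isE, drop = FALSE] - mC)^2) +
        rowSums((norm[, isE, drop = FALSE] - mE)^2)
    df <- n1 + n2 - 2L
    list(coef = mE - mC, sSq = rss / df,
         dfResidual = rep(df, nrow(norm)), meanExpr = rowMeans(norm),
         n1 = n1, n2 = n2)
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits the scaled inverse-chi-square prior s0^2 * chisq_d0 / d0 to the
#' observed residual variances by method of moments on
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`: the prior degrees of
#' freedom d0 solve `trigamma(d0/2) = var(e) - trigamma(d_g/2)` by
#' monotone bisection, and `s0^2 = exp(mean(e) + digamma(d0/2) -
#' log(d0/2))`. When the observed spread does not exceed the sampling
#' spread (`var(e) <= trigamma(d_g/2)`), d0 is infinite and
#' `s0^2 = exp(mean(e))`.
#'
#' Genes with zero residual variance are excluded from the moment
#' estimation (log of zero is undefined); at least two positive variances
#' are required.
#'
#' @param sSq per-gene residual variances.
#' @param dfResidual residual degrees of freedom (scalar or per-gene; must
#'   be constant across genes).
#' @return list with `d0` (prior df, possibly `Inf`) and `s0Sq` (prior
#'   variance).
#' @examples
#' estimateModeration(rep(2, 10), 4)  # zero spread: d0 = Inf, s0Sq = 2
#' @export
estimateModeration <- function(sSq, dfResidual) {
    dg <- unique(dfResidual)
    stopIf(length(dg) != 1L,
           "dfResidual must be constant across genes in this design")
    stopIf(dg <= 0, "residual degrees of freedom must be positive")
    pos <- sSq > 0
    stopIf(sum(pos) < 2L,
           "degenerate-variance: need >= 2 genes with positive residual variance")
    e <- log(sSq[pos]) - digamma(dg / 2) + log(dg / 2)
    meanE <- mean(e)
    evar <- stats::var(e) - trigamma(dg / 2)
    if (!is.finite(evar) || evar <= 0)
        return(list(d0 = Inf, s0Sq = exp(meanE)))
    ## trigamma is strictly decreasing: bisect for x = d0/2 on (1e-8, 1e8)
    lo <- 1e-8
    hi <- 1e8
    if (trigamma(lo) < evar) return(list(d0 = 2 * lo, s0Sq = s0From(meanE, lo)))
    if (trigamma(hi) > evar) return(list(d0 = Inf, s0Sq = exp(meanE)))
    for (i in seq_len(200L)) {
        mid <- sqrt(lo * hi)
        if (trigamma(mid) > evar) lo <- mid else hi <- mid
        if ((hi - lo) / hi < 1e-10) break
    }
    x <- (lo + hi) / 2
    list(d0 = 2 * x, s0Sq = s0From(meanE, x))
}

s0From <- function(meanE, x) exp(meanE + digamma(x) - log(x))

#' Moderated t-statistics
#'
#' Shrinks each gene's residual variance toward the prior,
#' `s_tilde^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` (the limit `s0^2`
#' when d0 is infinite), and tests the group-difference coefficient with
#' `t = coef / (s_tilde * sqrt(1/n1 + 1/n2))` on `d0 + d_g` degrees of
#' freedom (normal tail when d0 is infinite). With d0 = 0 this is exactly
#' the classical pooled two-sample t.
#'
#' Genes with `s_tilde = 0` have no defined statistic; they are returned
#' with `NA` and flagged in the `undefined` element, never given p = 0.
#'
#' @param coef,sSq,dfResidual per-gene OLS output from [fitGeneModels()].
#' @param fit moderation fit from [estimateModeration()] (list with `d0`,
#'   `s0Sq`).
#' @param n1,n2 group sizes defining the coefficient variance
#'   `1/n1 + 1/n2`.
#' @return list with vectors `tMod`, `pRaw`, `dfTotal`, and logical
#'   `undefined`.
#' @examples
#' moderatedT(coef = 2, sSq = 1, dfResidual = 4,
#'            fit = list(d0 = 4, s0Sq = 1), n1 = 3, n2 = 3)
#' @export
moderatedT <- function(coef, sSq, dfResidual, fit, n1, n2) {
    stopIf(is.null(fit$d0) || is.null(fit$s0Sq) || fit$d0 < 0 ||
           (is.finite(fit$d0) && fit$d0 > 0 && fit$s0Sq <= 0),
           "invalid moderation fit")
    d0 <- fit$d0
    v <- 1 / n1 + 1 / n2
    sTildeSq <- if (is.infinite(d0)) rep(fit$s0Sq, length(sSq))
                else (d0 * fit$s0Sq + dfResidual * sSq) / (d0 + dfResidual)
    undefined <- sTildeSq <= 0
    tMod <- rep(NA_real_, length(coef))
    pRaw <- rep(NA_real_, length(coef))
    dfTotal <- d0 + dfResidual
    ok <- !undefined
    tMod[ok] <- coef[ok] / sqrt(sTildeSq[ok] * v)
    if (is.infinite(d0)) {
        pRaw[ok] <- 2 * stats::pnorm(-abs(tMod[ok]))
    } else {
        pRaw[ok] <- 2 * stats::pt(-abs(tMod[ok]), df = dfTotal[ok])
    }
    ## keep p in (0, 1]: extreme statistics may underflow the t tail
    pRaw[ok] <- pmax(pmin(pRaw[ok], 1), .Machine$double.xmin)
    ## a zero difference on zero spread is a defined, null result
    zeroBoth <- undefined & coef == 0
    tMod[zeroBoth] <- 0
    pRaw[zeroBoth] <- 1
    undefined[zeroBoth] <- FALSE
    list(tMod = tMod, pRaw = pRaw,
         dfTotal = if (length(dfTotal) == 1L)
                       rep(dfTotal, length(coef)) else dfTotal,
         undefined = undefined)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via `stats::p.adjust`, method
#' `"BH"`), after validating that every p lies in (0, 1].
#'
#' @param p raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(p) {
    stopIf(length(p) == 0L, "no p-values supplied")
    stopIf(any(!is.finite(p)) || any(p <= 0) || any(p > 1),
           "validation error: p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Differential expression for one timepoint
#'
#' The full count-to-table chain for an Ethanol vs Control contrast at one
#' timepoint: low-expression filter, TMM factors, log2-CPM (prior 0.5 by
#' default), per-gene OLS, empirical-Bayes moderation, moderated t, and
#' Benjamini-Hochberg adjustment. Genes whose moderated variance is exactly
#' zero are excluded from the table and listed in
#' `attr(result, "excluded_genes")`.
#'
#' @param se `SummarizedExperiment` with assay `counts` and `colData`
#'   columns `treatment` and `timepoint`.
#' @param timepoint which timepoint to analyse (required when the object
#'   carries more than one).
#' @param minCpm,minSamples filter parameters, see [filterLowExpression()].
#' @param priorCount prior count for the log2-CPM transform.
#' @return `DataFrame` with columns `gene_id`, `log2fc`, `t_mod`, `p_raw`,
#'   `p_adj`, `mean_expr`, `df_total`; moderation parameters in
#'   `metadata()`-style attributes `d0` and `s0Sq`.
#' @examples
#' cfg <- simulationConfig(nGenes = 300, seed = 4)
#' se <- generateCounts(cfg, generateDesign(6, 3, "P5", 4))
#' head(runDGE(se))
#' @export
runDGE <- function(se, timepoint = NULL, minCpm = NULL, minSamples = NULL,
                   priorCount = 0.5) {
    stopifnot(is(se, "SummarizedExperiment"))
    cd <- colData(se)
    if (!is.null(timepoint)) {
        se <- se[, cd$timepoint == timepoint]
        cd <- colData(se)
    } else {
        stopIf(length(unique(cd$timepoint)) > 1L,
               "object spans several timepoints; pass `timepoint=`")
    }
    stopIf(!all(c("Control", "Ethanol") %in% cd$treatment),
           "both treatments must be present")
    se <- filterLowExpression(se, minCpm, minSamples)
    f <- tmmFactors(se)
    se <- log2CPM(se, factors = f, priorCount = priorCount)
    ols <- fitGeneModels(se)
    fit <- estimateModeration(ols$sSq, ols$dfResidual)
    mt <- moderatedT(ols$coef, ols$sSq, ols$dfResidual, fit, ols$n1, ols$n2)
    ok <- !mt$undefined
    tab <- DataFrame(gene_id = rownames(se)[ok],
                     log2fc = unname(ols$coef[ok]),
                     t_mod = mt$tMod[ok],
                     p_raw = mt$pRaw[ok],
                     p_adj = bhAdjust(mt$pRaw[ok]),
                     mean_expr = unname(ols$meanExpr[ok]),
                     df_total = mt$dfTotal[ok])
    attr(tab, "excluded_genes") <- rownames(se)[!ok]
    attr(tab, "d0") <- fit$d0
    attr(tab, "s0Sq") <- fit$s0Sq
    attr(tab, "norm_factors") <- f
    tab
}
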