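#' Per-transcript z-scores per animal
#'
#' For each transcript of interest, standardizes its log2-CPM across all
#' animals of the timepoint: `z_s = (x_s - mean(x)) / sd(x)` with the
#' sample standard deviation (denominator n-1). By default both treatment
#' groups are pooled in the reference (`zReference = "all"`); with
#' `"control"` the mean and sd come from Control animals only, so Ethanol
#' z-scores are expressed in Control units.
#'
#' Genes absent from the matrix are excluded with reason `"missing"`,
#' zero-variance genes with reason `"zero variance"`.
#'
#' @param norm log2-CPM matrix (genes x samples) or SE with a `logCPM`
#'   assay, restricted to one timepoint.
#' @param geneList character vector of transcripts to score.
#' @param zReference `"all"` (default) or `"control"`; `"control"` needs a
#'   `treatment` vector.
#' @param treatment per-sample treatment labels (taken from `colData` for
#'   SE input); only used for `zReference = "control"`.
#' @return A [ZScoreMatrix-class].
#' @examples
#' x <- rbind(g1 = c(1, 2, 3))
#' colnames(x) <- c("s1", "s2", "s3")
#' zMatrix(geneZScores(x, "g1"))  # -1, 0, 1
#' @export
geneZScores <- function(norm, geneList, zReference = c("all", "control"),
                        treatment = NULL) {
    zReference <- match.arg(zReference)
    if (is(norm, "SummarizedExperiment")) {
        if (is.null(treatment)) treatment <- colData(norm)$treatment
        norm <- assay(norm, "logCPM")
    }
    stopIf(length(geneList) == 0L, "empty-signature: gene list is empty")
    stopIf(anyDuplicated(geneList) > 0, "gene list contains duplicates")
    present <- geneList %in% rownames(norm)
    excl <- data.frame(gene_id = geneList[!present],
                       reason = rep("missing", sum(!present)),
                       stringsAsFactors = FALSE)
    x <- norm[geneList[present], , drop = FALSE]
    if (zReference == "control") {
        stopIf(is.null(treatment), "zReference='control' needs treatment labels")
        refIdx <- treatment == "Control"
        stopIf(sum(refIdx) < 2L, "need >= 2 Control animals for the reference")
    } else {
        refIdx <- rep(TRUE, ncol(x))
    }
    mu <- rowMeans(x[, refIdx, drop = FALSE])
    sd <- apply(x[, refIdx, drop = FALSE], 1L, stats::sd)
    flat <- sd == 0
    if (any(flat))
        excl <- rbind(excl, data.frame(gene_id = rownames(x)[flat],
                                       reason = "zero variance",
                                       stringsAsFactors = FALSE))
    x <- x[!flat, , drop = FALSE]
    stopIf(nrow(x) == 0L,
           "empty-signature: all genes excluded (%s)",
           paste(unique(excl$reason), collapse = ", "))
    z <- (x - mu[!flat]) / sd[!flat]
    new("ZScoreMatrix", z = z, excluded = excl, reference = zReference)
}

#' Average z-score per animal
#'
#' The signature score: the unweighted arithmetic mean of the per-transcript
#' z-scores down the gene axis, yielding one value per animal.
#'
#' @param zm a [ZScoreMatrix-class].
#' @return named numeric vector, one score per sample.
#' @export
signatureScore <- function(zm) {
    stopifnot(is(zm, "ZScoreMatrix"))
    stopIf(nrow(zm@z) == 0L, "empty-signature: no retained genes")
    colMeans(zm@z)
}

#' Two-group comparison of signature scores
#'
#' Classical two-sample pooled-variance Student's t-test, two-sided,
#' oriented Ethanol - Control, on `n1 + n2 - 2` degrees of freedom. The
#' direction is called from the sign of the mean difference when p falls
#' below `alpha`, else `"none"`. A zero pooled variance with a nonzero
#' difference yields an infinite t flagged via `infinite = TRUE`, with p
#' reported as the smallest positive double rather than 0.
#'
#' @param scores named numeric vector of per-animal scores.
#' @param treatment `"Control"`/`"Ethanol"` per animal, aligned with
#'   `scores`.
#' @param alpha significance level used only to call the direction.
#' @return list with `tStat`, `pValue`, `df`, `direction`, `meanDiff`,
#'   `infinite`.
#' @examples
#' compareGroups(c(-1, 0, 1, 1, 2, 3),
#'               rep(c("Control", "Ethanol"), each = 3))
#' @export
compareGroups <- function(scores, treatment, alpha = 0.05) {
    stopIf(length(scores) != length(treatment),
           "scores and treatment lengths differ")
    stopIf(!all(treatment %in% c("Control", "Ethanol")),
           "treatment must be Control or Ethanol")
    xC <- scores[treatment == "Control"]
    xE <- scores[treatment == "Ethanol"]
    n1 <- length(xC)
    n2 <- length(xE)
    stopIf(n1 < 2L || n2 < 2L, "each group needs >= 2 animals")
    df <- n1 + n2 - 2L
    meanDiff <- mean(xE) - mean(xC)
    pooledVar <- (sum((xC - mean(xC))^2) + sum((xE - mean(xE))^2)) / df
    infinite <- FALSE
    if (pooledVar == 0) {
        if (meanDiff == 0) {
            tStat <- 0
            pValue <- 1
        } else {
            tStat <- sign(meanDiff) * Inf
            pValue <- .Machine$double.xmin
            infinite <- TRUE
        }
    } else {
        tStat <- meanDiff / sqrt(pooledVar * (1 / n1 + 1 / n2))
        pValue <- max(2 * stats::pt(-abs(tStat), df = df),
                      .Machine$double.xmin)
    }
    direction <- "none"
    if (pValue < alpha)
        direction <- if (meanDiff > 0) "up_in_ethanol" else "down_in_ethanol"
    list(tStat = unname(tStat), pValue = unname(pValue), df = df,
         direction = direction, meanDiff = unname(meanDiff),
         infinite = infinite)
}

significanceStars <- function(p) {
    if (is.na(p)) return("")
    if (p < 0.001) return("***")
    if (p < 0.01) return("**")
    if (p < 0.05) return("*")
    ""
}

#' Score every catalog signature
#'
#' The full signature chain for one timepoint: each phenotype gene set is
#' first restricted to the transcripts significant in the
#' differential-expression table (adjusted p < `alpha`), the survivors are
#' z-scored across animals, averaged per animal, and the groups compared by
#' two-tailed Student's t-test. Signatures whose intersection is empty are
#' reported with `n_genes_tested = 0` and no statistic (they cannot be
#' analysed), mirroring how empty stage-specific oligodendrocyte sets are
#' handled in practice.
#'
#' @param norm SE with a `logCPM` assay (one timepoint) or log2-CPM matrix.
#' @param catalog a [GeneSetCatalog-class].
#' @param dge DGE table from [runDGE()] (needs `gene_id`, `p_adj`).
#' @param treatment per-sample treatment labels (from `colData` for SE
#'   input).
#' @param alpha significance gate for both the DE intersection and the
#'   direction call.
#' @param zReference `"all"` or `"control"`, see [geneZScores()].
#' @return A [SignatureScores-class].
#' @export
scoreAllSignatures <- function(norm, catalog, dge, treatment = NULL,
                               alpha = 0.05,
                               zReference = c("all", "control")) {
    zReference <- match.arg(zReference)
    stopifnot(is(catalog, "GeneSetCatalog"))
    if (is(norm, "SummarizedExperiment")) {
        if (is.null(treatment)) treatment <- colData(norm)$treatment
        normMat <- assay(norm, "logCPM")
    } else normMat <- norm
    stopIf(is.null(treatment), "treatment labels are required")
    sampleIds <- colnames(normMat)
    rows <- list()
    scores <- matrix(NA_real_, nrow = length(catalog), ncol = ncol(normMat),
                     dimnames = list(names(catalog), sampleIds))
    for (nm in names(catalog)) {
        set <- catalog[[nm]]
        hit <- intersectWithDEG(set, dge, alpha)
        nMissingDE <- hit$nGenesMissing
        if (hit$isEmpty) {
            rows[[nm]] <- data.frame(
                signature = nm, cell_type = set@cellType,
                phenotype = set@phenotype, n_genes_tested = 0L,
                n_genes_missing = nMissingDE, t_stat = NA_real_,
                p_value = NA_real_, direction = "none", stars = "",
                stringsAsFactors = FALSE)
            next
        }
        zm <- geneZScores(normMat, geneIds(hit$geneSet),
                          zReference = zReference, treatment = treatment)
        sc <- signatureScore(zm)
        cmp <- compareGroups(sc, treatment, alpha)
        scores[nm, ] <- sc
        rows[[nm]] <- data.frame(
            signature = nm, cell_type = set@cellType,
            phenotype = set@phenotype, n_genes_tested = nrow(zMatrix(zm)),
            n_genes_missing = nMissingDE + nrow(excludedGenes(zm)),
            t_stat = cmp$tStat, p_value = cmp$pValue,
            direction = cmp$direction, stars = significanceStars(cmp$pValue),
            stringsAsFactors = FALSE)
    }
    report <- DataFrame(do.call(rbind, rows))
    rownames(report) <- NULL
    new("SignatureScores", report = report, scores = scores)
}

#' Write signature results to TSV
#'
#' Writes the per-signature report plus a long-format per-animal score
#' table (`signature`, `sample_id`, `treatment`, `avg_z`).
#'
#' @param ss a [SignatureScores-class].
#' @param reportPath,scoresPath output paths.
#' @param treatment optional per-sample treatment labels for the long
#'   table.
#' @return named character vector of the paths, invisibly.
#' @export
writeSignatureScores <- function(ss, reportPath, scoresPath,
                                 treatment = NULL) {
    stopifnot(is(ss, "SignatureScores"))
    writeTsv(as.data.frame(signatureReport(ss)), reportPath)
    sc <- animalScores(ss)
    long <- data.frame(
        signature = rep(rownames(sc), each = ncol(sc)),
        sample_id = rep(colnames(sc), times = nrow(sc)),
        treatment = if (is.null(treatment)) NA_character_
                    else rep(treatment, times = nrow(sc)),
        avg_z = as.vector(t(sc)), stringsAsFactors = FALSE)
    long <- long[!is.na(long$avg_z), , drop = FALSE]
    writeTsv(long, scoresPath)
    invisible(c(report = reportPath, scores = scoresPath))
}
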