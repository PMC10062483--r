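#' Sample-level principal component analysis
#'
#' Centers each gene (row mean removed) and projects samples by singular
#' value decomposition, the standard ordination for inspecting
#' treatment/sex separation of expression libraries. Sign convention: each
#' component is flipped so that its largest-magnitude gene loading is
#' positive, making outputs deterministic.
#'
#' @param norm log2-CPM matrix (genes x samples) or SE with a `logCPM`
#'   assay.
#' @param nComponents number of components, at most
#'   `min(n_samples - 1, n_genes)`.
#' @return list with `coordinates` (samples x components, columns
#'   `PC1..PCk`), `varianceFraction` (per component, of the total variance
#'   across all components), and `loadings` (genes x components).
#' @export
pcaSamples <- function(norm, nComponents = 2L) {
    if (is(norm, "SummarizedExperiment")) norm <- assay(norm, "logCPM")
    nS <- ncol(norm)
    stopIf(nS < 2L, "PCA needs at least 2 samples")
    kmax <- min(nS - 1L, nrow(norm))
    stopIf(nComponents < 1L || nComponents > kmax,
           "nComponents must be between 1 and %d", kmax)
    centered <- norm - rowMeans(norm)
    sv <- svd(t(centered), nu = kmax, nv = kmax)
    d <- sv$d[seq_len(kmax)]
    totalVar <- sum(sv$d^2)
    k <- seq_len(nComponents)
    u <- sv$u[, k, drop = FALSE]
    v <- sv$v[, k, drop = FALSE]
    ## deterministic sign: largest |loading| positive per component
    for (j in k) {
        i <- which.max(abs(v[, j]))
        if (v[i, j] < 0) {
            v[, j] <- -v[, j]
            u[, j] <- -u[, j]
        }
    }
    coords <- sweep(u, 2L, d[k], "*")
    dimnames(coords) <- list(colnames(norm), paste0("PC", k))
    dimnames(v) <- list(rownames(norm), paste0("PC", k))
    list(coordinates = coords,
         varianceFraction = if (totalVar > 0) d[k]^2 / totalVar
                            else rep(0, nComponents),
         loadings = v)
}

#' Hierarchical clustering on Pearson-correlation distance
#'
#' Pairwise distance `1 - Pearson r` with average-linkage agglomeration
#' (via `stats::hclust`). Items are pre-sorted lexicographically by id so
#' ties resolve by label order, making the merge sequence deterministic.
#'
#' @param mat numeric matrix or SE with a `logCPM` assay.
#' @param axis cluster `"samples"` (columns, default) or `"genes"` (rows).
#' @return an `hclust` object (fields `merge`, `height`, `labels`).
#' @export
pearsonCluster <- function(mat, axis = c("samples", "genes")) {
    axis <- match.arg(axis)
    if (is(mat, "SummarizedExperiment")) mat <- assay(mat, "logCPM")
    x <- if (axis == "samples") mat else t(mat)
    stopIf(ncol(x) < 2L, "need >= 2 items to cluster")
    ids <- colnames(x)
    stopIf(is.null(ids), "items must be named")
    sds <- apply(x, 2L, stats::sd)
    stopIf(any(sds == 0), "zero-variance item(s): %s",
           paste(ids[sds == 0], collapse = ", "))
    x <- x[, order(ids), drop = FALSE]
    d <- stats::as.dist(1 - stats::cor(x))
    stats::hclust(d, method = "average")
}

#' Volcano classification counts
#'
#' Classifies each gene of a DGE table: `up` if adjusted p < `alpha` and
#' log2 fold change >= `lfcCut`; `down` if adjusted p < `alpha` and log2
#' fold change <= `-lfcCut` (boundaries inclusive); `ns` otherwise.
#'
#' @param dge DGE table with `p_adj` and `log2fc`.
#' @param alpha adjusted-p gate in (0, 1).
#' @param lfcCut positive log2-fold-change cut (default 0.5).
#' @return list with counts `nTotal`, `nUp`, `nDown`, `nNs` and the
#'   per-gene `class` factor.
#' @examples
#' volcanoClassify(data.frame(gene_id = "g", p_adj = 0.04, log2fc = 0.6))
#' @export
volcanoClassify <- function(dge, alpha = 0.05, lfcCut = 0.5) {
    stopIf(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
    stopIf(lfcCut <= 0, "lfcCut must be positive")
    dge <- as.data.frame(dge)
    cls <- rep("ns", nrow(dge))
    if (nrow(dge)) {
        sig <- dge$p_adj < alpha
        cls[sig & dge$log2fc >= lfcCut] <- "up"
        cls[sig & dge$log2fc <= -lfcCut] <- "down"
    }
    list(nTotal = nrow(dge), nUp = sum(cls == "up"),
         nDown = sum(cls == "down"), nNs = sum(cls == "ns"),
         class = factor(cls, levels = c("up", "down", "ns")))
}

#' Write exploratory summaries to TSV
#'
#' @param pca result of [pcaSamples()].
#' @param path output path. The variance fractions go into a `#`-prefixed
#'   header line above the per-sample coordinate table.
#' @return the path, invisibly.
#' @export
writePCA <- function(pca, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#variance_fraction: ",
                      paste(sprintf("%.15g", pca$varianceFraction),
                            collapse = "\t")), con)
    df <- data.frame(sample_id = rownames(pca$coordinates),
                     pca$coordinates, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writePCA
#' @param hc an `hclust` object from [pearsonCluster()]. Written as a
#'   merge-list TSV (`step`, `left`, `right`, `height`; negative entries
#'   are leaves, positive entries earlier merge steps).
#' @export
writeDendrogram <- function(hc, path) {
    df <- data.frame(step = seq_len(nrow(hc$merge)),
                     left = hc$merge[, 1L], right = hc$merge[, 2L],
                     height = sprintf("%.15g", hc$height),
                     stringsAsFactors = FALSE)
    attr(df, "labels") <- hc$labels
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#leaves: ", paste(hc$labels, collapse = "\t")), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writePCA
#' @param volcano result of [volcanoClassify()].
#' @export
writeVolcanoSummary <- function(volcano, path) {
    writeTsv(data.frame(n_total = volcano$nTotal, n_up = volcano$nUp,
                        n_down = volcano$nDown, n_ns = volcano$nNs), path)
}
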