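# Independent brute-force oracles, deliberately written loop-by-loop from
# the definitions, separate from the package's vectorized implementations.

# Trimmed-mean-of-M-values, literal recipe: reference by 75th-percentile
# CPM closest to the mean; per sample, M/A over doubly-positive genes,
# two-sided trims (30% on M, 5% on A) via sorted indices, weighted mean of
# M with inverse summed-binomial-variance weights, rescale to geometric
# mean 1.
oracleTMM <- function(counts, trimM = 0.3, trimA = 0.05) {
    N <- colSums(counts)
    q75 <- numeric(ncol(counts))
    for (s in seq_len(ncol(counts)))
        q75[s] <- quantile(counts[, s], 0.75) / N[s] * 1e6
    ref <- which.min(abs(q75 - mean(q75)))
    f <- rep(NA_real_, ncol(counts))
    for (s in seq_len(ncol(counts))) {
        if (s == ref) { f[s] <- 1; next }
        M <- c(); A <- c(); V <- c()
        for (g in seq_len(nrow(counts))) {
            y <- counts[g, s]; yr <- counts[g, ref]
            if (y > 0 && yr > 0) {
                p <- y / N[s]; pr <- yr / N[ref]
                ## the ratio form, not log2(p) - log2(pr): integer counts
                ## produce exact ties in M, and the two algebraic forms
                ## differ in the last ulp, which would break ties at the
                ## trim boundary differently
                M <- c(M, log2(p / pr))
                A <- c(A, (log2(p) + log2(pr)) / 2)
                V <- c(V, (1 - p) / (N[s] * p) + (1 - pr) / (N[ref] * pr))
            }
        }
        n <- length(M)
        lo <- floor(n * trimM) + 1; hi <- n + 1 - lo
        keepM <- rank(M) >= lo & rank(M) <= hi
        lo <- floor(n * trimA) + 1; hi <- n + 1 - lo
        keepA <- rank(A) >= lo & rank(A) <= hi
        keep <- keepM & keepA
        f[s] <- 2^(sum((M / V)[keep]) / sum((1 / V)[keep]))
    }
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(counts)
    f
}

# Literal Benjamini-Hochberg step-up: on sorted p, p_adj(i) is the minimum
# over j >= i of min(1, m * p(j) / j), mapped back to input order.
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    for (i in seq_len(m)) {
        best <- Inf
        for (j in i:m) best <- min(best, m * ps[j] / j)
        adj[i] <- min(1, best)
    }
    out <- numeric(m)
    out[o] <- adj
    out
}

# Textbook pooled-variance two-sample t (Ethanol - Control), two-sided p.
oracleStudentT <- function(xC, xE) {
    n1 <- length(xC); n2 <- length(xE)
    sp2 <- (sum((xC - mean(xC))^2) + sum((xE - mean(xE))^2)) / (n1 + n2 - 2)
    t <- (mean(xE) - mean(xC)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# Brute-force average-linkage agglomeration on a distance matrix: at each
# step merge the pair of clusters with the smallest mean pairwise distance.
# Returns merge heights and the member sets at each merge.
oracleAverageLinkage <- function(d) {
    d <- as.matrix(d)
    clusters <- as.list(seq_len(nrow(d)))
    heights <- c()
    members <- list()
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestH <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (i >= j) next
            h <- mean(d[clusters[[i]], clusters[[j]]])
            if (h < bestH) { bestH <- h; best <- c(i, j) }
        }
        merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
        clusters[[best[1]]] <- merged
        clusters[[best[2]]] <- NULL
        heights <- c(heights, bestH)
        members[[length(members) + 1L]] <- merged
    }
    list(heights = heights, members = members)
}

# Member sets at each hclust merge step, for comparison with the oracle.
hclustMembers <- function(hc) {
    out <- list()
    for (k in seq_len(nrow(hc$merge))) {
        grab <- function(x) if (x < 0) -x else out[[x]]
        out[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
    }
    out
}

# Small random count fixture with named dims.
randomCounts <- function(nGenes, nSamples, seed, mu_meanlog = 4,
                         mu_sdlog = 1.2, size = 10) {
    set.seed(seed)
    matrix(rnbinom(nGenes * nSamples, mu = rlnorm(nGenes, mu_meanlog,
                                                  mu_sdlog), size = size),
           nGenes, nSamples,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           sprintf("s%d", seq_len(nSamples))))
}

# A tiny two-timepoint simulated experiment for pipeline tests.
smallDataset <- function(dir, seed = 42L, nGenes = 400L,
                         effects = c(sigA = 1)) {
    catalog <- GeneSetCatalog(list(
        GeneSet("sigA", geneUniverse(nGenes)[1:25], "microglia",
                "neurodegenerative"),
        GeneSet("sigB", geneUniverse(nGenes)[26:45], "astrocyte",
                "acute_injury"),
        GeneSet("sigEmpty", geneUniverse(nGenes)[380:390], "cell_cycle",
                "G1S_positive")))
    cfg <- simulationConfig(nGenes = nGenes, seed = seed,
                            baselineLogMean = 4, effects = effects)
    se5 <- generateCounts(cfg, generateDesign(6, 3, "P5", seed), catalog)
    cfg2 <- simulationConfig(nGenes = nGenes, seed = seed + 1L,
                             baselineLogMean = 4, effects = effects)
    se6 <- generateCounts(cfg2, generateDesign(6, 3, "P6", seed + 1L),
                          catalog)
    se <- SummarizedExperiment::cbind(se5, se6)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeDataset(se, dir)
    writeGMT(catalog, file.path(dir, "catalog.gmt"))
    list(dir = dir, se = se, catalog = catalog, config = cfg)
}
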