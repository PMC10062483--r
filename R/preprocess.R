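#' Filter lowly expressed genes
#'
#' Keeps genes whose raw counts-per-million (library-size scaled, no TMM)
#' reach `minCpm` in at least `minSamples` samples; both bounds are
#' inclusive. The default `minCpm` corresponds to ~10 counts in the median
#' library; the default `minSamples` is the smallest treatment-group size
#' when a design is attached, else 1.
#'
#' @param se `SummarizedExperiment` with a `counts` assay, or a counts
#'   matrix.
#' @param minCpm minimum raw CPM (> 0).
#' @param minSamples minimum number of samples reaching `minCpm`.
#' @return the input restricted to retained genes (gene order preserved,
#'   samples untouched).
#' @examples
#' cfg <- simulationConfig(nGenes = 500, seed = 2)
#' se <- generateCounts(cfg, generateDesign(4, 2, "P5", 2))
#' dim(filterLowExpression(se))
#' @export
filterLowExpression <- function(se, minCpm = NULL, minSamples = NULL) {
    counts <- if (is(se, "SummarizedExperiment")) assay(se, "counts") else se
    stopIf(any(counts < 0), "counts must be non-negative")
    libSize <- colSums(counts)
    stopIf(any(libSize <= 0), "every sample needs a positive library size")
    if (is.null(minCpm))
        minCpm <- 10 / stats::median(libSize) * 1e6
    if (is.null(minSamples)) {
        minSamples <- 1L
        if (is(se, "SummarizedExperiment") &&
            "treatment" %in% colnames(colData(se)))
            minSamples <- min(table(colData(se)$treatment))
    }
    stopIf(minCpm <= 0, "minCpm must be positive")
    stopIf(minSamples < 1L || minSamples > ncol(counts),
           "minSamples must be between 1 and the number of samples")
    cpm <- sweep(counts, 2L, libSize, "/") * 1e6
    keep <- rowSums(cpm >= minCpm) >= minSamples
    stopIf(!any(keep), "empty-matrix: all genes removed by the filter")
    if (is(se, "SummarizedExperiment")) se[keep, ] else counts[keep, ,
                                                               drop = FALSE]
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample scaling factors from trimmed, precision-weighted log
#' expression ratios. The reference sample is the one whose 75th-percentile
#' CPM is closest to the mean 75th-percentile. For each other sample,
#' per-gene M (log2 ratio of library-scaled proportions against the
#' reference) and A (mean log2 proportion) are computed over genes positive
#' in both samples; the top and bottom 30% of M and 5% of A are discarded;
#' the factor is 2 to the weighted mean of the surviving M values, weighted
#' by inverse asymptotic binomial variance `(N-y)/(N*y)` summed over the
#' two samples. Factors are rescaled to geometric mean 1.
#'
#' @param counts gene x sample count matrix (or SE with a `counts` assay).
#' @param trimM,trimA two-sided trim fractions for M and A.
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @examples
#' m <- matrix(rpois(400, 50), 100, 4,
#'             dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:4)))
#' tmmFactors(m)
#' @export
tmmFactors <- function(counts, trimM = 0.3, trimA = 0.05) {
    if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
    nS <- ncol(counts)
    libSize <- colSums(counts)
    stopIf(any(libSize <= 0), "every sample needs a positive library size")
    ## reference: 75th-percentile CPM closest to the mean across samples
    q75 <- apply(counts, 2L, stats::quantile, probs = 0.75) / libSize * 1e6
    ref <- which.min(abs(q75 - mean(q75)))
    f <- rep(1, nS)
    for (s in seq_len(nS)) {
        if (s == ref) next
        f[s] <- pairTMM(counts[, s], counts[, ref], libSize[s], libSize[ref],
                        trimM, trimA,
                        sampleId = colnames(counts)[s])
    }
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(counts)
    f
}

# One sample against the reference: trimmed, precision-weighted mean M.
pairTMM <- function(y, yr, N, Nr, trimM, trimA, sampleId = "?") {
    pos <- y > 0 & yr > 0
    stopIf(!any(pos),
           "degenerate-sample: '%s' shares no positively expressed gene with the reference",
           sampleId)
    y <- y[pos]
    yr <- yr[pos]
    p <- y / N
    pr <- yr / Nr
    M <- log2(p / pr)
    A <- (log2(p) + log2(pr)) / 2
    ## asymptotic binomial variance of M, summed over the two samples;
    ## genes are weighted by its inverse (precision weighting)
    v <- (N - y) / (N * y) + (Nr - yr) / (Nr * yr)
    n <- length(M)
    loM <- floor(n * trimM) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1
    hiA <- n + 1 - loA
    rM <- rank(M)
    rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    stopIf(!any(keep), "degenerate-sample: trimming removed all genes for '%s'",
           sampleId)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Log2 counts-per-million transform
#'
#' `log2((count + priorCount) / (effectiveLibSize + 2 * priorCount) * 1e6)`
#' with effective library size = raw library size times the sample's TMM
#' factor. With `priorCount = 0`, per-sample CPM values sum exactly to
#' `1e6 / factor`; a positive prior keeps zero counts finite.
#'
#' @param se `SummarizedExperiment` with a `counts` assay, or a counts
#'   matrix.
#' @param factors per-sample normalization factors (default
#'   [tmmFactors()]).
#' @param priorCount non-negative prior count added to each observation;
#'   default 0.5.
#' @return For an SE input: the SE with an added `logCPM` assay,
#'   `colData$norm_factor` and `metadata$prior_count`. For a matrix input:
#'   the log2-CPM matrix with the factors in `attr(, "norm_factors")`.
#' @examples
#' m <- matrix(c(100L, 999900L), 2, 1,
#'             dimnames = list(c("a", "b"), "s1"))
#' log2CPM(m, factors = 1, priorCount = 0)["a", ]  # log2(100) = 6.6439
#' @export
log2CPM <- function(se, factors = NULL, priorCount = 0.5) {
    counts <- if (is(se, "SummarizedExperiment")) assay(se, "counts") else se
    if (is.null(factors)) factors <- tmmFactors(counts)
    stopIf(any(factors <= 0), "factors must be positive")
    stopIf(priorCount < 0, "priorCount must be >= 0")
    libSize <- colSums(counts)
    eff <- libSize * factors
    stopIf(any(eff + 2 * priorCount <= 0), "zero effective library size")
    vals <- log2(sweep(counts + priorCount, 2L, eff + 2 * priorCount, "/")
                 * 1e6)
    if (is(se, "SummarizedExperiment")) {
        assays(se)[["logCPM"]] <- vals
        colData(se)$norm_factor <- unname(factors)
        metadata(se)$prior_count <- priorCount
        se
    } else {
        attr(vals, "norm_factors") <- factors
        vals
    }
}

#' @importFrom SummarizedExperiment assays assays<- colData<-
NULL
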