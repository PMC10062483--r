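#' Generate a balanced two-treatment sample sheet
#'
#' Emulates the study design: within one timepoint, `nPerGroup` animals per
#' treatment (Control, Ethanol), sex-balanced within treatment, with
#' litters assigned round-robin so that every litter contributes animals to
#' both treatment groups (the classic split-litter design guarding against
#' litter confounds). With `nPerGroup = 6` and `nLitters = 3`, each litter
#' contributes one male and one female to each treatment.
#'
#' The seed only shuffles which litter label lands on which animal; the
#' balance guarantees are structural.
#'
#' @param nPerGroup animals per treatment group; must be even so sexes
#'   balance.
#' @param nLitters number of litters; recycled round-robin.
#' @param timepoint label such as `"P5"` or `"P6"`.
#' @param seed integer seed.
#' @return `data.frame` with columns `sample_id`, `treatment`, `sex`,
#'   `litter`, `timepoint`.
#' @examples
#' generateDesign(6, 3, "P5", seed = 1)
#' @export
generateDesign <- function(nPerGroup, nLitters, timepoint = "P5", seed = 1L) {
    stopIf(length(nPerGroup) != 1L || nPerGroup < 1L,
           "invalid-config: nPerGroup must be a positive integer")
    stopIf(nPerGroup %% 2L != 0L,
           "invalid-config: nPerGroup must be even (sex-balanced design)")
    stopIf(length(nLitters) != 1L || nLitters < 1L,
           "invalid-config: nLitters must be a positive integer")
    treatments <- c("Control", "Ethanol")
    litterPerm <- withSeed(seed, sample.int(nLitters))
    rows <- lapply(treatments, function(tr) {
        idx <- seq_len(nPerGroup)
        data.frame(
            sample_id = sprintf("%s_%s_%02d", timepoint,
                                ifelse(tr == "Control", "C", "E"), idx),
            treatment = tr,
            sex = rep_len(c("M", "F"), nPerGroup),
            litter = sprintf("L%d",
                             litterPerm[((idx - 1L) %% nLitters) + 1L]),
            timepoint = timepoint,
            stringsAsFactors = FALSE)
    })
    design <- do.call(rbind, rows)
    rownames(design) <- NULL
    design
}

#' Simulate a negative-binomial count experiment
#'
#' Counts for gene g in sample s are drawn NB with mean
#' `mu_gs = m_g * L_s * r_litter(s) * 2^(lfc_g * [s is Ethanol])` and
#' variance `mu + phi_g * mu^2`. Baseline means `m_g` are log-normal,
#' library factors `L_s` are log-normal, littermates share a log-normal
#' litter factor, and `lfc_g` is nonzero exactly for genes belonging to the
#' signatures named in `effects(config)`. Sex carries no built-in effect
#' and is kept as metadata only.
#'
#' @param config a [SimulationConfig-class]; its `seed` drives all draws
#'   (Mersenne-Twister, inversion normals).
#' @param design sample sheet from [generateDesign()] (any number of rows;
#'   the config's `nPerGroup`/`nLitters` are used only when `design` is
#'   omitted).
#' @param catalog optional [GeneSetCatalog-class] whose sets name the
#'   effect targets; required when `config` carries effects. All catalog
#'   genes must belong to the simulated gene universe.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `colData` = the design, and `rowData` columns `true_log2fc`
#'   and `is_null` (the ground-truth table).
#' @examples
#' cfg <- simulationConfig(nGenes = 200, seed = 3)
#' se <- generateCounts(cfg, generateDesign(4, 2, "P5", 3))
#' @export
generateCounts <- function(config, design = NULL, catalog = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    if (is.null(design))
        design <- generateDesign(config@nPerGroup, config@nLitters,
                                 seed = config@seed)
    checkDesign(design)
    nG <- config@nGenes
    nS <- nrow(design)
    geneIdsAll <- geneUniverse(nG)

    lfc <- numeric(nG)
    names(lfc) <- geneIdsAll
    if (length(config@effects)) {
        stopIf(is.null(catalog),
               "unknown-signature: effects given but no catalog supplied")
        missing <- setdiff(names(config@effects), names(catalog))
        stopIf(length(missing) > 0,
               "unknown-signature: %s not in catalog",
               paste(missing, collapse = ", "))
        for (nm in names(config@effects)) {
            g <- geneIds(catalog[[nm]])
            bad <- setdiff(g, geneIdsAll)
            stopIf(length(bad) > 0,
                   "catalog gene(s) outside the simulated universe: %s",
                   paste(utils::head(bad, 5L), collapse = ", "))
            lfc[g] <- config@effects[[nm]]
        }
    }

    isEth <- design$treatment == "Ethanol"
    litters <- sort(unique(design$litter))
    counts <- withSeed(config@seed, {
        m <- stats::rlnorm(nG, config@baselineLogMean, config@baselineLogSd)
        phi <- config@dispersionIntercept *
            stats::rlnorm(nG, 0, config@dispersionLogSd)
        L <- stats::rlnorm(nS, 0, config@libsizeLogSd)
        rLit <- stats::rlnorm(length(litters), 0, config@litterSd)
        names(rLit) <- litters
        mu <- outer(m, L * rLit[design$litter]) *
            2^(lfc %o% as.numeric(isEth))
        if (config@dispersionIntercept == 0) {
            matrix(stats::rpois(nG * nS, lambda = mu), nrow = nG)
        } else {
            matrix(stats::rnbinom(nG * nS, mu = mu, size = 1 / phi),
                   nrow = nG)
        }
    })
    dimnames(counts) <- list(geneIdsAll, design$sample_id)
    storage.mode(counts) <- "integer"
    SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(design, row.names = design$sample_id),
        rowData = DataFrame(true_log2fc = unname(lfc),
                            is_null = unname(lfc == 0),
                            row.names = geneIdsAll),
        metadata = list(config = config))
}

#' The simulated gene universe
#'
#' @param nGenes number of genes.
#' @return character vector `G00001`, `G00002`, ...
#' @export
geneUniverse <- function(nGenes) sprintf("G%05d", seq_len(nGenes))

#' Ground-truth effect table of a simulated experiment
#'
#' @param se a `SummarizedExperiment` from [generateCounts()].
#' @return `data.frame` with columns `gene_id`, `true_log2fc`, `is_null`.
#' @export
truthTable <- function(se) {
    rd <- rowData(se)
    stopIf(!all(c("true_log2fc", "is_null") %in% colnames(rd)),
           "object carries no simulation ground truth")
    data.frame(gene_id = rownames(se),
               true_log2fc = unname(rd$true_log2fc),
               is_null = unname(rd$is_null),
               row.names = NULL, stringsAsFactors = FALSE)
}

checkDesign <- function(design) {
    need <- c("sample_id", "treatment", "sex", "litter", "timepoint")
    stopIf(!is.data.frame(design) && !is(design, "DataFrame"),
           "design must be a data.frame")
    stopIf(!all(need %in% colnames(design)),
           "design is missing column(s): %s",
           paste(setdiff(need, colnames(design)), collapse = ", "))
    stopIf(anyDuplicated(design$sample_id) > 0, "sample_ids must be unique")
    stopIf(!all(design$treatment %in% c("Control", "Ethanol")),
           "treatment must be Control or Ethanol")
    stopIf(!all(design$sex %in% c("M", "F")), "sex must be M or F")
    tab <- table(design$timepoint, design$treatment)
    stopIf(any(tab < 2L),
           "each treatment needs >= 2 samples within every timepoint")
    invisible(TRUE)
}

#' Write a simulated dataset to TSV files
#'
#' Writes `counts.tsv` (first column `gene_id`, then one integer column per
#' sample), `samples.tsv` (`sample_id`, `treatment`, `sex`, `litter`,
#' `timepoint`) and `truth.tsv` (`gene_id`, `true_log2fc`, `is_null`).
#' Round-trips losslessly through [readCounts()] / [readSampleSheet()] /
#' [readTruth()].
#'
#' @param se `SummarizedExperiment` from [generateCounts()] (or any SE with
#'   a `counts` assay and a design-shaped `colData`).
#' @param outDir output directory, created if needed.
#' @return named character vector of the three paths, invisibly.
#' @export
writeDataset <- function(se, outDir) {
    design <- as.data.frame(colData(se))
    checkDesign(design)
    stopIf(!identical(design$sample_id, colnames(se)),
           "sample ids in colData and count columns disagree")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stopIf(!dir.exists(outDir), "cannot create output directory '%s'", outDir)
    paths <- c(counts = file.path(outDir, "counts.tsv"),
               samples = file.path(outDir, "samples.tsv"),
               truth = file.path(outDir, "truth.tsv"))
    writeCounts(assay(se, "counts"), paths[["counts"]])
    writeTsv(design[, c("sample_id", "treatment", "sex", "litter",
                        "timepoint")], paths[["samples"]])
    writeTsv(truthTable(se), paths[["truth"]])
    invisible(paths)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir directory holding `counts.tsv`, `samples.tsv` and (optionally)
#'   `truth.tsv`.
#' @return A `SummarizedExperiment` mirroring [generateCounts()] output.
#' @export
readDataset <- function(dir) {
    counts <- readCounts(file.path(dir, "counts.tsv"))
    design <- readSampleSheet(file.path(dir, "samples.tsv"))
    stopIf(!identical(design$sample_id, colnames(counts)),
           "sample ids in samples.tsv and counts.tsv disagree")
    rd <- NULL
    tpath <- file.path(dir, "truth.tsv")
    if (file.exists(tpath)) {
        truth <- readTruth(tpath)
        stopIf(!identical(truth$gene_id, rownames(counts)),
               "gene ids in truth.tsv and counts.tsv disagree")
        rd <- DataFrame(true_log2fc = truth$true_log2fc,
                        is_null = truth$is_null,
                        row.names = truth$gene_id)
    }
    SummarizedExperiment(assays = list(counts = counts),
                         colData = DataFrame(design,
                                             row.names = design$sample_id),
                         rowData = rd)
}
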