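.CONFIG_KEYS <- c("counts", "samples", "catalog", "outdir", "alpha",
                  "lfc_cut", "min_cpm", "min_samples", "prior_count",
                  "z_reference", "seed", "timepoints")

#' Validate a pipeline configuration
#'
#' Reads a YAML (or already-parsed list) run configuration, fills defaults,
#' and validates types, ranges and referenced paths. Unknown keys are
#' rejected by name.
#'
#' Keys: `counts`, `samples`, `catalog` (input paths), `outdir`, `alpha`
#' (default 0.05), `lfc_cut` (default 0.5), `min_cpm` / `min_samples`
#' (default: auto, see [filterLowExpression()]), `prior_count` (default
#' 0.5), `z_reference` (`all`/`control`, default `all`), `seed` (default
#' 1), `timepoints` (default: all found in the sample sheet).
#'
#' @param config path to a YAML file, or a named list.
#' @return validated, fully-defaulted named list (class `glia_run_config`).
#' @export
validateConfig <- function(config) {
    if (is.character(config)) {
        stopIf(length(config) != 1L || !file.exists(config),
               "validation: config file not found: %s", config)
        config <- yaml::read_yaml(config)
    }
    stopIf(!is.list(config), "validation: config must be a mapping")
    unknown <- setdiff(names(config), .CONFIG_KEYS)
    stopIf(length(unknown) > 0, "validation: unknown config key(s): %s",
           paste(unknown, collapse = ", "))
    for (key in c("counts", "samples", "catalog"))
        stopIf(is.null(config[[key]]), "validation: missing required key '%s'",
               key)
    defaults <- list(outdir = "gliascore_run", alpha = 0.05, lfc_cut = 0.5,
                     min_cpm = NULL, min_samples = NULL, prior_count = 0.5,
                     z_reference = "all", seed = 1L, timepoints = NULL)
    for (key in names(defaults))
        if (is.null(config[[key]])) config[key] <- defaults[key]
    for (key in c("counts", "samples", "catalog"))
        stopIf(!file.exists(config[[key]]),
               "validation: %s file not found: %s", key, config[[key]])
    stopIf(!is.numeric(config$alpha) || config$alpha <= 0 ||
           config$alpha >= 1, "validation: alpha must be in (0, 1)")
    stopIf(!is.numeric(config$lfc_cut) || config$lfc_cut <= 0,
           "validation: lfc_cut must be positive")
    stopIf(!is.null(config$min_cpm) && config$min_cpm <= 0,
           "validation: min_cpm must be positive")
    stopIf(!is.null(config$min_samples) && config$min_samples < 1,
           "validation: min_samples must be >= 1")
    stopIf(config$prior_count < 0, "validation: prior_count must be >= 0")
    stopIf(!config$z_reference %in% c("all", "control"),
           "validation: z_reference must be 'all' or 'control'")
    config$seed <- as.integer(config$seed)
    structure(config, class = "glia_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, independently for each timepoint in the sample sheet:
#' low-expression filter, TMM normalization, log2-CPM, moderated-t
#' differential expression with BH adjustment, signature intersection +
#' average-z scoring + Student's t comparison, and the exploratory
#' summaries (PCA, Pearson clustering of significant genes, volcano
#' counts). Writes per-stage TSVs under `outdir/<timepoint>/` plus a
#' `manifest.json` with the config hash, package version and a checksum
#' per output file. A run is a pure function of (config, input files,
#' seed): every stage output is byte-identical on repeat; only the
#' manifest's timestamp differs.
#'
#' @param config path to a YAML config or a list, see [validateConfig()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (a list; also written as JSON).
#' @export
runPipeline <- function(config, quiet = FALSE) {
    config <- validateConfig(config)
    say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

    counts <- readCounts(config$counts)
    design <- readSampleSheet(config$samples)
    stopIf(!setequal(design$sample_id, colnames(counts)),
           "sample ids in counts and sample sheet disagree")
    counts <- counts[, design$sample_id, drop = FALSE]
    catalog <- readGMT(config$catalog)
    timepoints <- config$timepoints
    if (is.null(timepoints)) timepoints <- sort(unique(design$timepoint))

    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    stopIf(!dir.exists(config$outdir), "cannot create outdir '%s'",
           config$outdir)
    outputs <- character()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
                 call. = FALSE))
    }

    for (tp in timepoints) {
        sel <- design$timepoint == tp
        stopIf(!any(sel), "no samples for timepoint '%s'", tp)
        tpDesign <- design[sel, , drop = FALSE]
        se <- SummarizedExperiment(
            assays = list(counts = counts[, tpDesign$sample_id,
                                          drop = FALSE]),
            colData = DataFrame(tpDesign, row.names = tpDesign$sample_id))
        tpDir <- file.path(config$outdir, tp)
        dir.create(tpDir, showWarnings = FALSE, recursive = TRUE)
        say("[%s] %d genes x %d samples", tp, nrow(se), ncol(se))

        norm <- stage("preprocess", {
            seF <- filterLowExpression(se, config$min_cpm,
                                       config$min_samples)
            say("[%s] preprocess: %d genes retained", tp, nrow(seF))
            log2CPM(seF, factors = tmmFactors(seF),
                    priorCount = config$prior_count)
        })
        normPath <- file.path(tpDir, "normalized.tsv")
        writeNormalized(norm, normPath)

        dge <- stage("dge", runDGE(se, minCpm = config$min_cpm,
                                   minSamples = config$min_samples,
                                   priorCount = config$prior_count))
        nSig <- sum(dge$p_adj < config$alpha)
        say("[%s] dge: %d/%d genes at adj p < %g", tp, nSig, nrow(dge),
            config$alpha)
        dgePath <- file.path(tpDir, "dge.tsv")
        writeDGETable(dge, dgePath)

        ss <- stage("score", scoreAllSignatures(
            norm, catalog, dge, alpha = config$alpha,
            zReference = config$z_reference))
        rep <- signatureReport(ss)
        say("[%s] score: %d/%d signatures testable", tp,
            sum(rep$n_genes_tested > 0), nrow(rep))
        sigPaths <- writeSignatureScores(
            ss, file.path(tpDir, "signatures.tsv"),
            file.path(tpDir, "signature_scores.tsv"),
            treatment = colData(norm)$treatment)

        expl <- stage("explore", {
            pca <- pcaSamples(norm, nComponents = min(2L, ncol(norm) - 1L))
            sigGenes <- dge$gene_id[dge$p_adj < config$alpha]
            hc <- if (length(sigGenes) >= 2L)
                pearsonCluster(assay(norm, "logCPM")[sigGenes, ,
                                                     drop = FALSE],
                               axis = "samples") else NULL
            vol <- volcanoClassify(dge, config$alpha, config$lfc_cut)
            say("[%s] explore: volcano %d up / %d down / %d ns", tp,
                vol$nUp, vol$nDown, vol$nNs)
            list(pca = pca, hc = hc, vol = vol)
        })
        pcaPath <- file.path(tpDir, "pca.tsv")
        writePCA(expl$pca, pcaPath)
        volPath <- file.path(tpDir, "volcano.tsv")
        writeVolcanoSummary(expl$vol, volPath)
        tpOut <- c(normPath, dgePath, sigPaths, pcaPath, volPath)
        if (!is.null(expl$hc)) {
            dendPath <- file.path(tpDir, "dendrogram.tsv")
            writeDendrogram(expl$hc, dendPath)
            tpOut <- c(tpOut, dendPath)
        }
        outputs <- c(outputs, tpOut)
    }

    ## the hash identifies the analysis parameters, not where they are
    ## written: outdir is excluded
    hashCfg <- unclass(config)
    hashCfg$outdir <- NULL
    manifest <- list(
        config = unclass(config),
        config_hash = unname(tools::md5sum(writeTempJSON(hashCfg))),
        package_version = as.character(utils::packageVersion("gliaScore")),
        inputs = as.list(tools::md5sum(c(config$counts, config$samples,
                                         config$catalog))),
        outputs = as.list(tools::md5sum(sort(unname(outputs)))),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(manifest)
}

writeTempJSON <- function(x) {
    p <- tempfile(fileext = ".json")
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null")
    p
}
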