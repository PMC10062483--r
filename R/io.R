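# TSV readers/writers for the package's file dialects.

#' Read and write count matrices
#'
#' The counts TSV dialect: first column `gene_id`, remaining columns one per
#' sample, integer cells, tab-separated with a header line.
#'
#' @param path file path.
#' @return `readCounts`: integer matrix with gene ids as rownames and sample
#'   ids as colnames.
#' @export
readCounts <- function(path) {
    stopIf(!file.exists(path), "no such file: %s", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    stopIf(colnames(df)[1L] != "gene_id",
           "counts TSV must start with a 'gene_id' column")
    m <- as.matrix(df[, -1L, drop = FALSE])
    stopIf(!is.numeric(m), "counts must be numeric")
    stopIf(any(m < 0), "counts must be non-negative")
    storage.mode(m) <- "integer"
    rownames(m) <- df$gene_id
    m
}

#' @rdname readCounts
#' @param counts gene x sample matrix with dimnames.
#' @export
writeCounts <- function(counts, path) {
    stopIf(is.null(rownames(counts)) || is.null(colnames(counts)),
           "counts must carry gene and sample ids")
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    writeTsv(df, path)
}

#' Read a sample sheet TSV
#'
#' Columns: `sample_id`, `treatment` (Control/Ethanol), `sex` (M/F),
#' `litter`, `timepoint`.
#'
#' @param path file path.
#' @return validated `data.frame`.
#' @export
readSampleSheet <- function(path) {
    stopIf(!file.exists(path), "no such file: %s", path)
    design <- utils::read.delim(path, stringsAsFactors = FALSE,
                                colClasses = "character")
    checkDesign(design)
    design
}

#' Read a ground-truth effect table TSV
#'
#' Columns: `gene_id`, `true_log2fc`, `is_null`.
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
readTruth <- function(path) {
    stopIf(!file.exists(path), "no such file: %s", path)
    truth <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopIf(!all(c("gene_id", "true_log2fc", "is_null") %in% colnames(truth)),
           "truth TSV must have gene_id, true_log2fc, is_null")
    truth$is_null <- as.logical(truth$is_null)
    stopIf(!identical(truth$is_null, truth$true_log2fc == 0),
           "truth table inconsistent: is_null must equal (true_log2fc == 0)")
    truth
}

#' Write and read a normalized log2-CPM matrix
#'
#' The normalized TSV carries the per-sample TMM factors and the prior
#' count in `#norm_factors:` / `#prior_count:` comment header lines,
#' followed by the usual `gene_id` + one-column-per-sample layout.
#'
#' @param norm a `SummarizedExperiment` from [log2CPM()].
#' @param path file path.
#' @return the path, invisibly (`writeNormalized`); a
#'   `SummarizedExperiment` with assay `logCPM`, `colData$norm_factor` and
#'   `metadata$prior_count` (`readNormalized`).
#' @export
writeNormalized <- function(norm, path) {
    stopIf(!"logCPM" %in% assayNames(norm),
           "object has no 'logCPM' assay; run log2CPM() first")
    f <- colData(norm)$norm_factor
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        paste0("#norm_factors: ",
               paste(sprintf("%s=%.15g", colnames(norm), f), collapse = "\t")),
        paste0("#prior_count: ",
               sprintf("%.15g", metadata(norm)$prior_count))), con)
    vals <- assay(norm, "logCPM")
    df <- data.frame(gene_id = rownames(vals),
                     apply(vals, 2L, function(x) sprintf("%.15g", x)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeNormalized
#' @export
readNormalized <- function(path) {
    stopIf(!file.exists(path), "no such file: %s", path)
    hdr <- readLines(path, n = 2L)
    stopIf(!startsWith(hdr[1L], "#norm_factors: ") ||
           !startsWith(hdr[2L], "#prior_count: "),
           "missing #norm_factors/#prior_count header in %s", path)
    kv <- strsplit(sub("^#norm_factors: ", "", hdr[1L]), "\t")[[1L]]
    parts <- strsplit(kv, "=", fixed = TRUE)
    f <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
    names(f) <- vapply(parts, `[`, character(1), 1L)
    prior <- as.numeric(sub("^#prior_count: ", "", hdr[2L]))
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene_id
    stopIf(!identical(colnames(m), names(f)),
           "sample ids in header and columns disagree")
    SummarizedExperiment(
        assays = list(logCPM = m),
        colData = DataFrame(norm_factor = unname(f), row.names = names(f)),
        metadata = list(prior_count = prior))
}

#' Write a differential-expression table TSV
#'
#' Columns: `gene_id`, `log2fc`, `t_mod`, `p_raw`, `p_adj`, `mean_expr`,
#' `df_total`.
#'
#' @param dge a `DataFrame`/`data.frame` from [runDGE()].
#' @param path file path.
#' @export
writeDGETable <- function(dge, path) {
    writeTsv(as.data.frame(dge), path)
}

#' @rdname writeDGETable
#' @return `readDGETable`: `data.frame` with the columns above.
#' @export
readDGETable <- function(path) {
    stopIf(!file.exists(path), "no such file: %s", path)
    dge <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "log2fc", "t_mod", "p_raw", "p_adj", "mean_expr",
              "df_total")
    stopIf(!all(need %in% colnames(dge)),
           "DGE table is missing column(s): %s",
           paste(setdiff(need, colnames(dge)), collapse = ", "))
    dge
}
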