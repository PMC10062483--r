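#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set exchange format: one set per line with
#' fields `name`, `description`, then the member genes. When the
#' description matches `cell_type:phenotype` against the package's
#' controlled vocabulary it is parsed into those tags; otherwise it is kept
#' as a free-text provenance note.
#'
#' @param path GMT file path.
#' @return A [GeneSetCatalog-class].
#' @examples
#' p <- tempfile(fileext = ".gmt")
#' writeLines("mg_homeo\tmicroglia:homeostatic\tP2ry12\tTmem119", p)
#' readGMT(p)
#' @export
readGMT <- function(path) {
    stopIf(!file.exists(path), "no such file: %s", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list()
    prov <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        stopIf(length(f) < 3L,
               "GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
               i, length(f))
        nm <- f[1L]
        stopIf(nm %in% names(sets), "duplicate set name '%s' at line %d",
               nm, i)
        desc <- f[2L]
        genes <- f[-(1:2)]
        ct <- NA_character_
        ph <- NA_character_
        m <- regmatches(desc, regexec("^([a-z_]+):([A-Za-z0-9_]+)$", desc))[[1L]]
        if (length(m) == 3L && m[2L] %in% names(.PHENOTYPES) &&
            m[3L] %in% .PHENOTYPES[[m[2L]]]) {
            ct <- m[2L]
            ph <- m[3L]
        } else if (nzchar(desc)) {
            prov[nm] <- desc
        }
        sets[[nm]] <- GeneSet(nm, genes, ct, ph)
    }
    GeneSetCatalog(sets, prov)
}

#' Write a catalog to GMT
#'
#' Emits canonical GMT: one tab-separated line per set (name, description,
#' genes) with a trailing newline. The description is
#' `cell_type:phenotype` when both tags are set, else the provenance note.
#' Names and gene ids containing tabs are rejected (they would corrupt the
#' format).
#'
#' @param catalog a [GeneSetCatalog-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGMT <- function(catalog, path) {
    stopifnot(is(catalog, "GeneSetCatalog"))
    validObject(catalog)
    lines <- vapply(geneSets(catalog), function(s) {
        fields <- c(s@name, gmtDescription(s, catalog), s@genes)
        stopIf(any(grepl("\t", fields, fixed = TRUE)),
               "set '%s' contains a tab character; not representable in GMT",
               s@name)
        paste(fields, collapse = "\t")
    }, character(1))
    con <- file(path, "w")
    on.exit(close(con))
    if (length(lines)) writeLines(unname(lines), con)
    invisible(path)
}

gmtDescription <- function(s, catalog) {
    if (!is.na(s@cellType) && !is.na(s@phenotype))
        return(paste0(s@cellType, ":", s@phenotype))
    if (s@name %in% names(catalog@provenance))
        return(catalog@provenance[[s@name]])
    "na"
}

#' Deterministic synthetic phenotype catalog
#'
#' Builds a stand-in catalog with the size structure of curated cerebellar
#' glial signature collections: 822 microglia-associated genes split into
#' homeostatic and neurodegenerative phenotypes (roughly 40/60), 309
#' astrocyte-associated genes across acute-injury, chronic-neurodegenerative
#' and pan-injury phenotypes (the pan-injury set deliberately overlaps the
#' acute and chronic sets), 799 oligodendrocyte-lineage genes across the
#' OPC/COP/NFOL/MFOL/MOL maturation stages, and four 50-gene cell-cycle
#' sets (positive/negative regulation of the G1-S and G2-M transitions).
#' Member genes are drawn without replacement from the synthetic gene
#' universe; the gene memberships are synthetic, only the set sizes mirror
#' real curated collections.
#'
#' @param seed integer seed.
#' @param nGenes size of the gene universe to draw from (>= 2130).
#' @return A [GeneSetCatalog-class] with 14 sets.
#' @examples
#' cat14 <- fixtureCatalog(seed = 1)
#' sum(lengths(lapply(geneSets(cat14)[1:2], geneIds)))  # 822 microglia genes
#' @export
fixtureCatalog <- function(seed = 1L, nGenes = 19595L) {
    sizes <- list(
        microglia = c(homeostatic = 329L, neurodegenerative = 493L),  # 822
        astrocyte = c(acute_injury = 124L,
                      chronic_neurodegenerative = 124L,
                      pan_injury = 61L),                              # 309
        oligodendrocyte = c(OPC = 250L, COP = 150L, NFOL = 133L,
                            MFOL = 133L, MOL = 133L),                 # 799
        cell_cycle = c(G1S_positive = 50L, G1S_negative = 50L,
                       G2M_positive = 50L, G2M_negative = 50L))
    nNeeded <- sum(unlist(sizes))
    stopIf(nGenes < nNeeded,
           "gene universe too small: need >= %d genes", nNeeded)
    universe <- geneUniverse(nGenes)
    withSeed(seed, {
        pool <- sample(universe, nNeeded)
        at <- 0L
        take <- function(n) {
            out <- pool[(at + 1L):(at + n)]
            at <<- at + n
            out
        }
        sets <- list()
        prov <- character()
        for (ct in names(sizes)) {
            for (ph in names(sizes[[ct]])) {
                nm <- paste(ct, ph, sep = "_")
                sets[[nm]] <- GeneSet(nm, take(sizes[[ct]][[ph]]), ct, ph)
                prov[nm] <- "synthetic fixture set"
            }
        }
        ## pan-injury astrocytes also include genes from the acute and
        ## chronic sets (pan = shared injury response); overlap permitted.
        pan <- sets[["astrocyte_pan_injury"]]
        extra <- c(sample(geneIds(sets[["astrocyte_acute_injury"]]), 30L),
                   sample(geneIds(sets[["astrocyte_chronic_neurodegenerative"]]),
                          30L))
        sets[["astrocyte_pan_injury"]] <-
            GeneSet(pan@name, c(geneIds(pan), extra), pan@cellType,
                    pan@phenotype)
        GeneSetCatalog(sets, prov)
    })
}

#' Intersect a signature with significantly dysregulated genes
#'
#' Restricts a phenotype signature to the transcripts called significant by
#' the differential-expression stage (adjusted p below `alpha`); this is
#' the gate applied before z-score signature scoring. Genes absent from the
#' DGE table (e.g. removed by the low-expression filter) are dropped
#' silently but counted. Order within the set is preserved; an empty
#' result is legal and flagged.
#'
#' @param set a [GeneSet-class].
#' @param dge DGE table (`data.frame`/`DataFrame` with `gene_id`, `p_adj`).
#' @param alpha adjusted-p significance gate in (0, 1); default 0.05.
#' @return list with elements `geneSet` (the restricted [GeneSet-class]),
#'   `nGenesMissing` (set genes absent from the table) and `isEmpty`.
#' @examples
#' dge <- data.frame(gene_id = c("A", "B", "C"),
#'                   p_adj = c(0.01, 0.20, 0.04))
#' intersectWithDEG(GeneSet("s", c("A", "B", "C")), dge, 0.05)
#' @export
intersectWithDEG <- function(set, dge, alpha = 0.05) {
    stopifnot(is(set, "GeneSet"))
    stopIf(!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
           alpha >= 1, "alpha must be in (0, 1)")
    dge <- as.data.frame(dge)
    stopIf(!all(c("gene_id", "p_adj") %in% colnames(dge)),
           "dge table must have gene_id and p_adj columns")
    padj <- dge$p_adj[match(geneIds(set), dge$gene_id)]
    present <- !is.na(padj)
    keep <- present & padj < alpha
    sub <- GeneSet(set@name, geneIds(set)[keep], set@cellType, set@phenotype)
    list(geneSet = sub,
         nGenesMissing = sum(!present),
         isEmpty = length(geneIds(sub)) == 0L)
}
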