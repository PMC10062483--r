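#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData assayNames
NULL

## Controlled vocabulary: which phenotype labels are admissible for each
## cell type. Pan-injury astrocyte sets may overlap the acute/chronic sets;
## overlap across sets is permitted everywhere and never deduplicated.
.PHENOTYPES <- list(
    microglia       = c("homeostatic", "neurodegenerative"),
    astrocyte       = c("acute_injury", "chronic_neurodegenerative",
                        "pan_injury"),
    oligodendrocyte = c("OPC", "COP", "NFOL", "MFOL", "MOL"),
    cell_cycle      = c("G1S_positive", "G1S_negative",
                        "G2M_positive", "G2M_negative")
)

#' GeneSet: a named phenotype signature
#'
#' A signature gene list tagged with the cell type it marks (microglia,
#' astrocyte, oligodendrocyte lineage, or cell-cycle regulation) and the
#' phenotype state within that cell type (e.g. homeostatic vs
#' neurodegenerative microglia, acute-injury vs pan-injury astrocytes,
#' OPC through MOL oligodendrocyte maturation stages, positive/negative
#' regulation of the G1-S and G2-M transitions).
#'
#' Gene identifiers are matched by exact, case-sensitive string equality
#' throughout the package; identifier harmonization is the caller's job.
#'
#' @slot name unique signature name.
#' @slot cellType one of `"microglia"`, `"astrocyte"`, `"oligodendrocyte"`,
#'   `"cell_cycle"`, or `NA` when unknown (e.g. free-text GMT description).
#' @slot phenotype phenotype label valid for `cellType`, or `NA`.
#' @slot genes character vector of gene identifiers, no duplicates. May be
#'   empty only for intersection results (flagged by the caller).
#'
#' @aliases GeneSet
#' @export
setClass("GeneSet",
    representation(name = "character", cellType = "character",
                   phenotype = "character", genes = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@cellType) != 1L || length(object@phenotype) != 1L)
        msg <- c(msg, "'cellType' and 'phenotype' must be length 1")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "duplicate gene ids within a set")
    ct <- object@cellType
    ph <- object@phenotype
    if (!is.na(ct) && !ct %in% names(.PHENOTYPES))
        msg <- c(msg, sprintf("unknown cell type '%s'", ct))
    if (!is.na(ct) && !is.na(ph) && ct %in% names(.PHENOTYPES) &&
        !ph %in% .PHENOTYPES[[ct]])
        msg <- c(msg, sprintf("phenotype '%s' is not valid for cell type '%s'",
                              ph, ct))
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' @param name signature name.
#' @param genes character vector of member gene ids.
#' @param cellType,phenotype controlled-vocabulary tags (see
#'   [GeneSet-class]); `NA` allowed.
#' @return A [GeneSet-class] object.
#' @examples
#' GeneSet("mg_homeo", c("P2ry12", "Tmem119"), "microglia", "homeostatic")
#' @export
GeneSet <- function(name, genes, cellType = NA_character_,
                    phenotype = NA_character_) {
    new("GeneSet", name = as.character(name), genes = as.character(genes),
        cellType = as.character(cellType), phenotype = as.character(phenotype))
}

#' GeneSetCatalog: a keyed collection of signatures
#'
#' @slot sets list of [GeneSet-class] objects; names are the set names and
#'   must be unique.
#' @slot provenance named character vector, one free-text note per set.
#'
#' @aliases GeneSetCatalog
#' @export
setClass("GeneSetCatalog",
    representation(sets = "list", provenance = "character"))

setValidity("GeneSetCatalog", function(object) {
    msg <- character()
    if (!all(vapply(object@sets, is, logical(1), "GeneSet")))
        msg <- c(msg, "all elements of 'sets' must be GeneSet objects")
    nm <- vapply(object@sets, function(s) s@name, character(1))
    if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicate set name(s): %s",
                              paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (length(object@sets) && !identical(names(object@sets), unname(nm)))
        msg <- c(msg, "list names must equal the set names")
    if (length(object@provenance) &&
        !all(names(object@provenance) %in% nm))
        msg <- c(msg, "provenance entries must be named after sets")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCatalog
#'
#' @param sets list of [GeneSet-class] objects.
#' @param provenance optional named character vector of free-text notes.
#' @return A [GeneSetCatalog-class].
#' @export
GeneSetCatalog <- function(sets = list(), provenance = character()) {
    names(sets) <- vapply(sets, function(s) s@name, character(1))
    new("GeneSetCatalog", sets = sets, provenance = provenance)
}

#' SimulationConfig: parameters of the count simulator
#'
#' Negative-binomial parameterization: variance = mu + phi * mu^2, with a
#' per-gene dispersion phi drawn log-normally around `dispersionIntercept`.
#' Per-gene baseline means are log-normal(`baselineLogMean`,
#' `baselineLogSd`) (natural-log scale); per-sample library factors are
#' log-normal(0, `libsizeLogSd`); littermates share a multiplicative
#' log-normal(0, `litterSd`) random effect. Treatment effects are injected
#' at the mean level in the Ethanol group only, as `2^log2fc`, for every
#' gene of each named signature.
#'
#' @slot nGenes number of genes in the simulated universe.
#' @slot nPerGroup animals per treatment group (must be even: sex-balanced).
#' @slot nLitters number of litters, assigned round-robin across both groups.
#' @slot baselineLogMean,baselineLogSd log-normal parameters of per-gene
#'   baseline mean counts.
#' @slot dispersionIntercept central NB dispersion phi.
#' @slot dispersionLogSd log-normal spread of per-gene phi around the
#'   intercept.
#' @slot libsizeLogSd log-normal spread of per-sample library-size factors.
#' @slot litterSd log-scale sd of the shared litter effect (0 disables it).
#' @slot effects named numeric vector: log2 fold change per signature name.
#' @slot seed integer seed; the generator uses R's Mersenne-Twister RNG
#'   with inversion for normals (R >= 3.6 defaults).
#'
#' @aliases SimulationConfig
#' @export
setClass("SimulationConfig",
    representation(nGenes = "integer", nPerGroup = "integer",
                   nLitters = "integer", baselineLogMean = "numeric",
                   baselineLogSd = "numeric", dispersionIntercept = "numeric",
                   dispersionLogSd = "numeric", libsizeLogSd = "numeric",
                   litterSd = "numeric", effects = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
    if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be positive")
    if (object@nPerGroup %% 2L != 0L)
        msg <- c(msg, "nPerGroup must be even (sex-balanced design)")
    if (object@nLitters < 1L) msg <- c(msg, "nLitters must be positive")
    for (sl in c("baselineLogSd", "dispersionIntercept", "dispersionLogSd",
                 "libsizeLogSd", "litterSd"))
        if (slot(object, sl) < 0)
            msg <- c(msg, sprintf("%s must be >= 0", sl))
    if (length(object@effects) && is.null(names(object@effects)))
        msg <- c(msg, "effects must be a named vector (signature -> log2fc)")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults emulate a balanced bulk RNA-seq study: 19,595 detected
#' transcripts, 6 animals per treatment group (3 male / 3 female from 3
#' litters), and a median library near 2e7 reads.
#'
#' @param nGenes,nPerGroup,nLitters design dimensions.
#' @param baselineLogMean,baselineLogSd,dispersionIntercept,dispersionLogSd,libsizeLogSd,litterSd
#'   distribution parameters; see [SimulationConfig-class].
#' @param effects named numeric vector of signature log2 fold changes,
#'   e.g. `c(microglia_neurodegenerative = 1)`.
#' @param seed integer seed.
#' @return A [SimulationConfig-class].
#' @examples
#' simulationConfig(nGenes = 2000, seed = 1,
#'                  effects = c(microglia_neurodegenerative = 1))
#' @export
simulationConfig <- function(nGenes = 19595L, nPerGroup = 6L, nLitters = 3L,
                             baselineLogMean = 5.8, baselineLogSd = 1.5,
                             dispersionIntercept = 0.05,
                             dispersionLogSd = 0.25, libsizeLogSd = 0.2,
                             litterSd = 0, effects = numeric(0),
                             seed = 1L) {
    if (any(c(nGenes, nPerGroup, nLitters) < 1))
        stop("invalid-config: nGenes, nPerGroup and nLitters must be positive")
    new("SimulationConfig", nGenes = as.integer(nGenes),
        nPerGroup = as.integer(nPerGroup), nLitters = as.integer(nLitters),
        baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
        dispersionIntercept = dispersionIntercept,
        dispersionLogSd = dispersionLogSd, libsizeLogSd = libsizeLogSd,
        litterSd = litterSd, effects = effects, seed = as.integer(seed))
}

#' ZScoreMatrix: per-transcript z-scores per animal
#'
#' Each retained gene row of `z` is the per-animal z-score of that
#' transcript's log2-CPM across all samples of the timepoint: mean 0 and
#' sample standard deviation 1 (denominator n-1) within 1e-10. Genes that
#' were absent from the expression matrix or had zero variance are listed
#' in `excluded` with a reason.
#'
#' With `reference = "control"` the mean/sd come from Control animals only,
#' so the mean-0/sd-1 contract holds over the Control columns rather than
#' all columns.
#'
#' @slot z numeric matrix, retained genes x samples.
#' @slot excluded data.frame with columns `gene_id`, `reason`.
#' @slot reference `"all"` or `"control"` — which samples defined the
#'   standardization.
#'
#' @aliases ZScoreMatrix
#' @export
setClass("ZScoreMatrix",
    representation(z = "matrix", excluded = "data.frame",
                   reference = "character"),
    prototype(reference = "all"))

setValidity("ZScoreMatrix", function(object) {
    msg <- character()
    z <- object@z
    if (!is.numeric(z)) msg <- c(msg, "'z' must be numeric")
    if (is.null(rownames(z)) || is.null(colnames(z)))
        msg <- c(msg, "'z' must carry gene and sample ids as dimnames")
    if (!identical(colnames(object@excluded), c("gene_id", "reason")))
        msg <- c(msg, "'excluded' must have columns gene_id, reason")
    if (!object@reference %in% c("all", "control"))
        msg <- c(msg, "'reference' must be \"all\" or \"control\"")
    if (nrow(z) && identical(object@reference, "all")) {
        m <- rowMeans(z)
        s <- apply(z, 1L, stats::sd)
        if (any(abs(m) >= 1e-10))
            msg <- c(msg, "a retained z row has |mean| >= 1e-10")
        if (any(abs(s - 1) >= 1e-10))
            msg <- c(msg, "a retained z row has |sd - 1| >= 1e-10")
    }
    if (length(msg)) msg else TRUE
})

#' SignatureScores: per-signature reports plus per-animal scores
#'
#' The result of scoring every catalog signature: one report row per
#' signature (genes tested after the differential-expression gate, genes
#' missing, Student's t statistic, two-sided p, direction) and the matrix
#' of per-animal average z-scores underlying each testable row.
#'
#' @slot report `DataFrame` with columns `signature`, `cell_type`,
#'   `phenotype`, `n_genes_tested`, `n_genes_missing`, `t_stat`, `p_value`,
#'   `direction`, `stars`.
#' @slot scores numeric matrix, signatures x samples, of per-animal average
#'   z-scores (`NA` rows for signatures with empty intersections).
#'
#' @aliases SignatureScores
#' @export
setClass("SignatureScores",
    representation(report = "DataFrame", scores = "matrix"))

setValidity("SignatureScores", function(object) {
    need <- c("signature", "cell_type", "phenotype", "n_genes_tested",
              "n_genes_missing", "t_stat", "p_value", "direction", "stars")
    msg <- character()
    if (!all(need %in% colnames(object@report)))
        msg <- c(msg, "report is missing required columns")
    if (nrow(object@report) != nrow(object@scores))
        msg <- c(msg, "report and scores disagree on the number of signatures")
    if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s' (%s / %s): %d gene(s)\n", object@name,
                ifelse(is.na(object@cellType), "?", object@cellType),
                ifelse(is.na(object@phenotype), "?", object@phenotype),
                length(object@genes)))
    if (length(object@genes))
        cat("  ", paste(utils::head(object@genes, 8L), collapse = ", "),
            if (length(object@genes) > 8L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "GeneSetCatalog", function(object) {
    cat(sprintf("GeneSetCatalog with %d set(s)\n", length(object@sets)))
    for (s in utils::head(object@sets, 12L))
        cat(sprintf("  %-36s %-15s %-26s %5d genes\n", s@name,
                    ifelse(is.na(s@cellType), "?", s@cellType),
                    ifelse(is.na(s@phenotype), "?", s@phenotype),
                    length(s@genes)))
    if (length(object@sets) > 12L)
        cat(sprintf("  ... and %d more\n", length(object@sets) - 12L))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  %d genes, %d per group x 2 treatments, %d litters, seed %d\n",
                object@nGenes, object@nPerGroup, object@nLitters, object@seed))
    cat(sprintf("  baseline lognormal(%.3g, %.3g), NB dispersion ~ %.3g, libsize sd %.3g, litter sd %.3g\n",
                object@baselineLogMean, object@baselineLogSd,
                object@dispersionIntercept, object@libsizeLogSd,
                object@litterSd))
    if (length(object@effects))
        cat("  effects:", paste(sprintf("%s=%+.2f", names(object@effects),
                                        object@effects), collapse = ", "), "\n")
})

setMethod("show", "ZScoreMatrix", function(object) {
    cat(sprintf("ZScoreMatrix: %d gene(s) x %d sample(s), %d excluded\n",
                nrow(object@z), ncol(object@z), nrow(object@excluded)))
})

setMethod("show", "SignatureScores", function(object) {
    cat(sprintf("SignatureScores for %d signature(s) across %d sample(s)\n",
                nrow(object@report), ncol(object@scores)))
    show(object@report)
})

## ---- accessors ----

#' @rdname GeneSet-class
#' @param object,x a `GeneSet` or `GeneSetCatalog`.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname GeneSet-class
#' @export
setMethod("geneIds", "GeneSet", function(object) object@genes)

#' @rdname GeneSet-class
#' @export
setGeneric("cellType", function(object) standardGeneric("cellType"))

#' @rdname GeneSet-class
#' @export
setMethod("cellType", "GeneSet", function(object) object@cellType)

#' @rdname GeneSet-class
#' @export
setGeneric("phenotype", function(object) standardGeneric("phenotype"))

#' @rdname GeneSet-class
#' @export
setMethod("phenotype", "GeneSet", function(object) object@phenotype)

#' @rdname GeneSet-class
#' @export
setGeneric("setName", function(object) standardGeneric("setName"))

#' @rdname GeneSet-class
#' @export
setMethod("setName", "GeneSet", function(object) object@name)

#' @rdname GeneSetCatalog-class
#' @param x a `GeneSetCatalog`.
#' @export
setMethod("length", "GeneSetCatalog", function(x) length(x@sets))

#' @rdname GeneSetCatalog-class
#' @export
setMethod("names", "GeneSetCatalog", function(x) names(x@sets))

#' @rdname GeneSetCatalog-class
#' @param i set name or index.
#' @export
setMethod("[[", "GeneSetCatalog", function(x, i) x@sets[[i]])

#' @rdname GeneSetCatalog-class
#' @param object a `GeneSetCatalog`.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname GeneSetCatalog-class
#' @export
setMethod("geneSets", "GeneSetCatalog", function(object) object@sets)

#' @rdname SignatureScores-class
#' @param object a `SignatureScores`.
#' @export
setGeneric("signatureReport", function(object) standardGeneric("signatureReport"))

#' @rdname SignatureScores-class
#' @export
setMethod("signatureReport", "SignatureScores", function(object) object@report)

#' @rdname SignatureScores-class
#' @export
setGeneric("animalScores", function(object) standardGeneric("animalScores"))

#' @rdname SignatureScores-class
#' @export
setMethod("animalScores", "SignatureScores", function(object) object@scores)

#' @rdname ZScoreMatrix-class
#' @param object a `ZScoreMatrix`.
#' @export
setGeneric("zMatrix", function(object) standardGeneric("zMatrix"))

#' @rdname ZScoreMatrix-class
#' @export
setMethod("zMatrix", "ZScoreMatrix", function(object) object@z)

#' @rdname ZScoreMatrix-class
#' @export
setGeneric("excludedGenes", function(object) standardGeneric("excludedGenes"))

#' @rdname ZScoreMatrix-class
#' @export
setMethod("excludedGenes", "ZScoreMatrix", function(object) object@excluded)
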