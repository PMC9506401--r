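#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.MARKERS    <- c("16S", "ITS")
.TISSUES    <- c("shoot", "root", "rhizosphere", "seed", "spermosphere", "control")
.SUBSTRATES <- c("sand", "soil", "none")
.SEEDLIKE   <- c("seed", "spermosphere")

#' Default host-species panel
#'
#' The seventeen angiosperm hosts of the jar experiment the package is
#' organised around: two model species, eight monocot crops and seven dicot
#' crops. All screening functions take an explicit host vector, so the panel
#' is a default, not a hard-wired constant.
#'
#' @return Character vector of 17 host names.
#' @export
#' @examples
#' defaultHosts()
defaultHosts <- function() {
    c("Arabidopsis", "Barley", "Brachiaria", "Brachypodium", "Cassava",
      "Coffee", "Maize", "Panicum", "Pea", "Phaseolus", "Rice", "Sorghum",
      "Soy", "Sugarcane", "Sunflower", "Tomato", "Wheat")
}

.err <- function(class, msg, ...) {
    stop(errorCondition(msg, ...,
                        class = c(class, "rareTransmitError", "error",
                                  "condition")))
}

# ---------------------------------------------------------------------------
# OtuTable: integer OTU read counts (OTUs x samples) for one marker
# ---------------------------------------------------------------------------

#' OtuTable: OTU read counts for one marker
#'
#' An \code{OtuTable} is a \linkS4class{SummarizedExperiment} holding
#' non-negative integer read counts with OTUs as rows and samples as columns,
#' per-sample metadata (host, tissue, substrate, replicate) in
#' \code{colData}, per-OTU taxonomy in \code{rowData} and the amplicon
#' marker (\code{"16S"} or \code{"ITS"}) in \code{metadata}. 16S and ITS
#' tables are never merged; every analysis runs per marker.
#'
#' @aliases OtuTable-class
#' @exportClass OtuTable
setClass("OtuTable", contains = "SummarizedExperiment")

.validOtuTable <- function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (nrow(m) < 1L || ncol(m) < 1L)
            msg <- c(msg, "need at least 1 OTU and 1 sample")
        if (anyNA(m))
            msg <- c(msg, "counts contain NA")
        else if (any(m < 0))
            msg <- c(msg, "counts contain negative values")
        else if (any(m != floor(m)))
            msg <- c(msg, "counts contain non-integer values")
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msg <- c(msg, "OTU ids must be present and unique")
        if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
            msg <- c(msg, "sample ids must be present and unique")
    }
    mk <- metadata(object)$marker
    if (is.null(mk) || length(mk) != 1L || !mk %in% .MARKERS)
        msg <- c(msg, "metadata(x)$marker must be one of '16S', 'ITS'")
    if (length(msg)) msg else TRUE
}
setValidity("OtuTable", .validOtuTable)

#' Construct an OtuTable
#'
#' @param counts Integer matrix of read counts, OTUs as rows and samples as
#'   columns, with rownames (OTU ids) and colnames (sample ids).
#' @param marker \code{"16S"} or \code{"ITS"}.
#' @param sampleData Optional \code{DataFrame}/\code{data.frame} of sample
#'   metadata (columns \code{host}, \code{tissue}, \code{substrate},
#'   \code{replicate}), one row per sample in \code{counts}.
#' @param taxonomy Optional \code{DataFrame}/\code{data.frame} of per-OTU
#'   taxonomy (rank columns \code{kingdom} \dots \code{genus} plus a logical
#'   \code{nontarget}), one row per OTU.
#' @return A validated \linkS4class{OtuTable}.
#' @export
#' @examples
#' m <- matrix(c(0L, 5L, 3L, 1L), 2, 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("s1", "s2")))
#' tab <- OtuTable(m, marker = "ITS")
#' totalReads(tab)
OtuTable <- function(counts, marker = c("16S", "ITS"), sampleData = NULL,
                     taxonomy = NULL) {
    marker <- match.arg(marker)
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = colnames(counts))
    else {
        sampleData <- as(sampleData, "DataFrame")
        if (!is.null(sampleData$sample_id) && is.null(rownames(sampleData)))
            rownames(sampleData) <- sampleData$sample_id
        sampleData <- sampleData[colnames(counts), , drop = FALSE]
        .checkMetadataEnums(sampleData)
    }
    if (is.null(taxonomy))
        taxonomy <- DataFrame(row.names = rownames(counts))
    else {
        taxonomy <- as(taxonomy, "DataFrame")
        if (!is.null(taxonomy$otu_id) && is.null(rownames(taxonomy)))
            rownames(taxonomy) <- taxonomy$otu_id
        taxonomy <- taxonomy[rownames(counts), , drop = FALSE]
    }
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = sampleData, rowData = taxonomy,
                               metadata = list(marker = marker))
    new("OtuTable", se)
}

# ---------------------------------------------------------------------------
# GroupedAbundance: replicate-collapsed relative abundances in percent
# ---------------------------------------------------------------------------

#' GroupedAbundance: relative abundances per host x tissue x substrate group
#'
#' A \linkS4class{SummarizedExperiment} whose \code{relabund} assay holds
#' relative abundances in percent (each group/column sums to 100, except
#' all-zero groups, which stay zero and carry \code{colData(x)$empty ==
#' TRUE}). Columns are replicate-collapsed (host, tissue, substrate) groups.
#'
#' @aliases GroupedAbundance-class
#' @exportClass GroupedAbundance
setClass("GroupedAbundance", contains = "SummarizedExperiment")

.validGroupedAbundance <- function(object) {
    msg <- character()
    if (!"relabund" %in% assayNames(object))
        return("assay 'relabund' is required")
    m <- assay(object, "relabund")
    if (any(m < 0) || anyNA(m))
        msg <- c(msg, "relative abundances must be non-negative and non-NA")
    need <- c("host", "tissue", "substrate", "empty")
    if (!all(need %in% colnames(colData(object))))
        msg <- c(msg, paste("colData must contain",
                            paste(need, collapse = ", ")))
    else {
        cs <- colSums(m)
        empty <- colData(object)$empty
        bad <- !empty & abs(cs - 100) > 1e-6
        if (any(bad))
            msg <- c(msg, "non-empty groups must sum to 100 (tol 1e-6)")
        if (any(empty & cs != 0))
            msg <- c(msg, "groups flagged empty must be all-zero")
    }
    if (length(msg)) msg else TRUE
}
setValidity("GroupedAbundance", .validGroupedAbundance)

# ---------------------------------------------------------------------------
# PresenceMatrix: thresholded detection calls
# ---------------------------------------------------------------------------

#' PresenceMatrix: boolean detection matrix with its threshold
#'
#' A \linkS4class{SummarizedExperiment} with a logical \code{presence} assay
#' (OTUs x samples or OTUs x groups) recording detection above a relative
#' abundance threshold (percent, strict inequality), which is kept in
#' \code{metadata(x)$threshold_percent} as provenance.
#'
#' @aliases PresenceMatrix-class
#' @exportClass PresenceMatrix
setClass("PresenceMatrix", contains = "SummarizedExperiment")

.validPresenceMatrix <- function(object) {
    msg <- character()
    if (!"presence" %in% assayNames(object))
        return("assay 'presence' is required")
    if (!is.logical(assay(object, "presence")))
        msg <- c(msg, "presence assay must be logical")
    th <- metadata(object)$threshold_percent
    if (is.null(th) || length(th) != 1L || is.na(th) || th < 0)
        msg <- c(msg, "metadata(x)$threshold_percent must be a single number >= 0")
    if (length(msg)) msg else TRUE
}
setValidity("PresenceMatrix", .validPresenceMatrix)

# ---------------------------------------------------------------------------
# UncommonSet: result of an occupancy screen in one compartment
# ---------------------------------------------------------------------------

#' UncommonSet: OTUs flagged uncommon within one compartment
#'
#' Records the outcome of an occupancy screen: the compartment (tissue and
#' substrate, or a seed-class tissue), the OTU ids flagged uncommon, the full
#' OTU universe screened, and the screen parameters. Uncommon and common OTUs
#' partition the universe.
#'
#' @aliases UncommonSet-class
#' @exportClass UncommonSet
setClass("UncommonSet",
         representation(tissue = "character", substrate = "character",
                        otuIds = "character", universe = "character",
                        params = "list"))

setValidity("UncommonSet", function(object) {
    if (!all(object@otuIds %in% object@universe))
        return("uncommon OTU ids must be a subset of the screened universe")
    TRUE
})

setMethod("show", "UncommonSet", function(object) {
    cat(sprintf("UncommonSet: %d uncommon of %d OTUs in %s/%s\n",
                length(object@otuIds), length(object@universe),
                object@tissue, object@substrate))
    p <- object@params
    if (length(p))
        cat("  params:", paste(names(p), unlist(p), sep = "=",
                               collapse = ", "), "\n")
})

setMethod("show", "OtuTable", function(object) {
    cat(sprintf("OtuTable (%s): %d OTUs x %d samples, %d reads\n",
                metadata(object)$marker, nrow(object), ncol(object),
                sum(assay(object, "counts"))))
    callNextMethod()
})

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' SimulationConfig: parameters of the synthetic multi-host community
#'
#' Holds every knob of the generative model behind \code{\link{simulateCommunity}}:
#' the host panel, replication, OTU class sizes, the seed-carriage Bernoulli
#' probability, the per-jar Poisson propagule rate for rare soil microbes,
#' the root biotic-filtering probability, log-normal base-abundance and
#' read-depth parameters, and the read-sampling mode.
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(hosts = "character", replicates = "integer",
                        seedReplicates = "integer", classSizes = "integer",
                        pSeedCarriage = "numeric", lambdaSoil = "numeric",
                        rootFilterProb = "numeric",
                        hostsPerDeterministicSeed = "integer",
                        abundMeanlog = "numeric", abundSdlog = "numeric",
                        depthMeanlog = "numeric", depthSdlog = "numeric",
                        depthMin = "numeric", depthMax = "numeric",
                        sampling = "character"))

.OTU_CLASSES <- c("core_seed", "rare_seed_deterministic",
                  "rare_seed_stochastic", "soil_common", "soil_rare",
                  "host_specialist", "contaminant")

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (length(object@hosts) < 1L || anyDuplicated(object@hosts))
        msg <- c(msg, "hosts must be non-empty and unique")
    if (object@replicates < 1L || object@seedReplicates < 1L)
        msg <- c(msg, "replicates must be >= 1")
    if (!setequal(names(object@classSizes), .OTU_CLASSES) ||
        any(object@classSizes < 0L))
        msg <- c(msg, "classSizes must name all OTU classes with sizes >= 0")
    for (p in c("pSeedCarriage", "rootFilterProb"))
        if (slot(object, p) < 0 || slot(object, p) > 1)
            msg <- c(msg, paste(p, "must be in [0, 1]"))
    if (object@lambdaSoil < 0)
        msg <- c(msg, "lambdaSoil must be >= 0")
    if (object@depthMin < 1 || object@depthMax < object@depthMin)
        msg <- c(msg, "depth bounds must satisfy 1 <= depthMin <= depthMax")
    if (!object@sampling %in% c("multinomial", "expected"))
        msg <- c(msg, "sampling must be 'multinomial' or 'expected'")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %d hosts x %d reps, %d OTUs; ",
                       "pSeedCarriage=%.2f, lambdaSoil=%.2f, ",
                       "rootFilterProb=%.2f, sampling=%s\n"),
                length(object@hosts), object@replicates,
                sum(object@classSizes), object@pSeedCarriage,
                object@lambdaSoil, object@rootFilterProb, object@sampling))
})

.checkMetadataEnums <- function(df, hosts = character()) {
    if (!all(c("host", "tissue", "substrate", "replicate") %in% colnames(df)))
        .err("rt_missing_columns",
             "metadata must have columns host, tissue, substrate, replicate")
    bad <- setdiff(unique(df$tissue), .TISSUES)
    if (length(bad))
        .err("rt_bad_enum", paste("unknown tissue value(s):",
                                  paste(bad, collapse = ", ")))
    bad <- setdiff(unique(df$substrate), .SUBSTRATES)
    if (length(bad))
        .err("rt_bad_enum", paste("unknown substrate value(s):",
                                  paste(bad, collapse = ", ")))
    seedlike <- df$tissue %in% .SEEDLIKE
    if (any(seedlike & df$substrate != "none"))
        .err("rt_substrate_mismatch",
             "seed/spermosphere samples must have substrate 'none'")
    if (any(!seedlike & df$substrate == "none" & df$tissue != "control"))
        .err("rt_substrate_mismatch",
             "substrate 'none' is only valid for seed/spermosphere samples")
    if (any(!is.finite(df$replicate)) || any(df$replicate < 1))
        .err("rt_bad_replicate", "replicate must be a positive integer")
    if (length(hosts)) {
        bad <- setdiff(unique(df$host), hosts)
        if (length(bad))
            .err("rt_unknown_host", paste("unknown host name(s):",
                                          paste(bad, collapse = ", ")))
    }
    invisible(TRUE)
}
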