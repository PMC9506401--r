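#' @include AllClasses.R
NULL

#' Accessors for rareTransmit containers
#'
#' \code{marker} returns the amplicon marker of a table; \code{otuCounts}
#' the integer count matrix (OTUs x samples); \code{sampleData} the
#' per-sample metadata; \code{taxonomy} the per-OTU taxonomy;
#' \code{totalReads} the grand total of reads; \code{uncommonIds} the OTU
#' ids an occupancy screen flagged uncommon; \code{screenParams} the screen
#' parameters recorded on an \linkS4class{UncommonSet}.
#'
#' @param x An \linkS4class{OtuTable}, \linkS4class{GroupedAbundance},
#'   \linkS4class{PresenceMatrix} or \linkS4class{UncommonSet} as
#'   appropriate.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases marker otuCounts sampleData taxonomy totalReads uncommonIds
#'   screenParams
NULL

#' @rdname accessors
#' @export
setGeneric("marker", function(x) standardGeneric("marker"))
#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))
#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @rdname accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("uncommonIds", function(x) standardGeneric("uncommonIds"))
#' @rdname accessors
#' @export
setGeneric("screenParams", function(x) standardGeneric("screenParams"))

#' @rdname accessors
setMethod("marker", "SummarizedExperiment",
          function(x) metadata(x)$marker)
#' @rdname accessors
setMethod("otuCounts", "OtuTable", function(x) assay(x, "counts"))
#' @rdname accessors
setMethod("sampleData", "SummarizedExperiment", function(x) colData(x))
#' @rdname accessors
setMethod("taxonomy", "SummarizedExperiment", function(x) rowData(x))
#' @rdname accessors
setMethod("totalReads", "OtuTable",
          function(x) sum(assay(x, "counts")))
#' @rdname accessors
setMethod("uncommonIds", "UncommonSet", function(x) x@otuIds)
#' @rdname accessors
setMethod("screenParams", "UncommonSet", function(x) x@params)

#' Relative abundances of a GroupedAbundance (percent)
#'
#' @param x A \linkS4class{GroupedAbundance}.
#' @return Numeric matrix (OTUs x groups), columns summing to 100 except
#'   flagged-empty groups.
#' @export
relAbundance <- function(x) {
    stopifnot(is(x, "GroupedAbundance"))
    assay(x, "relabund")
}

#' Presence calls of a PresenceMatrix
#'
#' @param x A \linkS4class{PresenceMatrix}.
#' @return Logical matrix (OTUs x samples/groups).
#' @export
isPresent <- function(x) {
    stopifnot(is(x, "PresenceMatrix"))
    assay(x, "presence")
}

#' Detection threshold of a PresenceMatrix (percent)
#'
#' @param x A \linkS4class{PresenceMatrix}.
#' @return The strict relative-abundance threshold (percent) used.
#' @export
presenceThreshold <- function(x) {
    stopifnot(is(x, "PresenceMatrix"))
    metadata(x)$threshold_percent
}
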