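#' @include AllClasses.R
NULL

#' Default non-target keyword rules
#'
#' Case-insensitive substrings that mark an OTU as non-target (host
#' organelle or other non-microbial amplification) when they occur in any
#' taxonomy rank.
#'
#' @return Character vector of patterns.
#' @export
defaultNontargetRules <- function() {
    c("mitochondri", "chloroplast", "plant", "protist", "viridiplantae",
      "streptophyta")
}

#' Flag non-target OTUs by taxonomy keywords
#'
#' An OTU is flagged when any of its rank strings contains any rule
#' (case-insensitive, fixed substrings), or when its \code{nontarget}
#' annotation column is already TRUE. Deterministic given the rules.
#'
#' @param tax \code{DataFrame}/\code{data.frame} of taxonomy, rownames (or
#'   an \code{otu_id} column) identifying OTUs.
#' @param rules Non-empty character vector of keyword patterns
#'   (default \code{\link{defaultNontargetRules}()}).
#' @return Character vector of flagged OTU ids.
#' @export
#' @examples
#' tax <- data.frame(otu_id = c("a", "b"),
#'                   family = c("mitochondria", "Nectriaceae"),
#'                   genus = c("", "Fusarium"))
#' flagNontarget(tax)  # "a"
flagNontarget <- function(tax, rules = defaultNontargetRules()) {
    if (!length(rules))
        .err("rt_bad_rules", "rules must be non-empty")
    tax <- as.data.frame(tax)
    ids <- if (!is.null(tax$otu_id)) as.character(tax$otu_id) else
        rownames(tax)
    ranks <- intersect(c("kingdom", "phylum", "class", "order", "family",
                         "genus"), colnames(tax))
    hit <- if (!is.null(tax$nontarget)) as.logical(tax$nontarget) else
        rep(FALSE, nrow(tax))
    hit[is.na(hit)] <- FALSE
    for (r in ranks) {
        v <- tolower(as.character(tax[[r]]))
        v[is.na(v)] <- ""
        for (p in tolower(rules))
            hit <- hit | grepl(p, v, fixed = TRUE)
    }
    ids[hit]
}

#' Remove OTUs from a count table
#'
#' @param x An \linkS4class{OtuTable}.
#' @param otuIds OTU ids to drop (ids not in the table are ignored).
#' @return The reduced \linkS4class{OtuTable}.
#' @export
removeOtus <- function(x, otuIds) {
    stopifnot(is(x, "OtuTable"))
    keep <- !rownames(x) %in% otuIds
    if (!any(keep))
        .err("rt_empty_table", "removing these OTUs would empty the table")
    x[keep, ]
}

#' Drop low-total (singleton) OTUs
#'
#' Removes OTUs whose total read count across all samples is below
#' \code{minTotalReads}; the default 2 discards singletons (OTUs backed by
#' a single read). The sample axis is unchanged. The rule uses post-merge
#' OTU totals, which has the same effect on any OTU the downstream screens
#' can see.
#'
#' @param x An \linkS4class{OtuTable}.
#' @param minTotalReads Minimum total reads an OTU must have to be kept.
#' @return The filtered \linkS4class{OtuTable}.
#' @export
dropSingletons <- function(x, minTotalReads = 2L) {
    stopifnot(is(x, "OtuTable"))
    keep <- rowSums(otuCounts(x)) >= minTotalReads
    if (!any(keep))
        .err("rt_empty_table", "no OTU reaches minTotalReads")
    x[keep, ]
}

#' Sum replicates into host x tissue x substrate groups
#'
#' Each output column is the elementwise sum of the member replicates of
#' one observed (host, tissue, substrate) group; total reads are conserved
#' exactly (integer arithmetic). Groups with zero member samples are never
#' emitted. Control (unplanted jar) samples are excluded by default.
#'
#' @param x An \linkS4class{OtuTable} with embedded sample metadata.
#' @param keepControls Keep control samples as their own groups?
#' @return An \linkS4class{OtuTable} of collapsed groups; \code{colData}
#'   has \code{host}, \code{tissue}, \code{substrate} and \code{n_samples}.
#' @export
collapseReplicates <- function(x, keepControls = FALSE) {
    stopifnot(is(x, "OtuTable"))
    meta <- as.data.frame(colData(x))
    need <- c("host", "tissue", "substrate")
    if (!all(need %in% colnames(meta)))
        .err("rt_missing_metadata",
             "every sample needs host/tissue/substrate metadata; see attachAnnotations()")
    keep <- if (keepControls) rep(TRUE, nrow(meta)) else
        meta$tissue != "control"
    m <- otuCounts(x)[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    key <- paste(meta$host, meta$tissue, meta$substrate, sep = "|")
    groups <- unique(key)
    out <- matrix(0L, nrow(m), length(groups),
                  dimnames = list(rownames(m), groups))
    for (g in groups)
        out[, g] <- as.integer(rowSums(m[, key == g, drop = FALSE]))
    parts <- do.call(rbind, strsplit(groups, "|", fixed = TRUE))
    cd <- DataFrame(host = parts[, 1L], tissue = parts[, 2L],
                    substrate = parts[, 3L],
                    n_samples = as.integer(table(key)[groups]),
                    row.names = groups)
    se <- SummarizedExperiment(assays = list(counts = out), colData = cd,
                               rowData = rowData(x),
                               metadata = list(marker = marker(x),
                                               collapsed = TRUE))
    new("OtuTable", se)
}

#' Normalise collapsed counts to relative percentages
#'
#' Scales each group (column) to sum to 100. All-zero groups are left zero
#' and flagged via \code{colData(x)$empty}.
#'
#' @param x A collapsed \linkS4class{OtuTable}
#'   (see \code{\link{collapseReplicates}}).
#' @return A \linkS4class{GroupedAbundance}.
#' @export
relativeAbundance <- function(x) {
    stopifnot(is(x, "OtuTable"))
    cd <- colData(x)
    if (!all(c("host", "tissue", "substrate") %in% colnames(cd)))
        .err("rt_missing_metadata",
             "columns must carry host/tissue/substrate metadata")
    m <- otuCounts(x)
    tot <- colSums(m)
    rel <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    nz <- tot > 0
    rel[, nz] <- sweep(m[, nz, drop = FALSE], 2L, tot[nz], "/") * 100
    cd$empty <- !nz
    se <- SummarizedExperiment(assays = list(relabund = rel), colData = cd,
                               rowData = rowData(x),
                               metadata = list(marker = marker(x)))
    new("GroupedAbundance", se)
}

#' Threshold abundances into presence/absence calls
#'
#' A cell is present iff its relative abundance strictly exceeds
#' \code{threshold_percent}. At threshold 0 this is detection by at least
#' one read. Raising the threshold can only turn present cells absent
#' (monotonicity). An \linkS4class{OtuTable} input is converted to
#' per-sample relative abundance internally.
#'
#' @param x A \linkS4class{GroupedAbundance} or \linkS4class{OtuTable}.
#' @param threshold_percent Detection threshold in percent (>= 0; strict
#'   inequality).
#' @return A \linkS4class{PresenceMatrix} recording the threshold used.
#' @export
presence <- function(x, threshold_percent = 0) {
    if (length(threshold_percent) != 1L || is.na(threshold_percent) ||
        threshold_percent < 0)
        .err("rt_bad_threshold", "threshold_percent must be a single number >= 0")
    if (is(x, "GroupedAbundance")) {
        rel <- relAbundance(x)
    } else if (is(x, "OtuTable")) {
        m <- otuCounts(x)
        tot <- colSums(m)
        rel <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
        nz <- tot > 0
        rel[, nz] <- sweep(m[, nz, drop = FALSE], 2L, tot[nz], "/") * 100
    } else {
        .err("rt_bad_input", "x must be a GroupedAbundance or OtuTable")
    }
    se <- SummarizedExperiment(assays = list(presence = rel > threshold_percent),
                               colData = colData(x), rowData = rowData(x),
                               metadata = c(metadata(x),
                                            list(threshold_percent = threshold_percent)))
    new("PresenceMatrix", se)
}
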