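#' @include AllClasses.R
NULL

.compartmentCols <- function(se, tissue = NULL, substrate = NULL) {
    cd <- colData(se)
    keep <- rep(TRUE, ncol(se))
    if (!is.null(tissue)) keep <- keep & cd$tissue %in% tissue
    if (!is.null(substrate)) keep <- keep & cd$substrate %in% substrate
    which(keep)
}

#' Host-species occupancy of each OTU within a compartment
#'
#' Counts, for every OTU, the number of distinct host species detected in
#' one compartment (tissue x substrate) of a presence matrix over collapsed
#' groups. Occupancy is computed within a compartment by default because
#' the uncommon screens are applied per sample type; passing
#' \code{tissue = NULL, substrate = NULL} gives the dataset-wide mode.
#'
#' @param pres A \linkS4class{PresenceMatrix} whose columns carry
#'   \code{host}/\code{tissue}/\code{substrate} metadata.
#' @param tissue,substrate Compartment selectors (single values), or NULL
#'   for no restriction.
#' @param hosts Hosts defining the denominator H (default: hosts observed
#'   in the selected columns).
#' @return A \code{DataFrame}: \code{otu_id}, \code{tissue},
#'   \code{substrate}, \code{n_hosts_present}, \code{n_hosts_total},
#'   \code{occupancy_fraction}.
#' @export
speciesOccupancy <- function(pres, tissue = NULL, substrate = NULL,
                             hosts = NULL) {
    stopifnot(is(pres, "PresenceMatrix"))
    cols <- .compartmentCols(pres, tissue, substrate)
    if (!length(cols))
        .err("rt_empty_compartment", "compartment selects zero columns")
    p <- isPresent(pres)[, cols, drop = FALSE]
    hostOf <- as.character(colData(pres)$host[cols])
    if (is.null(hosts)) hosts <- unique(hostOf)
    if (!length(hosts))
        .err("rt_empty_compartment", "compartment contains zero hosts")
    n <- vapply(rownames(p), function(o) {
        length(unique(hostOf[p[o, ] & hostOf %in% hosts]))
    }, integer(1L))
    DataFrame(otu_id = rownames(p),
              tissue = if (is.null(tissue)) NA_character_ else tissue,
              substrate = if (is.null(substrate)) NA_character_ else substrate,
              n_hosts_present = unname(n),
              n_hosts_total = length(hosts),
              occupancy_fraction = unname(n) / length(hosts),
              row.names = rownames(p))
}

#' Screen OTUs as uncommon by host occupancy
#'
#' An OTU is uncommon iff it is present in at most \code{maxHosts} host
#' species. With the defaults (maxHosts = 9 of H = 17) the cutoff fraction
#' is 9/17, just under 53\% occupancy. \code{maxHosts = H} flags every OTU;
#' \code{maxHosts = 0} only OTUs absent from all hosts. The screen is
#' antitone in \code{maxHosts}.
#'
#' @param occ Occupancy \code{DataFrame} from \code{\link{speciesOccupancy}}
#'   (one compartment).
#' @param maxHosts Maximum number of host species an uncommon OTU may
#'   occupy (default 9).
#' @return An \linkS4class{UncommonSet}.
#' @export
screenUncommon <- function(occ, maxHosts = 9L) {
    H <- occ$n_hosts_total[1L]
    if (maxHosts < 0L || maxHosts > H)
        .err("rt_bad_threshold", "maxHosts must be in [0, H]")
    unc <- occ$otu_id[occ$n_hosts_present <= maxHosts]
    new("UncommonSet",
        tissue = as.character(occ$tissue[1L]),
        substrate = as.character(occ$substrate[1L]),
        otuIds = as.character(unc), universe = as.character(occ$otu_id),
        params = list(maxHosts = as.integer(maxHosts), H = as.integer(H)))
}

#' Occupancy cutoff fraction of the uncommon screen
#'
#' @param maxHosts,H Screen parameters (defaults 9 and 17).
#' @return \code{maxHosts / H} (e.g. 9/17, about 0.529).
#' @export
uncommonCutoff <- function(maxHosts = 9L, H = 17L) maxHosts / H

#' Screen seed or spermosphere OTUs as uncommon by sample occupancy
#'
#' For seed-class tissues the screen counts samples, not host species: an
#' OTU is uncommon iff present in at most \code{floor(N/2)} of the N
#' samples (i.e. common OTUs occur in more than half of the
#' seeds/spermospheres).
#'
#' @param pres A \linkS4class{PresenceMatrix} over per-sample presence.
#' @param tissue \code{"seed"} or \code{"spermosphere"}.
#' @return An \linkS4class{UncommonSet} with \code{params$maxSamples}.
#' @export
screenUncommonSeedlike <- function(pres, tissue = c("seed", "spermosphere")) {
    stopifnot(is(pres, "PresenceMatrix"))
    tissue <- match.arg(tissue)
    cols <- .compartmentCols(pres, tissue = tissue)
    if (!length(cols))
        .err("rt_empty_compartment",
             paste("no", tissue, "samples in the presence matrix"))
    p <- isPresent(pres)[, cols, drop = FALSE]
    N <- ncol(p)
    maxS <- floor(N / 2)
    unc <- rownames(p)[rowSums(p) <= maxS]
    new("UncommonSet", tissue = tissue, substrate = "none",
        otuIds = unc, universe = rownames(p),
        params = list(nSamples = N, maxSamples = as.integer(maxS)))
}

#' Keep uncommon OTUs whose peak abundance exceeds a floor
#'
#' From an uncommon set, retains the OTUs whose maximum relative abundance
#' across the compartment's collapsed groups strictly exceeds
#' \code{minPeakPercent}. Antitone in \code{minPeakPercent}.
#'
#' @param rel A \linkS4class{GroupedAbundance}.
#' @param uncommon An \linkS4class{UncommonSet} (or character vector of OTU
#'   ids, in which case all columns are used).
#' @param minPeakPercent Peak-abundance floor in percent (>= 0; strict).
#' @return Character vector of abundant-and-uncommon OTU ids.
#' @export
screenAbundant <- function(rel, uncommon, minPeakPercent = 5) {
    stopifnot(is(rel, "GroupedAbundance"))
    if (minPeakPercent < 0)
        .err("rt_bad_threshold", "minPeakPercent must be >= 0")
    if (is(uncommon, "UncommonSet")) {
        ids <- uncommonIds(uncommon)
        cols <- .compartmentCols(rel, uncommon@tissue, uncommon@substrate)
        if (!length(cols)) cols <- seq_len(ncol(rel))
    } else {
        ids <- as.character(uncommon)
        cols <- seq_len(ncol(rel))
    }
    ids <- intersect(ids, rownames(rel))
    if (!length(ids)) return(character())
    m <- relAbundance(rel)[ids, cols, drop = FALSE]
    peak <- apply(m, 1L, max)
    ids[peak > minPeakPercent]
}

#' Rank uncommon OTUs by total abundance
#'
#' Orders the uncommon OTUs by their total summed relative abundance across
#' the selected groups (ties broken by lexicographically smaller OTU id)
#' and returns the first \code{n}.
#'
#' @param rel A \linkS4class{GroupedAbundance}.
#' @param uncommon An \linkS4class{UncommonSet} or character vector of ids.
#' @param n Number of top OTUs to return (>= 1); if larger than the pool,
#'   all are returned, ranked.
#' @param columns Optional column indices/names restricting the groups
#'   summed over (default: the uncommon set's compartment, else all).
#' @return Ranked character vector of OTU ids (length <= n).
#' @export
topUncommon <- function(rel, uncommon, n = 40L, columns = NULL) {
    stopifnot(is(rel, "GroupedAbundance"))
    if (n < 1L)
        .err("rt_bad_threshold", "n must be >= 1")
    if (is(uncommon, "UncommonSet")) {
        ids <- uncommonIds(uncommon)
        if (is.null(columns)) {
            columns <- .compartmentCols(rel, uncommon@tissue,
                                        uncommon@substrate)
            if (!length(columns)) columns <- seq_len(ncol(rel))
        }
    } else {
        ids <- as.character(uncommon)
        if (is.null(columns)) columns <- seq_len(ncol(rel))
    }
    ids <- intersect(ids, rownames(rel))
    if (!length(ids)) return(character())
    tot <- rowSums(relAbundance(rel)[ids, columns, drop = FALSE])
    ids[order(-tot, ids)][seq_len(min(n, length(ids)))]
}
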