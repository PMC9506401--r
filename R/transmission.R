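#' @include AllClasses.R
NULL

#' Sorensen (Dice) similarity of two presence sets
#'
#' Computes \code{2 |A intersect B| / (|A| + |B|)} on sets of OTU ids; the
#' degenerate both-empty case is defined as 0. Symmetric and bounded in
#' [0, 1]; 1 iff the sets are equal and non-empty.
#'
#' @param A,B Character vectors of OTU ids (duplicates ignored).
#' @return Similarity in [0, 1].
#' @export
#' @examples
#' sorensen(c("a", "b", "c"), c("b", "c", "d"))  # 4/6
sorensen <- function(A, B) {
    A <- unique(as.character(A)); B <- unique(as.character(B))
    denom <- length(A) + length(B)
    if (denom == 0L) return(0)
    2 * length(intersect(A, B)) / denom
}

#' Per-host substrate-similarity table of uncommon OTUs
#'
#' For every host and vegetative tissue, compares the set of uncommon OTUs
#' detected in the host's sterile-sand-grown group (A) against its
#' field-soil-grown group (B) with the Sorensen index. Seed-transmitted
#' OTUs detected on both substrates raise the index; the column
#' (per-tissue) means summarise how much of the uncommon diversity in
#' soil-grown plants is seed-derived. Hosts missing one substrate for a
#' tissue are omitted (and listed in \code{$omitted}).
#'
#' @param pres A \linkS4class{PresenceMatrix} over collapsed groups.
#' @param uncommonSets List of \linkS4class{UncommonSet}s, one per
#'   (tissue, substrate) compartment screened.
#' @param tissues Tissues to tabulate (default shoot, root, rhizosphere).
#' @return A list: \code{$entries} (\code{DataFrame} with host, tissue,
#'   similarity, set sizes and intersection), \code{$means} (named numeric,
#'   per-tissue arithmetic mean over hosts, rounded to 2 decimals) and
#'   \code{$omitted}.
#' @export
substrateSimilarityTable <- function(pres, uncommonSets,
                                     tissues = c("rhizosphere", "root",
                                                 "shoot")) {
    stopifnot(is(pres, "PresenceMatrix"))
    p <- isPresent(pres)
    cd <- colData(pres)
    uncOf <- function(ti, su) {
        for (u in uncommonSets)
            if (identical(u@tissue, ti) && identical(u@substrate, su))
                return(uncommonIds(u))
        NULL
    }
    rows <- list(); omitted <- character()
    hosts <- unique(as.character(cd$host))
    for (ti in tissues) {
        uSand <- uncOf(ti, "sand"); uSoil <- uncOf(ti, "soil")
        if (is.null(uSand) || is.null(uSoil))
            .err("rt_missing_screen",
                 paste("no uncommon set supplied for tissue", ti))
        for (h in hosts) {
            iSand <- which(cd$host == h & cd$tissue == ti &
                           cd$substrate == "sand")
            iSoil <- which(cd$host == h & cd$tissue == ti &
                           cd$substrate == "soil")
            if (!length(iSand) || !length(iSoil)) {
                omitted <- c(omitted, paste(h, ti, sep = "/"))
                next
            }
            A <- intersect(uSand, rownames(p)[p[, iSand[1L]]])
            B <- intersect(uSoil, rownames(p)[p[, iSoil[1L]]])
            rows[[length(rows) + 1L]] <-
                data.frame(host = h, tissue = ti,
                           similarity = sorensen(A, B),
                           n_sand = length(A), n_soil = length(B),
                           n_shared = length(intersect(A, B)),
                           stringsAsFactors = FALSE)
        }
    }
    entries <- DataFrame(do.call(rbind, rows))
    means <- vapply(tissues, function(ti)
        round(mean(entries$similarity[entries$tissue == ti]), 2L),
        numeric(1L))
    if (length(omitted))
        warning("hosts omitted (one substrate unobserved): ",
                paste(omitted, collapse = ", "))
    list(entries = entries, means = means, omitted = omitted)
}

#' Parameters of the inoculum-source rules
#'
#' Numeric reconstruction of the expert annotation rules: how many
#' soil-grown rhizosphere hosts must carry an OTU before a soil origin is
#' credited (\code{soilSupport}); whether sand-grown detection in any
#' tissue of the host counts as seed evidence (\code{crossTissue}, default
#' TRUE since seed carriage is a property of the host's seed lot, not of
#' one tissue); the maximum number of collapsed groups an OTU may occupy
#' dataset-wide before it stops looking like a one-off stochastic
#' propagule (\code{stochasticMaxGroups}); and the biotic-filtering
#' thresholds (high soil-rhizosphere occupancy \code{filterRhizoMin} with
#' low soil-root occupancy \code{filterRootMax}).
#'
#' @param soilSupport Minimum soil-rhizosphere host occupancy for a soil
#'   call (default 2).
#' @param crossTissue Count sand detections in any tissue of the host as
#'   seed evidence (default TRUE)?
#' @param stochasticMaxGroups Dataset-wide group-occurrence ceiling for the
#'   stochastic flag (default 2).
#' @param filterRhizoMin,filterRootMax Biotic-filtering thresholds
#'   (defaults 10 and 4).
#' @return Named list of parameters.
#' @export
transmissionParams <- function(soilSupport = 2L, crossTissue = TRUE,
                               stochasticMaxGroups = 2L,
                               filterRhizoMin = 10L, filterRootMax = 4L) {
    list(soilSupport = as.integer(soilSupport),
         crossTissue = isTRUE(crossTissue),
         stochasticMaxGroups = as.integer(stochasticMaxGroups),
         filterRhizoMin = as.integer(filterRhizoMin),
         filterRootMax = as.integer(filterRootMax))
}

.callEvidence <- function(otu, host, tissue, p, cd, params) {
    hostCols <- cd$host == host
    sandCols <- hostCols & cd$substrate == "sand"
    if (!params$crossTissue)
        sandSeedCols <- sandCols & cd$tissue == tissue
    else sandSeedCols <- sandCols
    soilFocal <- hostCols & cd$substrate == "soil" & cd$tissue == tissue
    list(sandDetections = sum(p[otu, sandSeedCols]),
         anySand = sum(p[otu, sandCols]) > 0L,
         soilDetections = sum(p[otu, hostCols & cd$substrate == "soil"]),
         inSoilFocal = any(p[otu, soilFocal]),
         soilRhizoOccupancy = length(unique(cd$host[
             cd$substrate == "soil" & cd$tissue == "rhizosphere" & p[otu, ]])),
         soilRootOccupancy = length(unique(cd$host[
             cd$substrate == "soil" & cd$tissue == "root" & p[otu, ]])),
         datasetGroups = sum(p[otu, ]))
}

#' Classify the inoculum source of one OTU in one host and tissue
#'
#' Applies the rule reconstruction of the source annotations: the source is
#' \code{"seed"} if the OTU is detected in the host's sterile-sand-grown
#' group (any tissue when \code{params$crossTissue}, else the focal
#' tissue); otherwise \code{"soil"} if it is absent from all the host's
#' sand groups, present in the host's soil-grown focal group, and detected
#' in at least \code{params$soilSupport} soil-grown rhizosphere hosts
#' dataset-wide; otherwise \code{"unknown"}. A soil call is therefore
#' impossible whenever any sand detection exists for the host.
#'
#' @param otu,host,tissue The call coordinates.
#' @param pres A \linkS4class{PresenceMatrix} over collapsed groups.
#' @param params See \code{\link{transmissionParams}}.
#' @return One-row \code{DataFrame} (a transmission call) with the source,
#'   flag placeholders and evidence counts.
#' @export
classifySource <- function(otu, host, tissue, pres,
                           params = transmissionParams()) {
    stopifnot(is(pres, "PresenceMatrix"))
    p <- isPresent(pres); cd <- colData(pres)
    if (!otu %in% rownames(p))
        .err("rt_unknown_otu", paste("OTU not in presence matrix:", otu))
    ev <- .callEvidence(otu, host, tissue, p, cd, params)
    source <- if (ev$sandDetections >= 1L) "seed"
    else if (!ev$anySand && ev$inSoilFocal &&
             ev$soilRhizoOccupancy >= params$soilSupport) "soil"
    else "unknown"
    DataFrame(otu_id = otu, host = host, tissue = tissue, source = source,
              stochastic = NA, biotic_filtered = NA,
              sand_detections = ev$sandDetections,
              soil_detections = ev$soilDetections,
              soil_rhizo_occupancy = ev$soilRhizoOccupancy,
              soil_root_occupancy = ev$soilRootOccupancy,
              dataset_groups = ev$datasetGroups)
}

#' Classify every uncommon OTU detected in soil-grown groups
#'
#' Generates one transmission call per (OTU, host, tissue) where the OTU
#' belongs to the (tissue, soil) compartment's uncommon set (or the
#' whitelist) and is detected in that host's soil-grown group, then
#' annotates the stochastic and biotic-filtering flags.
#'
#' @param pres A \linkS4class{PresenceMatrix} over collapsed groups.
#' @param uncommonSets List of \linkS4class{UncommonSet}s.
#' @param tissues Tissues to call (default shoot, root, rhizosphere).
#' @param params See \code{\link{transmissionParams}}.
#' @param whitelist Extra OTU ids callable even if not screened uncommon.
#' @return \code{DataFrame} of transmission calls.
#' @export
classifyAll <- function(pres, uncommonSets,
                        tissues = c("shoot", "root", "rhizosphere"),
                        params = transmissionParams(),
                        whitelist = character()) {
    stopifnot(is(pres, "PresenceMatrix"))
    p <- isPresent(pres); cd <- colData(pres)
    calls <- list()
    for (ti in tissues) {
        unc <- NULL
        for (u in uncommonSets)
            if (identical(u@tissue, ti) && identical(u@substrate, "soil"))
                unc <- union(uncommonIds(u), whitelist)
        if (is.null(unc)) next
        cols <- which(cd$tissue == ti & cd$substrate == "soil")
        for (j in cols) {
            hits <- intersect(rownames(p)[p[, j]], unc)
            h <- as.character(cd$host[j])
            for (o in hits)
                calls[[length(calls) + 1L]] <-
                    classifySource(o, h, ti, pres, params)
        }
    }
    if (!length(calls))
        return(DataFrame(otu_id = character(), host = character(),
                         tissue = character(), source = character()))
    annotateFlags(do.call(rbind, calls), pres, params)
}

#' Annotate stochastic-inoculum and biotic-filtering flags
#'
#' \code{stochastic} is TRUE when the OTU occurs in at most
#' \code{params$stochasticMaxGroups} collapsed groups dataset-wide (a
#' one-off propagule). \code{biotic_filtered} is TRUE when the OTU occupies
#' at least \code{params$filterRhizoMin} soil-grown rhizosphere hosts while
#' entering at most \code{params$filterRootMax} soil-grown root hosts
#' (abundant outside, excluded inside).
#'
#' @param calls \code{DataFrame} of transmission calls.
#' @param pres The \linkS4class{PresenceMatrix} the calls were made on.
#' @param params See \code{\link{transmissionParams}}.
#' @return The calls with both flag columns filled in.
#' @export
annotateFlags <- function(calls, pres, params = transmissionParams()) {
    stopifnot(is(pres, "PresenceMatrix"))
    p <- isPresent(pres); cd <- colData(pres)
    groupsOf <- rowSums(p)
    rhizoOcc <- vapply(rownames(p), function(o) length(unique(
        cd$host[cd$substrate == "soil" & cd$tissue == "rhizosphere" &
                p[o, ]])), integer(1L))
    rootOcc <- vapply(rownames(p), function(o) length(unique(
        cd$host[cd$substrate == "soil" & cd$tissue == "root" & p[o, ]])),
        integer(1L))
    o <- calls$otu_id
    calls$stochastic <- unname(groupsOf[o] <= params$stochasticMaxGroups)
    calls$biotic_filtered <- unname(rhizoOcc[o] >= params$filterRhizoMin &
                                    rootOcc[o] <= params$filterRootMax)
    calls
}
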