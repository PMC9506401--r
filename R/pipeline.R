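#' @include AllClasses.R
NULL

#' Run the uncommon-microbiome screening pipeline on one table
#'
#' Convenience wrapper chaining the standard stages for one marker:
#' non-target removal, singleton removal, replicate collapsing, relative
#' abundance, presence calling, and the per-compartment occupancy screen
#' over the vegetative tissues on both substrates.
#'
#' @param tab An \linkS4class{OtuTable} with embedded metadata/taxonomy.
#' @param maxHosts Uncommon screen ceiling (default 9).
#' @param threshold Presence threshold in percent (default 0).
#' @param dropNontarget Apply the keyword non-target filter (default TRUE)?
#' @param minTotalReads Singleton filter floor (default 2).
#' @param tissues Vegetative tissues to screen.
#' @return A list: \code{$table} (filtered), \code{$grouped} (collapsed
#'   counts), \code{$rel} (\linkS4class{GroupedAbundance}), \code{$pres}
#'   (\linkS4class{PresenceMatrix} over groups) and \code{$uncommon}
#'   (list of \linkS4class{UncommonSet}, one per tissue x substrate).
#' @export
screenCompartments <- function(tab, maxHosts = 9L, threshold = 0,
                               dropNontarget = TRUE, minTotalReads = 2L,
                               tissues = c("shoot", "root",
                                           "rhizosphere")) {
    stopifnot(is(tab, "OtuTable"))
    if (dropNontarget) {
        flagged <- flagNontarget(taxonomy(tab))
        if (length(flagged)) tab <- removeOtus(tab, flagged)
    }
    tab <- dropSingletons(tab, minTotalReads = minTotalReads)
    grouped <- collapseReplicates(tab)
    rel <- relativeAbundance(grouped)
    pres <- presence(rel, threshold_percent = threshold)
    uncommon <- list()
    for (ti in tissues)
        for (su in c("sand", "soil")) {
            if (!length(.compartmentCols(pres, ti, su))) next
            occ <- speciesOccupancy(pres, tissue = ti, substrate = su)
            uncommon[[paste(ti, su, sep = "|")]] <-
                screenUncommon(occ, maxHosts = maxHosts)
        }
    list(table = tab, grouped = grouped, rel = rel, pres = pres,
         uncommon = uncommon)
}

#' Published per-host substrate-similarity reference table
#'
#' The reference table of per-host Sorensen similarities between the
#' uncommon OTU sets of soil- and sand-grown plants (17 hosts; fungal and
#' bacterial columns for rhizosphere, roots and shoots) shipped with the
#' package for validating the column-mean computation.
#'
#' @return A \code{data.frame} with a \code{host} column and six
#'   similarity columns.
#' @export
referenceSimilarity <- function() {
    path <- system.file("extdata", "substrate_similarity_reference.tsv",
                        package = "rareTransmit", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Column means of a per-host similarity table
#'
#' Arithmetic mean over hosts of each similarity column, reported to two
#' decimals (the precision the per-host entries carry).
#'
#' @param df A \code{data.frame} as returned by
#'   \code{\link{referenceSimilarity}}.
#' @return Named numeric vector of rounded column means.
#' @export
similarityColumnMeans <- function(df = referenceSimilarity()) {
    num <- vapply(df, is.numeric, logical(1L))
    round(colMeans(df[, num, drop = FALSE]), 2L)
}
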