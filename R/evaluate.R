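#' @include AllClasses.R
NULL

#' Score transmission calls against simulated ground truth
#'
#' Standard confusion accounting of per-call predicted source versus the
#' true source of the OTU's class (seed / soil / unknown). OTUs present in
#' the truth but never reaching a call (screened out, or undetected in
#' soil-grown groups) are reported separately as unscreened, never counted
#' against precision or recall.
#'
#' @param calls \code{DataFrame} of transmission calls (see
#'   \code{\link{classifyAll}}).
#' @param truth The \code{$truth} element of an \code{rtSimulation} (or
#'   its \code{classes} table).
#' @return A list: \code{$confusion} (3 x 3 table, rows = truth),
#'   \code{$perClass} (\code{DataFrame} of precision, recall, F1 per
#'   source), \code{$accuracy} (fraction of calls whose source matches the
#'   truth) and \code{$unscreened} (OTU ids never called).
#' @export
evaluateCalls <- function(calls, truth) {
    classes <- if (!is.null(truth$classes)) truth$classes else truth
    if (!all(c("otu_id", "source") %in% colnames(classes)))
        .err("rt_bad_input", "truth must have otu_id and source columns")
    bad <- setdiff(calls$otu_id, classes$otu_id)
    if (length(bad))
        .err("rt_universe_mismatch",
             paste("calls contain OTUs absent from the truth:",
                   paste(utils::head(bad, 5L), collapse = ", ")))
    lev <- c("seed", "soil", "unknown")
    trueOf <- stats::setNames(classes$source, classes$otu_id)
    actual <- factor(unname(trueOf[calls$otu_id]), levels = lev)
    predicted <- factor(calls$source, levels = lev)
    confusion <- table(truth = actual, call = predicted)
    perClass <- DataFrame(
        source = lev,
        precision = unname(vapply(lev, function(cl) {
            tp <- confusion[cl, cl]; fp <- sum(confusion[, cl]) - tp
            if (tp + fp == 0) NA_real_ else tp / (tp + fp)
        }, numeric(1L))),
        recall = unname(vapply(lev, function(cl) {
            tp <- confusion[cl, cl]; fn <- sum(confusion[cl, ]) - tp
            if (tp + fn == 0) NA_real_ else tp / (tp + fn)
        }, numeric(1L))))
    perClass$F1 <- ifelse(
        is.na(perClass$precision) | is.na(perClass$recall) |
            (perClass$precision + perClass$recall) == 0, NA_real_,
        2 * perClass$precision * perClass$recall /
            (perClass$precision + perClass$recall))
    list(confusion = confusion, perClass = perClass,
         accuracy = if (nrow(calls)) sum(diag(confusion)) / nrow(calls)
                    else NA_real_,
         unscreened = setdiff(classes$otu_id, calls$otu_id))
}

#' Closed-form expected host occupancy of an OTU class
#'
#' Analytic expectations under the generative model, used as the oracle
#' for law-of-large-numbers checks of the simulator. For
#' \code{rare_seed_stochastic} the per-host carriage probability is
#' \code{pSeedCarriage}, so expected occupancy is \code{H * pSeedCarriage};
#' for \code{soil_rare}, per-jar presence probability is
#' \code{1 - exp(-lambdaSoil)} and a host (with R replicate jars) is
#' occupied with probability \code{1 - exp(-R * lambdaSoil)}.
#'
#' @param class One of the simulator's OTU classes.
#' @param config A \linkS4class{SimulationConfig}.
#' @return A list: \code{$p_unit} (per seed-lot or per-jar presence
#'   probability) and \code{$expected_hosts} (expected host occupancy).
#' @export
#' @examples
#' expectedOccupancy("soil_rare",
#'                   simulationConfig(lambdaSoil = 0.5))$p_unit
#' # 1 - exp(-0.5), about 0.393
expectedOccupancy <- function(class, config = simulationConfig()) {
    class <- match.arg(class, .OTU_CLASSES)
    H <- length(config@hosts); R <- config@replicates
    switch(class,
           core_seed = list(p_unit = 1, expected_hosts = H),
           rare_seed_deterministic = list(
               p_unit = config@hostsPerDeterministicSeed / H,
               expected_hosts = min(config@hostsPerDeterministicSeed, H)),
           rare_seed_stochastic = list(
               p_unit = config@pSeedCarriage,
               expected_hosts = H * config@pSeedCarriage),
           soil_common = list(p_unit = 1, expected_hosts = H),
           soil_rare = {
               pJar <- 1 - exp(-config@lambdaSoil)
               pHost <- 1 - exp(-R * config@lambdaSoil)
               list(p_unit = pJar, expected_hosts = H * pHost)
           },
           host_specialist = list(p_unit = 1 / H, expected_hosts = 1),
           contaminant = list(p_unit = NA_real_, expected_hosts = 1))
}

#' Empirical host occupancy of each OTU from simulation truth
#'
#' Counts, per OTU of one class, the distinct hosts with at least one
#' inoculation event (restricted to soil-grown rhizospheres for the soil
#' classes, matching the unit of the closed-form expectation).
#'
#' @param truth The \code{$truth} of an \code{rtSimulation}.
#' @param class OTU class to tabulate.
#' @return Named integer vector: hosts occupied per OTU (zero-occupancy
#'   OTUs included).
#' @export
empiricalOccupancy <- function(truth, class) {
    class <- match.arg(class, .OTU_CLASSES)
    ids <- truth$classes$otu_id[truth$classes$class == class]
    ev <- truth$events
    if (class %in% c("soil_common", "soil_rare"))
        ev <- ev[ev$tissue == "rhizosphere" & ev$substrate == "soil", ,
                 drop = FALSE]
    occ <- stats::setNames(integer(length(ids)), ids)
    ev <- ev[ev$otu_id %in% ids, , drop = FALSE]
    if (nrow(ev)) {
        tab <- table(unique(data.frame(otu = ev$otu_id,
                                       host = ev$host))$otu)
        occ[names(tab)] <- as.integer(tab)
    }
    occ
}
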