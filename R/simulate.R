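#' @include AllClasses.R
NULL

#' Build a simulation configuration
#'
#' Parameters of the generative model for synthetic multi-host, multi-
#' compartment OTU tables with known transmission structure. Propagule
#' arrival of rare soil microbes into jars is Poisson (sparse inoculum
#' unevenly split into jars); seed carriage is a per-host (seed-lot)
#' Bernoulli; root entry of soil microbes is gated by a per host x OTU
#' biotic filter. Read depths are log-normal, clipped to [depthMin,
#' depthMax]; reads are drawn multinomially at the sampled depth.
#'
#' @param hosts Host panel (default \code{\link{defaultHosts}()}).
#' @param replicates Jars per host x substrate (default 3).
#' @param seedReplicates Seed and spermosphere samples per host (default 2).
#' @param classSizes Named integer vector of OTU counts per class:
#'   \code{core_seed}, \code{rare_seed_deterministic},
#'   \code{rare_seed_stochastic}, \code{soil_common}, \code{soil_rare},
#'   \code{host_specialist}, \code{contaminant}.
#' @param pSeedCarriage Per-host Bernoulli probability that a seed lot
#'   carries a \code{rare_seed_stochastic} OTU (default 0.3).
#' @param lambdaSoil Mean Poisson propagule count per jar for
#'   \code{soil_rare} OTUs (default 0.5; \code{Inf} = saturated inoculum).
#' @param rootFilterProb Probability that a host's root excludes a given
#'   soil OTU (default 0.3).
#' @param hostsPerDeterministicSeed Hosts carrying each
#'   \code{rare_seed_deterministic} OTU (default 3).
#' @param abundMeanlog,abundSdlog Log-normal base-abundance parameters
#'   (defaults 0 and 1.5: a heavy-tailed community).
#' @param depthMeanlog,depthSdlog,depthMin,depthMax Log-normal read-depth
#'   parameters; defaults log(8000), 1, 10 and 80000 reads.
#' @param sampling \code{"multinomial"} (default) or \code{"expected"}
#'   (deterministic expected counts, >= 1 read per inoculated OTU - the
#'   no-sampling-noise regime).
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(hosts = defaultHosts(), replicates = 3L,
                             seedReplicates = 2L,
                             classSizes = c(core_seed = 6L,
                                            rare_seed_deterministic = 12L,
                                            rare_seed_stochastic = 25L,
                                            soil_common = 12L,
                                            soil_rare = 35L,
                                            host_specialist = 8L,
                                            contaminant = 6L),
                             pSeedCarriage = 0.3, lambdaSoil = 0.5,
                             rootFilterProb = 0.3,
                             hostsPerDeterministicSeed = 3L,
                             abundMeanlog = 0, abundSdlog = 1.5,
                             depthMeanlog = log(8000), depthSdlog = 1,
                             depthMin = 10, depthMax = 80000,
                             sampling = c("multinomial", "expected")) {
    full <- stats::setNames(integer(length(.OTU_CLASSES)), .OTU_CLASSES)
    full[names(classSizes)] <- as.integer(classSizes)
    new("SimulationConfig", hosts = hosts,
        replicates = as.integer(replicates),
        seedReplicates = as.integer(seedReplicates), classSizes = full,
        pSeedCarriage = pSeedCarriage, lambdaSoil = lambdaSoil,
        rootFilterProb = rootFilterProb,
        hostsPerDeterministicSeed = as.integer(hostsPerDeterministicSeed),
        abundMeanlog = abundMeanlog, abundSdlog = abundSdlog,
        depthMeanlog = depthMeanlog, depthSdlog = depthSdlog,
        depthMin = depthMin, depthMax = depthMax,
        sampling = match.arg(sampling))
}

#' Deterministic-regime configuration
#'
#' The limiting regime with every stochastic channel off: certain seed
#' carriage (p = 1), saturated soil inoculum (lambda = Inf), no biotic
#' filtering and expected (non-multinomial) read counts with at least one
#' read per inoculated OTU. In this regime the pipeline plus classifier
#' recover the true source of every uncommon OTU.
#'
#' @param ... Overrides passed to \code{\link{simulationConfig}}.
#' @return A \linkS4class{SimulationConfig}.
#' @export
deterministicConfig <- function(...) {
    args <- list(pSeedCarriage = 1, lambdaSoil = Inf, rootFilterProb = 0,
                 sampling = "expected", depthMin = 2000)
    override <- list(...)
    args[names(override)] <- override
    do.call(simulationConfig, args)
}

.classSource <- c(core_seed = "seed", rare_seed_deterministic = "seed",
                  rare_seed_stochastic = "seed", soil_common = "soil",
                  soil_rare = "soil", host_specialist = "seed",
                  contaminant = "unknown")

.PHYLA <- list(
    "ITS" = c(Ascomycota = 0.55, Basidiomycota = 0.3,
              Mortierellomycota = 0.05, Glomeromycota = 0.05,
              Chytridiomycota = 0.05),
    "16S" = c(Proteobacteria = 0.45, Firmicutes = 0.2,
              Bacteroidetes = 0.15, Actinobacteria = 0.1,
              Cyanobacteria = 0.1))

.expectedCounts <- function(depth, w) {
    n <- length(w)
    depth <- max(depth, n)
    cnt <- pmax(1L, as.integer(round(depth * w / sum(w))))
    diff <- as.integer(depth) - sum(cnt)
    while (diff != 0L) {
        if (diff > 0L) {
            i <- which.max(cnt); cnt[i] <- cnt[i] + diff; diff <- 0L
        } else {
            i <- which.max(cnt)
            take <- min(-diff, cnt[i] - 1L)
            cnt[i] <- cnt[i] - take; diff <- diff + take
            if (take == 0L) break  # cannot reduce further
        }
    }
    cnt
}

.simulateMarker <- function(config, mk) {
    hosts <- config@hosts; H <- length(hosts); R <- config@replicates
    prefix <- if (mk == "16S") "BactOTU" else "FungOTU"

    # sample frame: jar tissues x substrates x reps, plus seed/spermosphere
    jarGrid <- expand.grid(replicate = seq_len(R),
                           tissue = c("shoot", "root", "rhizosphere"),
                           substrate = c("sand", "soil"), host = hosts,
                           stringsAsFactors = FALSE)
    seedGrid <- expand.grid(replicate = seq_len(config@seedReplicates),
                            tissue = .SEEDLIKE, substrate = "none",
                            host = hosts, stringsAsFactors = FALSE)
    samp <- rbind(jarGrid, seedGrid)
    samp$sample_id <- sprintf("%s_%s_%s_%s_r%d", mk, samp$host, samp$tissue,
                              samp$substrate, samp$replicate)
    nS <- nrow(samp)
    hostIdx <- match(samp$host, hosts)

    sizes <- config@classSizes
    nOtu <- sum(sizes)
    classOf <- rep(names(sizes), sizes)
    otuIds <- sprintf("%s%03d", prefix, seq_len(nOtu))
    baseAbund <- stats::rlnorm(nOtu, config@abundMeanlog, config@abundSdlog)

    rowsOf <- function(cl) which(classOf == cl)

    # per-host seed-lot carriage (nOtu x H); FALSE outside seed classes
    carry <- matrix(FALSE, nOtu, H)
    carry[rowsOf("core_seed"), ] <- TRUE
    for (o in rowsOf("rare_seed_deterministic"))
        carry[o, sample.int(H, min(config@hostsPerDeterministicSeed, H))] <- TRUE
    rs <- rowsOf("rare_seed_stochastic")
    if (length(rs))
        carry[rs, ] <- matrix(
            stats::runif(length(rs) * H) < config@pSeedCarriage,
            length(rs), H)
    hs <- rowsOf("host_specialist")
    for (k in seq_along(hs))
        carry[hs[k], ((k - 1L) %% H) + 1L] <- TRUE

    # root biotic filter for soil classes (nOtu x H)
    soilRows <- c(rowsOf("soil_common"), rowsOf("soil_rare"))
    filt <- matrix(FALSE, nOtu, H)
    if (length(soilRows))
        filt[soilRows, ] <- matrix(
            stats::runif(length(soilRows) * H) < config@rootFilterProb,
            length(soilRows), H)

    # Poisson propagules per soil jar for soil_rare (jar = host x rep)
    jars <- expand.grid(replicate = seq_len(R), host = hosts,
                        stringsAsFactors = FALSE)
    nJ <- nrow(jars)
    sr <- rowsOf("soil_rare")
    K <- matrix(0L, nOtu, nJ)
    if (length(sr)) {
        K[sr, ] <- if (is.infinite(config@lambdaSoil))
            matrix(1L, length(sr), nJ)
        else matrix(stats::rpois(length(sr) * nJ, config@lambdaSoil),
                    length(sr), nJ)
    }
    jarIdx <- ifelse(samp$substrate == "soil",
                     match(paste(samp$host, samp$replicate),
                           paste(jars$host, jars$replicate)), NA_integer_)

    # presence (inoculation) matrix
    P <- matrix(FALSE, nOtu, nS, dimnames = list(otuIds, samp$sample_id))
    seedRows <- which(.classSource[classOf] == "seed")
    if (length(seedRows))
        P[seedRows, ] <- carry[seedRows, hostIdx, drop = FALSE]
    sc <- rowsOf("soil_common")
    soilRhizo <- samp$substrate == "soil" & samp$tissue == "rhizosphere"
    soilRoot <- samp$substrate == "soil" & samp$tissue == "root"
    if (length(sc)) {
        P[sc, soilRhizo] <- TRUE
        P[sc, soilRoot] <- !filt[sc, hostIdx[soilRoot], drop = FALSE]
    }
    if (length(sr)) {
        inoc <- K[sr, , drop = FALSE] >= 1L
        P[sr, soilRhizo] <- inoc[, jarIdx[soilRhizo], drop = FALSE]
        P[sr, soilRoot] <- inoc[, jarIdx[soilRoot], drop = FALSE] &
            !filt[sr, hostIdx[soilRoot], drop = FALSE]
    }
    ct <- rowsOf("contaminant")
    for (o in ct) P[o, sample.int(nS, 1L)] <- TRUE

    # read depths and counts
    depths <- as.integer(round(pmin(pmax(
        stats::rlnorm(nS, config@depthMeanlog, config@depthSdlog),
        config@depthMin), config@depthMax)))
    counts <- matrix(0L, nOtu, nS, dimnames = dimnames(P))
    for (s in seq_len(nS)) {
        idx <- which(P[, s])
        if (!length(idx)) { depths[s] <- 0L; next }
        w <- baseAbund[idx]
        if (config@sampling == "multinomial") {
            w <- w * stats::rlnorm(length(idx), 0, 0.5)
            counts[idx, s] <- as.integer(stats::rmultinom(1L, depths[s], w))
        } else {
            cnt <- .expectedCounts(depths[s], w)
            counts[idx, s] <- cnt
            depths[s] <- sum(cnt)
        }
    }

    # taxonomy labels
    probs <- .PHYLA[[mk]]
    tax <- DataFrame(otu_id = otuIds,
                     kingdom = if (mk == "16S") "Bacteria" else "Fungi",
                     phylum = sample(names(probs), nOtu, replace = TRUE,
                                     prob = probs),
                     genus = sprintf("Genus%02d",
                                     sample.int(40L, nOtu, replace = TRUE)),
                     nontarget = FALSE, row.names = otuIds)

    meta <- DataFrame(sample_id = samp$sample_id, host = samp$host,
                      tissue = samp$tissue, substrate = samp$substrate,
                      replicate = as.integer(samp$replicate),
                      depth = depths, row.names = samp$sample_id)
    tab <- OtuTable(counts, marker = mk, sampleData = meta, taxonomy = tax)

    ev <- which(P, arr.ind = TRUE)
    events <- DataFrame(otu_id = otuIds[ev[, 1L]],
                        marker = rep(mk, nrow(ev)),
                        host = samp$host[ev[, 2L]],
                        tissue = samp$tissue[ev[, 2L]],
                        substrate = samp$substrate[ev[, 2L]],
                        replicate = as.integer(samp$replicate[ev[, 2L]]))
    fi <- which(filt, arr.ind = TRUE)
    filtering <- DataFrame(otu_id = otuIds[fi[, 1L]],
                           marker = rep(mk, nrow(fi)),
                           host = hosts[fi[, 2L]],
                           filtered = rep(TRUE, nrow(fi)))
    classes <- DataFrame(otu_id = otuIds, marker = mk, class = classOf,
                         source = unname(.classSource[classOf]),
                         row.names = otuIds)
    list(table = tab, classes = classes, events = events,
         filtering = filtering)
}

#' Simulate a multi-host community with ground-truth transmission labels
#'
#' Generates, for each requested marker, a full OTU count table (all hosts,
#' jar tissues on both substrates plus seed and spermosphere samples, with
#' embedded metadata and taxonomy) together with the ground truth: each
#' OTU's class and source, every per-sample inoculation event, and the
#' per host x OTU biotic-filtering outcomes. Deterministic given
#' \code{seed}: the same seed yields bit-identical output. Every nonzero
#' count traces to an inoculation event.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param markers Markers to simulate (independent OTU pools).
#' @param seed Integer RNG seed.
#' @return A list of class \code{rtSimulation}: \code{$tables} (named list
#'   of \linkS4class{OtuTable}), \code{$truth} (list with \code{classes},
#'   \code{events}, \code{filtering}), \code{$config}, \code{$seed}.
#' @export
#' @examples
#' sim <- simulateCommunity(simulationConfig(), markers = "ITS", seed = 1)
#' sim$tables$ITS
simulateCommunity <- function(config = simulationConfig(),
                              markers = c("16S", "ITS"), seed = 1L) {
    validObject(config)
    markers <- match.arg(markers, .MARKERS, several.ok = TRUE)
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(as.integer(seed))
    parts <- lapply(markers, function(mk) .simulateMarker(config, mk))
    names(parts) <- markers
    out <- list(tables = lapply(parts, `[[`, "table"),
                truth = list(
                    classes = do.call(rbind,
                                      lapply(parts, `[[`, "classes")),
                    events = do.call(rbind, lapply(parts, `[[`, "events")),
                    filtering = do.call(rbind,
                                        lapply(parts, `[[`, "filtering"))),
                config = config, seed = as.integer(seed))
    class(out) <- "rtSimulation"
    out
}

#' @export
print.rtSimulation <- function(x, ...) {
    cat("rtSimulation:", paste(names(x$tables), collapse = " + "),
        "| seed", x$seed, "\n")
    for (mk in names(x$tables)) {
        t <- x$tables[[mk]]
        cat(sprintf("  %s: %d OTUs x %d samples, %d reads\n", mk,
                    nrow(t), ncol(t), totalReads(t)))
    }
    invisible(x)
}
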