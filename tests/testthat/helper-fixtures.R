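suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

# Presence matrix over collapsed groups, built directly for white-box tests.
makePres <- function(m, host, tissue, substrate, threshold = 0) {
    cd <- DataFrame(host = host, tissue = tissue, substrate = substrate,
                    row.names = colnames(m))
    se <- SummarizedExperiment(assays = list(presence = m), colData = cd,
                               metadata = list(marker = "ITS",
                                               threshold_percent = threshold))
    new("PresenceMatrix", se)
}

# Grouped relative-abundance container from a percent matrix.
makeRel <- function(m, host, tissue, substrate) {
    cd <- DataFrame(host = host, tissue = tissue, substrate = substrate,
                    empty = colSums(m) == 0, row.names = colnames(m))
    se <- SummarizedExperiment(assays = list(relabund = m), colData = cd,
                               metadata = list(marker = "ITS"))
    new("GroupedAbundance", se)
}

makeUncommon <- function(ids, universe = ids, tissue = "root",
                         substrate = "soil") {
    new("UncommonSet", tissue = tissue, substrate = substrate,
        otuIds = ids, universe = universe, params = list())
}

# Small replicated jar experiment: 2 hosts x 2 tissues x 2 substrates x 2 reps.
tinyExperiment <- function(seed = 42, nOtu = 6L) {
    set.seed(seed)
    grid <- expand.grid(replicate = 1:2, tissue = c("root", "shoot"),
                        substrate = c("sand", "soil"),
                        host = c("Maize", "Rice"), stringsAsFactors = FALSE)
    grid$sample_id <- sprintf("s%02d", seq_len(nrow(grid)))
    counts <- matrix(rpois(nOtu * nrow(grid), 20), nOtu, nrow(grid),
                     dimnames = list(sprintf("OTU%d", seq_len(nOtu)),
                                     grid$sample_id))
    meta <- DataFrame(grid, row.names = grid$sample_id)
    OtuTable(counts, marker = "ITS", sampleData = meta)
}

writeTsv <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(lines, tf)
    tf
}
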