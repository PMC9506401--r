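Package: rareTransmit
Title: Occupancy Screening and Seed/Soil Source Classification for the
    Rare Plant Microbiome
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the uncommon (low host-occupancy)
    fraction of multi-host plant microbiome surveys. Reads and validates
    amplicon OTU count tables (bacterial 16S and fungal ITS) with
    per-sample metadata and per-OTU taxonomy, applies table-hygiene
    filters (non-target removal, singleton removal), collapses replicates
    and derives relative-abundance and presence matrices. Screens OTUs by
    host-species occupancy and peak abundance, quantifies vertical (seed)
    versus horizontal (soil) transmission with Sorensen presence-absence
    similarity between sterile-sand- and field-soil-grown plants, and
    classifies each uncommon OTU's inoculum source (seed, soil or
    unknown) with stochastic-inoculum and biotic-filtering flags.
    Includes descriptive summaries (phylum roll-ups, richness, binary
    PCA, Bray-Curtis-ordered heatmap binning) and a synthetic multi-host
    community generator with ground-truth transmission labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    biomformat,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'evaluate.R'
    'pipeline.R'
    'preprocess.R'
    'rarity.R'
    'simulate.R'
    'summaries.R'
    'tables_io.R'
    'transmission.R'
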