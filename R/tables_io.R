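#' @include AllClasses.R
NULL

# Canonical on-disk layout: samples as rows, OTUs as columns, tab-separated,
# UTF-8, first column `sample_id`. The loaders transpose into the
# OTU-per-row orientation every Bioconductor container uses.

#' Read an OTU count table
#'
#' Reads a tab-separated count table (samples as rows, OTU ids as column
#' headers, first column \code{sample_id}) or a BIOM 2.x file into a
#' validated \linkS4class{OtuTable}. Cells must be non-negative integers;
#' offending cells are reported by sample and OTU id.
#'
#' @param path Path to the file.
#' @param marker \code{"16S"} or \code{"ITS"}; carried on the table, and
#'   tables of different markers are never merged.
#' @param dialect \code{"tsv"} (default) or \code{"biom"} (requires the
#'   \pkg{biomformat} package).
#' @return An \linkS4class{OtuTable}.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tOTU1\tOTU2", "s1\t0\t5", "s2\t3\t1"), tf)
#' tab <- loadCounts(tf, marker = "16S")
#' totalReads(tab)  # 9
loadCounts <- function(path, marker = c("16S", "ITS"),
                       dialect = c("tsv", "biom")) {
    marker <- match.arg(marker)
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        .err("rt_missing_file", paste("file not found:", path))
    if (dialect == "biom") {
        if (!requireNamespace("biomformat", quietly = TRUE))
            .err("rt_missing_dependency",
                 "the 'biomformat' package is required for dialect = 'biom'")
        b <- biomformat::read_biom(path)
        m <- as.matrix(biomformat::biom_data(b))  # OTUs x samples
        storage.mode(m) <- "double"
        .checkCells(m, otuAxis = "rows")
        storage.mode(m) <- "integer"
        return(OtuTable(m, marker = marker))
    }
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (ncol(df) < 2L)
        .err("rt_bad_layout",
             "count TSV needs a sample_id column plus >= 1 OTU column")
    sampleIds <- as.character(df[[1L]])
    if (anyDuplicated(sampleIds))
        .err("rt_duplicate_ids", "duplicate sample ids in count table")
    otuIds <- colnames(df)[-1L]
    if (anyDuplicated(otuIds))
        .err("rt_duplicate_ids", "duplicate OTU ids in count table")
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        .err("rt_bad_counts", "count table contains non-numeric cells")
    rownames(m) <- sampleIds
    .checkCells(m, otuAxis = "cols")
    m <- t(m)
    storage.mode(m) <- "integer"
    OtuTable(m, marker = marker)
}

.checkCells <- function(m, otuAxis) {
    bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
    if (nrow(bad)) {
        i <- bad[1L, 1L]; j <- bad[1L, 2L]
        samp <- if (otuAxis == "cols") rownames(m)[i] else colnames(m)[j]
        otu  <- if (otuAxis == "cols") colnames(m)[j] else rownames(m)[i]
        .err("rt_bad_counts",
             sprintf("invalid count (negative, NA or non-integer) at sample '%s', OTU '%s'",
                     samp, otu))
    }
    invisible(TRUE)
}

#' Write an OTU count table in the canonical TSV layout
#'
#' Samples as rows, OTUs as columns; round-trips bit-exactly through
#' \code{\link{loadCounts}}.
#'
#' @param x An \linkS4class{OtuTable}.
#' @param path Output path.
#' @param dialect \code{"tsv"} or \code{"biom"}.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(x, path, dialect = c("tsv", "biom")) {
    stopifnot(is(x, "OtuTable"))
    dialect <- match.arg(dialect)
    m <- otuCounts(x)
    if (dialect == "biom") {
        if (!requireNamespace("biomformat", quietly = TRUE))
            .err("rt_missing_dependency",
                 "the 'biomformat' package is required for dialect = 'biom'")
        biomformat::write_biom(biomformat::make_biom(m), path)
        return(invisible(path))
    }
    df <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read per-sample metadata
#'
#' Expects columns \code{sample_id}, \code{host}, \code{tissue},
#' \code{substrate}, \code{replicate}. Tissues must be one of shoot, root,
#' rhizosphere, seed, spermosphere or control; seed and spermosphere rows
#' must have substrate \code{none}. Unknown host names are rejected unless
#' \code{hosts} is empty (permissive mode).
#'
#' @param path Path to a tab-separated metadata file.
#' @param hosts Character vector of allowed host names
#'   (default \code{\link{defaultHosts}()}); \code{character()} disables the
#'   check.
#' @return A \code{DataFrame} keyed by \code{sample_id}.
#' @export
loadMetadata <- function(path, hosts = defaultHosts()) {
    if (!file.exists(path))
        .err("rt_missing_file", paste("file not found:", path))
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    need <- c("sample_id", "host", "tissue", "substrate", "replicate")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        .err("rt_missing_columns",
             paste("metadata is missing column(s):",
                   paste(miss, collapse = ", ")))
    if (anyDuplicated(df$sample_id))
        .err("rt_duplicate_ids", "duplicate sample_id in metadata")
    .checkMetadataEnums(df, hosts = hosts)
    out <- DataFrame(df[, need], row.names = df$sample_id)
    out$replicate <- as.integer(out$replicate)
    out
}

#' Read per-OTU taxonomy annotations
#'
#' Expects a column \code{otu_id} plus any prefix chain of the seven-rank
#' hierarchy (\code{kingdom}, \code{phylum}, \code{class}, \code{order},
#' \code{family}, \code{genus}); an optional logical \code{nontarget}
#' column is carried through (defaulting to \code{FALSE}).
#'
#' @param path Path to a tab-separated taxonomy file.
#' @return A \code{DataFrame} keyed by \code{otu_id}.
#' @export
loadTaxonomy <- function(path) {
    if (!file.exists(path))
        .err("rt_missing_file", paste("file not found:", path))
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    if (!"otu_id" %in% colnames(df))
        .err("rt_missing_columns", "taxonomy is missing column otu_id")
    if (anyDuplicated(df$otu_id))
        .err("rt_duplicate_ids", "duplicate otu_id in taxonomy")
    ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
    have <- intersect(ranks, colnames(df))
    # ranks must be a prefix chain of the hierarchy
    if (length(have) && !identical(have, ranks[seq_along(have)]))
        .err("rt_bad_ranks",
             paste("taxonomy ranks must be a prefix chain of",
                   paste(ranks, collapse = " > ")))
    if (!"nontarget" %in% colnames(df))
        df$nontarget <- FALSE
    DataFrame(df, row.names = df$otu_id)
}

#' Attach metadata and taxonomy to a count table
#'
#' Subsets and orders external metadata/taxonomy to the table's samples and
#' OTUs and embeds them (colData/rowData). Missing rows are an error; use
#' \code{\link{validateDataset}} first to find them.
#'
#' @param x An \linkS4class{OtuTable}.
#' @param meta \code{DataFrame} from \code{\link{loadMetadata}}.
#' @param tax \code{DataFrame} from \code{\link{loadTaxonomy}}, or NULL.
#' @return The annotated \linkS4class{OtuTable}.
#' @export
attachAnnotations <- function(x, meta, tax = NULL) {
    stopifnot(is(x, "OtuTable"))
    miss <- setdiff(colnames(x), rownames(meta))
    if (length(miss))
        .err("rt_missing_metadata",
             paste("samples without metadata:", paste(miss, collapse = ", ")))
    if (!is.null(tax)) {
        miss <- setdiff(rownames(x), rownames(tax))
        if (length(miss))
            .err("rt_missing_taxonomy",
                 paste("OTUs without taxonomy:", paste(miss, collapse = ", ")))
    }
    OtuTable(otuCounts(x), marker = marker(x),
             sampleData = meta[colnames(x), , drop = FALSE],
             taxonomy = if (is.null(tax)) NULL else
                 tax[rownames(x), , drop = FALSE])
}

#' Cross-check counts, metadata and taxonomy for consistency
#'
#' Reports (never raises): samples lacking metadata, OTUs lacking taxonomy,
#' empty samples (zero total reads), and host x tissue x substrate groups
#' with fewer than the configured number of replicates. An empty report
#' means the dataset is fully consistent. The check is read-only and
#' idempotent.
#'
#' @param counts An \linkS4class{OtuTable}.
#' @param meta \code{DataFrame} of sample metadata (rownames = sample ids).
#' @param tax \code{DataFrame} of taxonomy (rownames = OTU ids), or NULL to
#'   skip the taxonomy check.
#' @param replicates Expected replicates per jar group (default 3).
#' @return A list of class \code{rtValidationReport} with elements
#'   \code{samples_without_metadata}, \code{otus_without_taxonomy},
#'   \code{empty_samples}, \code{underreplicated_groups} and the logical
#'   \code{consistent}.
#' @export
validateDataset <- function(counts, meta, tax = NULL, replicates = 3L) {
    stopifnot(is(counts, "OtuTable"))
    m <- otuCounts(counts)
    noMeta <- setdiff(colnames(m), rownames(meta))
    noTax <- if (is.null(tax)) character() else
        setdiff(rownames(m), rownames(tax))
    empty <- colnames(m)[colSums(m) == 0L]
    metaIn <- meta[intersect(rownames(meta), colnames(m)), , drop = FALSE]
    jar <- metaIn[!metaIn$tissue %in% c(.SEEDLIKE, "control"), , drop = FALSE]
    under <- data.frame(host = character(), tissue = character(),
                        substrate = character(), n = integer())
    if (nrow(jar)) {
        tab <- as.data.frame(table(host = jar$host, tissue = jar$tissue,
                                   substrate = jar$substrate),
                             stringsAsFactors = FALSE)
        tab <- tab[tab$Freq > 0L & tab$Freq < replicates, , drop = FALSE]
        under <- data.frame(host = tab$host, tissue = tab$tissue,
                            substrate = tab$substrate, n = tab$Freq)
    }
    rep <- list(samples_without_metadata = noMeta,
                otus_without_taxonomy = noTax,
                empty_samples = empty,
                underreplicated_groups = under)
    rep$consistent <- !length(noMeta) && !length(noTax) && !length(empty) &&
        !nrow(under)
    class(rep) <- "rtValidationReport"
    rep
}

#' @export
print.rtValidationReport <- function(x, ...) {
    if (x$consistent) {
        cat("Dataset consistent: no issues found.\n")
        return(invisible(x))
    }
    .sec <- function(label, v) {
        if (length(v))
            cat(label, ": ", paste(v, collapse = ", "), "\n", sep = "")
    }
    .sec("Samples without metadata", x$samples_without_metadata)
    .sec("OTUs without taxonomy", x$otus_without_taxonomy)
    .sec("Empty samples", x$empty_samples)
    if (nrow(x$underreplicated_groups)) {
        cat("Under-replicated groups:\n")
        print(x$underreplicated_groups)
    }
    invisible(x)
}
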