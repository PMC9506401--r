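#' @include AllClasses.R
NULL

#' Phylum roll-up of uncommon OTUs in one compartment
#'
#' Tallies, per phylum, the number of uncommon OTUs detected in at least
#' one host of the compartment (union across hosts), and the mean (over
#' hosts) summed relative read abundance those OTUs contribute. OTUs
#' without a phylum are bucketed as \code{"unclassified"}.
#'
#' @param rel A \linkS4class{GroupedAbundance}.
#' @param uncommon The compartment's \linkS4class{UncommonSet}.
#' @param tax Taxonomy \code{DataFrame} with a \code{phylum} column
#'   (default: the taxonomy embedded in \code{rel}).
#' @return A list: \code{$phyla} (\code{DataFrame} of phylum,
#'   \code{n_uncommon_otus}, \code{mean_read_percent}),
#'   \code{$n_uncommon}, \code{$n_total} (OTUs detected in the
#'   compartment) and \code{$percent_uncommon_of_total}.
#' @export
phylumRollup <- function(rel, uncommon, tax = taxonomy(rel)) {
    stopifnot(is(rel, "GroupedAbundance"), is(uncommon, "UncommonSet"))
    cols <- .compartmentCols(rel, uncommon@tissue, uncommon@substrate)
    if (!length(cols))
        .err("rt_empty_compartment", "compartment selects zero groups")
    m <- relAbundance(rel)[, cols, drop = FALSE]
    detected <- rownames(m)[rowSums(m > 0) > 0L]
    unc <- intersect(uncommonIds(uncommon), detected)
    phylumOf <- rep("unclassified", nrow(m))
    names(phylumOf) <- rownames(m)
    if (!is.null(tax) && "phylum" %in% colnames(tax)) {
        ph <- as.character(tax[rownames(m), "phylum"])
        ok <- !is.na(ph) & nzchar(ph)
        phylumOf[ok] <- ph[ok]
    }
    if (!length(unc)) {
        return(list(phyla = DataFrame(phylum = character(),
                                      n_uncommon_otus = integer(),
                                      mean_read_percent = numeric()),
                    n_uncommon = 0L, n_total = length(detected),
                    percent_uncommon_of_total = 0))
    }
    phyla <- sort(unique(phylumOf[unc]))
    nOtus <- vapply(phyla, function(ph) sum(phylumOf[unc] == ph),
                    integer(1L))
    meanPct <- vapply(phyla, function(ph) {
        ids <- unc[phylumOf[unc] == ph]
        mean(colSums(m[ids, , drop = FALSE]))
    }, numeric(1L))
    list(phyla = DataFrame(phylum = phyla, n_uncommon_otus = unname(nOtus),
                           mean_read_percent = unname(meanPct)),
         n_uncommon = length(unc), n_total = length(detected),
         percent_uncommon_of_total =
             100 * length(unc) / max(1L, length(detected)))
}

#' Per-sample (or per-group) OTU richness
#'
#' Counts OTUs detected in each column of a presence matrix or count
#' table, with means per tissue x substrate.
#'
#' @param x A \linkS4class{PresenceMatrix} or \linkS4class{OtuTable}.
#' @return A list: \code{$per_sample} (\code{DataFrame} of sample,
#'   richness plus any tissue/substrate metadata) and \code{$means}
#'   (data.frame of per tissue x substrate mean richness, when metadata is
#'   available).
#' @export
richness <- function(x) {
    p <- if (is(x, "PresenceMatrix")) isPresent(x)
         else if (is(x, "OtuTable")) otuCounts(x) > 0L
         else .err("rt_bad_input", "x must be a PresenceMatrix or OtuTable")
    r <- colSums(p)
    cd <- colData(x)
    per <- DataFrame(sample = colnames(p), richness = unname(r))
    means <- NULL
    if (all(c("tissue", "substrate") %in% colnames(cd))) {
        per$tissue <- cd$tissue; per$substrate <- cd$substrate
        agg <- stats::aggregate(
            r, by = list(tissue = as.character(cd$tissue),
                         substrate = as.character(cd$substrate)), FUN = mean)
        names(agg)[3L] <- "mean_richness"
        means <- agg
    }
    list(per_sample = per, means = means)
}

#' Principal component analysis of a binary presence matrix
#'
#' Ordinates samples by eigendecomposition of the (n - 1)-normalised
#' covariance of the 0/1 matrix (samples in rows). Component signs are
#' fixed so that each component's largest-magnitude loading is positive,
#' making the output deterministic. Variance explained is non-increasing
#' across components.
#'
#' @param pres A \linkS4class{PresenceMatrix} (>= 3 samples).
#' @param nComponents Number of components to return (default 2).
#' @return A list: \code{$scores} (samples x components),
#'   \code{$loadings}, \code{$varExplained} (fractions).
#' @export
binaryPca <- function(pres, nComponents = 2L) {
    stopifnot(is(pres, "PresenceMatrix"))
    X <- t(isPresent(pres)) * 1  # samples x OTUs
    if (nrow(X) < 3L)
        .err("rt_too_few_samples", "binaryPca needs at least 3 samples")
    Xc <- scale(X, center = TRUE, scale = FALSE)
    C <- crossprod(Xc) / (nrow(X) - 1L)
    e <- eigen(C, symmetric = TRUE)
    k <- min(nComponents, ncol(X))
    V <- e$vectors[, seq_len(k), drop = FALSE]
    for (j in seq_len(k))
        if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
    rownames(V) <- colnames(X)
    scores <- Xc %*% V
    dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
    colnames(V) <- colnames(scores)
    ev <- pmax(e$values, 0)
    list(scores = scores, loadings = V,
         varExplained = ev[seq_len(k)] / sum(ev))
}

#' Bray-Curtis dissimilarity of two abundance vectors
#'
#' \code{sum(|x - y|) / sum(x + y)}, defined as 0 when both vectors are
#' all-zero. Symmetric and bounded in [0, 1]; identical vectors give 0 and
#' disjoint supports give 1.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Dissimilarity in [0, 1].
#' @export
#' @examples
#' brayCurtis(c(2, 2), c(2, 0))  # 1/3
brayCurtis <- function(x, y) {
    if (length(x) != length(y))
        .err("rt_bad_input", "x and y must have equal length")
    if (any(x < 0) || any(y < 0))
        .err("rt_bad_input", "abundances must be non-negative")
    denom <- sum(x + y)
    if (denom == 0) return(0)
    sum(abs(x - y)) / denom
}

#' All-pairs Bray-Curtis dissimilarity matrix
#'
#' @param m Numeric matrix with observations as columns.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
brayCurtisMatrix <- function(m) {
    n <- ncol(m)
    d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(n))
        for (j in seq_len(i - 1L))
            d[i, j] <- d[j, i] <- brayCurtis(m[, i], m[, j])
    d
}

#' Hierarchical clustering order of a dissimilarity matrix
#'
#' Agglomerative clustering (default UPGMA/average linkage, the community
#' ecology default) of a square symmetric zero-diagonal dissimilarity
#' matrix. The matrix is sorted by label first so that tied merges resolve
#' deterministically.
#'
#' @param d Square symmetric numeric matrix with zero diagonal and
#'   labelled rows/columns.
#' @param linkage \code{"average"}, \code{"complete"} or \code{"single"}.
#' @return A list: \code{$order} (leaf labels left to right) and
#'   \code{$hclust} (the merge tree).
#' @export
clusterOrder <- function(d, linkage = c("average", "complete", "single")) {
    linkage <- match.arg(linkage)
    if (!is.matrix(d) || nrow(d) != ncol(d) ||
        !isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
        .err("rt_bad_input", "d must be a square symmetric matrix")
    if (any(diag(d) != 0))
        .err("rt_bad_input", "d must have a zero diagonal")
    lab <- sort(rownames(d))
    d <- d[lab, lab]
    h <- stats::hclust(stats::as.dist(d), method = linkage)
    list(order = lab[h$order], hclust = h)
}

#' Hosts whose sand and soil samples cluster together
#'
#' Given a dendrogram leaf order over host x substrate samples (exactly two
#' per host, one per substrate), reports the hosts whose two leaves sit
#' adjacent in the order: the substrate pair grouped by plant species
#' rather than by substrate. Hosts with a different number of samples are
#' skipped with a warning.
#'
#' @param leafOrder Character vector of leaf labels, left to right.
#' @param labels \code{data.frame} with columns \code{label}, \code{host},
#'   \code{substrate}.
#' @return Character vector of hosts grouped by plant.
#' @export
detectPlantGroupings <- function(leafOrder, labels) {
    stopifnot(all(c("label", "host", "substrate") %in% colnames(labels)))
    pos <- match(labels$label, leafOrder)
    if (anyNA(pos))
        .err("rt_bad_input", "labels$label must all appear in leafOrder")
    grouped <- character()
    for (h in unique(labels$host)) {
        i <- which(labels$host == h)
        if (length(i) != 2L) {
            warning("host '", h, "' has ", length(i),
                    " samples, expected 2; skipped")
            next
        }
        if (abs(pos[i[1L]] - pos[i[2L]]) == 1L)
            grouped <- c(grouped, h)
    }
    grouped
}

#' Heatmap colour-bin edges (percent)
#'
#' @return The upper edges of the non-zero bins:
#'   0.1, 0.25, 0.5, 1 and 5 percent.
#' @export
heatmapBinEdges <- function() c(0.1, 0.25, 0.5, 1, 5)

#' Bin relative abundances into the heatmap colour scale
#'
#' Maps percent values into 7 bins: exactly 0 is bin 0; then the
#' left-open intervals (0, 0.1], (0.1, 0.25], (0.25, 0.5], (0.5, 1],
#' (1, 5] and (5, Inf) are bins 1-6. The bins partition [0, Inf): every
#' non-negative value maps to exactly one bin.
#'
#' @param v Non-negative numeric vector (percent).
#' @return Integer vector of bin indices 0..6.
#' @export
#' @examples
#' binHeatmap(c(0, 0.1, 0.100001, 7.2))  # 0 1 2 6
binHeatmap <- function(v) {
    if (any(v < 0) || anyNA(v))
        .err("rt_bad_input", "values must be non-negative and non-NA")
    edges <- heatmapBinEdges()
    out <- integer(length(v))
    pos <- v > 0
    if (any(pos))
        out[pos] <- 1L + as.integer(rowSums(outer(v[pos], edges, ">")))
    out
}

#' Build a binned, Bray-Curtis-ordered heatmap specification
#'
#' Selects the top \code{n} most abundant uncommon OTUs, orders the
#' compartmentless sample axis (and optionally the OTU axis) by average-
#' linkage clustering of Bray-Curtis dissimilarity, and bins the abundance
#' values into the 7-level colour scale. Column clustering is the default
#' surface for plant-vs-substrate grouping detection.
#'
#' @param rel A \linkS4class{GroupedAbundance}.
#' @param uncommon \linkS4class{UncommonSet} or character vector of ids.
#' @param n Number of OTUs (default 40).
#' @param columns Optional column subset.
#' @param clusterRows Also cluster the OTU axis (default FALSE)?
#' @param linkage Linkage method for \code{\link{clusterOrder}}.
#' @return A list: \code{$otuIds}, \code{$sampleOrder}, \code{$binMatrix}
#'   (bin indices, OTUs x ordered samples), \code{$values} (the percent
#'   values), \code{$edges}.
#' @export
heatmapSpec <- function(rel, uncommon, n = 40L, columns = NULL,
                        clusterRows = FALSE, linkage = "average") {
    ids <- topUncommon(rel, uncommon, n = n, columns = columns)
    if (!length(ids))
        .err("rt_empty_compartment", "no uncommon OTUs to display")
    cols <- if (is.null(columns)) seq_len(ncol(rel)) else columns
    m <- relAbundance(rel)[ids, cols, drop = FALSE]
    co <- clusterOrder(brayCurtisMatrix(m), linkage = linkage)
    m <- m[, co$order, drop = FALSE]
    if (clusterRows && length(ids) > 2L) {
        ro <- clusterOrder(brayCurtisMatrix(t(m)), linkage = linkage)
        m <- m[ro$order, , drop = FALSE]
    }
    bins <- matrix(binHeatmap(as.vector(m)), nrow(m), ncol(m),
                   dimnames = dimnames(m))
    list(otuIds = rownames(m), sampleOrder = colnames(m), binMatrix = bins,
         values = m, edges = heatmapBinEdges())
}

#' Most abundant uncommon OTU per host in one compartment
#'
#' For each host with at least one uncommon OTU above \code{threshold}
#' percent in the compartment, reports the argmax OTU and its abundance
#' (lexicographically smaller id on ties). Hosts with none are omitted and
#' listed. The relaxed bacterial detection threshold is honoured by
#' screening the uncommon set at that threshold and passing it here.
#'
#' @param rel A \linkS4class{GroupedAbundance}.
#' @param uncommon \linkS4class{UncommonSet} for the compartment.
#' @param threshold Minimum abundance (percent, strict) for a top OTU to
#'   be reported (default 0).
#' @return A list: \code{$top} (\code{DataFrame} of host, otu_id,
#'   abundance) and \code{$omitted} (hosts with no qualifying OTU).
#' @export
perPlantTopOtu <- function(rel, uncommon, threshold = 0) {
    stopifnot(is(rel, "GroupedAbundance"), is(uncommon, "UncommonSet"))
    cols <- .compartmentCols(rel, uncommon@tissue, uncommon@substrate)
    if (!length(cols))
        .err("rt_empty_compartment", "compartment selects zero groups")
    ids <- intersect(uncommonIds(uncommon), rownames(rel))
    cd <- colData(rel)
    rows <- list(); omitted <- character()
    for (j in cols) {
        h <- as.character(cd$host[j])
        v <- relAbundance(rel)[ids, j, drop = FALSE][, 1L]
        names(v) <- ids
        v <- v[v > threshold]
        if (!length(v)) { omitted <- c(omitted, h); next }
        best <- sort(names(v)[v == max(v)])[1L]
        rows[[length(rows) + 1L]] <-
            data.frame(host = h, otu_id = best,
                       abundance = unname(v[best]),
                       stringsAsFactors = FALSE)
    }
    top <- if (length(rows)) DataFrame(do.call(rbind, rows)) else
        DataFrame(host = character(), otu_id = character(),
                  abundance = numeric())
    list(top = top, omitted = omitted)
}
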