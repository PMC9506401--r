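test_that("phylum roll-up tallies uncommon OTUs and mean read percent", {
    m <- matrix(c(10, 20, 30, 40,
                  5, 15, 25, 55), 4, 2,
                dimnames = list(paste0("o", 1:4), c("g1", "g2")))
    rel <- makeRel(m, c("Maize", "Rice"), "root", "soil")
    tax <- S4Vectors::DataFrame(
        phylum = c("Ascomycota", "Ascomycota", "Basidiomycota", NA),
        row.names = paste0("o", 1:4))
    unc <- makeUncommon(c("o1", "o2", "o4"), universe = paste0("o", 1:4))
    rs <- phylumRollup(rel, unc, tax)
    ph <- as.data.frame(rs$phyla)
    expect_equal(sum(ph$n_uncommon_otus), rs$n_uncommon)
    expect_equal(rs$n_uncommon, 3L)
    expect_equal(ph$n_uncommon_otus[ph$phylum == "Ascomycota"], 2L)
    expect_equal(ph$n_uncommon_otus[ph$phylum == "unclassified"], 1L)
    # mean over hosts of summed uncommon abundance per phylum
    expect_equal(ph$mean_read_percent[ph$phylum == "Ascomycota"],
                 mean(c(10 + 20, 5 + 15)))
    # single-phylum and empty cases
    unc1 <- makeUncommon("o3", universe = paste0("o", 1:4))
    rs1 <- phylumRollup(rel, unc1, tax)
    expect_equal(as.data.frame(rs1$phyla)$phylum, "Basidiomycota")
    unc0 <- makeUncommon(character(), universe = paste0("o", 1:4))
    rs0 <- phylumRollup(rel, unc0, tax)
    expect_equal(rs0$n_uncommon, 0L)
    expect_equal(rs0$percent_uncommon_of_total, 0)
})

test_that("richness counts detected OTUs per sample with group means", {
    tab <- tinyExperiment()
    m <- otuCounts(tab)
    m[, 1L] <- 0L
    m[, 2L] <- c(1L, 0L, 2L, 0L, 0L, 0L)
    tab <- OtuTable(m, "ITS", sampleData(tab))
    r <- richness(tab)
    per <- as.data.frame(r$per_sample)
    expect_equal(per$richness[1L], 0L)
    expect_equal(per$richness[2L], 2L)
    # brute-force mean for one tissue x substrate cell
    cd <- sampleData(tab)
    sel <- cd$tissue == "root" & cd$substrate == "sand"
    expect_equal(
        r$means$mean_richness[r$means$tissue == "root" &
                              r$means$substrate == "sand"],
        mean(colSums(m[, sel, drop = FALSE] > 0)))
})

test_that("binary PCA matches an independent prcomp decomposition", {
    set.seed(5)
    m <- matrix(runif(40) < 0.5, 8, 5,
                dimnames = list(paste0("o", 1:8), paste0("s", 1:5)))
    m[, 5L] <- m[, 4L]  # two identical samples
    pres <- makePres(m, host = paste0("H", 1:5), tissue = "root",
                     substrate = "soil")
    pca <- binaryPca(pres, nComponents = 3L)
    expect_true(all(diff(pca$varExplained) <= 1e-12))
    expect_equal(pca$scores["s4", ], pca$scores["s5", ])
    # oracle: prcomp on the same 0/1 matrix, compared up to component sign
    or <- stats::prcomp(t(m) * 1, center = TRUE, scale. = FALSE)
    for (j in 1:3) {
        d <- min(max(abs(pca$scores[, j] - or$x[, j])),
                 max(abs(pca$scores[, j] + or$x[, j])))
        expect_lt(d, 1e-8)
    }
    # deterministic sign: largest-magnitude loading is positive
    for (j in 1:3)
        expect_gte(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
    expect_error(binaryPca(makePres(m[, 1:2], paste0("H", 1:2), "root",
                                    "soil")),
                 class = "rt_too_few_samples")
})

test_that("Bray-Curtis matches hand arithmetic and vegan elementwise", {
    expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(brayCurtis(c(1, 0), c(0, 3)), 1)
    expect_equal(brayCurtis(c(2, 2), c(2, 0)), 1 / 3)
    expect_equal(brayCurtis(c(0, 0), c(0, 0)), 0)  # degenerate case
    expect_error(brayCurtis(c(-1, 0), c(0, 1)), class = "rt_bad_input")
    expect_error(brayCurtis(1:3, 1:2), class = "rt_bad_input")

    set.seed(6)
    for (i in 1:1000) {
        x <- runif(8, 0, 10); y <- runif(8, 0, 10)
        expect_equal(brayCurtis(x, y),
                     as.numeric(vegan::vegdist(rbind(x, y),
                                               method = "bray")))
        expect_equal(brayCurtis(x, y), brayCurtis(y, x))
        expect_true(brayCurtis(x, y) >= 0 && brayCurtis(x, y) <= 1)
    }
})

test_that("cluster order merges nearest pairs and is label-equivariant", {
    # 3-point line metric: a-b close, c far
    d <- matrix(c(0, 1, 10,
                  1, 0, 9,
                  10, 9, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    co <- clusterOrder(d)
    expect_equal(co$hclust$merge[1L, ], c(-1L, -2L))  # a,b merge first
    expect_true(which(co$order == "a") %in%
                    (which(co$order == "b") + c(-1L, 1L)))
    # identical samples merge first
    d2 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3,
                 dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    expect_equal(sort(abs(clusterOrder(d2)$hclust$merge[1L, ])), c(1, 2))
    # permuting input labels permutes output consistently
    perm <- c(3, 1, 2)
    co2 <- clusterOrder(d[perm, perm])
    expect_setequal(co2$order, co$order)
    expect_equal(co2$order, co$order)  # label-sorted internally
    expect_error(clusterOrder(matrix(c(0, 1, 2, 0), 2, 2,
                                     dimnames = list(c("a", "b"),
                                                     c("a", "b")))),
                 class = "rt_bad_input")
})

test_that("plant groupings are hosts with adjacent sand/soil leaves", {
    labels <- data.frame(
        label = c("Maize.sand", "Maize.soil", "Rice.sand", "Rice.soil"),
        host = rep(c("Maize", "Rice"), each = 2),
        substrate = rep(c("sand", "soil"), 2))
    byPlant <- c("Maize.sand", "Maize.soil", "Rice.sand", "Rice.soil")
    expect_setequal(detectPlantGroupings(byPlant, labels),
                    c("Maize", "Rice"))
    bySubstrate <- c("Maize.sand", "Rice.sand", "Maize.soil", "Rice.soil")
    expect_length(detectPlantGroupings(bySubstrate, labels), 0L)
    # brute-force adjacency oracle on random orders
    set.seed(8)
    for (i in 1:10) {
        ord <- sample(labels$label)
        got <- detectPlantGroupings(ord, labels)
        want <- character()
        for (h in unique(labels$host)) {
            pos <- match(labels$label[labels$host == h], ord)
            if (abs(diff(pos)) == 1L) want <- c(want, h)
        }
        expect_setequal(got, want)
    }
    # hosts with a sample count other than 2 are skipped with a warning
    lab3 <- rbind(labels, data.frame(label = "Soy.sand", host = "Soy",
                                     substrate = "sand"))
    expect_warning(detectPlantGroupings(c(byPlant, "Soy.sand"), lab3),
                   "Soy")
})

test_that("heatmap bins partition the non-negative line", {
    expect_identical(binHeatmap(c(0, 0.1, 0.100001, 7.2)),
                     c(0L, 1L, 2L, 6L))
    expect_identical(binHeatmap(c(0.25, 0.26, 0.5, 1, 1.01, 5)),
                     c(2L, 3L, 3L, 4L, 5L, 5L))
    expect_error(binHeatmap(-0.1), class = "rt_bad_input")
    set.seed(10)
    v <- c(0, runif(500, 0, 10), 10^runif(100, -4, 3))
    b <- binHeatmap(v)
    expect_true(all(b %in% 0:6))            # every value lands in one bin
    expect_identical(b == 0L, v == 0)
    edges <- c(0, heatmapBinEdges(), Inf)
    for (i in seq_along(v))
        if (v[i] > 0)
            expect_true(v[i] > edges[b[i]] && v[i] <= edges[b[i] + 1L])
})

test_that("per-plant top OTU is the argmax with lexicographic ties", {
    m <- matrix(c(40, 10,
                  40, 5,
                  20, 85), 3, 2, byrow = TRUE,
                dimnames = list(c("b", "a", "zz"), c("g1", "g2")))
    rel <- makeRel(m, c("Maize", "Rice"), "root", "soil")
    unc <- makeUncommon(c("a", "b", "zz"))
    top <- as.data.frame(perPlantTopOtu(rel, unc)$top)
    expect_equal(top$otu_id[top$host == "Maize"], "a")  # 40 == 40 tie
    expect_equal(top$otu_id[top$host == "Rice"], "zz")
    # threshold omits hosts with nothing above it
    res <- perPlantTopOtu(rel, makeUncommon("a"), threshold = 20)
    expect_equal(as.data.frame(res$top)$host, "Maize")
    expect_equal(res$omitted, "Rice")
    # brute-force argmax oracle on random tables
    set.seed(12)
    for (i in 1:5) {
        mm <- matrix(runif(30, 0, 10), 10, 3,
                     dimnames = list(sprintf("o%02d", 1:10),
                                     paste0("g", 1:3)))
        mm <- sweep(mm, 2, colSums(mm), "/") * 100
        rr <- makeRel(mm, c("Maize", "Rice", "Soy"), "root", "soil")
        tt <- as.data.frame(perPlantTopOtu(rr,
                                           makeUncommon(rownames(mm)))$top)
        for (j in 1:3)
            expect_equal(tt$otu_id[j], names(which.max(mm[, j])))
    }
})

test_that("heatmap specification binds top OTUs to a clustered order", {
    set.seed(13)
    m <- matrix(runif(60, 0, 5), 15, 4,
                dimnames = list(sprintf("o%02d", 1:15), paste0("g", 1:4)))
    m <- sweep(m, 2, colSums(m), "/") * 100
    rel <- makeRel(m, c("Maize", "Maize", "Rice", "Rice"),
                   c("root", "root", "root", "root"),
                   c("sand", "soil", "sand", "soil"))
    hs <- heatmapSpec(rel, rownames(m), n = 10L)
    expect_length(hs$otuIds, 10L)
    expect_setequal(hs$sampleOrder, colnames(m))
    expect_identical(dim(hs$binMatrix), c(10L, 4L))
    expect_true(all(hs$binMatrix %in% 0:6))
})
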