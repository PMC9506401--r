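# Independent Sorensen oracle: count shared elements by explicit loop.
bruteSorensen <- function(A, B) {
    A <- unique(A); B <- unique(B)
    if (length(A) + length(B) == 0L) return(0)
    shared <- 0L
    for (a in A) if (a %in% B) shared <- shared + 1L
    2 * shared / (length(A) + length(B))
}

test_that("Sorensen index matches hand arithmetic and its oracle exhaustively", {
    expect_equal(sorensen(c("a", "b", "c"), c("b", "c", "d")), 4 / 6)
    expect_equal(sorensen(c("a", "b"), c("a", "b")), 1)
    expect_equal(sorensen(character(), character()), 0)
    expect_equal(sorensen(c("a"), character()), 0)

    # exhaustive over all subset pairs of a 6-element universe
    u <- letters[1:6]
    subsets <- lapply(0:63, function(k) u[bitwAnd(k, 2^(0:5)) > 0])
    for (A in subsets) for (B in subsets) {
        s <- sorensen(A, B)
        expect_identical(s, bruteSorensen(A, B))
        expect_identical(s, sorensen(B, A))  # symmetry
        expect_true(s >= 0 && s <= 1)
    }
})

# Presence fixture: 2 hosts x {root} x {sand, soil} collapsed groups.
twoHostPres <- function(m) {
    makePres(m, host = rep(c("Maize", "Rice"), each = 2),
             tissue = "root",
             substrate = rep(c("sand", "soil"), 2))
}

test_that("substrate similarity credits OTUs detected on both substrates", {
    otus <- c("x", "y", "z")
    m <- matrix(FALSE, 3, 4,
                dimnames = list(otus, c("Maize.sand", "Maize.soil",
                                        "Rice.sand", "Rice.soil")))
    m["x", c("Maize.sand", "Maize.soil")] <- TRUE   # seed-transmitted in maize
    m["y", "Maize.soil"] <- TRUE
    m["z", "Rice.sand"] <- TRUE
    pres <- twoHostPres(m)
    unc <- list(makeUncommon(otus, tissue = "root", substrate = "sand"),
                makeUncommon(otus, tissue = "root", substrate = "soil"))
    st <- substrateSimilarityTable(pres, unc, tissues = "root")
    e <- as.data.frame(st$entries)
    maize <- e[e$host == "Maize", ]
    expect_equal(maize$similarity, 2 * 1 / (1 + 2))  # A={x}, B={x,y}
    expect_equal(maize$n_shared, 1L)
    rice <- e[e$host == "Rice", ]
    expect_equal(rice$similarity, 0)                 # disjoint sets
    expect_equal(unname(st$means["root"]),
                 round(mean(c(2 / 3, 0)), 2))
})

test_that("similarity means are invariant to host ordering", {
    set.seed(11)
    hosts <- paste0("H", 1:6)
    m <- matrix(runif(10 * 12) < 0.4, 10, 12,
                dimnames = list(paste0("o", 1:10),
                                paste0("g", 1:12)))
    # permute columns consistently with their labels
    cd <- expand.grid(substrate = c("sand", "soil"), host = hosts,
                      stringsAsFactors = FALSE)
    pres1 <- makePres(m, cd$host, "root", cd$substrate)
    perm <- sample(ncol(m))
    pres2 <- makePres(m[, perm], cd$host[perm], "root", cd$substrate[perm])
    unc <- list(makeUncommon(rownames(m), tissue = "root",
                             substrate = "sand"),
                makeUncommon(rownames(m), tissue = "root",
                             substrate = "soil"))
    s1 <- substrateSimilarityTable(pres1, unc, tissues = "root")
    s2 <- substrateSimilarityTable(pres2, unc, tissues = "root")
    expect_equal(s1$means, s2$means)
})

# Fixture for source rules: 17 hosts x {rhizosphere, root} x {sand, soil}.
ruleFixture <- function() {
    hosts <- defaultHosts()
    cd <- expand.grid(tissue = c("rhizosphere", "root"),
                      substrate = c("sand", "soil"), host = hosts,
                      stringsAsFactors = FALSE)
    ids <- paste(cd$host, cd$tissue, cd$substrate, sep = "|")
    m <- matrix(FALSE, 4, nrow(cd),
                dimnames = list(c("seedy", "soily", "lonely", "filtered"),
                                ids))
    # seedy: maize root on both substrates
    m["seedy", c("Maize|root|sand", "Maize|root|soil")] <- TRUE
    # soily: 16 soil rhizospheres + maize soil root, never sand
    m["soily", paste0(hosts[1:16], "|rhizosphere|soil")] <- TRUE
    m["soily", "Maize|root|soil"] <- TRUE
    # lonely: one soil root group of one host only
    m["lonely", "Rice|root|soil"] <- TRUE
    # filtered: 12 soil rhizospheres, 4 soil roots
    m["filtered", paste0(hosts[1:12], "|rhizosphere|soil")] <- TRUE
    m["filtered", paste0(hosts[1:4], "|root|soil")] <- TRUE
    makePres(m, cd$host, cd$tissue, cd$substrate)
}

test_that("source classification follows the seed/soil/unknown rules", {
    pres <- ruleFixture()
    seed <- classifySource("seedy", "Maize", "root", pres)
    expect_equal(seed$source, "seed")
    soil <- classifySource("soily", "Maize", "root", pres)
    expect_equal(soil$source, "soil")
    expect_equal(soil$soil_rhizo_occupancy, 16L)
    lone <- classifySource("lonely", "Rice", "root", pres)
    expect_equal(lone$source, "unknown")
})

test_that("a soil call is impossible with any sand detection for the host", {
    set.seed(21)
    hosts <- defaultHosts()
    cd <- expand.grid(tissue = c("rhizosphere", "root"),
                      substrate = c("sand", "soil"), host = hosts,
                      stringsAsFactors = FALSE)
    for (i in 1:20) {
        m <- matrix(runif(nrow(cd)) < 0.3, 1, nrow(cd),
                    dimnames = list("o", paste0("g", seq_len(nrow(cd)))))
        pres <- makePres(m, cd$host, cd$tissue, cd$substrate)
        h <- sample(hosts, 1)
        call <- classifySource("o", h, "root", pres)
        sandHit <- any(m[1, cd$host == h & cd$substrate == "sand"])
        if (call$source == "soil") expect_false(sandHit)
        if (sandHit) expect_equal(call$source, "seed")
    }
})

test_that("cross-tissue seed evidence can be restricted to the focal tissue", {
    hosts <- defaultHosts()
    cd <- expand.grid(tissue = c("rhizosphere", "root"),
                      substrate = c("sand", "soil"), host = hosts,
                      stringsAsFactors = FALSE)
    ids <- paste(cd$host, cd$tissue, cd$substrate, sep = "|")
    m <- matrix(FALSE, 1, nrow(cd), dimnames = list("o", ids))
    m["o", c("Maize|rhizosphere|sand", "Maize|root|soil")] <- TRUE
    pres <- makePres(m, cd$host, cd$tissue, cd$substrate)
    expect_equal(classifySource("o", "Maize", "root", pres)$source, "seed")
    strict <- transmissionParams(crossTissue = FALSE)
    call <- classifySource("o", "Maize", "root", pres, strict)
    expect_equal(call$source, "unknown")  # sand hit elsewhere blocks soil
})

test_that("stochastic and biotic-filtering flags follow their thresholds", {
    pres <- ruleFixture()
    calls <- rbind(classifySource("lonely", "Rice", "root", pres),
                   classifySource("filtered", "Maize", "root", pres),
                   classifySource("soily", "Maize", "root", pres))
    flagged <- annotateFlags(calls, pres)
    expect_true(flagged$stochastic[1L])        # 1 group dataset-wide
    expect_true(flagged$biotic_filtered[2L])   # 12 rhizo vs 4 roots
    expect_true(flagged$biotic_filtered[3L])   # 16 rhizo vs 1 root
    expect_false(flagged$stochastic[2L])       # 16 groups is no one-off

    # ubiquitous OTU: 17 rhizospheres and 15 roots carry neither flag
    hosts <- defaultHosts()
    cd <- expand.grid(tissue = c("rhizosphere", "root"),
                      substrate = c("sand", "soil"), host = hosts,
                      stringsAsFactors = FALSE)
    ids <- paste(cd$host, cd$tissue, cd$substrate, sep = "|")
    m <- matrix(FALSE, 1, nrow(cd), dimnames = list("ubiq", ids))
    m["ubiq", paste0(hosts, "|rhizosphere|soil")] <- TRUE
    m["ubiq", paste0(hosts[1:15], "|root|soil")] <- TRUE
    pres2 <- makePres(m, cd$host, cd$tissue, cd$substrate)
    call <- annotateFlags(classifySource("ubiq", "Maize", "root", pres2),
                          pres2)
    expect_false(call$stochastic)
    expect_false(call$biotic_filtered)
})
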