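test_that("census and histograms conserve domain counts", {
    empty <- RINGcat:::.emptyCatalog()
    expect_identical(unname(typeCensus(empty)), rep(0L, 8))
    cat8 <- chainCatalog(RING_TYPES, seed = 2)
    census <- typeCensus(cat8)
    expect_identical(unname(census), rep(1L, 8))
    ## a larger catalog with repeats, a modified and an incomplete row
    types <- rep(RING_TYPES[1:4], c(10, 6, 3, 2))
    cat21 <- chainCatalog(types, seed = 3)
    cat21$modified_position[1] <- 5L          # modified: counts normally
    inc <- cat21[2, ]; inc$ring_type <- "incomplete"; inc$complete <- FALSE
    cat21 <- rbind(cat21, inc)
    census <- typeCensus(cat21)
    expect_identical(sum(census),
                     sum(cat21$complete & cat21$ring_type %in% RING_TYPES))
    hist <- gapHistograms(cat21)
    for (tp in names(census)[census > 0]) {
        for (gi in 1:7) {
            h <- hist[hist$ring_type == tp & hist$gap_index == gi, ]
            expect_identical(sum(h$count), unname(census[tp]))
        }
    }
    pooled <- hist[hist$ring_type == "all" & hist$gap_index == 1, ]
    expect_identical(pooled$gap_size, 2L)
    expect_identical(pooled$count, unname(sum(census)))
})

test_that("single-domain histogram and pooled g1 follow construction", {
    cat1 <- chainCatalog("RING-H2", seed = 4)
    h <- gapHistograms(cat1)
    g1 <- h[h$ring_type == "all" & h$gap_index == 1, ]
    expect_identical(g1$gap_size, 2L)
    expect_identical(g1$count, 1L)
})

test_that("spacing consensus reports observed windows and value sets", {
    catG <- chainCatalog("RING-G", seed = 5)
    cons <- spacingConsensus(gapHistograms(catG))
    g2 <- cons[cons$ring_type == "RING-G" & cons$gap_index == 2, ]
    expect_identical(g2$min, 16L)
    expect_identical(g2$max, 16L)
    expect_identical(g2$values, "16")
    ## absent types omitted
    expect_false("RING-H2" %in% cons$ring_type)
    ## a generated RING-H2 set: g2 consensus within the spec window
    set.seed(6)
    catH <- chainCatalog(rep("RING-H2", 400), seed = 6)
    consH <- spacingConsensus(gapHistograms(catH))
    g2H <- consH[consH$ring_type == "RING-H2" & consH$gap_index == 2, ]
    expect_gte(g2H$min, 11L)
    expect_lte(g2H$max, 43L)
    ## with 400 draws the modal values 14/15 are certainly observed
    expect_lte(g2H$min, 14L)
    expect_gte(g2H$max, 15L)
})

test_that("sampled gap distributions match the generator model", {
    ## chi-square goodness of fit of the RING-H2 ml2-ml3 histogram
    ## against the modal-weighted sampling distribution
    n <- 1000L
    catH <- chainCatalog(rep("RING-H2", n), seed = 8)
    h <- gapHistograms(catH)
    g2 <- h[h$ring_type == "RING-H2" & h$gap_index == 2, ]
    window <- 11:43
    modal <- c(14L, 15L)
    p <- rep(0.2 / (length(window) - length(modal)), length(window))
    p[match(modal, window)] <- 0.8 / length(modal)
    obs <- integer(length(window))
    obs[match(g2$gap_size, window)] <- g2$count
    ## pool the sparse tail cells so expected counts stay reasonable
    tail <- !window %in% modal
    obsPooled <- c(obs[!tail], sum(obs[tail]))
    pPooled <- c(p[!tail], sum(p[tail]))
    gof <- suppressWarnings(
        stats::chisq.test(obsPooled, p = pPooled))
    expect_gt(gof$p.value, 0.01)
})

test_that("anchored frequency matrices count flank residues correctly", {
    ## single domain: every occupied column has one residue at 1.0
    cat1 <- chainCatalog("RING-H2", seed = 9)
    pfm <- anchoredFrequencyMatrix(cat1, "RING-H2", flank = 2)
    expect_true(all(abs(colSums(pfm@freq) - 1) < 1e-9))
    expect_true(all(apply(pfm@freq, 2, max) == 1))
    ## ligand columns are the ligand residue at frequency 1
    expect_identical(unname(pfm@freq["C", "ml1"]), 1)
    expect_identical(unname(pfm@freq["H", "ml4"]), 1)
    ## a planted Phe/Tyr motif before ml5 shows up at its planting rate
    set.seed(10)
    catH <- chainCatalog(rep("RING-H2", 500), seed = 10)
    pfmH <- anchoredFrequencyMatrix(catH, "RING-H2", flank = 1)
    ## planting rate 0.85, plus chance F/Y from the loop alphabet in the
    ## unplanted 15% (2 of 14 letters)
    fy <- sum(pfmH@freq[c("F", "Y"), "ml5-1"])
    expect_gt(fy, 0.80)
    expect_lt(fy, 0.95)
    ## coverage equals the domain count on always-present columns
    expect_identical(pfmH@coverage[match("ml5",
                                         colnames(pfmH@freq))], 500L)
    expect_error(anchoredFrequencyMatrix(catH, "RING-G"), "no complete")
})

test_that("over-represented residues honour threshold and equivalences", {
    freq <- matrix(0, nrow = length(AA_STANDARD), ncol = 3,
                   dimnames = list(AA_STANDARD, c("ml2-1", "ml4", "x")))
    freq["I", 1] <- 0.4; freq["V", 1] <- 0.3; freq["L", 1] <- 0.3
    freq["H", 2] <- 1
    freq[, 3] <- 1 / length(AA_STANDARD)
    pfm <- new("PositionFrequencyMatrix", freq = freq,
               coverage = c(10L, 10L, 10L), ringType = "RING-H2",
               nDomains = 10L)
    hits <- overRepresentedResidues(pfm, threshold = 0.5)
    expect_identical(hits$residues[hits$column == "ml2-1"], "I/V")
    expect_equal(hits$frequency[hits$column == "ml2-1"], 0.7)
    expect_identical(hits$residues[hits$column == "ml4"], "H")
    ## uniform column reports nothing
    expect_false("x" %in% hits$column)
    ## a single residue over threshold suppresses its pair entry
    freq["I", 1] <- 0.6; freq["V", 1] <- 0.2; freq["L", 1] <- 0.2
    pfm@freq <- freq
    hits2 <- overRepresentedResidues(pfm, threshold = 0.5)
    expect_identical(hits2$residues[hits2$column == "ml2-1"], "I")
    expect_error(overRepresentedResidues(pfm, threshold = 0), "threshold")
})

test_that("architecture grouping collapses repeats and sorts by size", {
    catalog <- chainCatalog(rep("RING-H2", 4), seed = 12)
    catalog$protein_id <- c("A", "B", "C", "D")
    ann <- data.frame(
        protein_id = c("A", "B", "B", "D"),
        domain_name = c("TM", "TM", "TM", "WD40"),
        start = c(5L, 5L, 40L, 10L),
        end = c(25L, 25L, 60L, 50L), stringsAsFactors = FALSE)
    grp <- architectureGroups(ann, catalog)
    a <- grp$assignment
    expect_identical(a$architecture[a$protein_id == "A"], "TM")
    expect_identical(a$architecture[a$protein_id == "B"], "TM")
    expect_identical(a$n_additional[a$protein_id == "B"], 2L)
    expect_identical(a$architecture[a$protein_id == "C"], "none")
    expect_identical(a$architecture[a$protein_id == "D"], "WD40")
    expect_identical(grp$groups$architecture[1], "TM")
    expect_identical(grp$groups$n_proteins[1], 2L)
    ## annotation-free catalog: one group with everything
    grp0 <- architectureGroups(NULL, catalog)
    expect_identical(grp0$groups$architecture, "none")
    expect_identical(grp0$groups$n_proteins, 4L)
    ## unknown protein in annotations is an error
    expect_error(architectureGroups(
        data.frame(protein_id = "Z", domain_name = "TM",
                   start = 1L, end = 2L), catalog), "unknown")
    ## without collapsing, repeat counts split the groups
    grp2 <- architectureGroups(ann, catalog, collapseRepeats = FALSE)
    a2 <- grp2$assignment
    expect_identical(a2$architecture[a2$protein_id == "B"], "TM+TM")
    ## empty input -> empty output
    empty <- architectureGroups(NULL, RINGcat:::.emptyCatalog())
    expect_identical(nrow(empty$assignment), 0L)
})
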