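test_that("uncentered Pearson distance follows the formula and bounds", {
    expect_equal(uncenteredPearsonDistance(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(uncenteredPearsonDistance(c(2, 4, 6), c(1, 2, 3)), 0)
    expect_equal(uncenteredPearsonDistance(c(1, 0), c(0, 1)), 1)
    ## anti-proportional profiles reach the upper bound 2
    expect_equal(uncenteredPearsonDistance(c(1, -1), c(-1, 1)), 2)
    expect_error(uncenteredPearson(c(0, 0), c(1, 2)), "zero-norm")
    expect_error(uncenteredPearson(1, 1), "length")
    ## matrix form agrees with the pairwise form; FPKM profiles stay
    ## in [0, 1]
    set.seed(19)
    m <- matrix(stats::rexp(60), nrow = 10)
    D <- as.matrix(uncenteredPearsonDist(m))
    for (i in 1:9) for (j in (i + 1):10)
        expect_equal(D[i, j],
                     max(0, uncenteredPearsonDistance(m[i, ], m[j, ])))
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
    expect_true(all(abs(D - t(D)) < 1e-12))
})

test_that("all-zero rows are filtered and reported", {
    m <- rbind(a = c(1, 2, 3), b = c(0, 0, 0), c = c(0, 1, 0),
               d = c(0, 0, 0))
    f <- filterAllZero(m)
    expect_identical(rownames(f), c("a", "c"))
    expect_identical(attr(f, "removed"), c("b", "d"))
    m2 <- m[c("a", "c"), ]
    expect_identical(attr(filterAllZero(m2), "removed"), character(0))
})

test_that("complete linkage matches the cubic oracle", {
    ## hand-checkable 4-point case
    set.seed(20)
    m4 <- matrix(stats::rexp(24), nrow = 4,
                 dimnames = list(paste0("g", 1:4), NULL))
    D <- as.matrix(uncenteredPearsonDist(m4))
    tree <- hclustComplete(m4)
    oracle <- oracleCompleteLinkage(D)
    expect_equal(sort(tree$height), sort(oracle$heights))
    ## random 6-tissue profiles: heights and every partition agree
    for (rep in 1:8) {
        m <- matrix(stats::rexp(20 * 6), nrow = 20,
                    dimnames = list(sprintf("g%02d", 1:20), NULL))
        D <- as.matrix(uncenteredPearsonDist(m))
        tree <- hclustComplete(m)
        oracle <- oracleCompleteLinkage(D)
        expect_equal(tree$height, oracle$heights, tolerance = 1e-12)
        ## merge heights are non-decreasing
        expect_true(all(diff(tree$height) >= -1e-12))
        for (k in c(2, 5, 10)) {
            mine <- membershipToSets(stats::cutree(tree, k))
            want <- oracle$partitions[[20 - k]]
            expect_identical(partitionSignature(mine),
                             partitionSignature(want))
        }
    }
})

test_that("identical rows merge first at height zero", {
    m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(9, 1, 1),
               d = c(1, 8, 1))
    tree <- hclustComplete(m)
    expect_equal(tree$height[1], 0)
    expect_identical(sort(tree$labels[-tree$merge[1, ]]), c("a", "b"))
})

test_that("cutTreeGroups labels groups in dendrogram order", {
    m <- rbind(a = c(10, 1, 1), b = c(9, 1, 2), c = c(1, 10, 1),
               d = c(1, 9, 2), e = c(1, 1, 10), f = c(2, 1, 9))
    tree <- hclustComplete(m)
    asg <- cutTreeGroups(tree, 3)
    expect_identical(sort(unique(asg$group)), c("I", "II", "III"))
    ## leftmost leaf belongs to group I
    leftmost <- tree$labels[tree$order[1]]
    expect_identical(asg$group[asg$gene == leftmost], "I")
    ## pairs stay together
    expect_identical(asg$group[asg$gene == "a"],
                     asg$group[asg$gene == "b"])
    ## k = 1 and k = n degenerate cases
    expect_identical(unique(cutTreeGroups(tree, 1)$group), "I")
    expect_identical(length(unique(cutTreeGroups(tree, 6)$group)), 6L)
    ## subgroups nest within groups
    asg2 <- cutTreeGroups(tree, 3, k2 = 6)
    expect_true(all(startsWith(asg2$subgroup, asg2$group)))
})

test_that("preferential tissue calling follows the fold rule", {
    p <- c(callus = 10, root = 1, stem = 1, leaf = 1, flower = 1,
           silique = 1)
    expect_identical(preferentialTissues(p), "callus")
    expect_identical(preferentialTissues(rep(5, 6)), character(0))
    expect_identical(preferentialTissues(c(3, 2, 2, 2, 2, 2)),
                     character(0))
    ## strict inequality: exactly 2-fold is not preferential
    expect_identical(preferentialTissues(c(4, 2, 2, 2, 2, 2)),
                     character(0))
    ## positive signal against all-zero rest is preferential
    expect_identical(preferentialTissues(c(a = 1, b = 0, c = 0)), "a")
    ## max baseline is stricter than mean
    q <- c(a = 10, b = 6, c = 1, d = 1, e = 1, f = 1)
    expect_identical(preferentialTissues(q, baseline = "mean"),
                     c("a", "b"))
    expect_identical(preferentialTissues(q, baseline = "max"),
                     character(0))
    sets <- preferentialTissueSets(rbind(g1 = p, g2 = rep(5, 6)))
    expect_identical(sets$g1, "callus")
    expect_identical(sets$g2, character(0))
})

test_that("group x type crosstab counts and percentages are conserved", {
    asg <- data.frame(gene = c("p1", "p2", "p3", "p4", "p5", "p6"),
                      group = c("I", "I", "II", "II", "II", "I"))
    types <- c(p1 = "RING-H2", p2 = "RING-H2", p3 = "RING-H2",
               p4 = "RING-D", p5 = "RING-D", p6 = "RING-D")
    ct <- groupTypeCrosstab(asg, types)
    expect_identical(ct$counts["I", "RING-H2"], 2L)
    expect_identical(ct$counts["II", "RING-D"], 2L)
    expect_equal(ct$percent["II", "RING-D"], 100 * 2 / 3)
    ## conservation: row sums = group sizes, column sums = type totals
    expect_equal(unname(rowSums(ct$counts)),
                 unname(as.numeric(table(asg$group)[
                     rownames(ct$counts)])))
    expect_equal(unname(colSums(ct$counts)[c("RING-H2", "RING-D")]),
                 c(3, 3))
    expect_equal(unname(colSums(ct$percent)[c("RING-H2", "RING-D")]),
                 c(100, 100))
    ## single gene, single type -> one cell at 100%
    ct1 <- groupTypeCrosstab(asg[1, ], types)
    expect_identical(ct1$counts["I", "RING-H2"], 1L)
    expect_equal(ct1$percent["I", "RING-H2"], 100)
    expect_error(groupTypeCrosstab(
        data.frame(gene = "zz", group = "I"), types), "zz")
})

test_that("planted expression groups are recovered by the 7-group cut", {
    sim <- simulateExpression(expressionSimConfig(nGenes = 300,
                                                  seed = 23))
    mat <- filterAllZero(sim$matrix)
    asg <- cutTreeGroups(hclustComplete(mat), 7)
    truth <- sim$truth$group[match(asg$gene, sim$truth$gene)]
    expect_gte(mclust::adjustedRandIndex(asg$group, truth), 0.95)
})
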