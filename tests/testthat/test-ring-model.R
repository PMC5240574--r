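test_that("LigandChain invariants hold and violations are rejected", {
    ch <- ligandChain(c("C","C","C","H","H","C","C","C"),
                      gaps = c(2, 14, 1, 2, 2, 10, 2))
    expect_identical(ligandGaps(ch), c(2L, 14L, 1L, 2L, 2L, 10L, 2L))
    expect_identical(chainSpan(ch), 8L + sum(ligandGaps(ch)))
    expect_identical(ligandPositions(ch),
                     1L + c(0L, cumsum(c(2L,14L,1L,2L,2L,10L,2L) + 1L)))
    expect_error(ligandChain(rep("C", 8), positions = c(1:7, 7)),
                 "increasing")
    expect_error(ligandChain(rep("C", 7), gaps = rep(2, 7)), "length 8")
    expect_error(ligandChain(rep("C", 8), gaps = c(-1, rep(2, 6))),
                 "non-negative")
})

test_that("the eight type specs encode the published consensus table", {
    specs <- ringTypeSpecs()
    expect_named(specs, RING_TYPES)
    ## every type: C x2 C at the start, Cys at ml1/ml7/ml8
    for (s in specs) {
        expect_identical(s@gapWindows[[1]], 2L)
        expect_identical(s@allowedResidues[[1]], "C")
        expect_identical(s@allowedResidues[[7]], "C")
        expect_identical(s@allowedResidues[[8]], "C")
    }
    ## distinguishing windows
    expect_identical(specs[["RING-v"]]@gapWindows[[4]], 7L)
    expect_identical(specs[["RING-HCb"]]@gapWindows[[7]], c(3L, 4L))
    expect_identical(specs[["RING-HCa"]]@gapWindows[[7]], 2L)
    expect_identical(range(specs[["RING-H2"]]@gapWindows[[2]]),
                     c(11L, 43L))
    expect_identical(range(specs[["RING-H2"]]@gapWindows[[6]]),
                     c(6L, 64L))
    expect_identical(range(specs[["RING-v"]]@gapWindows[[2]]),
                     c(11L, 77L))
    expect_identical(specs[["RING-G"]]@gapWindows[[2]], 16L)
    expect_identical(specs[["RING-G"]]@gapWindows[[6]], 13L)
    expect_identical(specs[["RING-G"]]@allowedResidues[[5]], "G")
    expect_identical(sort(specs[["RING-D"]]@allowedResidues[[5]]),
                     c("C", "D"))
    expect_identical(sort(specs[["RING-S/T"]]@allowedResidues[[6]]),
                     c("C", "S", "T"))
    ## every type window/alphabet is a subset of the scanner union
    w <- scanWindows()
    for (s in specs) {
        for (i in 1:7)
            expect_true(all(s@gapWindows[[i]] %in% w@gapWindows[[i]]))
        for (i in 1:8)
            expect_true(all(s@allowedResidues[[i]] %in%
                                w@slotAlphabets[[i]]))
    }
})

test_that("complete chains classify to the expected types", {
    cases <- list(
        list(res = c("C","C","C","H","H","C","C","C"),
             gaps = c(2,14,1,2,2,10,2), type = "RING-H2"),
        list(res = c("C","C","C","C","H","C","C","C"),
             gaps = c(2,12,1,7,2,12,2), type = "RING-v"),
        list(res = c("C","C","C","H","C","C","C","C"),
             gaps = c(2,11,1,2,2,10,4), type = "RING-HCb"),
        list(res = c("C","C","C","H","C","C","C","C"),
             gaps = c(2,11,1,2,2,10,2), type = "RING-HCa"),
        list(res = c("C","C","C","H","D","C","C","C"),
             gaps = c(2,13,1,2,2,10,2), type = "RING-D"),
        list(res = c("C","C","C","C","C","C","C","C"),
             gaps = c(2,12,1,4,2,12,2), type = "RING-C2"),
        list(res = c("C","S","C","H","C","C","C","C"),
             gaps = c(2,13,1,2,2,10,2), type = "RING-S/T"),
        list(res = c("C","C","C","H","C","T","C","C"),
             gaps = c(2,13,1,2,2,10,2), type = "RING-S/T"),
        list(res = c("C","C","C","H","G","C","C","C"),
             gaps = c(2,16,1,2,2,13,2), type = "RING-G"),
        list(res = rep("A", 8), gaps = c(2,12,1,2,2,10,2),
             type = "unclassified"))
    for (cs in cases) {
        got <- classifyChain(ligandChain(cs$res, gaps = cs$gaps))
        expect_identical(as.character(got), cs$type,
                         info = paste(cs$res, collapse = ""))
    }
})

test_that("residues are primary: off-window long loops warn, not reject", {
    ## HC signature with an ml2-ml3 gap of 50, outside every HC window
    ch <- ligandChain(c("C","C","C","H","C","C","C","C"),
                      gaps = c(2, 50, 1, 2, 2, 10, 2))
    got <- classifyChain(ch)
    expect_identical(as.character(got), "RING-HCa")
    expect_true(attr(got, "gapWarning"))
    expect_identical(attr(got, "offGaps"), 2L)
})

test_that("signature enumeration yields at most one type per chain", {
    ## exhaustive over the union residue signatures and the decisive
    ## gap dimensions; the long loops at representative extremes
    specs <- ringTypeSpecs()
    w <- scanWindows()
    sigs <- expand.grid(w@slotAlphabets, stringsAsFactors = FALSE)
    twoPlus <- 0L
    roundTrip <- TRUE
    for (r in seq_len(nrow(sigs))) {
        res <- unlist(sigs[r, ], use.names = FALSE)
        for (g7 in c(2L, 3L)) for (g4 in c(2L, 7L)) {
            ch <- ligandChain(res,
                              gaps = c(2L, 14L, 1L, g4, 2L, 12L, g7))
            compat <- vapply(specs, RINGcat:::.residuesCompatible,
                             logical(1), residues = res)
            hits <- names(specs)[compat]
            if (all(c("RING-HCa", "RING-HCb") %in% hits))
                hits <- setdiff(hits, if (g7 <= 2L) "RING-HCb"
                                else "RING-HCa")
            if (length(hits) > 1L) twoPlus <- twoPlus + 1L
            got <- as.character(classifyChain(ch))
            if (length(hits) == 0L && got != "unclassified")
                roundTrip <- FALSE
            if (length(hits) >= 1L && got != hits[1L])
                roundTrip <- FALSE
        }
    }
    expect_identical(twoPlus, 0L)
    expect_true(roundTrip)
})

test_that("chains built from any point of a spec classify back to it", {
    specs <- ringTypeSpecs()
    set.seed(11)
    for (nm in names(specs)) {
        s <- specs[[nm]]
        for (rep in 1:25) {
            res <- vapply(s@allowedResidues,
                          function(a) a[sample.int(length(a), 1)], "")
            req <- s@requires
            if (length(req) && !any(res[req$slots] %in% req$residues)) {
                slot <- req$slots[sample.int(length(req$slots), 1)]
                pool <- intersect(s@allowedResidues[[slot]],
                                  req$residues)
                res[slot] <- pool[sample.int(length(pool), 1)]
            }
            gaps <- vapply(s@gapWindows,
                           function(gw) gw[sample.int(length(gw), 1)],
                           0L)
            got <- classifyChain(ligandChain(res, gaps = gaps), specs)
            expect_identical(as.character(got), nm)
            expect_false(attr(got, "gapWarning"))
        }
    }
})

test_that("single-substitution chains recover their type and position", {
    ## frozen examples: exhaustive nearest-spec reasoning gives a unique
    ## answer in each case
    ch1 <- ligandChain(c("C","C","C","H","H","A","C","C"),
                       gaps = c(2, 14, 1, 2, 2, 10, 2))
    r1 <- classifyModified(ch1)
    expect_identical(r1$ringType, "RING-H2")
    expect_identical(r1$modifiedPosition, 6L)
    expect_false(r1$ambiguous)

    ch2 <- ligandChain(c("S","C","C","C","H","C","C","C"),
                       gaps = c(2, 12, 1, 7, 2, 12, 2))
    r2 <- classifyModified(ch2)
    expect_identical(r2$ringType, "RING-v")
    expect_identical(r2$modifiedPosition, 1L)

    ## two substitutions: incomplete by definition
    ch3 <- ligandChain(c("A","C","C","H","H","A","C","C"),
                       gaps = c(2, 14, 1, 2, 2, 10, 2))
    expect_error(classifyModified(ch3), "incomplete")

    ## property: every type, every slot, substitution by a letter not in
    ## any slot alphabet -> recovered position is the substituted slot
    specs <- ringTypeSpecs()
    set.seed(5)
    for (nm in names(specs)) {
        d <- sampleDomain(nm)
        res <- ligandResidues(d$chain)
        gaps <- ligandGaps(d$chain)
        for (slot in 1:8) {
            res2 <- res
            res2[slot] <- "M"
            r <- classifyModified(ligandChain(res2, gaps = gaps), specs)
            expect_identical(r$modifiedPosition, slot)
        }
    }
})

test_that("PHD-spacing chains are flagged and RING-v chains never are", {
    phd <- ligandChain(c("C","C","C","C","H","C","C","C"),
                       gaps = c(2, 12, 3, 4, 2, 12, 2))
    expect_true(isPhdLike(phd))
    v <- ligandChain(c("C","C","C","C","H","C","C","C"),
                     gaps = c(2, 12, 1, 7, 2, 12, 2))
    expect_false(isPhdLike(v))
    ## precondition signature absent
    h2 <- ligandChain(c("C","C","C","H","H","C","C","C"),
                      gaps = c(2, 12, 3, 4, 2, 12, 2))
    expect_false(isPhdLike(h2))
    ## RING-v requires g3 = 1 and g4 = 7: disjoint from the PHD window
    spec <- ringTypeSpecs()[["RING-v"]]
    for (g2 in c(11L, 30L, 77L)) {
        ch <- ligandChain(c("C","C","C","C","H","C","C","C"),
                          gaps = c(2L, g2, 1L, 7L, 2L, 12L, 2L))
        expect_false(isPhdLike(ch))
        expect_identical(as.character(classifyChain(ch)), "RING-v")
    }
})

test_that("type specs round-trip through the config file format", {
    specs <- ringTypeSpecs()
    f <- withr::local_tempfile(fileext = ".yml")
    writeTypeSpecs(specs, f)
    back <- readTypeSpecs(f)
    expect_identical(names(back), names(specs))
    for (nm in names(specs)) {
        expect_identical(back[[nm]]@allowedResidues,
                         specs[[nm]]@allowedResidues)
        expect_identical(back[[nm]]@gapWindows,
                         specs[[nm]]@gapWindows)
        expect_identical(back[[nm]]@requires, specs[[nm]]@requires)
    }
    ## extensibility: a user-defined type is read back intact
    ext <- specs["RING-H2"]
    ext[["RING-mH2"]] <- ext[["RING-H2"]]
    ext[["RING-mH2"]]@name <- "RING-mH2"
    writeTypeSpecs(ext, f)
    expect_identical(names(readTypeSpecs(f)), c("RING-H2", "RING-mH2"))
})
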