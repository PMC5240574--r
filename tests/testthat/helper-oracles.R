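## Independent oracles used across the suite. They deliberately avoid the
## package's internal search/merge code paths: chain enumeration is done
## by iterative cross-joins (the scanner uses depth-first recursion),
## complete linkage by a cubic scan over explicit cluster sets (the
## package uses stats::hclust), and pairwise alignment scores are
## cross-checked against Biostrings.

## All 8-position chains compatible with the windows, by cross-join.
oracleChains <- function(sequence, windows = scanWindows()) {
    letters <- strsplit(toupper(sequence), "")[[1L]]
    empty <- matrix(integer(0), ncol = 8L,
                    dimnames = list(NULL, paste0("ml", 1:8)))
    df <- data.frame(p1 = which(letters %in% windows@slotAlphabets[[1L]]))
    if (!nrow(df)) return(empty)
    for (k in 2:8) {
        nxt <- which(letters %in% windows@slotAlphabets[[k]])
        if (!length(nxt) || !nrow(df)) return(empty)
        idx <- expand.grid(i = seq_len(nrow(df)), p = nxt)
        cand <- df[idx$i, , drop = FALSE]
        cand[[paste0("p", k)]] <- idx$p
        gap <- cand[[k]] - cand[[k - 1L]] - 1L
        df <- cand[gap %in% windows@gapWindows[[k - 1L]], , drop = FALSE]
    }
    m <- unname(as.matrix(df))
    storage.mode(m) <- "integer"
    m[order(m[, 1L], m[, 8L] - m[, 1L], m[, 2L], m[, 3L], m[, 4L],
            m[, 5L], m[, 6L], m[, 7L]), , drop = FALSE]
}

## Full scan oracle: enumerate candidates at every relaxation level with
## oracleChains, apply the published filters, resolve overlaps with the
## documented key. Returns a data.frame comparable to scanProtein output.
oracleScan <- function(sequence, id = "protein",
                       specs = ringTypeSpecs(),
                       windows = scanWindows(),
                       findModified = TRUE, findIncomplete = TRUE) {
    letters <- strsplit(toupper(sequence), "")[[1L]]
    relaxSets <- list(integer(0))
    if (findModified) relaxSets <- c(relaxSets, as.list(1:8))
    if (findIncomplete)
        relaxSets <- c(relaxSets, combn(8L, 2L, simplify = FALSE))
    ## PHD mask from the canonical level
    can <- oracleChains(sequence, windows)
    phd <- vapply(seq_len(nrow(can)), function(i)
        isPhdLike(ligandChain(letters[can[i, ]],
                              positions = can[i, ])), logical(1L))
    maskS <- can[phd, 1L]; maskE <- can[phd, 8L]
    rows <- list()
    for (relax in relaxSets) {
        w <- windows
        for (s in relax)
            w@slotAlphabets[[s]] <- setdiff(AA_STANDARD,
                                            windows@slotAlphabets[[s]])
        m <- oracleChains(sequence, w)
        for (i in seq_len(nrow(m))) {
            ch <- ligandChain(letters[m[i, ]], positions = m[i, ])
            if (isPhdLike(ch)) next
            if (length(relax) > 0L && length(maskS) &&
                any(m[i, 1L] <= maskE & m[i, 8L] >= maskS)) next
            nsub <- length(relax)
            if (nsub == 0L) {
                type <- as.character(classifyChain(ch, specs))
                if (type == "unclassified") next
                modpos <- NA_integer_
            } else if (nsub == 1L) {
                r <- tryCatch(classifyModified(ch, specs),
                              error = function(e) NULL)
                if (is.null(r) || is.na(r$modifiedPosition)) next
                type <- r$ringType
                modpos <- r$modifiedPosition
                gaps <- ligandGaps(ch)
                bad <- vapply(c(1L, 3L, 4L, 5L, 7L), function(gi)
                    !gaps[gi] %in% specs[[type]]@gapWindows[[gi]],
                    logical(1L))
                if (any(bad)) next
            } else {
                type <- "incomplete"
                modpos <- NA_integer_
            }
            rows[[length(rows) + 1L]] <- data.frame(
                start = m[i, 1L], end = m[i, 8L], ring_type = type,
                nsub = nsub, modified_position = modpos,
                span = m[i, 8L] - m[i, 1L] + 1L,
                typicality = if (nsub == 1L)
                    RINGcat:::.spacingTypicality(ligandGaps(ch), type,
                                                 specs) else 0,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(protein_id = character(0), start = integer(0),
                          end = integer(0), ring_type = character(0),
                          modified_position = integer(0)))
    cand <- do.call(rbind, rows)
    prio <- match(cand$ring_type, RING_TYPES)
    prio[is.na(prio)] <- 9L
    typ <- ifelse(cand$nsub == 1L, cand$typicality, 0)
    ord <- order(cand$nsub, prio, -typ, cand$span, cand$start)
    occupied <- logical(nchar(sequence))
    keep <- logical(nrow(cand))
    for (i in ord) {
        rng <- cand$start[i]:cand$end[i]
        if (any(occupied[rng])) next
        occupied[rng] <- TRUE
        keep[i] <- TRUE
    }
    res <- cand[keep, , drop = FALSE]
    res <- res[order(res$start), , drop = FALSE]
    data.frame(protein_id = rep(id, nrow(res)), start = res$start,
               end = res$end, ring_type = res$ring_type,
               modified_position = res$modified_position,
               stringsAsFactors = FALSE, row.names = NULL)
}

## Cubic complete-linkage oracle over an explicit distance matrix.
## Returns merge heights and the partition (list of index sets) after
## each merge.
oracleCompleteLinkage <- function(D) {
    n <- nrow(D)
    clusters <- as.list(seq_len(n))
    heights <- numeric(0)
    partitions <- list()
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_len(length(clusters) - 1L))
            for (j in (i + 1L):length(clusters)) {
                d <- max(D[clusters[[i]], clusters[[j]]])
                if (d < bestD) { bestD <- d; best <- c(i, j) }
            }
        merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
        clusters <- c(clusters[-best], list(merged))
        heights <- c(heights, bestD)
        partitions[[length(partitions) + 1L]] <-
            lapply(clusters, sort)
    }
    list(heights = heights, partitions = partitions)
}

## Canonical signature of a partition (for label-free comparison).
partitionSignature <- function(groups) {
    sets <- vapply(groups, function(s)
        paste(sort(s), collapse = ","), "")
    paste(sort(sets), collapse = "|")
}

## Membership vector -> list of index sets.
membershipToSets <- function(cl)
    unname(lapply(split(seq_along(cl), cl), sort))

## Random protein sequence over the full standard alphabet.
randomProtein <- function(n)
    paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")

## A synthetic catalog data.frame built directly from sampled domains
## (no scanning involved), for the spacing-statistics tests.
chainCatalog <- function(types, seed = 1L) {
    set.seed(seed)
    rows <- lapply(seq_along(types), function(i) {
        d <- sampleDomain(types[i])
        g <- ligandGaps(d$chain)
        data.frame(protein_id = sprintf("p%04d", i), start = 1L,
                   end = chainSpan(d$chain), ring_type = types[i],
                   complete = TRUE, modified_position = NA_integer_,
                   gap_warning = FALSE, ambiguous = FALSE,
                   g1 = g[1L], g2 = g[2L], g3 = g[3L], g4 = g[4L],
                   g5 = g[5L], g6 = g[6L], g7 = g[7L],
                   residues = paste(ligandResidues(d$chain),
                                    collapse = ""),
                   sequence = d$fragment, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
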