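## Exhaustive constrained search for eight-ligand chains in protein
## sequences, and the cataloging step that turns raw chains into
## classified canonical, modified and incomplete RING domains.

## Depth-first enumeration of all 8-position chains whose residues lie in
## the slot alphabets and whose gaps lie in the windows. Returns an
## integer matrix with one row per chain (columns ml1..ml8), ordered by
## start position then span then remaining positions.
.findChainMatrix <- function(letters, gapWindows, slotAlphabets) {
    n <- length(letters)
    ok <- lapply(slotAlphabets, function(a) letters %in% a)
    hits <- vector("list", 64L)
    nh <- 0L
    pos <- integer(8L)
    descend <- function(k) {
        if (k == 8L) {
            nh <<- nh + 1L
            hits[[nh]] <<- pos
            return(invisible())
        }
        cand <- pos[k] + gapWindows[[k]] + 1L
        cand <- cand[cand <= n]
        cand <- cand[ok[[k + 1L]][cand]]
        for (p in cand) {
            pos[k + 1L] <<- p
            descend(k + 1L)
        }
    }
    for (p1 in which(ok[[1L]])) {
        pos[1L] <- p1
        descend(1L)
    }
    if (nh == 0L)
        return(matrix(integer(0), ncol = 8L))
    m <- do.call(rbind, hits[seq_len(nh)])
    o <- do.call(order, c(list(m[, 1L], m[, 8L] - m[, 1L]),
                          lapply(2:7, function(j) m[, j])))
    m[o, , drop = FALSE]
}

#' Find all candidate metal-ligand chains in a protein sequence
#'
#' Enumerates every chain of eight positions whose residues fall in the
#' scanner slot alphabets and whose seven inter-ligand gaps fall in the
#' scanner windows. The search is exhaustive within the constraints and
#' deterministic: chains are ordered by start position, then span.
#' Ambiguous residues (\code{X}) never match a ligand slot.
#'
#' @param sequence a protein sequence (character string).
#' @param windows a [ScanWindows-class]; default [scanWindows()].
#' @return List of [LigandChain-class] objects (empty when no chain
#'   matches).
#' @examples
#' seq <- paste0("MAAA", "CAACAAAAAAAAAAAAAACAHAAHAACAAAAAAAAAACAAC",
#'               "AAAA")
#' findLigandChains(seq)
#' @export
findLigandChains <- function(sequence, windows = scanWindows()) {
    letters <- strsplit(toupper(sequence), "")[[1L]]
    m <- .findChainMatrix(letters, windows@gapWindows,
                          windows@slotAlphabets)
    lapply(seq_len(nrow(m)), function(i)
        new("LigandChain", positions = m[i, ],
            residues = letters[m[i, ]]))
}

## Catalog schema shared by scanProtein/scanProteome and catalog I/O.
.emptyCatalog <- function() {
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), ring_type = character(0),
               complete = logical(0), modified_position = integer(0),
               gap_warning = logical(0), ambiguous = logical(0),
               g1 = integer(0), g2 = integer(0), g3 = integer(0),
               g4 = integer(0), g5 = integer(0), g6 = integer(0),
               g7 = integer(0), residues = character(0),
               sequence = character(0), stringsAsFactors = FALSE)
}

## Gather candidate domains at one relaxation level. `relax` is an
## integer vector of slots whose alphabet is replaced by "any standard
## residue except the canonical ones". Candidates overlapping a masked
## region (a PHD-like chain found at the canonical level) are dropped:
## the region is a PHD finger, not a degraded RING domain.
.gatherCandidates <- function(letters, specs, windows, relax,
                              mask = NULL) {
    alph <- windows@slotAlphabets
    for (s in relax)
        alph[[s]] <- setdiff(AA_STANDARD, windows@slotAlphabets[[s]])
    m <- .findChainMatrix(letters, windows@gapWindows, alph)
    out <- vector("list", nrow(m))
    for (i in seq_len(nrow(m))) {
        chain <- new("LigandChain", positions = m[i, ],
                     residues = letters[m[i, ]])
        if (isPhdLike(chain)) next
        if (!is.null(mask) && mask$n &&
            any(m[i, 1L] <= mask$end & m[i, 8L] >= mask$start))
            next
        nsub <- length(relax)
        if (nsub == 0L) {
            cls <- classifyChain(chain, specs)
            type <- as.character(cls)
            if (type == "unclassified") next
            out[[i]] <- list(chain = chain, nsub = 0L, type = type,
                             modpos = NA_integer_,
                             warning = attr(cls, "gapWarning"),
                             ambiguous = FALSE)
        } else if (nsub == 1L) {
            r <- tryCatch(classifyModified(chain, specs),
                          error = function(e) NULL)
            if (is.null(r) || is.na(r$modifiedPosition)) next
            ## a modified domain must still match its type's
            ## structure-fixing gaps (ml1-ml2, ml3-ml4, ml4-ml5,
            ## ml5-ml6, ml7-ml8); only the long loops are free
            off <- .offWindowGaps(ligandGaps(chain),
                                  specs[[r$ringType]])
            if (any(off %in% c(1L, 3L, 4L, 5L, 7L))) next
            out[[i]] <- list(chain = chain, nsub = 1L, type = r$ringType,
                             modpos = r$modifiedPosition,
                             warning = FALSE, ambiguous = r$ambiguous)
        } else {
            out[[i]] <- list(chain = chain, nsub = 2L,
                             type = "incomplete", modpos = NA_integer_,
                             warning = FALSE, ambiguous = FALSE)
        }
    }
    out[!vapply(out, is.null, logical(1L))]
}

## Spans of PHD-like chains found at the canonical level; they mask the
## relaxed searches so a PHD finger is never re-reported as a modified
## or incomplete RING domain.
.phdMask <- function(letters, windows) {
    m <- .findChainMatrix(letters, windows@gapWindows,
                          windows@slotAlphabets)
    phd <- logical(nrow(m))
    for (i in seq_len(nrow(m)))
        phd[i] <- isPhdLike(new("LigandChain", positions = m[i, ],
                                residues = letters[m[i, ]]))
    list(start = m[phd, 1L], end = m[phd, 8L], n = sum(phd))
}

## Deterministic overlap resolution: fewer substituted ligands first,
## then type priority (canonical abundance order, incomplete last),
## then -- among competing single-substitution readings of the same
## type -- the interpretation whose spacing is most typical for the
## type, then smaller span, then leftmost start.
.selectNonOverlapping <- function(cands, n, specs = ringTypeSpecs()) {
    if (!length(cands)) return(cands)
    nsub <- vapply(cands, `[[`, 0L, "nsub")
    prio <- vapply(cands, function(cd) {
        p <- match(cd$type, RING_TYPES)
        if (is.na(p)) 9L else p
    }, 0L)
    typ <- vapply(cands, function(cd) {
        if (cd$nsub != 1L) return(0)
        .spacingTypicality(ligandGaps(cd$chain), cd$type, specs)
    }, 0)
    span <- vapply(cands, function(cd) chainSpan(cd$chain), 0L)
    start <- vapply(cands, function(cd) ligandPositions(cd$chain)[1L], 0L)
    ord <- order(nsub, prio, -typ, span, start)
    occupied <- logical(n)
    keep <- logical(length(cands))
    for (i in ord) {
        rng <- start[i]:(start[i] + span[i] - 1L)
        if (any(occupied[rng])) next
        occupied[rng] <- TRUE
        keep[i] <- TRUE
    }
    cands[keep][order(start[keep])]
}

#' Scan one protein for RING domains
#'
#' The cataloging step: (1) canonical chains are found within the scanner
#' windows and classified; chains with the PHD spacing signature are
#' rejected; (2) a one-ligand-relaxed search (each slot in turn allowed to
#' be any residue except its canonical set) emits modified domains where
#' no canonical chain was accepted; (3) a two-ligand-relaxed search emits
#' incomplete domains (at least 6 of 8 ligands matched with consistent
#' spacing); (4) overlapping candidates are resolved deterministically
#' (fewest substitutions, then leftmost start, then smaller span, then
#' type abundance), so multiple non-overlapping domains per protein are
#' all reported.
#'
#' @param sequence protein sequence (character string).
#' @param id protein identifier recorded in the catalog.
#' @param specs list of [RingTypeSpec-class].
#' @param windows a [ScanWindows-class].
#' @param findModified,findIncomplete switch the relaxed searches off.
#' @return A catalog \code{data.frame} with one row per accepted domain:
#'   \code{protein_id}, 1-based inclusive \code{start}/\code{end},
#'   \code{ring_type} (a type name or \code{"incomplete"}),
#'   \code{complete}, \code{modified_position}, \code{gap_warning},
#'   \code{ambiguous}, gaps \code{g1..g7}, the eight ligand
#'   \code{residues}, and the spanned \code{sequence}.
#' @examples
#' seq <- paste0("MAAA", "CAACAAAAAAAAAAAAAACAHAAHAACAAAAAAAAAACAAC",
#'               "AAAA")
#' scanProtein(seq, id = "demo")
#' @export
scanProtein <- function(sequence, id = "protein",
                        specs = ringTypeSpecs(),
                        windows = scanWindows(),
                        findModified = TRUE, findIncomplete = TRUE) {
    letters <- strsplit(toupper(sequence), "")[[1L]]
    cands <- .gatherCandidates(letters, specs, windows, integer(0))
    mask <- .phdMask(letters, windows)
    if (findModified)
        for (s in 1:8)
            cands <- c(cands,
                       .gatherCandidates(letters, specs, windows, s,
                                         mask))
    if (findIncomplete)
        for (s in 1:7)
            for (t in (s + 1L):8L)
                cands <- c(cands,
                           .gatherCandidates(letters, specs, windows,
                                             c(s, t), mask))
    acc <- .selectNonOverlapping(cands, length(letters), specs)
    if (!length(acc)) return(.emptyCatalog())
    rows <- lapply(acc, function(cd) {
        p <- unname(ligandPositions(cd$chain))
        g <- ligandGaps(cd$chain)
        data.frame(protein_id = id, start = p[1L], end = p[8L],
                   ring_type = cd$type, complete = cd$nsub < 2L,
                   modified_position = cd$modpos,
                   gap_warning = cd$warning, ambiguous = cd$ambiguous,
                   g1 = g[1L], g2 = g[2L], g3 = g[3L], g4 = g[4L],
                   g5 = g[5L], g6 = g[6L], g7 = g[7L],
                   residues = paste(ligandResidues(cd$chain),
                                    collapse = ""),
                   sequence = paste(letters[p[1L]:p[8L]], collapse = ""),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Scan a whole proteome
#'
#' Applies [scanProtein()] to every record and concatenates the results,
#' with a per-protein summary counting proteins by number of reported
#' domains (complete domains only, mirroring the single- versus
#' double-domain census of RING surveys).
#'
#' @param sequences a named character vector or a
#'   \code{Biostrings::AAStringSet}; names are the protein ids and must be
#'   unique.
#' @inheritParams scanProtein
#' @return List with \code{catalog} (see [scanProtein()]) and
#'   \code{proteinSummary}, a \code{data.frame} of \code{n_domains} /
#'   \code{n_proteins}.
#' @examples
#' seqs <- c(p1 = paste0("MAAA",
#'           "CAACAAAAAAAAAAAAAACAHAAHAACAAAAAAAAAACAAC", "AAAA"))
#' scanProteome(seqs)$proteinSummary
#' @export
scanProteome <- function(sequences, specs = ringTypeSpecs(),
                         windows = scanWindows(),
                         findModified = TRUE, findIncomplete = TRUE) {
    if (methods::is(sequences, "XStringSet"))
        sequences <- stats::setNames(as.character(sequences),
                                     names(sequences))
    if (!length(sequences))
        return(list(catalog = .emptyCatalog(),
                    proteinSummary = data.frame(n_domains = integer(0),
                                                n_proteins = integer(0))))
    ids <- names(sequences)
    if (is.null(ids) || any(!nzchar(ids)))
        stop("every sequence must be named with a protein id")
    if (anyDuplicated(ids))
        stop("duplicate protein id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    parts <- lapply(ids, function(i)
        scanProtein(sequences[[i]], id = i, specs = specs,
                    windows = windows, findModified = findModified,
                    findIncomplete = findIncomplete))
    catalog <- do.call(rbind, c(parts, list(.emptyCatalog())))
    rownames(catalog) <- NULL
    nDom <- table(factor(catalog$protein_id[catalog$complete],
                         levels = ids))
    tab <- table(as.integer(nDom))
    proteinSummary <- data.frame(
        n_domains = as.integer(names(tab)),
        n_proteins = as.integer(tab))
    list(catalog = catalog, proteinSummary = proteinSummary)
}
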