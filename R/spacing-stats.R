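## Type census, per-type gap histograms, ligand-anchored residue
## frequency matrices, over-represented residue calling, and
## domain-architecture grouping.

## Complete, classified rows of a catalog (modified domains count under
## their assigned type; incomplete and unclassified are excluded).
.classifiedRows <- function(catalog)
    catalog[catalog$complete & catalog$ring_type %in% RING_TYPES, ,
            drop = FALSE]

#' Census of RING types in a catalog
#'
#' Counts complete, classified domains per RING type; modified domains are
#' counted under their assigned type, incomplete domains are excluded.
#'
#' @param catalog a domain catalog (see [scanProtein()]).
#' @return Named integer vector over the eight types (zeros included).
#' @examples
#' typeCensus(RINGcat:::.emptyCatalog())
#' @export
typeCensus <- function(catalog) {
    rows <- .classifiedRows(catalog)
    tab <- table(factor(rows$ring_type, levels = RING_TYPES))
    stats::setNames(as.integer(tab), RING_TYPES)
}

#' Per-type histograms of the seven inter-ligand gaps
#'
#' The machine-readable form of the spacing-variation tables: for each
#' RING type and each gap index, the count of domains per observed gap
#' size, plus a pooled histogram over all types
#' (\code{ring_type == "all"}).
#'
#' @param catalog a domain catalog.
#' @return \code{data.frame} with columns \code{ring_type},
#'   \code{gap_index} (1--7), \code{gap_size}, \code{count}.
#' @examples
#' cat1 <- data.frame(protein_id = "p", start = 1L, end = 27L,
#'   ring_type = "RING-H2", complete = TRUE, modified_position = NA,
#'   gap_warning = FALSE, ambiguous = FALSE, g1 = 2L, g2 = 14L, g3 = 1L,
#'   g4 = 2L, g5 = 2L, g6 = 10L, g7 = 2L, residues = "CCCHHCCC",
#'   sequence = "")
#' gapHistograms(cat1)
#' @export
gapHistograms <- function(catalog) {
    rows <- .classifiedRows(catalog)
    out <- list()
    gcols <- paste0("g", 1:7)
    groups <- c(stats::setNames(as.list(RING_TYPES), RING_TYPES),
                list(all = RING_TYPES))
    for (nm in names(groups)) {
        sub <- rows[rows$ring_type %in% groups[[nm]], , drop = FALSE]
        if (!nrow(sub)) next
        for (i in 1:7) {
            tab <- table(sub[[gcols[i]]])
            out[[length(out) + 1L]] <- data.frame(
                ring_type = if (nm == "all") "all" else nm,
                gap_index = i,
                gap_size = as.integer(names(tab)),
                count = as.integer(tab), stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(ring_type = character(0),
                          gap_index = integer(0), gap_size = integer(0),
                          count = integer(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Observed spacing consensus per type
#'
#' Summarises a spacing table into the observed window of each gap per
#' type: the \code{[min, max]} range, with the explicit value set also
#' reported when at most three distinct sizes were observed. Types absent
#' from the catalog are omitted.
#'
#' @param spacing a spacing table from [gapHistograms()].
#' @return \code{data.frame} with columns \code{ring_type},
#'   \code{gap_index}, \code{min}, \code{max}, \code{values} (comma list
#'   or \code{NA} when more than three distinct sizes).
#' @export
spacingConsensus <- function(spacing) {
    spacing <- spacing[spacing$ring_type != "all", , drop = FALSE]
    if (!nrow(spacing))
        return(data.frame(ring_type = character(0),
                          gap_index = integer(0), min = integer(0),
                          max = integer(0), values = character(0)))
    key <- interaction(spacing$ring_type, spacing$gap_index, drop = TRUE)
    out <- lapply(split(spacing, key), function(s) {
        sizes <- sort(unique(s$gap_size))
        data.frame(ring_type = s$ring_type[1L],
                   gap_index = s$gap_index[1L],
                   min = min(sizes), max = max(sizes),
                   values = if (length(sizes) <= 3L)
                       paste(sizes, collapse = ",") else NA_character_,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    res <- res[order(match(res$ring_type, RING_TYPES), res$gap_index), ]
    rownames(res) <- NULL
    res
}

#' Ligand-anchored residue-frequency matrix
#'
#' Builds the numerical equivalent of a sequence logo for one RING type:
#' for each of the eight metal-ligand slots, the ligand column itself plus
#' up to \code{flank} columns on each side. Flank columns are anchored on
#' the ligand, so the variable loops contribute only their ligand-adjacent
#' residues; columns where a domain's loop is shorter than the flank (or
#' that fall outside the domain span) simply receive fewer observations,
#' and the per-column observation count is recorded as coverage.
#' Frequencies are relative to the observed residues in each column.
#'
#' @param catalog a domain catalog.
#' @param ringType the type to summarise.
#' @param flank number of columns kept on each side of each ligand.
#' @return A [PositionFrequencyMatrix-class].
#' @export
anchoredFrequencyMatrix <- function(catalog, ringType, flank = 3L) {
    flank <- as.integer(flank)
    if (flank < 0L) stop("'flank' must be >= 0")
    rows <- .classifiedRows(catalog)
    rows <- rows[rows$ring_type == ringType, , drop = FALSE]
    if (!nrow(rows))
        stop("no complete domain of type ", ringType, " in the catalog")
    cols <- character(0)
    for (k in 1:8) {
        if (flank > 0L)
            cols <- c(cols, paste0("ml", k, "-", rev(seq_len(flank))))
        cols <- c(cols, paste0("ml", k))
        if (flank > 0L)
            cols <- c(cols, paste0("ml", k, "+", seq_len(flank)))
    }
    counts <- matrix(0L, nrow = length(AA_STANDARD), ncol = length(cols),
                     dimnames = list(AA_STANDARD, cols))
    gcols <- paste0("g", 1:7)
    for (r in seq_len(nrow(rows))) {
        g <- as.integer(unlist(rows[r, gcols]))
        anchor <- c(1L, cumsum(g + 1L) + 1L)  # ligand offsets in the span
        letters <- strsplit(rows$sequence[r], "")[[1L]]
        for (k in 1:8) {
            counts[letters[anchor[k]], paste0("ml", k)] <-
                counts[letters[anchor[k]], paste0("ml", k)] + 1L
            if (flank == 0L) next
            for (j in seq_len(flank)) {
                ## left flank stays inside the preceding loop
                if (k > 1L && j <= g[k - 1L]) {
                    aa <- letters[anchor[k] - j]
                    cn <- paste0("ml", k, "-", j)
                    if (aa %in% AA_STANDARD)
                        counts[aa, cn] <- counts[aa, cn] + 1L
                }
                ## right flank stays inside the following loop
                if (k < 8L && j <= g[k]) {
                    aa <- letters[anchor[k] + j]
                    cn <- paste0("ml", k, "+", j)
                    if (aa %in% AA_STANDARD)
                        counts[aa, cn] <- counts[aa, cn] + 1L
                }
            }
        }
    }
    coverage <- as.integer(colSums(counts))
    keep <- coverage > 0L
    freq <- counts[, keep, drop = FALSE]
    freq <- sweep(freq, 2L, colSums(freq), "/")
    new("PositionFrequencyMatrix", freq = freq,
        coverage = coverage[keep], ringType = ringType,
        nDomains = nrow(rows))
}

#' Default residue-equivalence pairs for over-representation calling
#'
#' Physico-chemically similar pairs that are reported jointly when their
#' combined column frequency crosses the threshold: Phe/Tyr, Ile/Val,
#' Glu/Asp, Lys/Gly, Ser/Thr, Ala/Val.
#'
#' @format List of character pairs.
#' @export
RESIDUE_EQUIVALENCES <- list(c("F", "Y"), c("I", "V"), c("E", "D"),
                             c("K", "G"), c("S", "T"), c("A", "V"))

#' Over-represented residues in an anchored frequency matrix
#'
#' Reports, per column, single residues whose frequency reaches the
#' threshold, and equivalence pairs (e.g. \{F,Y\}) whose combined
#' frequency reaches it when no single member does on its own.
#'
#' @param pfm a [PositionFrequencyMatrix-class].
#' @param threshold minimum column frequency in (0, 1].
#' @param equivalences list of residue pairs considered jointly;
#'   default [RESIDUE_EQUIVALENCES].
#' @return \code{data.frame} with columns \code{column},
#'   \code{residues} (e.g. \code{"F"} or \code{"I/V"}),
#'   \code{frequency}.
#' @export
overRepresentedResidues <- function(pfm, threshold = 0.5,
                                    equivalences = RESIDUE_EQUIVALENCES) {
    if (threshold <= 0 || threshold > 1)
        stop("'threshold' must be in (0, 1]")
    out <- list()
    f <- pfm@freq
    for (j in seq_len(ncol(f))) {
        col <- f[, j]
        singles <- names(col)[col >= threshold]
        for (s in singles)
            out[[length(out) + 1L]] <- data.frame(
                column = colnames(f)[j], residues = s,
                frequency = unname(col[s]), stringsAsFactors = FALSE)
        for (eq in equivalences) {
            if (any(eq %in% singles)) next
            fsum <- sum(col[eq], na.rm = TRUE)
            if (fsum >= threshold)
                out[[length(out) + 1L]] <- data.frame(
                    column = colnames(f)[j],
                    residues = paste(eq, collapse = "/"),
                    frequency = fsum, stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(column = character(0), residues = character(0),
                          frequency = numeric(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Group proteins by additional-domain architecture
#'
#' Groups catalog proteins by the ordered tuple of non-RING domain names
#' along the protein (N- to C-terminal), as annotated in a user-supplied
#' table. Repeated consecutive copies of the same domain collapse to one
#' key element by default (so a protein with one trans-membrane segment
#' and one with three fall in the same group), with the total copy number
#' kept per protein. Proteins with no additional domain form their own
#' group (\code{"none"}); groups are ordered by size, largest first.
#'
#' @param annotations \code{data.frame} with columns \code{protein_id},
#'   \code{domain_name}, \code{start}, \code{end}; may be empty.
#' @param catalog a domain catalog naming the proteins to group.
#' @param collapseRepeats collapse consecutive repeats of a domain name.
#' @return List with \code{assignment} (\code{protein_id},
#'   \code{architecture}, \code{n_additional}) and \code{groups}
#'   (\code{architecture}, \code{n_proteins}, size-sorted).
#' @export
architectureGroups <- function(annotations, catalog,
                               collapseRepeats = TRUE) {
    ids <- unique(catalog$protein_id)
    if (!length(ids))
        return(list(assignment = data.frame(protein_id = character(0),
                                            architecture = character(0),
                                            n_additional = integer(0)),
                    groups = data.frame(architecture = character(0),
                                        n_proteins = integer(0))))
    if (is.null(annotations))
        annotations <- data.frame(protein_id = character(0),
                                  domain_name = character(0),
                                  start = integer(0), end = integer(0))
    bad <- setdiff(annotations$protein_id, ids)
    if (length(bad))
        stop("annotation rows reference unknown protein(s): ",
             paste(utils::head(bad, 5L), collapse = ", "))
    arch <- vapply(ids, function(id) {
        rows <- annotations[annotations$protein_id == id, , drop = FALSE]
        if (!nrow(rows)) return("none")
        nm <- rows$domain_name[order(rows$start)]
        if (collapseRepeats) nm <- rle(nm)$values
        paste(nm, collapse = "+")
    }, "")
    nAdd <- vapply(ids, function(id)
        sum(annotations$protein_id == id), 0L)
    assignment <- data.frame(protein_id = ids, architecture = arch,
                             n_additional = as.integer(nAdd),
                             stringsAsFactors = FALSE, row.names = NULL)
    tab <- sort(table(arch), decreasing = TRUE)
    groups <- data.frame(architecture = names(tab),
                         n_proteins = as.integer(tab),
                         stringsAsFactors = FALSE)
    list(assignment = assignment, groups = groups)
}
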