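## Ligand-anchored multiple alignment: the eight metal-ligand columns are
## fixed and each of the seven inter-ligand blocks is aligned
## independently, so every row's ligands land in the same columns.

## Global (Needleman-Wunsch) alignment with match 1, mismatch 0, linear
## gap -1. Ties resolved diagonal > up > left, making the traceback
## deterministic. Returns the two aligned strings and the score.
.nwAlign <- function(a, b) {
    x <- strsplit(a, "")[[1L]]
    y <- strsplit(b, "")[[1L]]
    n <- length(x); m <- length(y)
    S <- matrix(0, n + 1L, m + 1L)
    S[, 1L] <- -(0:n)
    S[1L, ] <- -(0:m)
    for (i in seq_len(n))
        for (j in seq_len(m))
            S[i + 1L, j + 1L] <- max(
                S[i, j] + (x[i] == y[j]),
                S[i, j + 1L] - 1,
                S[i + 1L, j] - 1)
    ai <- character(0); bi <- character(0)
    i <- n; j <- m
    while (i > 0L || j > 0L) {
        if (i > 0L && j > 0L &&
            S[i + 1L, j + 1L] == S[i, j] + (x[i] == y[j])) {
            ai <- c(x[i], ai); bi <- c(y[j], bi)
            i <- i - 1L; j <- j - 1L
        } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] - 1) {
            ai <- c(x[i], ai); bi <- c("-", bi)
            i <- i - 1L
        } else {
            ai <- c("-", ai); bi <- c(y[j], bi)
            j <- j - 1L
        }
    }
    list(a = paste(ai, collapse = ""), b = paste(bi, collapse = ""),
         score = S[n + 1L, m + 1L])
}

.nwScore <- function(a, b) .nwAlign(a, b)$score

## Center-star merge: align every loop to the center loop and merge the
## per-pair insertions into a single master gap profile.
.centerStar <- function(loops) {
    k <- length(loops)
    if (k == 1L) return(loops)
    scores <- matrix(0, k, k)
    for (i in seq_len(k - 1L))
        for (j in (i + 1L):k)
            scores[i, j] <- scores[j, i] <- .nwScore(loops[i], loops[j])
    center <- which.max(rowSums(scores))
    cLen <- nchar(loops[center])
    alns <- vector("list", k)
    ins <- matrix(0L, k, cLen + 1L)  # gaps opened in the center, per slot
    for (i in seq_len(k)) {
        if (i == center) next
        al <- .nwAlign(loops[center], loops[i])
        alns[[i]] <- al
        slot <- 0L
        for (ch in strsplit(al$a, "")[[1L]]) {
            if (ch == "-") ins[i, slot + 1L] <- ins[i, slot + 1L] + 1L
            else slot <- slot + 1L
        }
    }
    master <- apply(ins, 2L, max)
    expand <- function(alignedC, alignedS) {
        outS <- character(0)
        slot <- 0L; used <- 0L
        cc <- strsplit(alignedC, "")[[1L]]
        ss <- strsplit(alignedS, "")[[1L]]
        for (p in seq_along(cc)) {
            if (cc[p] == "-") {
                outS <- c(outS, ss[p]); used <- used + 1L
            } else {
                outS <- c(outS, rep("-", master[slot + 1L] - used),
                          ss[p])
                slot <- slot + 1L; used <- 0L
            }
        }
        outS <- c(outS, rep("-", master[slot + 1L] - used))
        paste(outS, collapse = "")
    }
    out <- character(k)
    centerChars <- strsplit(loops[center], "")[[1L]]
    centerRow <- character(0)
    for (s in 0:cLen) {
        centerRow <- c(centerRow, rep("-", master[s + 1L]))
        if (s < cLen) centerRow <- c(centerRow, centerChars[s + 1L])
    }
    out[center] <- paste(centerRow, collapse = "")
    for (i in seq_len(k))
        if (i != center)
            out[i] <- expand(alns[[i]]$a, alns[[i]]$b)
    out
}

#' Align a set of inter-ligand loops to equal width
#'
#' The seven inter-ligand blocks of an anchored alignment are filled
#' independently, one call per block. Padding modes insert gap characters
#' deterministically to the common maximum width; \code{center-star}
#' picks the loop with maximal summed pairwise identity (global alignment
#' score, match 1 / mismatch 0 / gap -1) as the center, aligns every
#' other loop to it and merges the insertions, which can make the block
#' wider than the longest loop.
#'
#' @param loops character vector of loop sequences (may contain empty
#'   strings).
#' @param mode \code{"pad-right"}, \code{"pad-center"} (half the padding
#'   left, remainder right) or \code{"center-star"}.
#' @return Character vector of equal-width strings, input order
#'   preserved; empty input gives an empty block.
#' @examples
#' loopSubalign(c("ABCD", "AB"), "pad-right")
#' loopSubalign(c("ABCD", "ACD", "BCD"), "center-star")
#' @export
loopSubalign <- function(loops,
                         mode = c("pad-right", "pad-center",
                                  "center-star")) {
    mode <- match.arg(mode)
    if (!length(loops)) return(character(0))
    loops <- as.character(loops)
    w <- max(nchar(loops))
    if (mode == "pad-right")
        return(paste0(loops, strrep("-", w - nchar(loops))))
    if (mode == "pad-center") {
        pad <- w - nchar(loops)
        left <- pad %/% 2L
        return(paste0(strrep("-", left), loops,
                      strrep("-", pad - left)))
    }
    .centerStar(loops)
}

#' Build the ligand-anchored multiple alignment of a domain catalog
#'
#' Places the eight ligand residues of every domain in eight shared
#' columns and fills each of the seven inter-ligand blocks with
#' [loopSubalign()]. With the padding modes the block width equals the
#' maximum gap observed for that block, so the total width is
#' \code{8 + sum(max gaps)}. Removing the gap characters from any row
#' reproduces that domain's sequence exactly.
#'
#' @param catalog a domain catalog carrying domain \code{sequence}s
#'   (incomplete domains are excluded).
#' @param mode loop-alignment mode, see [loopSubalign()].
#' @return An [AnchoredAlignment-class]; row ids are
#'   \code{protein_id_start} so double-domain proteins stay distinct.
#' @export
anchorAlign <- function(catalog, mode = c("pad-right", "pad-center",
                                          "center-star")) {
    mode <- match.arg(mode)
    rows <- catalog[catalog$complete, , drop = FALSE]
    if (!nrow(rows)) stop("no complete domain to align")
    gcols <- paste0("g", 1:7)
    n <- nrow(rows)
    loops <- matrix("", n, 7L)
    ligs <- matrix("", n, 8L)
    for (r in seq_len(n)) {
        g <- as.integer(unlist(rows[r, gcols]))
        anchor <- c(1L, cumsum(g + 1L) + 1L)
        letters <- strsplit(rows$sequence[r], "")[[1L]]
        ligs[r, ] <- letters[anchor]
        for (i in 1:7)
            loops[r, i] <- paste(
                letters[seq(anchor[i] + 1L, length.out = g[i])],
                collapse = "")
    }
    blocks <- lapply(1:7, function(i) loopSubalign(loops[, i], mode))
    rowsOut <- character(n)
    for (r in seq_len(n))
        rowsOut[r] <- paste0(paste0(ligs[r, 1:7],
                                    vapply(blocks, `[`, "", r),
                                    collapse = ""), ligs[r, 8L])
    widths <- vapply(blocks, function(b) nchar(b[1L]), 0L)
    anchors <- as.integer(c(1L, 1L + cumsum(widths + 1L)))
    new("AnchoredAlignment",
        ids = paste0(rows$protein_id, "_", rows$start),
        rows = rowsOut, anchors = anchors, mode = mode)
}

#' Export an anchored alignment
#'
#' Writes the alignment as aligned FASTA (gap character \code{"-"}) and,
#' optionally, the eight ligand column indices as a sidecar TSV.
#'
#' @param alignment an [AnchoredAlignment-class].
#' @param fastaPath output FASTA path.
#' @param anchorsPath optional TSV path for the anchor columns.
#' @return \code{fastaPath}, invisibly.
#' @export
writeAnchoredAlignment <- function(alignment, fastaPath,
                                   anchorsPath = NULL) {
    seqs <- Biostrings::AAStringSet(
        stats::setNames(alignment@rows, alignment@ids))
    Biostrings::writeXStringSet(seqs, fastaPath)
    if (!is.null(anchorsPath))
        utils::write.table(
            data.frame(ligand = paste0("ml", 1:8),
                       column = alignment@anchors),
            anchorsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(fastaPath)
}
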