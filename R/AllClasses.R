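#' @import methods
NULL

#' The 20 standard amino-acid letters
#'
#' One-letter codes of the 20 standard amino acids, in alphabetical order.
#' The ambiguity code \code{X} is deliberately absent: it never matches a
#' metal-ligand slot.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Canonical order of the eight RING types
#'
#' Type names in descending order of abundance in plant RING surveys
#' (RING-H2 most common, RING-G rarest). This order is also the
#' deterministic tie-break used when a modified domain is equally close to
#' several types.
#'
#' @format Character vector of length 8.
#' @export
RING_TYPES <- c("RING-H2", "RING-HCa", "RING-HCb", "RING-v",
                "RING-C2", "RING-D", "RING-S/T", "RING-G")

## ---------------------------------------------------------------------------
## LigandChain
## ---------------------------------------------------------------------------

#' LigandChain: the eight metal-ligand positions of one candidate domain
#'
#' A RING domain coordinates two zinc ions through eight metal ligands
#' (ml1--ml8), normally Cys or His. A \code{LigandChain} records the eight
#' 1-based sequence positions and the residue observed at each. The seven
#' inter-ligand gaps (number of residues strictly between consecutive
#' ligands) are derived, not stored.
#'
#' @slot positions integer(8), strictly increasing 1-based indices.
#' @slot residues character(8), single upper-case amino-acid letters.
#'
#' @seealso [ligandChain()], [ligandGaps()], [classifyChain()]
#' @export
setClass("LigandChain",
    representation(positions = "integer", residues = "character"))

setValidity("LigandChain", function(object) {
    p <- object@positions
    r <- object@residues
    if (length(p) != 8L || length(r) != 8L)
        return("positions and residues must both have length 8")
    if (anyNA(p) || anyNA(r))
        return("positions/residues must not contain NA")
    if (any(diff(p) < 1L))
        return("positions must be strictly increasing")
    if (p[1L] < 1L)
        return("positions must be >= 1")
    if (!all(nchar(r) == 1L) || any(r != toupper(r)))
        return("residues must be single upper-case letters")
    TRUE
})

#' Construct a LigandChain
#'
#' Either supply the eight positions directly, or supply the seven gaps plus
#' a start position, in which case positions are derived as
#' \code{start, start + gap1 + 1, ...}.
#'
#' @param residues character(8) single-letter residues at ml1..ml8.
#' @param positions integer(8) strictly increasing 1-based indices
#'   (mutually exclusive with \code{gaps}).
#' @param gaps integer(7) residues strictly between consecutive ligands.
#' @param start 1-based position of ml1 when constructing from \code{gaps}.
#' @return A [LigandChain-class] object.
#' @examples
#' ligandChain(c("C","C","C","H","H","C","C","C"),
#'             gaps = c(2, 14, 1, 2, 2, 10, 2))
#' @export
ligandChain <- function(residues, positions = NULL, gaps = NULL, start = 1L) {
    residues <- toupper(as.character(residues))
    if (is.null(positions)) {
        if (is.null(gaps))
            stop("supply either 'positions' or 'gaps'")
        gaps <- as.integer(gaps)
        if (length(gaps) != 7L || anyNA(gaps) || any(gaps < 0L))
            stop("'gaps' must be 7 non-negative integers")
        positions <- as.integer(start) + c(0L, cumsum(gaps + 1L))
    }
    new("LigandChain", positions = as.integer(positions), residues = residues)
}

#' @describeIn ligandChain Seven inter-ligand gaps of a chain.
#' @param chain a [LigandChain-class].
#' @export
ligandGaps <- function(chain) diff(chain@positions) - 1L

#' @describeIn ligandChain Ligand positions (1-based).
#' @export
ligandPositions <- function(chain) chain@positions

#' @describeIn ligandChain Ligand residues.
#' @export
ligandResidues <- function(chain) chain@residues

#' @describeIn ligandChain Span of the chain in residues (ml1..ml8
#'   inclusive); always \code{8 + sum(gaps)}.
#' @export
chainSpan <- function(chain)
    chain@positions[8L] - chain@positions[1L] + 1L

setMethod("show", "LigandChain", function(object) {
    g <- ligandGaps(object)
    cat("LigandChain: ",
        paste0(object@residues, c(paste0("-x", g, "-"), "")), "\n",
        "  positions: ", paste(object@positions, collapse = " "),
        " (span ", chainSpan(object), ")\n", sep = "")
})

## ---------------------------------------------------------------------------
## RingTypeSpec
## ---------------------------------------------------------------------------

#' RingTypeSpec: consensus definition of one RING type
#'
#' Encodes one row of the type taxonomy: the residues allowed at each of the
#' eight metal-ligand slots, the gap window (allowed sizes of the
#' inter-ligand spacing) for each of the seven gaps, and an optional
#' "at least one of" requirement (e.g. RING-D needs an Asp at ml5 or ml6,
#' otherwise the chain is an ordinary RING-HC).
#'
#' @slot name type name, e.g. \code{"RING-H2"}.
#' @slot allowedResidues list of 8 character vectors.
#' @slot gapWindows list of 7 integer vectors of allowed gap sizes.
#' @slot requires list with elements \code{slots} (integer) and
#'   \code{residues} (character): at least one of \code{residues} must occur
#'   at one of \code{slots}; empty list if unconditional.
#'
#' @seealso [ringTypeSpecs()]
#' @export
setClass("RingTypeSpec",
    representation(name = "character", allowedResidues = "list",
                   gapWindows = "list", requires = "list"))

setValidity("RingTypeSpec", function(object) {
    if (length(object@allowedResidues) != 8L)
        return("allowedResidues must have 8 elements")
    if (length(object@gapWindows) != 7L)
        return("gapWindows must have 7 elements")
    if (!identical(as.integer(object@gapWindows[[1L]]), 2L))
        return("gap ml1-ml2 must be {2} for every RING type")
    for (i in c(1L, 7L, 8L))
        if (!identical(object@allowedResidues[[i]], "C"))
            return("ml1, ml7 and ml8 must be Cys for every RING type")
    TRUE
})

setMethod("show", "RingTypeSpec", function(object) {
    res <- vapply(object@allowedResidues, paste, "", collapse = "/")
    win <- vapply(object@gapWindows, function(w) {
        w <- sort(unique(as.integer(w)))
        if (length(w) > 3L && identical(w, seq(min(w), max(w))))
            paste0(min(w), "-", max(w)) else paste(w, collapse = ",")
    }, "")
    cat(object@name, ": ",
        paste0(res, c(paste0(" x", win, " "), "")), "\n", sep = "")
    if (length(object@requires))
        cat("  requires >=1 of {",
            paste(object@requires$residues, collapse = ","), "} at ml",
            paste(object@requires$slots, collapse = "/ml"), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## ScanWindows
## ---------------------------------------------------------------------------

#' ScanWindows: search-space constraints for the ligand-chain scanner
#'
#' The scanner enumerates candidate eight-ligand chains whose slot residues
#' fall in \code{slotAlphabets} and whose seven gaps fall in
#' \code{gapWindows}. The defaults are the unions over all eight type
#' definitions, with the long loops (ml2--ml3 and ml6--ml7) widened to the
#' extremes observed across plant RING surveys (8--77 and 4--64 residues).
#'
#' @slot gapWindows list of 7 integer vectors.
#' @slot slotAlphabets list of 8 character vectors of letters accepted as
#'   the ligand at each slot.
#'
#' @seealso [scanWindows()], [findLigandChains()]
#' @export
setClass("ScanWindows",
    representation(gapWindows = "list", slotAlphabets = "list"))

setValidity("ScanWindows", function(object) {
    if (length(object@gapWindows) != 7L)
        return("gapWindows must have 7 elements")
    if (length(object@slotAlphabets) != 8L)
        return("slotAlphabets must have 8 elements")
    if (any(vapply(object@gapWindows, length, 0L) == 0L))
        return("empty gap window")
    if (any(vapply(object@slotAlphabets, length, 0L) == 0L))
        return("empty slot alphabet")
    TRUE
})

#' Construct scanner windows
#'
#' @param gapWindows list of 7 integer vectors of allowed gap sizes;
#'   defaults to the union of all type windows with observed long-loop
#'   extremes.
#' @param slotAlphabets list of 8 character vectors; defaults to the union
#'   of the type residue sets.
#' @return A [ScanWindows-class] object.
#' @examples
#' w <- scanWindows()
#' w@gapWindows[[1]]   # the ml1-ml2 gap is always 2
#' @export
scanWindows <- function(gapWindows = NULL, slotAlphabets = NULL) {
    if (is.null(gapWindows))
        gapWindows <- list(2L, 8:77, 1:3, 2:7, 2:4, 4:64, 2:4)
    if (is.null(slotAlphabets))
        slotAlphabets <- list("C", c("C", "S"), "C", c("H", "C"),
                              c("H", "C", "D", "G"), c("C", "D", "S", "T"),
                              "C", "C")
    new("ScanWindows",
        gapWindows = lapply(gapWindows, function(w) sort(as.integer(w))),
        slotAlphabets = lapply(slotAlphabets, toupper))
}

setMethod("show", "ScanWindows", function(object) {
    win <- vapply(object@gapWindows, function(w)
        if (length(w) == 1L) as.character(w)
        else paste0(min(w), "-", max(w)), "")
    alph <- vapply(object@slotAlphabets, paste, "", collapse = "")
    cat("ScanWindows\n  slots: ", paste(alph, collapse = " "),
        "\n  gaps:  ", paste(win, collapse = " "), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## PositionFrequencyMatrix
## ---------------------------------------------------------------------------

#' PositionFrequencyMatrix: ligand-anchored residue frequencies
#'
#' Residue frequencies in columns anchored on the eight metal-ligand slots
#' plus a fixed number of flank columns on each side of each ligand
#' (columns named \code{ml5-1}, \code{ml5}, \code{ml5+1}, ...). Variable
#' loops contribute only their ligand-adjacent flank columns, so column
#' coverage (number of observations) varies and is stored alongside.
#'
#' @slot freq numeric matrix, rows = residues, columns = anchored columns;
#'   each column sums to 1 over observed residues.
#' @slot coverage integer, observations per column.
#' @slot ringType the RING type summarised.
#' @slot nDomains number of domains contributing.
#'
#' @seealso [anchoredFrequencyMatrix()], [overRepresentedResidues()]
#' @export
setClass("PositionFrequencyMatrix",
    representation(freq = "matrix", coverage = "integer",
                   ringType = "character", nDomains = "integer"))

setValidity("PositionFrequencyMatrix", function(object) {
    if (ncol(object@freq) != length(object@coverage))
        return("coverage must have one entry per column")
    cs <- colSums(object@freq)
    if (any(abs(cs[object@coverage > 0L] - 1) > 1e-9))
        return("columns with coverage must sum to 1")
    TRUE
})

setMethod("show", "PositionFrequencyMatrix", function(object) {
    cat("PositionFrequencyMatrix for ", object@ringType, " (",
        object@nDomains, " domains, ", ncol(object@freq), " columns)\n",
        sep = "")
    top <- apply(object@freq, 2L, function(f)
        if (all(f == 0)) "." else rownames(object@freq)[which.max(f)])
    cat("  consensus: ", paste(top, collapse = ""), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## AnchoredAlignment
## ---------------------------------------------------------------------------

#' AnchoredAlignment: multiple alignment with fixed metal-ligand columns
#'
#' An alignment of RING domains in which the eight ligand residues of every
#' row sit in the same eight columns; the seven inter-ligand blocks are
#' filled independently by [loopSubalign()].
#'
#' @slot ids row identifiers.
#' @slot rows aligned sequences (equal width, gap character \code{"-"}).
#' @slot anchors integer(8), 1-based column index of each ligand.
#' @slot mode loop-alignment mode used.
#'
#' @seealso [anchorAlign()], [writeAnchoredAlignment()]
#' @export
setClass("AnchoredAlignment",
    representation(ids = "character", rows = "character",
                   anchors = "integer", mode = "character"))

setValidity("AnchoredAlignment", function(object) {
    if (length(object@ids) != length(object@rows))
        return("ids and rows must have equal length")
    if (length(object@rows)) {
        w <- unique(nchar(object@rows))
        if (length(w) != 1L)
            return("all rows must have equal width")
        if (length(object@anchors) != 8L)
            return("anchors must have length 8")
        if (any(diff(object@anchors) < 1L) || object@anchors[8L] > w)
            return("anchors must be increasing and within the alignment")
    }
    TRUE
})

setMethod("show", "AnchoredAlignment", function(object) {
    cat("AnchoredAlignment: ", length(object@rows), " rows x ",
        if (length(object@rows)) nchar(object@rows[1L]) else 0L,
        " columns (loop mode ", object@mode, ")\n",
        "  ligand columns: ", paste(object@anchors, collapse = " "),
        "\n", sep = "")
    n <- min(3L, length(object@rows))
    if (n)
        cat(paste0("  ", format(object@ids[seq_len(n)], width = 12L), " ",
                   object@rows[seq_len(n)], collapse = "\n"), "\n", sep = "")
})
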