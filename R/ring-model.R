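## Rule-based RING-type taxonomy and chain classification.
##
## Residue identity is primary, spacing secondary: the gap windows of the
## long loops are empirical observations, not definitions, so a chain whose
## residue signature matches a type but whose ml2-ml3 or ml6-ml7 gap falls
## outside the tabulated window is still classified (with a warning flag).

#' The eight RING type definitions
#'
#' Returns the consensus definitions of the eight plant RING types as
#' [RingTypeSpec-class] objects, in canonical abundance order
#' (see [RING_TYPES]). Each spec lists the residues allowed at the eight
#' metal-ligand slots and the allowed window of each of the seven
#' inter-ligand gaps:
#'
#' \itemize{
#'  \item RING-H2: C C C H H C C C, gaps 2, 11-43, 1, 2, 2, 6-64, 2
#'  \item RING-HCa: C C C H C C C C, gaps 2, 10-45, \{1,3\}, \{2,3\},
#'    2-4, 6-43, 2
#'  \item RING-HCb: C C C H C C C C, gaps 2, 8-16, 1, 2, 2, 5-30, \{3,4\}
#'  \item RING-v: C C C C H C C C, gaps 2, 11-77, 1, 7, 2, 12-30, 2
#'  \item RING-C2: all Cys, gaps 2, 10-16, \{1,2\}, 2-6, 2, 10-36, 2
#'  \item RING-D: C C C H C/D C/D C C with at least one Asp,
#'    gaps 2, 12-15, 1, 2, 2, 10, 2
#'  \item RING-S/T: C C/S C H C S/T/C C C with at least one Ser/Thr at
#'    ml2 or ml6, gaps 2, 12-16, 1, \{2,3\}, 2, 4-14, 2
#'  \item RING-G: C C C H G C C C, gaps 2, 16, 1, 2, 2, 13, 2
#' }
#'
#' @return Named list of 8 [RingTypeSpec-class] objects.
#' @examples
#' specs <- ringTypeSpecs()
#' specs[["RING-v"]]
#' @export
ringTypeSpecs <- function() {
    mk <- function(name, residues, gaps, requires = list())
        new("RingTypeSpec", name = name, allowedResidues = residues,
            gapWindows = lapply(gaps, as.integer), requires = requires)
    C <- "C"
    specs <- list(
        mk("RING-H2",
           list(C, C, C, "H", "H", C, C, C),
           list(2L, 11:43, 1L, 2L, 2L, 6:64, 2L)),
        mk("RING-HCa",
           list(C, C, C, "H", C, C, C, C),
           list(2L, 10:45, c(1L, 3L), c(2L, 3L), 2:4, 6:43, 2L)),
        mk("RING-HCb",
           list(C, C, C, "H", C, C, C, C),
           list(2L, 8:16, 1L, 2L, 2L, 5:30, c(3L, 4L))),
        mk("RING-v",
           list(C, C, C, C, "H", C, C, C),
           list(2L, 11:77, 1L, 7L, 2L, 12:30, 2L)),
        mk("RING-C2",
           list(C, C, C, C, C, C, C, C),
           list(2L, 10:16, c(1L, 2L), 2:6, 2L, 10:36, 2L)),
        mk("RING-D",
           list(C, C, C, "H", c(C, "D"), c(C, "D"), C, C),
           list(2L, 12:15, 1L, 2L, 2L, 10L, 2L),
           requires = list(slots = c(5L, 6L), residues = "D")),
        mk("RING-S/T",
           list(C, c(C, "S"), C, "H", C, c("S", "T", C), C, C),
           list(2L, 12:16, 1L, c(2L, 3L), 2L, 4:14, 2L),
           requires = list(slots = c(2L, 6L), residues = c("S", "T"))),
        mk("RING-G",
           list(C, C, C, "H", "G", C, C, C),
           list(2L, 16L, 1L, 2L, 2L, 13L, 2L)))
    names(specs) <- vapply(specs, function(s) s@name, "")
    specs
}

## Modal (most frequently observed) values of the variable long-loop
## gaps per type. Domains of the same type tend to share their
## inter-ligand spacing, so these preferred values serve two roles: the
## synthetic generator concentrates its gap sampling on them, and the
## scanner prefers the modified-domain interpretation whose spacing is
## typical for its type when several single-substitution readings of a
## region compete.
.TYPE_MODAL_GAPS <- list(
    "RING-H2" = list("2" = c(14L, 15L), "6" = c(10L, 11L)),
    "RING-HCa" = list("2" = c(10L, 11L)),
    "RING-HCb" = list("7" = 4L),
    "RING-v" = list("2" = c(12L, 13L), "6" = c(12L, 15L)),
    "RING-C2" = list("2" = c(13L, 15L), "4" = c(4L, 5L),
                     "6" = c(11L, 16L)))

## Log-probability of a gap vector under the type's spacing model:
## 80% of the mass on the modal values, the rest uniform over the
## remainder of the type window; gaps with a single allowed value or no
## modal information contribute a constant, off-window gaps a strong
## penalty. Used only to rank competing interpretations.
.spacingTypicality <- function(gaps, type, specs) {
    spec <- specs[[type]]
    if (is.null(spec)) return(-Inf)
    modal <- .TYPE_MODAL_GAPS[[type]]
    score <- 0
    for (i in 1:7) {
        w <- spec@gapWindows[[i]]
        if (!gaps[i] %in% w) { score <- score - 20; next }
        m <- intersect(modal[[as.character(i)]], w)
        if (!length(m) || length(w) == 1L) next
        tailN <- length(setdiff(w, m))
        score <- score + if (gaps[i] %in% m) log(0.8 / length(m))
                         else log(0.2 / max(tailN, 1L))
    }
    score
}

## Does the residue vector satisfy a spec's slot sets and its
## "at least one of" requirement? Slots listed in `ignore` are exempt
## (used by the modified-domain classifier).
.residuesCompatible <- function(residues, spec, ignore = integer(0)) {
    for (i in setdiff(1:8, ignore))
        if (!residues[i] %in% spec@allowedResidues[[i]])
            return(FALSE)
    req <- spec@requires
    if (length(req)) {
        slots <- setdiff(req$slots, ignore)
        if (!any(residues[slots] %in% req$residues))
            return(FALSE)
    }
    TRUE
}

## Gap indices of a chain that fall outside a spec's windows.
.offWindowGaps <- function(gaps, spec) {
    off <- logical(7L)
    for (i in 1:7)
        off[i] <- !gaps[i] %in% spec@gapWindows[[i]]
    which(off)
}

#' Classify a complete ligand chain into one of the eight RING types
#'
#' Classification is residue-first: the signature at the eight ligand slots
#' (position of His/Cys at ml4--ml5, Asp/Gly/Ser/Thr substitutions of the
#' Cys-His-Cys pattern) selects the type; spacing is consulted only to
#' split RING-HCa from RING-HCb (ml7--ml8 gap of 2 versus 3 or more). A
#' residue-compatible chain whose gaps fall outside the tabulated windows
#' is still classified, with \code{attr(x, "gapWarning") == TRUE} and the
#' offending gap indices in \code{attr(x, "offGaps")}: the long-loop
#' windows are observed ranges, not definitions.
#'
#' @param chain a [LigandChain-class] with no substituted ligand.
#' @param specs list of [RingTypeSpec-class], default [ringTypeSpecs()].
#' @return Type name, or \code{"unclassified"} when the residues match no
#'   spec; with attributes \code{gapWarning} and \code{offGaps}.
#' @examples
#' ch <- ligandChain(c("C","C","C","H","H","C","C","C"),
#'                   gaps = c(2, 14, 1, 2, 2, 10, 2))
#' classifyChain(ch)
#' @export
classifyChain <- function(chain, specs = ringTypeSpecs()) {
    res <- ligandResidues(chain)
    gaps <- ligandGaps(chain)
    compat <- vapply(specs, .residuesCompatible, logical(1L),
                     residues = res)
    hits <- names(specs)[compat]
    ## HCa and HCb share a residue signature: split on the ml7-ml8 gap
    if (all(c("RING-HCa", "RING-HCb") %in% hits))
        hits <- setdiff(hits,
                        if (gaps[7L] <= 2L) "RING-HCb" else "RING-HCa")
    if (!length(hits)) {
        out <- "unclassified"
        attr(out, "gapWarning") <- FALSE
        attr(out, "offGaps") <- integer(0)
        return(out)
    }
    type <- hits[1L]
    off <- .offWindowGaps(gaps, specs[[type]])
    out <- type
    attr(out, "gapWarning") <- length(off) > 0L
    attr(out, "offGaps") <- off
    out
}

#' Classify a chain carrying one substituted metal ligand
#'
#' A modified RING domain has exactly one of its eight ligands replaced by
#' a non-canonical residue. The classifier finds the type(s) whose residue
#' signature matches at the other seven slots; among those, candidates
#' whose decisive gaps (ml1--ml2, ml3--ml4, ml4--ml5, ml5--ml6, ml7--ml8)
#' fall inside the type windows are preferred. If several types remain the
#' most frequent one wins (the order of [RING_TYPES]) and the result is
#' flagged ambiguous.
#'
#' @param chain a [LigandChain-class] deviating from every spec at exactly
#'   one slot.
#' @param specs list of [RingTypeSpec-class].
#' @return List with elements \code{ringType}, \code{modifiedPosition}
#'   (1--8), and \code{ambiguous}. If the chain deviates from no spec the
#'   plain classification is returned with \code{modifiedPosition = NA}.
#' @examples
#' ch <- ligandChain(c("C","C","C","H","H","A","C","C"),
#'                   gaps = c(2, 14, 1, 2, 2, 10, 2))
#' classifyModified(ch)
#' @export
classifyModified <- function(chain, specs = ringTypeSpecs()) {
    res <- ligandResidues(chain)
    gaps <- ligandGaps(chain)
    dev <- lapply(specs, function(s) {
        d <- which(!vapply(1:8, function(i)
            res[i] %in% s@allowedResidues[[i]], logical(1L)))
        ## the "at least one of" requirement must be satisfiable by the
        ## non-deviant slots, else the spec cannot claim this chain
        if (length(s@requires)) {
            slots <- setdiff(s@requires$slots, d)
            if (!any(res[slots] %in% s@requires$residues))
                return(NULL)
        }
        d
    })
    nDev <- vapply(dev, function(d) if (is.null(d)) NA_integer_
                   else length(d), 0L)
    if (all(is.na(nDev)) || min(nDev, na.rm = TRUE) >= 2L)
        stop("incomplete: chain deviates from every RING type at two or ",
             "more metal ligands")
    if (min(nDev, na.rm = TRUE) == 0L) {
        type <- classifyChain(chain, specs)
        return(list(ringType = as.character(type),
                    modifiedPosition = NA_integer_, ambiguous = FALSE))
    }
    cand <- names(specs)[!is.na(nDev) & nDev == 1L]
    ## prefer candidates whose short, structure-fixing gaps are in-window
    decisive <- c(1L, 3L, 4L, 5L, 7L)
    gapOK <- vapply(cand, function(nm)
        !any(.offWindowGaps(gaps, specs[[nm]]) %in% decisive), logical(1L))
    if (any(gapOK)) cand <- cand[gapOK]
    pick <- cand[order(match(cand, RING_TYPES))][1L]
    list(ringType = pick,
         modifiedPosition = dev[[pick]][1L],
         ambiguous = length(cand) > 1L)
}

#' Is a C4HC3 chain PHD-like rather than RING-v?
#'
#' RING-v and PHD fingers share the C4HC3 ligand signature (Cys at ml4,
#' His at ml5) but differ in spacing: RING-v has 1 residue between
#' ml3--ml4 and a unique 7 between ml4--ml5, while PHD fingers show 2--4
#' and 4--5 respectively. Chains matching the PHD spacing must be excluded
#' from the RING catalog.
#'
#' @param chain a [LigandChain-class].
#' @return \code{TRUE} iff the chain has the C4HC3 signature with the
#'   ml3--ml4 gap in 2--4 and the ml4--ml5 gap in 4--5.
#' @examples
#' phd <- ligandChain(c("C","C","C","C","H","C","C","C"),
#'                    gaps = c(2, 12, 3, 4, 2, 12, 2))
#' isPhdLike(phd)
#' @export
isPhdLike <- function(chain) {
    res <- ligandResidues(chain)
    g <- ligandGaps(chain)
    res[4L] == "C" && res[5L] == "H" &&
        g[3L] >= 2L && g[3L] <= 4L && g[4L] >= 4L && g[4L] <= 5L
}

#' Read and write RING type specifications as a plain config file
#'
#' Serializes a list of [RingTypeSpec-class] to YAML (one section per
#' type: allowed residues per slot, gap windows, optional requirement) so
#' the taxonomy can be extended, e.g. with additional species-specific
#' types.
#'
#' @param specs named list of [RingTypeSpec-class].
#' @param path file path.
#' @return \code{readTypeSpecs} returns the list of specs;
#'   \code{writeTypeSpecs} returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeTypeSpecs(ringTypeSpecs(), f)
#' identicalSpecs <- readTypeSpecs(f)
#' @export
writeTypeSpecs <- function(specs, path) {
    x <- lapply(specs, function(s) {
        out <- list(
            residues = vapply(s@allowedResidues, paste, "", collapse = ""),
            gaps = lapply(s@gapWindows, as.integer))
        if (length(s@requires))
            out$requires <- list(
                slots = as.integer(s@requires$slots),
                residues = as.character(s@requires$residues))
        out
    })
    yaml::write_yaml(x, path)
    invisible(path)
}

#' @rdname writeTypeSpecs
#' @export
readTypeSpecs <- function(path) {
    x <- yaml::read_yaml(path)
    specs <- lapply(names(x), function(nm) {
        s <- x[[nm]]
        req <- if (is.null(s$requires)) list() else
            list(slots = as.integer(s$requires$slots),
                 residues = as.character(s$requires$residues))
        new("RingTypeSpec", name = nm,
            allowedResidues = lapply(s$residues,
                function(r) strsplit(r, "")[[1L]]),
            gapWindows = lapply(s$gaps, as.integer),
            requires = req)
    })
    names(specs) <- names(x)
    specs
}
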