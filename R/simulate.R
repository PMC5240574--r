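## Ground-truth-labelled synthetic proteomes and expression matrices.
## The generator emulates the statistical structure the analysis assumes:
## planted domains of each type with spacings drawn from the tabulated
## windows (weighted towards the modal values), PHD decoys, modified and
## incomplete variants, conserved flank motifs, and expression matrices
## with tissue-preferential groups under multiplicative log-normal noise.

## Letters that never occur in any ligand-slot alphabet; loops and flanks
## drawn from this set cannot create spurious chains.
.LOOP_ALPHABET <- setdiff(AA_STANDARD, c("C", "H", "S", "D", "G", "T"))

## Conserved residues planted in the ligand flanks at the observed rates
## (Phe/Tyr before ml5 in RING-H2, Ile/Val before ml2, Ala/Val before
## ml5 in RING-v).
.DEFAULT_FLANK_MOTIFS <- list(
    list(types = "RING-H2", anchor = 5L, offset = -1L,
         residues = c("F", "Y"), rate = 0.85),
    list(types = c("RING-H2", "RING-HCa", "RING-HCb", "RING-v"),
         anchor = 2L, offset = -1L, residues = c("I", "V"), rate = 0.6),
    list(types = "RING-v", anchor = 5L, offset = -1L,
         residues = c("A", "V"), rate = 0.7))

.sample1 <- function(x) x[sample.int(length(x), 1L)]

.sampleGap <- function(spec, i, modalMass = 0.8) {
    w <- spec@gapWindows[[i]]
    if (length(w) == 1L) return(w)
    modal <- .TYPE_MODAL_GAPS[[spec@name]][[as.character(i)]]
    modal <- intersect(modal, w)
    if (!length(modal)) return(.sample1(w))
    tail <- setdiff(w, modal)
    if (!length(tail) || stats::runif(1L) < modalMass)
        .sample1(modal)
    else
        .sample1(tail)
}

#' Configuration of the synthetic proteome generator
#'
#' Defaults emulate the structure of a plant RING survey: type mix
#' proportional to the published census (371:215:47:44:38:10:5:1),
#' roughly 2.6\% modified domains (19/731), 1.5\% incomplete, a small
#' PHD-decoy fraction, 10\% domain-free background proteins, and a
#' 16/715 chance that a canonical protein carries two domains. Loops and
#' flanks are drawn from an alphabet free of ligand letters (the "clean"
#' background) so the planted truth is unambiguous; \code{hardMode}
#' restores the full alphabet outside planted domains.
#'
#' @param nProteins number of proteins.
#' @param seed mandatory RNG seed.
#' @param typeProbs named probabilities over the eight types.
#' @param kindProbs probabilities over element kinds
#'   (canonical/modified/incomplete/decoy/none); must sum to 1.
#' @param pDouble probability that a canonical protein carries a second
#'   domain.
#' @param flankMotifs list of flank-motif planting rules (type set,
#'   anchored ligand, offset, residue set, rate).
#' @param modalMass sampling mass placed on the modal gap values.
#' @param flankLen,linkerLen length ranges of terminal flanks and of the
#'   linker between double domains.
#' @param hardMode allow ligand letters in the background outside planted
#'   domains (recovery is then no longer guaranteed to be exact).
#' @return A list of class \code{ProteomeSimConfig}.
#' @export
proteomeSimConfig <- function(nProteins = 800L, seed,
                              typeProbs = NULL,
                              kindProbs = c(canonical = 0.809,
                                            modified = 0.026,
                                            incomplete = 0.015,
                                            decoy = 0.05, none = 0.10),
                              pDouble = 16 / 715,
                              flankMotifs = .DEFAULT_FLANK_MOTIFS,
                              modalMass = 0.8,
                              flankLen = c(10L, 30L),
                              linkerLen = c(20L, 40L),
                              hardMode = FALSE) {
    if (missing(seed)) stop("'seed' is mandatory for reproducibility")
    if (is.null(typeProbs))
        typeProbs <- stats::setNames(
            c(371, 215, 47, 44, 38, 10, 5, 1) / 731, RING_TYPES)
    if (abs(sum(kindProbs) - 1) > 1e-8)
        stop("kind probabilities must sum to 1")
    if (abs(sum(typeProbs) - 1) > 1e-8)
        stop("type probabilities must sum to 1")
    structure(list(nProteins = as.integer(nProteins), seed = seed,
                   typeProbs = typeProbs, kindProbs = kindProbs,
                   pDouble = pDouble, flankMotifs = flankMotifs,
                   modalMass = modalMass, flankLen = flankLen,
                   linkerLen = linkerLen, hardMode = hardMode),
              class = "ProteomeSimConfig")
}

#' Sample one synthetic RING domain fragment
#'
#' Draws gaps from the type's windows (weighted towards the modal
#' values), fills the ligand slots with allowed residues (honouring the
#' "at least one of" requirements of RING-D and RING-S/T), fills loops
#' from the ligand-free background alphabet, and plants configured flank
#' motifs. The returned chain always classifies back to its type.
#'
#' @param ringType one of [RING_TYPES].
#' @param config a [proteomeSimConfig()]; only the motif/modal settings
#'   are used (the caller controls the RNG seed).
#' @param specs list of [RingTypeSpec-class].
#' @return List with \code{fragment} (character string), \code{chain}
#'   (a [LigandChain-class] with positions relative to the fragment) and
#'   \code{ringType}.
#' @export
sampleDomain <- function(ringType, config = NULL,
                         specs = ringTypeSpecs()) {
    spec <- specs[[ringType]]
    if (is.null(spec)) stop("unknown RING type: ", ringType)
    modalMass <- if (is.null(config)) 0.8 else config$modalMass
    motifs <- if (is.null(config)) .DEFAULT_FLANK_MOTIFS else
        config$flankMotifs
    gaps <- vapply(1:7, function(i) .sampleGap(spec, i, modalMass), 0L)
    residues <- vapply(spec@allowedResidues, .sample1, "")
    req <- spec@requires
    if (length(req) && !any(residues[req$slots] %in% req$residues)) {
        slot <- .sample1(req$slots)
        residues[slot] <- .sample1(
            intersect(spec@allowedResidues[[slot]], req$residues))
    }
    span <- 8L + sum(gaps)
    letters <- sample(.LOOP_ALPHABET, span, replace = TRUE)
    anchor <- c(1L, cumsum(gaps + 1L) + 1L)
    letters[anchor] <- residues
    for (m in motifs) {
        if (!ringType %in% m$types) next
        if (stats::runif(1L) >= m$rate) next
        pos <- anchor[m$anchor] + m$offset
        ## the motif must stay inside the adjacent loop
        ok <- if (m$offset < 0L)
            m$anchor > 1L && -m$offset <= gaps[m$anchor - 1L]
        else
            m$anchor < 8L && m$offset <= gaps[m$anchor]
        if (ok) letters[pos] <- .sample1(m$residues)
    }
    list(fragment = paste(letters, collapse = ""),
         chain = new("LigandChain", positions = anchor,
                     residues = letters[anchor]),
         ringType = ringType)
}

## A PHD-spacing decoy: C4HC3 signature with ml3-ml4 gap 2-3 and
## ml4-ml5 gap 4-5, which the scanner must reject.
.sampleDecoy <- function() {
    gaps <- c(2L, .sample1(10:16), .sample1(2:3), .sample1(4:5), 2L,
              .sample1(12:20), 2L)
    residues <- c("C", "C", "C", "C", "H", "C", "C", "C")
    span <- 8L + sum(gaps)
    letters <- sample(.LOOP_ALPHABET, span, replace = TRUE)
    anchor <- c(1L, cumsum(gaps + 1L) + 1L)
    letters[anchor] <- residues
    list(fragment = paste(letters, collapse = ""),
         chain = new("LigandChain", positions = anchor,
                     residues = residues))
}

## Substitute `nSub` distinct ligand slots by background letters.
.substituteLigands <- function(domain, nSub) {
    letters <- strsplit(domain$fragment, "")[[1L]]
    anchor <- ligandPositions(domain$chain)
    slots <- sort(sample.int(8L, nSub))
    for (s in slots)
        letters[anchor[s]] <- .sample1(.LOOP_ALPHABET)
    domain$fragment <- paste(letters, collapse = "")
    domain$chain <- new("LigandChain", positions = anchor,
                        residues = letters[anchor])
    domain$substituted <- slots
    domain
}

#' Generate a synthetic proteome with planted ground truth
#'
#' Each protein carries zero, one or two planted elements according to
#' the configured kind mix: canonical domains of the eight types,
#' modified domains (one substituted ligand), incomplete domains (two
#' substituted ligands), PHD-spacing decoys, or nothing. The truth table
#' records every element with exact coordinates. The same seed yields
#' byte-identical output.
#'
#' @param config a [proteomeSimConfig()].
#' @return List with \code{sequences}
#'   (\code{Biostrings::AAStringSet}) and \code{truth}
#'   (\code{data.frame}: \code{protein_id}, \code{kind},
#'   \code{ring_type}, \code{start}, \code{end},
#'   \code{modified_position}, \code{gaps}).
#' @examples
#' sim <- plantProteome(proteomeSimConfig(nProteins = 10, seed = 1))
#' sim$truth[, c("protein_id", "kind", "ring_type")]
#' @export
plantProteome <- function(config) {
    stopifnot(inherits(config, "ProteomeSimConfig"))
    set.seed(config$seed)
    bgAlphabet <- if (config$hardMode) AA_STANDARD else .LOOP_ALPHABET
    seqs <- character(config$nProteins)
    ids <- sprintf("syn%04d", seq_len(config$nProteins))
    truth <- vector("list", config$nProteins)
    for (i in seq_len(config$nProteins)) {
        kind <- sample(names(config$kindProbs), 1L,
                       prob = config$kindProbs)
        elements <- list()
        if (kind == "canonical") {
            nDom <- 1L + (stats::runif(1L) < config$pDouble)
            for (d in seq_len(nDom)) {
                type <- sample(names(config$typeProbs), 1L,
                               prob = config$typeProbs)
                el <- sampleDomain(type, config)
                el$kind <- "canonical"
                elements[[d]] <- el
            }
        } else if (kind == "modified") {
            type <- sample(names(config$typeProbs), 1L,
                           prob = config$typeProbs)
            el <- .substituteLigands(sampleDomain(type, config), 1L)
            el$kind <- "modified"
            elements[[1L]] <- el
        } else if (kind == "incomplete") {
            type <- sample(names(config$typeProbs), 1L,
                           prob = config$typeProbs)
            el <- .substituteLigands(sampleDomain(type, config), 2L)
            el$kind <- "incomplete"
            elements[[1L]] <- el
        } else if (kind == "decoy") {
            el <- .sampleDecoy()
            el$ringType <- NA_character_
            el$kind <- "decoy"
            elements[[1L]] <- el
        }
        flank <- function() paste(
            sample(bgAlphabet,
                   .sample1(config$flankLen[1L]:config$flankLen[2L]),
                   replace = TRUE), collapse = "")
        pieces <- flank()
        rows <- list()
        for (el in elements) {
            start <- nchar(pieces) + 1L
            pieces <- paste0(pieces, el$fragment)
            rows[[length(rows) + 1L]] <- data.frame(
                protein_id = ids[i], kind = el$kind,
                ring_type = if (is.null(el$ringType)) NA_character_
                            else el$ringType,
                start = start, end = start + nchar(el$fragment) - 1L,
                modified_position = if (is.null(el$substituted))
                    NA_integer_ else el$substituted[1L],
                gaps = paste(ligandGaps(el$chain), collapse = ","),
                stringsAsFactors = FALSE)
            if (length(elements) > 1L)
                pieces <- paste0(pieces, paste(
                    sample(bgAlphabet,
                           .sample1(config$linkerLen[1L]:
                                    config$linkerLen[2L]),
                           replace = TRUE), collapse = ""))
        }
        pieces <- paste0(pieces, flank())
        seqs[i] <- pieces
        truth[[i]] <- if (length(rows)) do.call(rbind, rows) else
            data.frame(protein_id = ids[i], kind = "none",
                       ring_type = NA_character_, start = NA_integer_,
                       end = NA_integer_,
                       modified_position = NA_integer_,
                       gaps = NA_character_, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    if (is.null(truth))
        truth <- data.frame(protein_id = character(0),
                            kind = character(0),
                            ring_type = character(0),
                            start = integer(0), end = integer(0),
                            modified_position = integer(0),
                            gaps = character(0),
                            stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(sequences = Biostrings::AAStringSet(
             stats::setNames(seqs, ids)),
         truth = truth)
}

#' Configuration of the synthetic expression generator
#'
#' Emulates a tissue-expression survey over six tissues with seven
#' planted groups, each preferentially expressed (fold-change
#' \code{fold}) in one tissue -- or two for the small mixed group --
#' under multiplicative log-normal noise, plus an optional fraction of
#' all-zero rows. Default group proportions follow the published group
#' sizes (58:8:63:87:231:84:136).
#'
#' @param nGenes number of genes (including all-zero rows).
#' @param seed mandatory RNG seed.
#' @param tissues tissue labels.
#' @param groupProbs proportions of the seven groups.
#' @param patterns list of preferential tissue sets per group.
#' @param fold planted fold change (> 1).
#' @param baseline baseline FPKM of non-preferential tissues.
#' @param noiseSd standard deviation of the log-normal noise (log
#'   scale).
#' @param fracZero fraction of all-zero rows.
#' @return A list of class \code{ExpressionSimConfig}.
#' @export
expressionSimConfig <- function(nGenes = 600L, seed,
                                tissues = c("callus", "root", "stem",
                                            "leaf", "flower", "silique"),
                                groupProbs = c(58, 8, 63, 87, 231, 84,
                                               136) / 667,
                                patterns = list("silique",
                                                c("silique", "root"),
                                                "callus", "flower",
                                                "leaf", "root", "stem"),
                                fold = 10, baseline = 5,
                                noiseSd = 0.2, fracZero = 0) {
    if (missing(seed)) stop("'seed' is mandatory for reproducibility")
    if (fold <= 1) stop("'fold' must be > 1")
    if (abs(sum(groupProbs) - 1) > 1e-8)
        stop("group proportions must sum to 1")
    if (length(patterns) != length(groupProbs))
        stop("one pattern per group required")
    structure(list(nGenes = as.integer(nGenes), seed = seed,
                   tissues = tissues, groupProbs = groupProbs,
                   patterns = patterns, fold = fold,
                   baseline = baseline, noiseSd = noiseSd,
                   fracZero = fracZero),
              class = "ExpressionSimConfig")
}

#' Simulate a gene x tissue FPKM matrix with planted groups
#'
#' @param config an [expressionSimConfig()].
#' @return List with \code{matrix} (genes x tissues FPKM) and
#'   \code{truth} (\code{data.frame}: \code{gene}, \code{group} as Roman
#'   numeral or \code{"none"} for all-zero rows, \code{tissues} as a
#'   comma-separated preferential set).
#' @examples
#' sim <- simulateExpression(expressionSimConfig(nGenes = 20, seed = 1))
#' head(sim$truth)
#' @export
simulateExpression <- function(config) {
    stopifnot(inherits(config, "ExpressionSimConfig"))
    set.seed(config$seed)
    nT <- length(config$tissues)
    nZero <- round(config$fracZero * config$nGenes)
    nExpr <- config$nGenes - nZero
    groups <- sample(seq_along(config$groupProbs), nExpr,
                     replace = TRUE, prob = config$groupProbs)
    mat <- matrix(0, nrow = config$nGenes, ncol = nT,
                  dimnames = list(sprintf("gene%04d",
                                          seq_len(config$nGenes)),
                                  config$tissues))
    for (i in seq_len(nExpr)) {
        v <- rep(config$baseline, nT)
        pref <- match(config$patterns[[groups[i]]], config$tissues)
        v[pref] <- config$baseline * config$fold
        if (config$noiseSd > 0)
            v <- v * exp(stats::rnorm(nT, 0, config$noiseSd))
        mat[i, ] <- v
    }
    groupLabel <- c(as.character(utils::as.roman(
        seq_along(config$groupProbs))))
    truth <- data.frame(
        gene = rownames(mat),
        group = c(groupLabel[groups], rep("none", nZero)),
        tissues = c(vapply(groups, function(g)
            paste(config$patterns[[g]], collapse = ","), ""),
            rep(NA_character_, nZero)),
        stringsAsFactors = FALSE)
    list(matrix = mat, truth = truth)
}
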