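## Readers and writers: FASTA in; catalog TSV (1-based inclusive), BED
## (0-based half-open), run configuration (YAML) out.

#' Read protein sequences from FASTA
#'
#' Multi-record FASTA (wrapped or unwrapped lines); record ids are the
#' first whitespace-delimited token of each header and must be unique;
#' sequences are upper-cased.
#'
#' @param path FASTA file path.
#' @return A \code{Biostrings::AAStringSet}.
#' @export
readProteins <- function(path) {
    seqs <- Biostrings::readAAStringSet(path)
    if (!length(seqs)) stop("no FASTA record in ", path)
    ids <- sub("\\s.*$", "", names(seqs))
    if (any(!nzchar(ids)))
        stop("empty FASTA header in ", path)
    if (anyDuplicated(ids))
        stop("duplicate protein id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (any(Biostrings::width(seqs) == 0L))
        stop("empty sequence for id(s): ",
             paste(ids[Biostrings::width(seqs) == 0L], collapse = ", "))
    names(seqs) <- ids
    Biostrings::AAStringSet(toupper(seqs))
}

.CATALOG_COLUMNS <- c("protein_id", "start", "end", "ring_type",
                      "complete", "modified_position", "gap_warning",
                      "ambiguous", paste0("g", 1:7), "residues",
                      "sequence")

#' Write / read a domain catalog as TSV
#'
#' Lossless round trip of the catalog produced by [scanProtein()] /
#' [scanProteome()]: tab-separated, stable column order, 1-based
#' inclusive coordinates, blank \code{modified_position} meaning none.
#'
#' @param catalog a catalog \code{data.frame}.
#' @param path TSV file path.
#' @return \code{readCatalog} returns the catalog; \code{writeCatalog}
#'   returns \code{path} invisibly.
#' @export
writeCatalog <- function(catalog, path) {
    utils::write.table(catalog[, .CATALOG_COLUMNS], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
    cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = "",
                             colClasses = c(
                                 protein_id = "character",
                                 ring_type = "character",
                                 residues = "character",
                                 sequence = "character"))
    missing <- setdiff(.CATALOG_COLUMNS, names(cat))
    if (length(missing))
        stop("catalog misses column(s): ",
             paste(missing, collapse = ", "))
    known <- c(RING_TYPES, "incomplete", "unclassified")
    bad <- setdiff(unique(cat$ring_type), known)
    if (length(bad))
        stop("unknown ring_type value(s): ", paste(bad, collapse = ", "))
    cat$complete <- as.logical(cat$complete)
    cat$gap_warning <- as.logical(cat$gap_warning)
    cat$ambiguous <- as.logical(cat$ambiguous)
    cat$modified_position <- as.integer(cat$modified_position)
    for (g in paste0("g", 1:7)) cat[[g]] <- as.integer(cat[[g]])
    cat$start <- as.integer(cat$start)
    cat$end <- as.integer(cat$end)
    cat$sequence <- ifelse(is.na(cat$sequence), "", cat$sequence)
    cat[, .CATALOG_COLUMNS]
}

#' Convert catalog coordinates to/from BED convention
#'
#' The catalog uses 1-based inclusive protein coordinates; BED uses
#' 0-based half-open. The two converters are exact inverses.
#'
#' @param catalog a catalog \code{data.frame}.
#' @param bed a \code{data.frame} with \code{chrom}, \code{chromStart},
#'   \code{chromEnd}, \code{name}.
#' @return \code{catalogToBed}: a BED \code{data.frame};
#'   \code{bedToCatalogCoords}: a \code{data.frame} with
#'   \code{protein_id}, 1-based \code{start}/\code{end},
#'   \code{ring_type}.
#' @export
catalogToBed <- function(catalog) {
    data.frame(chrom = catalog$protein_id,
               chromStart = catalog$start - 1L,
               chromEnd = catalog$end,
               name = catalog$ring_type, stringsAsFactors = FALSE)
}

#' @rdname catalogToBed
#' @export
bedToCatalogCoords <- function(bed) {
    data.frame(protein_id = bed$chrom,
               start = bed$chromStart + 1L,
               end = bed$chromEnd,
               ring_type = bed$name, stringsAsFactors = FALSE)
}

#' @rdname catalogToBed
#' @param path BED file path.
#' @export
writeCatalogBed <- function(catalog, path) {
    utils::write.table(catalogToBed(catalog), path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' Read a gene x tissue expression matrix from TSV
#'
#' Expects a header of tissue labels and gene ids in the first column.
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes in rows.
#' @export
readExpressionMatrix <- function(path) {
    df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
    if (anyDuplicated(rownames(df)))
        stop("duplicate gene id(s) in ", path)
    as.matrix(df)
}

#' Pipeline run configuration
#'
#' A single configuration object drives [runPipeline()]; it is
#' serializable to and from a plain YAML file, and its defaults reproduce
#' the study settings (k = 7 expression groups, 2-fold preferential
#' threshold, mean-of-rest baseline, raw FPKM, pad-right loop mode).
#'
#' @param fasta input protein FASTA (required by [runPipeline()]).
#' @param outDir output directory.
#' @param annotations optional additional-domain annotation TSV
#'   (\code{protein_id}, \code{domain_name}, \code{start}, \code{end}).
#' @param expression optional expression matrix TSV.
#' @param k,k2 expression group / subgroup counts.
#' @param fold preferential-expression fold threshold.
#' @param baseline \code{"mean"} or \code{"max"} of the other tissues.
#' @param log2 cluster log2(FPKM + 1) instead of raw FPKM.
#' @param mode loop-alignment mode for the anchored alignment.
#' @param flank flank width of the frequency matrices.
#' @param findModified,findIncomplete scanner switches.
#' @param seed seed recorded in the run summary.
#' @return A list of class \code{RunConfig}.
#' @export
runConfig <- function(fasta = NULL, outDir = tempfile("ringcat_run_"),
                      annotations = NULL, expression = NULL,
                      k = 7L, k2 = NULL, fold = 2, baseline = "mean",
                      log2 = FALSE, mode = "pad-right", flank = 3L,
                      findModified = TRUE, findIncomplete = TRUE,
                      seed = 1L) {
    structure(list(fasta = fasta, outDir = outDir,
                   annotations = annotations, expression = expression,
                   k = as.integer(k), k2 = k2, fold = fold,
                   baseline = baseline, log2 = log2, mode = mode,
                   flank = as.integer(flank),
                   findModified = findModified,
                   findIncomplete = findIncomplete, seed = seed),
              class = "RunConfig")
}

#' @rdname runConfig
#' @param config a \code{RunConfig}.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    x <- yaml::read_yaml(path)
    do.call(runConfig, x)
}
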