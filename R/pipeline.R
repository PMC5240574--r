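## End-to-end pipeline: scan -> classify -> spacing stats -> anchored
## alignment -> (architecture groups) -> (expression clustering), with
## all artifacts written to an output directory and a machine-readable
## run summary.

#' Run the full cataloging pipeline
#'
#' Executes the stages in order on the inputs named by the configuration:
#' proteome scan and classification, type census and spacing statistics,
#' anchored-frequency matrices of the types present, ligand-anchored
#' alignment, optional architecture grouping (when an annotation table is
#' given) and optional expression clustering with preferential-tissue
#' calling and the group x type cross-tabulation (when an expression
#' matrix is given). Input paths are validated before any stage runs; a
#' stage failure aborts with the stage name. All outputs are
#' deterministic given identical inputs and configuration.
#'
#' @param config a [runConfig()].
#' @return Invisibly, the run summary (also written as
#'   \code{summary.json}): per-stage counts, the seed, and the package
#'   version.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    inputs <- c(fasta = config$fasta, annotations = config$annotations,
                expression = config$expression)
    for (nm in names(inputs))
        if (!is.null(inputs[[nm]]) && !file.exists(inputs[[nm]]))
            stop("input file for '", nm, "' not found: ", inputs[[nm]])
    if (is.null(config$fasta)) stop("'fasta' input is required")
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outDir, f)
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))

    summary <- list(seed = config$seed,
                    package = as.character(utils::packageVersion(
                        "RINGcat")))

    seqs <- stage("read", readProteins(config$fasta))
    summary$n_proteins_input <- length(seqs)

    scan <- stage("scan", scanProteome(
        seqs, findModified = config$findModified,
        findIncomplete = config$findIncomplete))
    catalog <- scan$catalog
    writeCatalog(catalog, out("catalog.tsv"))
    writeCatalogBed(catalog, out("catalog.bed"))
    summary$n_domains <- nrow(catalog)
    summary$n_complete <- sum(catalog$complete)
    summary$n_modified <- sum(!is.na(catalog$modified_position))
    summary$n_incomplete <- sum(catalog$ring_type == "incomplete")
    summary$domains_per_protein <- stats::setNames(
        as.list(scan$proteinSummary$n_proteins),
        scan$proteinSummary$n_domains)

    census <- stage("stats", typeCensus(catalog))
    utils::write.table(
        data.frame(ring_type = names(census), count = census),
        out("census.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    spacing <- gapHistograms(catalog)
    utils::write.table(spacing, out("spacing.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(spacingConsensus(spacing), out("consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    summary$census <- as.list(census)

    for (type in names(census)[census > 0L]) {
        pfm <- anchoredFrequencyMatrix(catalog, type, config$flank)
        utils::write.table(
            cbind(residue = rownames(pfm@freq),
                  as.data.frame(pfm@freq, check.names = FALSE)),
            out(paste0("pfm_", gsub("[^A-Za-z0-9]", "_", type),
                       ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (any(catalog$complete)) {
        aln <- stage("align", anchorAlign(catalog, mode = config$mode))
        writeAnchoredAlignment(aln, out("alignment.fasta"),
                               out("anchors.tsv"))
        summary$alignment_width <- nchar(aln@rows[1L])
    }

    if (!is.null(config$annotations)) {
        ann <- utils::read.delim(config$annotations,
                                 stringsAsFactors = FALSE)
        grp <- stage("architecture", architectureGroups(ann, catalog))
        utils::write.table(grp$assignment, out("architecture.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary$n_architecture_groups <- nrow(grp$groups)
    }

    if (!is.null(config$expression)) {
        mat <- stage("expression", readExpressionMatrix(
            config$expression))
        mat <- filterAllZero(mat)
        summary$n_genes_all_zero <- length(attr(mat, "removed"))
        summary$n_genes_clustered <- nrow(mat)
        tree <- stage("expression", hclustComplete(mat,
                                                   log2 = config$log2))
        ape::write.tree(ape::as.phylo(tree), out("dendrogram.nwk"))
        assignment <- cutTreeGroups(tree, config$k, config$k2)
        prefs <- preferentialTissueSets(mat, fold = config$fold,
                                        baseline = config$baseline)
        assignment$preferential_tissues <- vapply(
            prefs[assignment$gene], paste, "", collapse = ",")
        utils::write.table(assignment, out("expression_groups.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        genes <- intersect(assignment$gene,
                           catalog$protein_id[catalog$complete])
        if (length(genes)) {
            ct <- groupTypeCrosstab(
                assignment[assignment$gene %in% genes, , drop = FALSE],
                catalog)
            utils::write.table(
                cbind(group = rownames(ct$counts),
                      as.data.frame(ct$counts)),
                out("crosstab.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
        }
        summary$expression_groups <- as.list(table(assignment$group))
    }

    jsonlite::write_json(summary, out("summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(summary)
}
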