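## Clustering of gene x tissue FPKM profiles with uncentered Pearson
## distance and complete linkage, preferential-tissue calling at a fold
## threshold, and the expression-group x RING-type cross-tabulation.

#' Remove genes with zero expression in every tissue
#'
#' Genes whose FPKM is zero in all tissues carry no profile shape (their
#' uncentered correlation is undefined) and are excluded before
#' clustering.
#'
#' @param mat numeric matrix, genes in rows, tissues in columns.
#' @return The retained rows, with the removed gene ids in
#'   \code{attr(x, "removed")}.
#' @examples
#' m <- rbind(a = c(1, 2), b = c(0, 0))
#' filterAllZero(m)
#' @export
filterAllZero <- function(mat) {
    mat <- as.matrix(mat)
    zero <- rowSums(mat != 0) == 0L
    out <- mat[!zero, , drop = FALSE]
    attr(out, "removed") <- rownames(mat)[zero]
    out
}

#' Uncentered Pearson correlation distance
#'
#' \code{uncenteredPearson} computes the uncentered correlation
#' \eqn{r = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}} (the cosine
#' similarity, without mean-centering); the distance is \eqn{d = 1 - r},
#' bounded by \eqn{[0, 2]} in general and by \eqn{[0, 1]} for
#' non-negative profiles such as FPKM.
#'
#' @param x,y numeric profiles of equal length (at least 2), not both
#'   all-zero.
#' @return Correlation in \eqn{[-1, 1]} / distance in \eqn{[0, 2]}.
#' @examples
#' uncenteredPearsonDistance(c(2, 4, 6), c(1, 2, 3))  # proportional: 0
#' uncenteredPearsonDistance(c(1, 0), c(0, 1))        # orthogonal: 1
#' @export
uncenteredPearson <- function(x, y) {
    if (length(x) != length(y) || length(x) < 2L)
        stop("profiles must have equal length >= 2")
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0)
        stop("zero-norm profile: filter all-zero genes first")
    sum(x * y) / (nx * ny)
}

#' @rdname uncenteredPearson
#' @export
uncenteredPearsonDistance <- function(x, y)
    1 - uncenteredPearson(x, y)

#' All-pairs uncentered Pearson distance of a profile matrix
#'
#' @param mat numeric matrix, genes in rows; no all-zero row.
#' @return A \code{stats::dist} object.
#' @export
uncenteredPearsonDist <- function(mat) {
    mat <- as.matrix(mat)
    norms <- sqrt(rowSums(mat^2))
    if (any(norms == 0))
        stop("zero-norm profile(s): ",
             paste(utils::head(rownames(mat)[norms == 0], 5L),
                   collapse = ", "))
    r <- tcrossprod(mat / norms)
    d <- 1 - r
    d[d < 0] <- 0
    stats::as.dist(d)
}

#' Complete-linkage clustering on uncentered Pearson distances
#'
#' Agglomerative hierarchical clustering of expression profiles with the
#' uncentered Pearson distance and complete linkage, as used for
#' tissue-expression grouping. Deterministic for a given input order.
#'
#' @param mat numeric matrix, genes in rows (at least 2), tissues in
#'   columns; pre-filter with [filterAllZero()].
#' @param log2 cluster \code{log2(FPKM + 1)} instead of raw FPKM.
#' @return A \code{stats::hclust} tree.
#' @export
hclustComplete <- function(mat, log2 = FALSE) {
    mat <- as.matrix(mat)
    if (nrow(mat) < 2L) stop("need at least 2 profiles")
    if (log2) mat <- log2(mat + 1)
    stats::hclust(uncenteredPearsonDist(mat), method = "complete")
}

#' Cut a dendrogram into labelled expression groups
#'
#' Cuts the tree into \code{k} groups labelled with Roman numerals in
#' dendrogram leaf order (the leftmost leaf's group is \code{I}).
#' Optionally a deeper cut into \code{k2 > k} clusters assigns subgroup
#' letters (\code{V-A}, \code{V-B}, ...) within each group, again in leaf
#' order.
#'
#' @param tree a \code{stats::hclust} tree.
#' @param k number of groups (1..n).
#' @param k2 optional number of clusters for the subgroup cut.
#' @return \code{data.frame} with \code{gene}, \code{group} and (when
#'   \code{k2} is given) \code{subgroup}.
#' @export
cutTreeGroups <- function(tree, k, k2 = NULL) {
    cl <- stats::cutree(tree, k = k)
    leafOrder <- tree$labels[tree$order]
    groupOrder <- unique(cl[leafOrder])
    roman <- as.character(utils::as.roman(seq_len(k)))
    group <- roman[match(cl, groupOrder)]
    out <- data.frame(gene = names(cl), group = group,
                      stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(k2)) {
        if (k2 < k) stop("'k2' must be >= 'k'")
        cl2 <- stats::cutree(tree, k = k2)
        sub <- rep(NA_character_, nrow(out))
        for (gg in unique(out$group)) {
            sel <- out$group == gg
            inLeaf <- leafOrder[leafOrder %in% out$gene[sel]]
            subOrder <- unique(cl2[inLeaf])
            sub[sel] <- LETTERS[match(cl2[out$gene[sel]], subOrder)]
        }
        out$subgroup <- paste0(out$group, "-", sub)
    }
    out
}

#' Preferentially expressed tissues of one profile
#'
#' A tissue is called preferential when its signal exceeds
#' \code{fold} times the baseline over the other tissues (the mean by
#' default; the maximum as a stricter option). A tissue with positive
#' signal while all others are zero is always preferential.
#'
#' @param profile named numeric vector of FPKM values.
#' @param fold fold-change threshold (default 2, i.e. ">2-fold higher").
#' @param baseline \code{"mean"} or \code{"max"} of the other tissues.
#' @return Character vector of preferential tissue names (possibly
#'   empty).
#' @examples
#' preferentialTissues(c(callus = 10, root = 1, stem = 1, leaf = 1,
#'                       flower = 1, silique = 1))
#' @export
preferentialTissues <- function(profile, fold = 2,
                                baseline = c("mean", "max")) {
    baseline <- match.arg(baseline)
    nm <- names(profile)
    if (is.null(nm)) nm <- paste0("tissue", seq_along(profile))
    base <- vapply(seq_along(profile), function(t) {
        rest <- profile[-t]
        if (baseline == "mean") mean(rest) else max(rest)
    }, 0)
    nm[profile > fold * base]
}

#' Call preferential tissues for every gene of a matrix
#'
#' @param mat numeric matrix, genes in rows, tissues in columns.
#' @inheritParams preferentialTissues
#' @return Named list of character vectors, one per gene.
#' @export
preferentialTissueSets <- function(mat, fold = 2,
                                   baseline = c("mean", "max")) {
    baseline <- match.arg(baseline)
    mat <- as.matrix(mat)
    out <- lapply(seq_len(nrow(mat)), function(i)
        preferentialTissues(mat[i, ], fold = fold, baseline = baseline))
    names(out) <- rownames(mat)
    out
}

#' Cross-tabulate expression groups by RING type
#'
#' Counts genes per (expression group, RING type) cell; the percentage is
#' taken per type, i.e. 100 x count / column total, so each column of the
#' percentage matrix sums to 100 for types with any gene.
#'
#' @param assignment \code{data.frame} with \code{gene} and \code{group}
#'   (from [cutTreeGroups()]).
#' @param types named character vector mapping gene id to RING type (or a
#'   catalog \code{data.frame}, in which case each protein's first
#'   complete domain type is used).
#' @return List with integer matrix \code{counts} and numeric matrix
#'   \code{percent} (groups x types).
#' @export
groupTypeCrosstab <- function(assignment, types) {
    if (is.data.frame(types)) {
        rows <- types[types$complete & types$ring_type %in% RING_TYPES, ,
                      drop = FALSE]
        types <- stats::setNames(rows$ring_type, rows$protein_id)
        types <- types[!duplicated(names(types))]
    }
    tt <- types[assignment$gene]
    if (anyNA(tt))
        stop("no RING type for gene(s): ",
             paste(utils::head(assignment$gene[is.na(tt)], 5L),
                   collapse = ", "))
    groups <- unique(assignment$group)
    counts <- table(factor(assignment$group, levels = groups),
                    factor(tt, levels = RING_TYPES))
    counts <- matrix(as.integer(counts), nrow = length(groups),
                     dimnames = list(groups, RING_TYPES))
    totals <- colSums(counts)
    percent <- sweep(counts, 2L, pmax(totals, 1L), "/") * 100
    percent[, totals == 0L] <- NA_real_
    list(counts = counts, percent = percent)
}
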