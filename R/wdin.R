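#' Within-condition Spearman correlation of a gene pair
#'
#' Restricts the two genes' values to the samples of one condition and
#' returns their Spearman rank correlation. Because Spearman correlation
#' is invariant under strictly monotone per-sample transforms, the
#' result is the same whether \code{x} holds raw values or rank
#' z-scores.
#'
#' @param x a \linkS4class{TissueExpression}.
#' @param geneU,geneV gene symbols present in \code{x}.
#' @param condition one of the two condition labels of \code{x}.
#' @return Spearman rho in [-1, 1], or \code{NA_real_} when either gene
#'   has zero variance within the condition (correlation undefined).
#' @export
conditionCorrelation <- function(x, geneU, geneV, condition) {
    if (!all(c(geneU, geneV) %in% rownames(x)))
        stop("gene(s) absent from the matrix: ",
             paste(setdiff(c(geneU, geneV), rownames(x)), collapse = ", "))
    keep <- conditionOf(x) == condition
    if (!any(keep))
        stop("no samples with condition '", condition, "'")
    if (sum(keep) < 3L)
        stop("condition '", condition, "' has < 3 samples")
    a <- assay(x)[geneU, keep]
    b <- assay(x)[geneV, keep]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = "spearman")
}

## Row-wise within-condition Spearman machinery: rank each gene across
## the condition's samples, center/scale, then a pairwise correlation is
## a plain inner product. Rows with zero rank variance come back NaN and
## are treated as undefined.
.spearmanRows <- function(vals) {
    r <- t(apply(vals, 1L, rank))       # ties -> average, Spearman convention
    mu <- rowMeans(r)
    r <- r - mu
    ss <- sqrt(rowSums(r^2))
    r / ss   # zero-variance rows become NaN
}

#' Screen a background network for diverse interactions
#'
#' Every background edge whose two genes are measured in \code{x} is
#' tested for the diverse-interaction pattern: Spearman correlation of
#' magnitude at least \code{hi} in one condition and below \code{lo} in
#' the other. Retained edges form the tissue's weighted diverse
#' interaction network (WDIN); each carries weight = disease-condition
#' correlation minus normal-condition correlation, and a status of
#' \code{"active"} (weight > 0; co-expression gained under disease) or
#' \code{"inactive"} (weight < 0; lost).
#'
#' @param x a \linkS4class{TissueExpression} (rank-normalized input is
#'   conventional; Spearman correlation makes it equivalent to raw).
#' @param bg a \linkS4class{BackgroundNetwork}.
#' @param normal,disease the condition labels playing the control and
#'   disease roles.
#' @param hi high-correlation threshold (default 0.8): the "strongly
#'   correlated" side must reach it.
#' @param lo low-correlation threshold (default 0.2): the other
#'   condition must stay below it.
#' @param useAbsolute when TRUE (default) the test is on |rho|, so
#'   strong negative co-expression also counts as "strongly correlated";
#'   when FALSE the thresholds apply to signed rho.
#' @return a \linkS4class{WDIN}. Edges whose genes are missing from
#'   \code{x}, or whose correlation is undefined in either condition,
#'   are skipped; their counts are reported with a message.
#' @examples
#' spec <- simulationSpec(nGenes = 60, meanDegree = 3, nSamples = 40,
#'                        nPlanted = 8, seed = 7)
#' bg <- simulateScaffold(spec)
#' expr <- simulateExpression(spec, bg)[[1]]
#' z <- rankNormalize(expr)
#' detectDiverseEdges(z, bg, normal = "WK", disease = "GK")
#' @export
detectDiverseEdges <- function(x, bg, normal, disease,
                               hi = 0.8, lo = 0.2, useAbsolute = TRUE) {
    stopifnot(is(bg, "BackgroundNetwork"))
    if (!(lo >= 0 && lo < hi && hi <= 1))
        stop("thresholds must satisfy 0 <= lo < hi <= 1")
    condLabels <- unique(conditionOf(x))
    if (!all(c(normal, disease) %in% condLabels))
        stop("condition label(s) not found in the expression data: ",
             paste(setdiff(c(normal, disease), condLabels), collapse = ", "))

    genes <- rownames(x)
    e <- bg@edges
    present <- e[, 1L] %in% genes & e[, 2L] %in% genes
    nSkipped <- sum(!present)
    if (nSkipped)
        message(nSkipped, " background edge(s) skipped: gene(s) not measured")
    e <- e[present, , drop = FALSE]

    corFor <- function(cond) {
        keep <- conditionOf(x) == cond
        if (sum(keep) < 3L)
            stop("condition '", cond, "' has < 3 samples")
        used <- unique(as.vector(e))
        rs <- .spearmanRows(assay(x)[used, keep, drop = FALSE])
        rowSums(rs[e[, 1L], , drop = FALSE] * rs[e[, 2L], , drop = FALSE])
    }
    if (nrow(e)) {
        rN <- corFor(normal)
        rD <- corFor(disease)
    } else rN <- rD <- numeric(0)

    undef <- !is.finite(rN) | !is.finite(rD)
    if (any(undef))
        message(sum(undef),
                " edge(s) skipped: zero within-condition variance")
    e <- e[!undef, , drop = FALSE]
    rN <- rN[!undef]; rD <- rD[!undef]

    tN <- if (useAbsolute) abs(rN) else rN
    tD <- if (useAbsolute) abs(rD) else rD
    keep <- (tN >= hi & tD < lo) | (tD >= hi & tN < lo)

    edges <- data.frame(u = e[keep, 1L], v = e[keep, 2L],
                        rNormal = rN[keep], rDisease = rD[keep],
                        stringsAsFactors = FALSE)
    edges$weight <- edges$rDisease - edges$rNormal
    edges$status <- ifelse(edges$weight > 0, "active", "inactive")
    edges <- edges[.corder(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL

    new("WDIN", tissue = x@tissue, edges = edges,
        params = list(hi = hi, lo = lo, useAbsolute = useAbsolute,
                      normal = normal, disease = disease))
}
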