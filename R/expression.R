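#' Read a gene-by-sample expression matrix with sample metadata
#'
#' Reads a tab-delimited expression matrix (header row of sample IDs,
#' first column of gene symbols) together with a metadata table mapping
#' each sample to one of two phenotype labels, and returns a validated
#' \linkS4class{TissueExpression}.
#'
#' @param matrixPath path to the TSV expression matrix.
#' @param metadataPath path to a TSV with columns \code{sample_id},
#'   \code{condition} and optionally \code{tissue}.
#' @param tissue optional tissue label; defaults to the metadata's
#'   \code{tissue} column when present, else \code{"unspecified"}.
#' @return a \linkS4class{TissueExpression}.
#' @examples
#' mat <- tempfile(); meta <- tempfile()
#' writeLines(c("gene\tS1\tS2\tS3\tS4\tS5\tS6",
#'              "A\t1\t2\t3\t4\t5\t6",
#'              "B\t6\t5\t4\t3\t2\t1"), mat)
#' writeLines(c("sample_id\tcondition",
#'              paste0("S", 1:6, "\t", rep(c("GK", "WK"), each = 3))), meta)
#' readExpression(mat, meta)
#' @export
readExpression <- function(matrixPath, metadataPath, tissue = NULL) {
    raw <- utils::read.delim(matrixPath, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (ncol(raw) < 2L)
        stop("expression matrix needs a gene column plus >= 1 sample column")
    genes <- raw[[1L]]
    if (anyDuplicated(genes))
        stop("duplicate gene symbols in expression matrix: ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                   dimnames = dimnames(vals)))
    if (any(bad <- is.na(num) & !is.na(vals))) {
        idx <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                     genes[idx[1L]], colnames(vals)[idx[2L]]))
    }
    if (any(is.na(num))) {
        idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
        stop(sprintf("missing expression value at gene '%s', sample '%s'",
                     genes[idx[1L]], colnames(vals)[idx[2L]]))
    }
    rownames(num) <- genes

    md <- utils::read.delim(metadataPath, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    if (!all(c("sample_id", "condition") %in% names(md)))
        stop("metadata must have columns 'sample_id' and 'condition'")
    missing <- setdiff(colnames(num), md$sample_id)
    if (length(missing))
        stop("sample(s) absent from metadata: ", paste(missing, collapse = ", "))
    md <- md[match(colnames(num), md$sample_id), , drop = FALSE]
    conds <- unique(md$condition)
    if (length(conds) != 2L)
        stop(sprintf("exactly two condition labels required, found %d (%s)",
                     length(conds), paste(conds, collapse = ", ")))
    if (is.null(tissue))
        tissue <- if ("tissue" %in% names(md)) md$tissue[1L] else "unspecified"

    TissueExpressionFromMatrix(num, md$condition, tissue = tissue)
}

#' Construct a TissueExpression from an in-memory matrix
#'
#' @param values numeric gene-by-sample matrix with row and column names.
#' @param condition character/factor of length \code{ncol(values)}.
#' @param tissue character(1) tissue label.
#' @param normalized logical(1); TRUE when \code{values} already holds
#'   rank z-scores.
#' @return a \linkS4class{TissueExpression}.
#' @export
TissueExpressionFromMatrix <- function(values, condition,
                                       tissue = "unspecified",
                                       normalized = FALSE) {
    se <- SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(condition = as.character(condition),
                                       row.names = colnames(values)))
    out <- new("TissueExpression", se, tissue = tissue)
    metadata(out)$normalized <- normalized
    validObject(out)
    out
}

#' Condition label of each sample
#' @param x a \linkS4class{TissueExpression}.
#' @return named character vector, one label per sample.
#' @export
conditionOf <- function(x) {
    stats::setNames(as.character(colData(x)$condition), colnames(x))
}

#' Per-sample rank z-score normalization
#'
#' For every sample (column), genes are ranked ascending by expression
#' (largest expression gets the largest rank) and the rank vector is
#' standardized to a z-score, \eqn{z = (r - \mu) / \sigma}, using the mean
#' and population standard deviation of that column's ranks. The result
#' is dimensionless, invariant to any strictly monotone per-sample
#' transform of the raw values, and is what all downstream correlation
#' work consumes.
#'
#' @param x a \linkS4class{TissueExpression} of raw values.
#' @param tieMethod how tied expression values share ranks: "average"
#'   (fractional ranks, the default and the convention matching Spearman
#'   correlation), "min" or "max".
#' @return a \linkS4class{TissueExpression} whose assay holds rank
#'   z-scores; \code{metadata()$normalized} is TRUE and the tie method
#'   and standard-deviation convention are recorded in metadata.
#' @examples
#' te <- TissueExpressionFromMatrix(
#'     matrix(rnorm(60), 10, 6,
#'            dimnames = list(paste0("G", 1:10), paste0("S", 1:6))),
#'     rep(c("GK", "WK"), each = 3))
#' z <- rankNormalize(te)
#' colMeans(SummarizedExperiment::assay(z))   # ~0 per sample
#' @export
rankNormalize <- function(x, tieMethod = c("average", "min", "max")) {
    tieMethod <- match.arg(tieMethod)
    vals <- assay(x)
    z <- vals
    for (j in seq_len(ncol(vals))) {
        r <- rank(vals[, j], ties.method = tieMethod)
        mu <- mean(r)
        sigma <- sqrt(mean((r - mu)^2))   # population sd of the ranks
        if (sigma == 0)
            stop(sprintf(
                "sample '%s' has identical values for all genes; rank z-score undefined",
                colnames(vals)[j]))
        z[, j] <- (r - mu) / sigma
    }
    out <- TissueExpressionFromMatrix(z, conditionOf(x),
                                      tissue = x@tissue, normalized = TRUE)
    metadata(out)$tieMethod <- tieMethod
    metadata(out)$sdConvention <- "population"
    out
}
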