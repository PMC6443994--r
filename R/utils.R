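## Edge identity everywhere in the package is the unordered gene pair,
## stored canonically with u < v (C locale ordering for reproducibility
## across platforms).

.canonicalPairs <- function(u, v) {
    u <- as.character(u); v <- as.character(v)
    swap <- .clt(v, u)
    tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
    cbind(u = u, v = v)
}

## locale-independent string comparisons
.clt <- function(a, b) {
    old <- Sys.getlocale("LC_COLLATE")
    on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
    Sys.setlocale("LC_COLLATE", "C")
    a < b
}

.csort <- function(x) {
    old <- Sys.getlocale("LC_COLLATE")
    on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
    Sys.setlocale("LC_COLLATE", "C")
    sort(x, method = "radix")
}

.corder <- function(...) order(..., method = "radix")

.pairKey <- function(u, v) paste(u, v, sep = "|")

#' Canonical unordered-pair keys of a network's edges
#'
#' @param x a \linkS4class{BackgroundNetwork}, \linkS4class{WDIN},
#'   \linkS4class{CoreModule}, \linkS4class{MergedCoreModule},
#'   \linkS4class{EdgeRanking}, or a two-column matrix/data.frame of
#'   gene pairs.
#' @param ... unused.
#' @return character vector of \code{"u|v"} keys with \code{u < v}.
#' @export
#' @rdname edgeKeys
setMethod("edgeKeys", "BackgroundNetwork", function(x, ...)
    .pairKey(x@edges[, 1L], x@edges[, 2L]))

#' @rdname edgeKeys
#' @export
setMethod("edgeKeys", "WDIN", function(x, ...)
    .pairKey(x@edges$u, x@edges$v))

#' @rdname edgeKeys
#' @export
setMethod("edgeKeys", "CoreModule", function(x, ...)
    .pairKey(x@edges$u, x@edges$v))

#' @rdname edgeKeys
#' @export
setMethod("edgeKeys", "MergedCoreModule", function(x, ...)
    .pairKey(x@edges$u, x@edges$v))

#' @rdname edgeKeys
#' @export
setMethod("edgeKeys", "EdgeRanking", function(x, ...)
    .pairKey(x@table$u, x@table$v))

#' @rdname edgeKeys
#' @export
setMethod("edgeKeys", "matrix", function(x, ...) {
    p <- .canonicalPairs(x[, 1L], x[, 2L])
    .pairKey(p[, 1L], p[, 2L])
})

#' @rdname edgeKeys
#' @export
setMethod("edgeKeys", "data.frame", function(x, ...) {
    p <- .canonicalPairs(x[[1L]], x[[2L]])
    .pairKey(p[, 1L], p[, 2L])
})

## ---- small accessors ----

#' Tissue label of an object
#' @param x a TissueExpression, WDIN or CoreModule.
#' @return character(1)
#' @export
#' @rdname tissueLabel
setMethod("tissueLabel", "TissueExpression", function(x) x@tissue)

#' @rdname tissueLabel
#' @export
setMethod("tissueLabel", "WDIN", function(x) x@tissue)

#' @rdname tissueLabel
#' @export
setMethod("tissueLabel", "CoreModule", function(x) x@tissue)

#' Edge and node counts
#' @param x a network-like object.
#' @return integer(1)
#' @export
#' @rdname numEdges
setMethod("numEdges", "BackgroundNetwork", function(x) nrow(x@edges))

#' @rdname numEdges
#' @export
setMethod("numEdges", "WDIN", function(x) nrow(x@edges))

#' @rdname numEdges
#' @export
setMethod("numEdges", "CoreModule", function(x) nrow(x@edges))

#' @rdname numEdges
#' @export
setMethod("numEdges", "MergedCoreModule", function(x) nrow(x@edges))

#' @rdname numNodes
#' @export
setMethod("numNodes", "BackgroundNetwork", function(x)
    length(nodeNames(x)))

#' @rdname numNodes
#' @export
setMethod("numNodes", "WDIN", function(x) length(nodeNames(x)))

#' @rdname numNodes
#' @export
setMethod("numNodes", "CoreModule", function(x) length(nodeNames(x)))

#' @rdname numNodes
#' @export
setMethod("numNodes", "MergedCoreModule", function(x) length(nodeNames(x)))

#' Node (gene) names of a network-like object
#' @param x a network-like object.
#' @return sorted character vector of gene symbols incident to >= 1 edge.
#' @export
#' @rdname nodeNames
setMethod("nodeNames", "BackgroundNetwork", function(x)
    .csort(unique(as.vector(x@edges))))

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "WDIN", function(x)
    .csort(unique(c(x@edges$u, x@edges$v))))

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "CoreModule", function(x)
    .csort(unique(c(x@edges$u, x@edges$v))))

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "MergedCoreModule", function(x)
    .csort(unique(c(x@edges$u, x@edges$v))))

#' Edge table of a network-like object
#' @param x a WDIN, CoreModule, MergedCoreModule or EdgeRanking.
#' @return data.frame, one row per edge.
#' @export
#' @rdname edgeTable
setMethod("edgeTable", "WDIN", function(x) x@edges)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "CoreModule", function(x) x@edges)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "MergedCoreModule", function(x) x@edges)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "EdgeRanking", function(x) x@table)

## ---- show methods ----

setMethod("show", "BackgroundNetwork", function(object) {
    cat("BackgroundNetwork:", numNodes(object), "nodes,",
        numEdges(object), "edges\n")
})

setMethod("show", "WDIN", function(object) {
    e <- object@edges
    cat(sprintf("WDIN [%s]: %d nodes, %d diverse edges (%d active, %d inactive)\n",
        object@tissue, numNodes(object), nrow(e),
        sum(e$status == "active"), sum(e$status == "inactive")))
    p <- object@params
    if (length(p))
        cat(sprintf("  screen: |rho| >= %s in one condition, < %s in the other (%s)\n",
            format(p$hi), format(p$lo),
            if (isTRUE(p$useAbsolute)) "absolute" else "signed"))
})

setMethod("show", "NodeRanking", function(object) {
    cat(sprintf("NodeRanking: %d candidates, %d seeds (%s)\n",
        length(object@scores), length(object@seeds),
        if (object@iterations > 0L)
            sprintf("%d iterations", object@iterations) else "linear solve"))
    top <- names(object@ranks)[order(object@ranks)][seq_len(min(5L, length(object@ranks)))]
    if (length(top)) cat("  top candidates:", paste(top, collapse = ", "), "\n")
})

setMethod("show", "EdgeRanking", function(object) {
    cat(sprintf("EdgeRanking: %d edges, seed policy '%s'\n",
        nrow(object@table), object@policy))
})

setMethod("show", "CoreModule", function(object) {
    cat(sprintf("CoreModule [%s]: top %.1f%% of prioritized edges -> %d nodes, %d edges, clustering coefficient %.4f\n",
        object@tissue, 100 * object@fraction, numNodes(object),
        numEdges(object), object@clusteringCoefficient))
})

setMethod("show", "MergedCoreModule", function(object) {
    cat(sprintf("MergedCoreModule: %d edges among %d nodes (alpha = %s, %s Jaccard)\n",
        numEdges(object), numNodes(object), format(object@alpha),
        object@method))
    cats <- object@edges$category
    if (nrow(object@edges) && !all(is.na(cats))) {
        tab <- table(cats)
        cat("  categories:",
            paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
            "\n")
    }
})

setMethod("show", "SimulationSpec", function(object) {
    cat(sprintf("SimulationSpec: %d genes, mean degree %.1f, %d samples/condition, %d tissue(s), %d planted edge(s), seed %d\n",
        object@nGenes, object@meanDegree, object@nSamples,
        length(object@tissues), nrow(object@plantedEdges), object@seed))
})

## run code under a local, derived RNG state and restore the caller's
.withSeed <- function(seed, expr) {
    if (!is.null(old <- globalenv()$.Random.seed)) {
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed %% .Machine$integer.max))
    expr
}
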