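## Edge tables (data.frames with u, v columns) are the working currency
## of the module sweep; CoreModule wraps the selected one.

.edgesOf <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is(x, "WDIN") || is(x, "CoreModule") || is(x, "MergedCoreModule"))
        return(edgeTable(x))
    if (is(x, "BackgroundNetwork"))
        return(data.frame(u = x@edges[, 1L], v = x@edges[, 2L],
                          stringsAsFactors = FALSE))
    if (igraph::is_igraph(x)) {
        el <- igraph::as_edgelist(x)
        return(data.frame(u = el[, 1L], v = el[, 2L],
                          stringsAsFactors = FALSE))
    }
    stop("cannot extract an edge table from an object of class ",
         class(x)[1L])
}

.adjacency01 <- function(edges, nodes = NULL) {
    if (is.null(nodes)) nodes <- .csort(unique(c(edges$u, edges$v)))
    i <- match(edges$u, nodes); j <- match(edges$v, nodes)
    Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                         dims = c(length(nodes), length(nodes)),
                         dimnames = list(nodes, nodes))
}

#' Top-fraction prioritized-edge subnetwork
#'
#' Retains the first \code{ceiling(fraction * |edges|)} edges of the
#' ascending edge-ranking order together with their WDIN weights.
#'
#' @param edgeRanking an \linkS4class{EdgeRanking}.
#' @param wdin the \linkS4class{WDIN} the ranking was computed on.
#' @param fraction fraction of top edges to keep, in (0, 1].
#' @return data.frame of the retained edges (u, v, rNormal, rDisease,
#'   weight, status), in ranking order.
#' @export
topFractionSubnetwork <- function(edgeRanking, wdin, fraction) {
    if (!(fraction > 0 && fraction <= 1))
        stop("fraction must lie in (0, 1]")
    tab <- edgeRanking@table
    m <- ceiling(fraction * nrow(tab))
    if (m == 0L) stop("fraction retains zero edges")
    top <- tab[seq_len(m), , drop = FALSE]
    w <- wdin@edges
    hit <- match(.pairKey(top$u, top$v), .pairKey(w$u, w$v))
    if (anyNA(hit))
        stop("ranked edge(s) absent from the WDIN")
    out <- w[hit, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Maximum connected component of an edge subgraph
#'
#' Returns the connected component with the most nodes; ties break
#' toward more edges, then toward the lexicographically smallest node
#' set, so the result is deterministic.
#'
#' @param edges an edge table (data.frame with u, v and any extra
#'   columns) or an object coercible to one.
#' @return the component's edge table (columns preserved).
#' @export
maximumConnectedComponent <- function(edges) {
    e <- .edgesOf(edges)
    if (!nrow(e)) stop("empty edge subgraph")
    g <- igraph::graph_from_data_frame(e[, c("u", "v")], directed = FALSE)
    comp <- igraph::components(g)
    size <- comp$csize
    best <- which(size == max(size))
    if (length(best) > 1L) {
        membOf <- comp$membership[e$u]   # component of each edge
        nEdges <- vapply(best, function(b) sum(membOf == b), integer(1))
        best <- best[nEdges == max(nEdges)]
        if (length(best) > 1L) {
            keyOf <- vapply(best, function(b)
                paste(.csort(names(comp$membership)[comp$membership == b]),
                      collapse = "|"), character(1))
            best <- best[.corder(keyOf)[1L]]
        }
    }
    keep <- comp$membership[e$u] == best[1L]
    out <- e[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Average local clustering coefficient
#'
#' Watts–Strogatz average of per-node local clustering coefficients,
#' \eqn{C(v) = 2 T(v) / (d_v (d_v - 1))} with \eqn{T(v)} the triangles
#' through \eqn{v}; nodes of degree < 2 contribute 0. Edge weights are
#' ignored. The empty graph scores 0 by convention. For an
#' Erdős–Rényi graph at fixed mean degree the value scales like
#' \eqn{1/N}, so a module scoring well above that signals genuine
#' clustering.
#'
#' @param x an edge table, \linkS4class{WDIN}, \linkS4class{CoreModule},
#'   \linkS4class{MergedCoreModule}, \linkS4class{BackgroundNetwork} or
#'   igraph object.
#' @return numeric in [0, 1].
#' @export
avgClustering <- function(x) {
    e <- .edgesOf(x)
    if (!nrow(e)) return(0)
    A <- .adjacency01(e)
    deg <- Matrix::rowSums(A)
    ## closed wedges: diag(A^3) = 2 * triangles through each node
    tri2 <- Matrix::rowSums((A %*% A) * A)
    denom <- deg * (deg - 1)
    local <- ifelse(denom > 0, tri2 / denom, 0)
    mean(local)
}

#' Select the clustering-coefficient-maximizing core module
#'
#' Sweeps top-fraction prioritized-edge subnetworks (default top 2.5\%
#' to 25\% in 2.5\% steps), takes the maximum connected component of
#' each, and returns the component with the largest average clustering
#' coefficient as the tissue's core module; a coefficient tie resolves
#' toward the smaller fraction (the minimal edge set). The full sweep
#' table is kept in the \code{sweep} slot for reporting. Optionally, a
#' disease gene list can be supplied to record per-fraction hit counts.
#'
#' @param wdin a \linkS4class{WDIN}.
#' @param edgeRanking an \linkS4class{EdgeRanking} on \code{wdin}.
#' @param fractions fractions to sweep; default \code{seq(0.025, 0.25,
#'   by = 0.025)}.
#' @param hitGenes optional character vector; each sweep row then
#'   reports how many of these genes the component covers.
#' @return a \linkS4class{CoreModule}.
#' @export
selectCoreModule <- function(wdin, edgeRanking,
                             fractions = seq(0.025, 0.25, by = 0.025),
                             hitGenes = NULL) {
    if (!length(fractions)) stop("fractions must be nonempty")
    fractions <- sort(fractions)
    rows <- vector("list", length(fractions))
    mccs <- vector("list", length(fractions))
    for (i in seq_along(fractions)) {
        sub <- topFractionSubnetwork(edgeRanking, wdin, fractions[i])
        mcc <- maximumConnectedComponent(sub)
        cc <- avgClustering(mcc)
        nodes <- unique(c(mcc$u, mcc$v))
        rows[[i]] <- data.frame(
            fraction = fractions[i],
            mccNodes = length(nodes), mccEdges = nrow(mcc),
            clusteringCoefficient = cc,
            hitGenes = if (is.null(hitGenes)) NA_integer_
                       else length(intersect(hitGenes, nodes)))
        mccs[[i]] <- mcc
    }
    sweep <- do.call(rbind, rows)
    if (is.null(hitGenes)) sweep$hitGenes <- NULL
    best <- which.max(sweep$clusteringCoefficient)  # first max = smallest fraction
    new("CoreModule", tissue = wdin@tissue, fraction = fractions[best],
        edges = mccs[[best]],
        clusteringCoefficient = sweep$clusteringCoefficient[best],
        sweep = sweep)
}
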