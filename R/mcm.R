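## adjacency list of a module's edge table: gene -> character vector of
## neighbors within the module
.neighborList <- function(edges) {
    if (!nrow(edges)) return(list())
    ends <- c(edges$u, edges$v)
    other <- c(edges$v, edges$u)
    split(other, ends)
}

.interactionSet <- function(u, v, nbr) {
    unique(c(nbr[[u]], nbr[[v]]))
}

#' Per-interaction Jaccard index across two core modules
#'
#' Measures how similarly an interaction is embedded in two modules.
#' Under the default \code{"neighborhood"} strategy the interaction's
#' footprint in module X is \eqn{S_X(e) = N_X(u) \cup N_X(v)}, the union
#' of its endpoints' neighbor sets within X (empty when neither endpoint
#' is in X), and the index is \eqn{|S_A \cap S_B| / |S_A \cup S_B|}.
#' Alternative strategies: \code{"edge_set"} compares the two modules'
#' whole edge sets (constant per module pair), and
#' \code{"adjacent_edges"} compares the sets of edges incident to the
#' interaction's endpoints.
#'
#' @param edge length-2 character vector (the gene pair) or a
#'   \code{"u|v"} key.
#' @param modA,modB \linkS4class{CoreModule} objects (or edge tables).
#' @param method Jaccard strategy; see Details.
#' @return numeric in [0, 1].
#' @export
interactionJaccard <- function(edge, modA, modB,
                               method = c("neighborhood", "edge_set",
                                          "adjacent_edges")) {
    method <- match.arg(method)
    if (length(edge) == 1L) edge <- strsplit(edge, "|", fixed = TRUE)[[1L]]
    stopifnot(length(edge) == 2L)
    ea <- .edgesOf(modA); eb <- .edgesOf(modB)
    key <- .pairKey(.canonicalPairs(edge[1L], edge[2L])[, 1L],
                    .canonicalPairs(edge[1L], edge[2L])[, 2L])
    inA <- key %in% .pairKey(ea$u, ea$v)
    inB <- key %in% .pairKey(eb$u, eb$v)
    if (!inA && !inB)
        stop("interaction ", key, " is absent from both modules")
    sets <- switch(method,
        neighborhood = {
            na <- .neighborList(ea); nb <- .neighborList(eb)
            list(.interactionSet(edge[1L], edge[2L], na),
                 .interactionSet(edge[1L], edge[2L], nb))
        },
        edge_set = list(.pairKey(ea$u, ea$v), .pairKey(eb$u, eb$v)),
        adjacent_edges = {
            adj <- function(e) {
                k <- .pairKey(e$u, e$v)
                k[e$u %in% edge | e$v %in% edge]
            }
            list(adj(ea), adj(eb))
        })
    u <- length(union(sets[[1L]], sets[[2L]]))
    if (u == 0L) return(0)
    length(intersect(sets[[1L]], sets[[2L]])) / u
}

#' Merge tissue core modules into a merged core module
#'
#' Takes the union of the modules' edge sets and admits an interaction
#' when its \code{\link{interactionJaccard}} exceeds \code{alpha} for at
#' least one ordered pair of distinct modules. Admitted edges carry each
#' source tissue's WDIN weight (NA where that tissue's module lacks the
#' edge); categories are filled later by \code{\link{classifyEdges}}.
#'
#' @param modules named list of >= 2 \linkS4class{CoreModule} objects;
#'   names default to the modules' tissue labels.
#' @param alpha merge threshold in (0, 1); default 0.1.
#' @param method per-interaction Jaccard strategy (see
#'   \code{\link{interactionJaccard}}).
#' @return a \linkS4class{MergedCoreModule} (possibly empty, with a
#'   warning).
#' @export
mergeCoreModules <- function(modules, alpha = 0.1,
                             method = c("neighborhood", "edge_set",
                                        "adjacent_edges")) {
    method <- match.arg(method)
    if (length(modules) < 2L) stop("need >= 2 core modules to merge")
    if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
    if (is.null(names(modules)))
        names(modules) <- vapply(modules, tissueLabel, character(1))
    tissues <- names(modules)
    if (anyDuplicated(tissues)) stop("module tissue labels must be unique")

    tabs <- lapply(modules, .edgesOf)
    keys <- lapply(tabs, function(e) .pairKey(e$u, e$v))
    nbrs <- if (method == "neighborhood") lapply(tabs, .neighborList) else NULL
    allKeys <- .csort(unique(unlist(keys)))
    pairsUV <- do.call(rbind, strsplit(allKeys, "|", fixed = TRUE))

    pairIdx <- utils::combn(seq_along(modules), 2L)
    admitted <- logical(length(allKeys))
    for (i in seq_along(allKeys)) {
        u <- pairsUV[i, 1L]; v <- pairsUV[i, 2L]
        for (p in seq_len(ncol(pairIdx))) {
            a <- pairIdx[1L, p]; b <- pairIdx[2L, p]
            if (!(allKeys[i] %in% keys[[a]]) && !(allKeys[i] %in% keys[[b]]))
                next
            J <- if (method == "neighborhood") {
                sa <- .interactionSet(u, v, nbrs[[a]])
                sb <- .interactionSet(u, v, nbrs[[b]])
                un <- length(union(sa, sb))
                if (un == 0L) 0 else length(intersect(sa, sb)) / un
            } else {
                interactionJaccard(c(u, v), tabs[[a]], tabs[[b]],
                                   method = method)
            }
            if (J > alpha) { admitted[i] <- TRUE; break }
        }
    }

    keep <- allKeys[admitted]
    edges <- data.frame(u = pairsUV[admitted, 1L, drop = TRUE],
                        v = pairsUV[admitted, 2L, drop = TRUE],
                        stringsAsFactors = FALSE)
    if (!nrow(edges))
        edges <- data.frame(u = character(0), v = character(0))
    for (t in seq_along(tissues)) {
        w <- rep(NA_real_, nrow(edges))
        hit <- match(keep, keys[[t]])
        w[!is.na(hit)] <- tabs[[t]]$weight[hit[!is.na(hit)]]
        edges[[tissues[t]]] <- w
    }
    edges$category <- rep(NA_character_, nrow(edges))
    rownames(edges) <- NULL
    mcm <- new("MergedCoreModule", tissues = tissues, alpha = alpha,
               method = method, edges = edges)
    if (!nrow(edges))
        warning("merged core module is empty at alpha = ", alpha)
    mcm
}

#' Sweep the merge threshold alpha
#'
#' Builds the merged core module at each supplied alpha and reports its
#' size and average clustering coefficient (0 for an empty merge). The
#' recommended alpha — attached as attribute \code{"recommendedAlpha"} —
#' is the clustering-coefficient argmax, with ties resolved toward the
#' larger (stricter) alpha.
#'
#' @param modules named list of \linkS4class{CoreModule} objects.
#' @param alphas thresholds to sweep; default \code{c(0.3, 0.2, 0.1,
#'   0.05)}.
#' @param method per-interaction Jaccard strategy.
#' @return data.frame (alpha, mcmNodes, mcmEdges, clusteringCoefficient)
#'   sorted by decreasing alpha, with attribute \code{recommendedAlpha}.
#' @export
sweepAlpha <- function(modules, alphas = c(0.3, 0.2, 0.1, 0.05),
                       method = c("neighborhood", "edge_set",
                                  "adjacent_edges")) {
    method <- match.arg(method)
    if (!length(alphas)) stop("alphas must be nonempty")
    alphas <- sort(alphas, decreasing = TRUE)
    rows <- lapply(alphas, function(a) {
        mcm <- suppressWarnings(mergeCoreModules(modules, alpha = a,
                                                 method = method))
        data.frame(alpha = a, mcmNodes = numNodes(mcm),
                   mcmEdges = numEdges(mcm),
                   clusteringCoefficient = avgClustering(mcm))
    })
    out <- do.call(rbind, rows)
    best <- which.max(out$clusteringCoefficient)  # first max = largest alpha
    attr(out, "recommendedAlpha") <- out$alpha[best]
    out
}
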