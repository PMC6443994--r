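#' Column-normalized transition matrix of a WDIN
#'
#' Builds the walk matrix \eqn{M(u, v) = t(w(u, v)) / \sum_{x \in N(v)}
#' t(w(x, v))} over the WDIN's nodes, where \eqn{t} transforms the (signed)
#' diverse-interaction weight into a non-negative walk affinity:
#' \code{"absolute"} uses |w| (the magnitude of dysfunction, the default),
#' \code{"shifted"} uses (w + 2)/4, and \code{"unweighted"} ignores
#' weights. Every column over a non-isolated node sums to 1, so the
#' matrix is column-stochastic and applying it to a probability vector
#' conserves total mass.
#'
#' @param wdin a nonempty \linkS4class{WDIN}.
#' @param weightTransform one of "absolute", "shifted", "unweighted".
#' @return a sparse column-stochastic \code{\link[Matrix]{dgCMatrix}}
#'   with gene-symbol dimnames.
#' @export
transitionMatrix <- function(wdin,
                             weightTransform = c("absolute", "shifted",
                                                 "unweighted")) {
    weightTransform <- match.arg(weightTransform)
    e <- wdin@edges
    if (!nrow(e)) stop("WDIN has no edges")
    nodes <- nodeNames(wdin)
    t <- switch(weightTransform,
                absolute   = abs(e$weight),
                shifted    = (e$weight + 2) / 4,
                unweighted = rep(1, nrow(e)))
    i <- match(e$u, nodes); j <- match(e$v, nodes)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(t, t),
                              dims = c(length(nodes), length(nodes)),
                              dimnames = list(nodes, nodes))
    W <- Matrix::colSums(A)
    if (any(W == 0))
        stop("cannot normalize: zero total incident weight at node(s) ",
             paste(nodes[W == 0], collapse = ", "))
    M <- A %*% Matrix::Diagonal(x = 1 / W)
    dimnames(M) <- list(nodes, nodes)
    methods::as(M, "CsparseMatrix")
}

.seedVector <- function(nodes, seeds) {
    present <- intersect(seeds, nodes)
    if (!length(present))
        stop("none of the seed genes is present in the WDIN")
    if (length(dropped <- setdiff(seeds, nodes)))
        warning(length(dropped), " seed gene(s) absent from the WDIN dropped: ",
                paste(utils::head(dropped, 5L), collapse = ", "),
                if (length(dropped) > 5L) ", ..." else "")
    p0 <- stats::setNames(numeric(length(nodes)), nodes)
    p0[present] <- 1 / length(present)
    list(p0 = p0, seeds = .csort(present))
}

.rankCandidates <- function(p, seeds) {
    cand <- setdiff(names(p), seeds)
    scores <- p[cand]
    ## descending score; ties broken by gene symbol for reproducibility
    ord <- order(-scores, names(scores), method = "radix")
    ranks <- stats::setNames(integer(length(cand)), names(scores))
    ranks[ord] <- seq_along(ord)
    list(scores = scores, ranks = ranks)
}

#' Rank candidate genes by weighted random walk with restart
#'
#' Iterates the restart walk
#' \eqn{p_{s+1} = (1 - \gamma) M p_s + \gamma (1 - \eta) p_0}
#' to stationarity, where \eqn{M} is the column-stochastic
#' \code{\link{transitionMatrix}} of the WDIN, \eqn{p_0} is uniform over
#' the seed genes present in the network, \eqn{\gamma} is the restart
#' probability and \eqn{\eta} a global restart-mass damping (with the
#' default \eqn{\eta = 0} this is standard RWR and total probability is
#' conserved at every step; \eqn{\eta > 0} rescales all scores uniformly
#' and leaves the ranking unchanged). Candidates (all WDIN nodes outside
#' the seed set) are ranked by descending steady-state probability; ties
#' break lexicographically.
#'
#' @param wdin a \linkS4class{WDIN}.
#' @param seeds character vector of seed (known disease) genes; seeds
#'   absent from the WDIN are dropped with a warning.
#' @param gamma restart probability in (0, 1); default 0.3.
#' @param eta restart damping in [0, 1); default 0.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param maxIter iteration cap; default 10000.
#' @param weightTransform passed to \code{\link{transitionMatrix}}.
#' @return a \linkS4class{NodeRanking}.
#' @seealso \code{\link{rwrLinearOracle}} for an exact dense solve of the
#'   same stationary system.
#' @export
rwr <- function(wdin, seeds, gamma = 0.3, eta = 0, tol = 1e-10,
                maxIter = 10000L,
                weightTransform = c("absolute", "shifted", "unweighted")) {
    stopifnot(gamma > 0, gamma < 1, eta >= 0, eta < 1, tol > 0)
    M <- transitionMatrix(wdin, weightTransform)
    sv <- .seedVector(rownames(M), seeds)
    p0 <- sv$p0
    restart <- gamma * (1 - eta) * p0
    p <- p0
    sums <- numeric(0)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        pNew <- as.numeric((1 - gamma) * (M %*% p)) + restart
        names(pNew) <- names(p0)
        sums[it] <- sum(pNew)
        delta <- sum(abs(pNew - p))
        p <- pNew
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
        stop(sprintf("RWR did not converge in %d iterations (L1 residual %.3g)",
                     maxIter, delta))
    rk <- .rankCandidates(p, sv$seeds)
    new("NodeRanking", scores = rk$scores, ranks = rk$ranks,
        seeds = sv$seeds, steadyState = p, iterations = it,
        probabilitySums = sums)
}

#' Exact stationary solution of the restart walk (dense solve)
#'
#' Solves \eqn{(I - (1 - \gamma) M)\, p = \gamma (1 - \eta) p_0}
#' directly, giving the same steady state as \code{\link{rwr}} to
#' machine precision. Intended as an independent cross-check of the
#' iterative solver on small networks; guarded at 2000 nodes.
#'
#' @inheritParams rwr
#' @return a \linkS4class{NodeRanking} with \code{iterations = 0}.
#' @export
rwrLinearOracle <- function(wdin, seeds, gamma = 0.3, eta = 0,
                            weightTransform = c("absolute", "shifted",
                                                "unweighted")) {
    stopifnot(gamma > 0, gamma < 1, eta >= 0, eta < 1)
    M <- transitionMatrix(wdin, weightTransform)
    n <- nrow(M)
    if (n > 2000L)
        stop("dense oracle is limited to networks of <= 2000 nodes")
    sv <- .seedVector(rownames(M), seeds)
    A <- diag(n) - (1 - gamma) * as.matrix(M)
    p <- tryCatch(solve(A, gamma * (1 - eta) * sv$p0),
                  error = function(e) stop("singular stationary system: ",
                                           conditionMessage(e)))
    p <- stats::setNames(as.numeric(p), rownames(M))
    rk <- .rankCandidates(p, sv$seeds)
    new("NodeRanking", scores = rk$scores, ranks = rk$ranks,
        seeds = sv$seeds, steadyState = p, iterations = 0L,
        probabilitySums = numeric(0))
}

#' Rank WDIN edges by the mean rank of their endpoints
#'
#' Each edge receives the arithmetic mean of its two endpoints' rank
#' values as its index and edges are ordered ascending (position 1 =
#' most disease-associated). Seed genes have no candidate rank; under
#' policy \code{"seeds_first"} (default) they are assigned rank 0,
#' placing seed-adjacent edges at the top, while \code{"drop_seed_edges"}
#' removes seed-incident edges from the ranking. Index ties break by the
#' lexicographic gene pair.
#'
#' @param wdin a \linkS4class{WDIN}.
#' @param nodeRanking a \linkS4class{NodeRanking} computed on
#'   \code{wdin}.
#' @param seedRankPolicy "seeds_first" or "drop_seed_edges".
#' @return an \linkS4class{EdgeRanking}.
#' @export
rankEdges <- function(wdin, nodeRanking,
                      seedRankPolicy = c("seeds_first", "drop_seed_edges")) {
    seedRankPolicy <- match.arg(seedRankPolicy)
    e <- wdin@edges
    ranks <- c(stats::setNames(as.numeric(nodeRanking@ranks),
                               names(nodeRanking@ranks)),
               stats::setNames(numeric(length(nodeRanking@seeds)),
                               nodeRanking@seeds))
    if (seedRankPolicy == "drop_seed_edges") {
        keep <- !(e$u %in% nodeRanking@seeds | e$v %in% nodeRanking@seeds)
        e <- e[keep, , drop = FALSE]
    }
    if (!all(c(e$u, e$v) %in% names(ranks)))
        stop("node(s) without a rank value: ",
             paste(utils::head(setdiff(c(e$u, e$v), names(ranks)), 5L),
                   collapse = ", "))
    idx <- (ranks[e$u] + ranks[e$v]) / 2
    tab <- data.frame(u = e$u, v = e$v, index = as.numeric(idx),
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$index, tab$u, tab$v, method = "radix"), , drop = FALSE]
    rownames(tab) <- NULL
    new("EdgeRanking", table = tab, policy = seedRankPolicy)
}

#' Hypergeometric enrichment of known disease genes in the top-k
#'
#' Counts how many of an independent test gene set land in the top
#' \code{k} ranked candidates and computes the one-sided hypergeometric
#' tail probability \eqn{P(X \ge hits)} of drawing \code{k} candidates
#' from the full candidate set with the covered test genes as successes.
#' Test genes overlapping the seed set are removed first (seeds would
#' trivially inflate the enrichment).
#'
#' @param nodeRanking a \linkS4class{NodeRanking}.
#' @param testGenes character vector of validation genes.
#' @param k top-rank cutoff (<= number of candidates).
#' @return list with \code{hits}, \code{p}, \code{k},
#'   \code{nCandidates}, and \code{nTestInNetwork} (test genes that are
#'   ranked candidates).
#' @export
validateRanking <- function(nodeRanking, testGenes, k) {
    if (!length(testGenes)) stop("test gene set is empty")
    overlap <- intersect(testGenes, nodeRanking@seeds)
    if (length(overlap)) {
        warning(length(overlap), " test gene(s) overlapping the seed set removed")
        testGenes <- setdiff(testGenes, overlap)
    }
    if (!length(testGenes)) stop("test gene set is empty after removing seeds")
    cand <- names(nodeRanking@ranks)
    N <- length(cand)
    if (k > N) stop("k exceeds the number of candidates (", N, ")")
    K <- length(intersect(testGenes, cand))
    topk <- cand[nodeRanking@ranks <= k]
    hits <- length(intersect(topk, testGenes))
    p <- stats::phyper(hits - 1L, K, N - K, k, lower.tail = FALSE)
    list(hits = hits, p = as.numeric(p), k = k,
         nCandidates = N, nTestInNetwork = K)
}
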