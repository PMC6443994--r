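## Shared fixtures and independent oracles for the test suite.
## Oracles here deliberately use brute-force or textbook constructions,
## never the package's own code paths.

## minimal in-memory expression object
toyExpression <- function(values, condition, tissue = "toy") {
    TissueExpressionFromMatrix(values, condition, tissue = tissue)
}

## a WDIN assembled directly from an edge table (bypasses the screen) --
## for graph-algorithm tests where correlations are irrelevant
wdinFromEdges <- function(u, v, weight, tissue = "toy") {
    p <- t(mapply(function(a, b) sort(c(a, b)), u, v))
    e <- data.frame(u = p[, 1], v = p[, 2],
                    rNormal = 0, rDisease = weight, weight = weight,
                    status = ifelse(weight > 0, "active", "inactive"),
                    stringsAsFactors = FALSE)
    e <- e[order(e$u, e$v, method = "radix"), ]
    rownames(e) <- NULL
    new("WDIN", tissue = tissue, edges = e,
        params = list(hi = 0.8, lo = 0.2, useAbsolute = TRUE))
}

coreModuleFromEdges <- function(u, v, weight, tissue = "toy",
                                fraction = 0.1) {
    w <- wdinFromEdges(u, v, weight, tissue)
    new("CoreModule", tissue = tissue, fraction = fraction,
        edges = w@edges, clusteringCoefficient = avgClustering(w@edges),
        sweep = data.frame())
}

## random connected-ish weighted graph for RWR batteries
randomWDIN <- function(nNodes, meanDegree = 4, seed = 1) {
    set.seed(seed)
    repeat {
        g <- igraph::sample_gnp(nNodes, meanDegree / (nNodes - 1))
        ## keep the largest component so every node is walkable
        comp <- igraph::components(g)
        keep <- which(comp$membership == which.max(comp$csize))
        g <- igraph::induced_subgraph(g, keep)
        if (igraph::ecount(g) >= 2) break
    }
    el <- igraph::as_edgelist(g)
    genes <- sprintf("N%03d", seq_len(igraph::vcount(g)))
    w <- runif(nrow(el), -1, 1)
    w[w == 0] <- 0.5
    wdinFromEdges(genes[el[, 1]], genes[el[, 2]], w)
}

## --- independent oracles ---

## brute-force average local clustering coefficient over a node/edge list
bruteAvgClustering <- function(u, v) {
    nodes <- unique(c(u, v))
    key <- paste(pmin(u, v), pmax(u, v))
    hasEdge <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% key
    local <- vapply(nodes, function(x) {
        nbr <- unique(c(v[u == x], u[v == x]))
        d <- length(nbr)
        if (d < 2) return(0)
        tri <- 0
        for (i in seq_len(d - 1)) for (j in (i + 1):d)
            if (hasEdge(nbr[i], nbr[j])) tri <- tri + 1
        2 * tri / (d * (d - 1))
    }, numeric(1))
    mean(local)
}

## textbook Spearman for tie-free data: 1 - 6*sum(d^2)/(n(n^2-1))
spearmanNoTies <- function(x, y) {
    d <- rank(x) - rank(y)
    n <- length(x)
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

## exhaustive hypergeometric tail by enumerating all top-k draws
enumHyperTail <- function(N, K, k, hits) {
    draws <- combn(N, k)
    success <- seq_len(K)          # label the K test genes 1..K
    cnt <- sum(apply(draws, 2, function(d) sum(d %in% success) >= hits))
    cnt / ncol(draws)
}
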