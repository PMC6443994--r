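## EdgeRanking straight from an explicit order, for sweep tests
erFromOrder <- function(u, v) {
    new("EdgeRanking",
        table = data.frame(u = pmin(u, v), v = pmax(u, v),
                           index = seq_along(u), stringsAsFactors = FALSE),
        policy = "seeds_first")
}

test_that("top-fraction subnetworks use a ceiling cutoff and nest as the fraction grows", {
    u <- sprintf("a%02d", 1:10); v <- sprintf("b%02d", 1:10)
    w <- wdinFromEdges(u, v, rep(0.5, 10))
    er <- erFromOrder(u, v)

    expect_equal(nrow(topFractionSubnetwork(er, w, 0.25)), 3L)  # ceil(2.5)
    expect_equal(nrow(topFractionSubnetwork(er, w, 1.0)), 10L)
    expect_error(topFractionSubnetwork(er, w, 0), "fraction")

    ## 40 edges at 2.5% -> exactly 1 edge
    u40 <- sprintf("c%02d", 1:40); v40 <- sprintf("d%02d", 1:40)
    w40 <- wdinFromEdges(u40, v40, rep(1, 40))
    expect_equal(nrow(topFractionSubnetwork(erFromOrder(u40, v40), w40, 0.025)),
                 1L)

    ## nesting
    prev <- character(0)
    for (f in seq(0.1, 1, by = 0.1)) {
        cur <- edgeKeys(topFractionSubnetwork(er, w, f)[, c("u", "v")])
        expect_true(all(prev %in% cur))
        prev <- cur
    }
})

test_that("maximum connected component picks the largest component deterministically", {
    ## triangle beats a disjoint edge
    e <- data.frame(u = c("A", "B", "A", "X"), v = c("B", "C", "C", "Y"))
    mcc <- maximumConnectedComponent(e)
    expect_setequal(unique(c(mcc$u, mcc$v)), c("A", "B", "C"))

    ## connected graph returns itself
    conn <- data.frame(u = c("A", "B"), v = c("B", "C"))
    expect_equal(nrow(maximumConnectedComponent(conn)), 2L)

    ## node-count tie: two disjoint edges -> lexicographically smallest
    tie <- data.frame(u = c("C", "A"), v = c("D", "B"))
    mccTie <- maximumConnectedComponent(tie)
    expect_setequal(unique(c(mccTie$u, mccTie$v)), c("A", "B"))

    ## node tie broken by edge count: triangle vs 3-node path
    tie2 <- data.frame(u = c("A", "B", "A", "X", "Y"),
                       v = c("B", "C", "C", "Y", "Z"))
    mcc2 <- maximumConnectedComponent(tie2)
    expect_setequal(unique(c(mcc2$u, mcc2$v)), c("A", "B", "C"))
})

test_that("average clustering matches hand values and brute-force enumeration", {
    tri <- data.frame(u = c("A", "B", "A"), v = c("B", "C", "C"))
    expect_equal(avgClustering(tri), 1.0)

    path <- data.frame(u = c("A", "B"), v = c("B", "C"))
    expect_equal(avgClustering(path), 0.0)

    ## 4-clique minus edge CD: A and B close 2 of 3 neighbor pairs
    ## (2/3 each); C and D have adjacent neighbor pairs (1 each)
    ## -> (2/3 + 2/3 + 1 + 1) / 4 = 5/6
    k4m <- data.frame(u = c("A", "A", "A", "B", "B"),
                      v = c("B", "C", "D", "C", "D"))
    expect_equal(avgClustering(k4m), 5 / 6)
    expect_equal(avgClustering(k4m), bruteAvgClustering(k4m$u, k4m$v))

    ## random battery against brute force
    set.seed(77)
    for (i in 1:60) {
        n <- sample(4:12, 1)
        g <- igraph::sample_gnp(n, runif(1, 0.2, 0.8))
        el <- igraph::as_edgelist(g)
        if (!nrow(el)) next
        u <- sprintf("n%02d", el[, 1]); v <- sprintf("n%02d", el[, 2])
        expect_equal(avgClustering(data.frame(u = u, v = v)),
                     bruteAvgClustering(u, v), tolerance = 1e-12)
    }
})

test_that("core-module selection maximizes clustering with ties to the smaller fraction", {
    ## top-ranked edges form a triangle; the rest is a tree hanging off it
    u <- c("A", "B", "A", "C", "D", "E", "F")
    v <- c("B", "C", "C", "D", "E", "F", "G")
    w <- wdinFromEdges(u, v, rep(1, 7))
    er <- erFromOrder(u, v)
    cm <- selectCoreModule(w, er, fractions = c(0.2, 0.4, 0.8, 1))
    ## smallest fraction containing the full triangle wins at coefficient 1
    expect_equal(cm@fraction, 0.4)   # ceil(0.4*7) = 3 edges: the triangle
    expect_equal(cm@clusteringCoefficient, 1.0)
    expect_setequal(unique(c(cm@edges$u, cm@edges$v)), c("A", "B", "C"))

    ## definition check: selected coefficient >= every swept coefficient
    expect_true(all(cm@clusteringCoefficient >=
                    cm@sweep$clusteringCoefficient))

    ## single-edge degenerate case
    w1 <- wdinFromEdges("A", "B", 1)
    cm1 <- selectCoreModule(w1, erFromOrder("A", "B"),
                            fractions = c(0.5, 1))
    expect_equal(numEdges(cm1), 1L)
    expect_equal(cm1@clusteringCoefficient, 0)
    expect_equal(cm1@fraction, 0.5)   # tie at 0 -> smaller fraction
})

test_that("ER clustering scales roughly like 1/N at fixed mean degree", {
    ## mirrored random-graph sanity: C(N) for G(n, p = d/(n-1)) tracks
    ## d/N, so doubling N should roughly halve the coefficient
    meanC <- function(n, d, reps, seed0) {
        vals <- vapply(seq_len(reps), function(i) {
            set.seed(seed0 + i)
            g <- igraph::sample_gnp(n, d / (n - 1))
            el <- igraph::as_edgelist(g)
            avgClustering(data.frame(u = sprintf("n%03d", el[, 1]),
                                     v = sprintf("n%03d", el[, 2])))
        }, numeric(1))
        mean(vals)
    }
    c100 <- meanC(100, 6, 50, 1000)
    c200 <- meanC(200, 6, 50, 2000)
    expect_gt(c100, c200)
    expect_gt(c100 / c200, 1.5)
    expect_lt(c100 / c200, 2.7)
})
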