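test_that("readNetwork deduplicates, drops self-loops, and rejects empty files", {
    f <- tempfile()
    writeLines(c("A B", "B A", "A B"), f)
    bg <- readNetwork(f)
    expect_equal(numEdges(bg), 1L)
    expect_identical(edgeKeys(bg), "A|B")

    writeLines(c("A A", "A B"), f)
    expect_message(bg2 <- readNetwork(f), "self-loop")
    expect_equal(numEdges(bg2), 1L)

    writeLines(c("A B", "B C", "A C"), f)
    tri <- readNetwork(f)
    expect_equal(numNodes(tri), 3L)
    expect_equal(numEdges(tri), 3L)

    writeLines(character(0), f)
    expect_error(readNetwork(f), "empty")
})

test_that("within-condition Spearman correlation matches the textbook formula", {
    vals <- rbind(u = c(1, 2, 3, 4, 9, 9, 9),
                  v = c(2, 1, 4, 3, 1, 2, 3),
                  w = c(10, 20, 30, 40, 5, 6, 7),
                  x = c(8, 6, 4, 2, 3, 2, 1))
    colnames(vals) <- paste0("S", 1:7)
    te <- toyExpression(vals, c(rep("GK", 4), rep("WK", 3)))

    expect_equal(conditionCorrelation(te, "u", "w", "GK"), 1.0)
    expect_equal(conditionCorrelation(te, "u", "x", "GK"), -1.0)
    ## u = (1,2,3,4) vs v = (2,1,4,3): 1 - 6*4/(4*15) = 0.6
    expect_equal(conditionCorrelation(te, "u", "v", "GK"), 0.6)
    expect_equal(conditionCorrelation(te, "u", "v", "GK"),
                 spearmanNoTies(vals["u", 1:4], vals["v", 1:4]))

    ## zero variance within the condition -> undefined marker
    expect_true(is.na(conditionCorrelation(te, "u", "v", "WK")))
    expect_error(conditionCorrelation(te, "u", "nope", "GK"), "nope")
})

## build a two-condition dataset whose within-condition correlations for
## the pair (u, v) are pinned near chosen values by construction; a
## block of independent background genes keeps the per-sample rank
## transform fine-grained, as in a real expression matrix
pinnedExpression <- function(rGK, rWK, n = 50, nBackground = 60, seed = 5) {
    set.seed(seed)
    draw <- function(r, n) {
        x <- rnorm(n); y <- r * x + sqrt(1 - r^2) * rnorm(n)
        cbind(x, y)
    }
    gk <- draw(rGK, n); wk <- draw(rWK, n)
    bgv <- matrix(rnorm(2 * n * nBackground), nrow = nBackground,
                  dimnames = list(sprintf("bg%02d", seq_len(nBackground)),
                                  NULL))
    vals <- rbind(u = c(gk[, 1], wk[, 1]), v = c(gk[, 2], wk[, 2]),
                  a = bgv[1, ], b = bgv[2, ], bgv[-(1:2), ])
    colnames(vals) <- paste0("S", seq_len(2 * n))
    toyExpression(vals, rep(c("GK", "WK"), each = n))
}

test_that("the diverse-interaction screen applies the hi/lo rule and weight convention", {
    bg <- backgroundNetwork(c("u", "a"), c("v", "b"))

    ## strongly correlated under disease only -> retained, active
    te <- pinnedExpression(rGK = 0.97, rWK = 0, seed = 5)
    z <- rankNormalize(te)
    w <- detectDiverseEdges(z, bg, normal = "WK", disease = "GK")
    expect_identical(edgeKeys(w), "u|v")
    e <- edgeTable(w)
    expect_gt(e$rDisease, 0.8)
    expect_lt(abs(e$rNormal), 0.2)
    expect_equal(e$weight, e$rDisease - e$rNormal)
    expect_identical(e$status, "active")

    ## strongly correlated under normal only -> retained, inactive
    w2 <- detectDiverseEdges(rankNormalize(pinnedExpression(0, 0.97, seed = 6)),
                             bg, normal = "WK", disease = "GK")
    expect_identical(edgeTable(w2)$status, "inactive")

    ## equally correlated in both conditions -> not retained
    w3 <- detectDiverseEdges(rankNormalize(pinnedExpression(0.5, 0.5, seed = 7)),
                             bg, normal = "WK", disease = "GK")
    expect_false("u|v" %in% edgeKeys(w3))

    ## strong negative correlation counts under the absolute test only
    te4 <- pinnedExpression(-0.97, 0, seed = 8)
    z4 <- rankNormalize(te4)
    w4abs <- detectDiverseEdges(z4, bg, normal = "WK", disease = "GK",
                                useAbsolute = TRUE)
    w4sgn <- detectDiverseEdges(z4, bg, normal = "WK", disease = "GK",
                                useAbsolute = FALSE)
    expect_true("u|v" %in% edgeKeys(w4abs))
    expect_false("u|v" %in% edgeKeys(w4sgn))
})

test_that("swapping condition roles negates weights and flips statuses", {
    spec <- simulationSpec(nGenes = 80, meanDegree = 3, nSamples = 40,
                           nPlanted = 10, seed = 3)
    bg <- simulateScaffold(spec)
    z <- rankNormalize(simulateExpression(spec, bg)[[1]])
    fwd <- suppressMessages(
        detectDiverseEdges(z, bg, normal = "WK", disease = "GK"))
    rev <- suppressMessages(
        detectDiverseEdges(z, bg, normal = "GK", disease = "WK"))
    expect_identical(edgeKeys(fwd), edgeKeys(rev))
    expect_gt(numEdges(fwd), 0L)
    ef <- edgeTable(fwd); er <- edgeTable(rev)
    expect_equal(ef$weight, -er$weight)
    expect_identical(ef$status == "active", er$status == "inactive")
})

test_that("raising hi or lowering lo never adds an edge, and the WDIN stays inside the background", {
    spec <- simulationSpec(nGenes = 100, meanDegree = 4, nSamples = 30,
                           nPlanted = 12, rHigh = 0.9, seed = 9)
    bg <- simulateScaffold(spec)
    z <- rankNormalize(simulateExpression(spec, bg)[[1]])
    base <- detectDiverseEdges(z, bg, normal = "WK", disease = "GK",
                               hi = 0.7, lo = 0.3)
    expect_true(all(edgeKeys(base) %in% edgeKeys(bg)))
    stricterHi <- detectDiverseEdges(z, bg, normal = "WK", disease = "GK",
                                     hi = 0.85, lo = 0.3)
    stricterLo <- detectDiverseEdges(z, bg, normal = "WK", disease = "GK",
                                     hi = 0.7, lo = 0.15)
    expect_true(all(edgeKeys(stricterHi) %in% edgeKeys(base)))
    expect_true(all(edgeKeys(stricterLo) %in% edgeKeys(base)))
    expect_error(detectDiverseEdges(z, bg, normal = "WK", disease = "GK",
                                    hi = 0.2, lo = 0.8), "thresholds")
})
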