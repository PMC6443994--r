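#' Run the full multi-level comparative pipeline on simulated data
#'
#' Convenience driver covering every stage: simulate scaffold and
#' expression, rank-normalize, screen for diverse interactions per
#' tissue, prioritize nodes by restart random walk from a seed set,
#' rank edges, extract each tissue's core module, merge the modules,
#' and classify the merged edges. On real data call the stage functions
#' directly; this driver exists for end-to-end simulation studies and
#' reproducibility checks.
#'
#' Seed genes default to the planted-edge genes of the first tissue's
#' first few pairs (the simulation's designated disease neighborhood);
#' supply \code{seedGenes} to override.
#'
#' @param spec a \linkS4class{SimulationSpec} (use >= 2 tissues to
#'   exercise the merge and classification stages).
#' @param seedGenes optional character vector of RWR seed genes.
#' @param nSeedPairs when \code{seedGenes} is NULL, how many planted
#'   pairs per tissue donate their genes to the seed set (default 5).
#' @param hi,lo,useAbsolute diverse-interaction screen thresholds.
#' @param gamma RWR restart probability.
#' @param fractions core-module sweep fractions.
#' @param alpha merge threshold.
#' @return list with elements \code{scaffold}, \code{expression},
#'   \code{normalized}, \code{planted}, \code{seedGenes}, \code{wdins},
#'   \code{nodeRankings}, \code{edgeRankings}, \code{coreModules},
#'   \code{alphaSweep}, \code{mcm} (classified), and \code{summary}
#'   (category counts).
#' @export
runPipeline <- function(spec, seedGenes = NULL, nSeedPairs = 5L,
                        hi = 0.8, lo = 0.2, useAbsolute = TRUE,
                        gamma = 0.3,
                        fractions = seq(0.025, 0.25, by = 0.025),
                        alpha = 0.1) {
    scaffold <- simulateScaffold(spec)
    expr <- simulateExpression(spec, scaffold)
    planted <- attr(expr, "plantedEdges")
    normal <- unname(spec@conditions["normal"])
    disease <- unname(spec@conditions["disease"])

    if (is.null(seedGenes)) {
        ## designated disease neighborhood: a few module genes when a
        ## module is planted, else genes of the first planted pairs
        mg <- moduleGenes(spec)
        seedGenes <- if (length(mg)) {
            utils::head(mg, max(2L, ceiling(length(mg) / 4)))
        } else {
            unique(unlist(lapply(spec@tissues, function(tis) {
                pt <- planted[planted$tissue == tis, , drop = FALSE]
                pt <- utils::head(pt, nSeedPairs)
                c(pt$u, pt$v)
            })))
        }
    }

    normalized <- lapply(expr, rankNormalize)
    wdins <- lapply(normalized, detectDiverseEdges, bg = scaffold,
                    normal = normal, disease = disease,
                    hi = hi, lo = lo, useAbsolute = useAbsolute)
    nodeRankings <- lapply(wdins, function(w)
        suppressWarnings(rwr(w, seedGenes, gamma = gamma)))
    edgeRankings <- Map(rankEdges, wdins, nodeRankings)
    coreModules <- Map(function(w, er)
        selectCoreModule(w, er, fractions = fractions),
        wdins, edgeRankings)

    if (length(coreModules) >= 2L) {
        alphaSweep <- sweepAlpha(coreModules)
        mcm <- classifyEdges(suppressWarnings(
            mergeCoreModules(coreModules, alpha = alpha)))
        summary <- categoryCounts(mcm)
    } else {
        alphaSweep <- NULL; mcm <- NULL; summary <- NULL
    }

    list(scaffold = scaffold, expression = expr, normalized = normalized,
         planted = planted, seedGenes = seedGenes, wdins = wdins,
         nodeRankings = nodeRankings, edgeRankings = edgeRankings,
         coreModules = coreModules, alphaSweep = alphaSweep,
         mcm = mcm, summary = summary)
}
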