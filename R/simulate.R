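#' Specify a synthetic two-condition, multi-tissue study
#'
#' Builds a \linkS4class{SimulationSpec} describing an Erdős–Rényi
#' scaffold interactome and, per tissue, planted gene pairs whose
#' within-condition correlation differs sharply between phenotypes —
#' the ground truth the diverse-interaction screen should recover.
#' Planted pairs are sampled from the scaffold edges (pairwise disjoint
#' in genes, so each pair's bivariate correlation structure is exact) by
#' \code{\link{simulateScaffold}} + \code{\link{samplePlantedEdges}}, or
#' supplied explicitly via \code{plantedEdges}.
#'
#' @param nGenes scaffold size (>= 2).
#' @param meanDegree expected scaffold degree (> 0).
#' @param nSamples samples per condition per tissue (>= 3).
#' @param nPlanted number of planted pairs per tissue, sampled
#'   gene-disjointly from the scaffold (ignored when \code{plantedEdges}
#'   is given).
#' @param rHigh,rLow Pearson correlations of a planted pair in its high
#'   and low condition (defaults 0.95 and 0; the induced Spearman
#'   correlation of a bivariate Gaussian is \eqn{(6/\pi)
#'   \arcsin(r/2)}, about 0.945 for r = 0.95).
#' @param highCondition which phenotype carries the high correlation:
#'   "disease" (default; recovered edges are then active) or "normal".
#' @param plantedEdges optional data.frame (tissue, u, v, rHigh, rLow,
#'   highCondition) overriding the sampled planting.
#' @param backgroundR correlation of non-planted scaffold pairs in both
#'   conditions; the default 0 leaves them independent. Nonzero values
#'   require the scaffold pairs to be gene-disjoint.
#' @param noiseSd marginal standard deviation of the simulated values.
#' @param nModuleGenes size of an optional planted co-expression module
#'   (see \linkS4class{SimulationSpec}); its clique edges are added to
#'   the scaffold and its genes excluded from pairwise planting. 0
#'   (default) disables it.
#' @param moduleR within-module pairwise Pearson correlation in the
#'   high condition (latent-factor construction; default 0.9).
#' @param moduleHighCondition phenotype in which the module is
#'   co-expressed; default "disease".
#' @param conditions named character c(normal=, disease=); defaults to
#'   the Goto–Kakizaki / Wistar–Kyoto strain labels c(normal = "WK",
#'   disease = "GK").
#' @param tissues tissue labels; default a single "tissue1".
#' @param seed master RNG seed; every random draw derives from it.
#' @return a \linkS4class{SimulationSpec}.
#' @export
simulationSpec <- function(nGenes = 300L, meanDegree = 4, nSamples = 100L,
                           nPlanted = 30L, rHigh = 0.95, rLow = 0,
                           highCondition = "disease",
                           plantedEdges = NULL, backgroundR = 0,
                           noiseSd = 1, nModuleGenes = 0L, moduleR = 0.9,
                           moduleHighCondition = "disease",
                           conditions = c(normal = "WK", disease = "GK"),
                           tissues = "tissue1", seed = 1L) {
    if (is.null(plantedEdges)) {
        plantedEdges <- data.frame(tissue = character(0), u = character(0),
                                   v = character(0), rHigh = numeric(0),
                                   rLow = numeric(0),
                                   highCondition = character(0))
        attr(plantedEdges, "autoPlant") <-
            list(nPlanted = as.integer(nPlanted), rHigh = rHigh, rLow = rLow,
                 highCondition = highCondition)
    }
    new("SimulationSpec", nGenes = as.integer(nGenes),
        meanDegree = as.numeric(meanDegree), nSamples = as.integer(nSamples),
        plantedEdges = plantedEdges, backgroundR = as.numeric(backgroundR),
        noiseSd = as.numeric(noiseSd),
        nModuleGenes = as.integer(nModuleGenes),
        moduleR = as.numeric(moduleR),
        moduleHighCondition = moduleHighCondition,
        conditions = conditions, tissues = tissues, seed = as.integer(seed))
}

.specGeneNames <- function(spec)
    sprintf("G%0*d", nchar(spec@nGenes), seq_len(spec@nGenes))

#' Genes of the spec's planted co-expression module
#' @param spec a \linkS4class{SimulationSpec}.
#' @return character vector (empty when no module is planted).
#' @export
moduleGenes <- function(spec) {
    stopifnot(is(spec, "SimulationSpec"))
    utils::head(.specGeneNames(spec), spec@nModuleGenes)
}

#' Simulate the Erdős–Rényi scaffold interactome
#'
#' G(n, p) with \eqn{p = meanDegree / (n - 1)}, giving the requested
#' expected mean degree; gene symbols are zero-padded \code{G...} labels.
#' Deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return a \linkS4class{BackgroundNetwork}.
#' @export
simulateScaffold <- function(spec) {
    stopifnot(is(spec, "SimulationSpec"))
    n <- spec@nGenes
    p <- spec@meanDegree / (n - 1)
    if (p > 1) stop("meanDegree too large for nGenes")
    genes <- .specGeneNames(spec)
    g <- .withSeed(spec@seed, igraph::sample_gnp(n, p))
    el <- igraph::as_edgelist(g)
    if (!nrow(el))
        stop("scaffold came out empty; increase nGenes or meanDegree")
    u <- genes[el[, 1L]]; v <- genes[el[, 2L]]
    mg <- moduleGenes(spec)
    if (length(mg)) {      # planted-module clique joins the interactome
        cl <- utils::combn(mg, 2L)
        u <- c(u, cl[1L, ]); v <- c(v, cl[2L, ])
    }
    backgroundNetwork(u, v)
}

#' Sample gene-disjoint planted pairs from a scaffold
#'
#' Greedily samples scaffold edges sharing no genes, in seed-determined
#' random order, and labels them with the requested correlation profile.
#'
#' @param bg a \linkS4class{BackgroundNetwork}.
#' @param n number of pairs to plant.
#' @param rHigh,rLow,highCondition planted correlation profile.
#' @param tissue tissue label for the planted rows.
#' @param seed RNG seed.
#' @param exclude genes that may not appear in planted pairs.
#' @return data.frame (tissue, u, v, rHigh, rLow, highCondition).
#' @export
samplePlantedEdges <- function(bg, n, rHigh = 0.95, rLow = 0,
                               highCondition = "disease",
                               tissue = "tissue1", seed = 1L,
                               exclude = character(0)) {
    e <- bg@edges
    e <- e[!(e[, 1L] %in% exclude | e[, 2L] %in% exclude), , drop = FALSE]
    ord <- .withSeed(seed, sample.int(nrow(e)))
    used <- character(0)
    picked <- integer(0)
    for (i in ord) {
        if (e[i, 1L] %in% used || e[i, 2L] %in% used) next
        picked <- c(picked, i)
        used <- c(used, e[i, ])
        if (length(picked) == n) break
    }
    if (length(picked) < n)
        stop("scaffold supports only ", length(picked),
             " gene-disjoint planted pairs (requested ", n, ")")
    data.frame(tissue = tissue, u = e[picked, 1L], v = e[picked, 2L],
               rHigh = rHigh, rLow = rLow, highCondition = highCondition,
               stringsAsFactors = FALSE)
}

## correlated bivariate Gaussian draw: y = r x + sqrt(1 - r^2) eps
.bvn <- function(n, r) {
    x <- stats::rnorm(n)
    y <- r * x + sqrt(1 - r^2) * stats::rnorm(n)
    cbind(x, y)
}

#' Simulate two-condition expression with planted diverse interactions
#'
#' For each tissue, draws a gene-by-sample matrix with
#' \code{2 * nSamples} columns (one block per condition). Each planted
#' pair is sampled from a bivariate Gaussian with correlation
#' \code{rHigh} in its high condition and \code{rLow} in the other;
#' genes outside planted pairs are independent Gaussians (or share the
#' spec's \code{backgroundR} along non-planted scaffold edges when that
#' is nonzero and the scaffold pairs are disjoint). Marginals have
#' standard deviation \code{noiseSd}. Deterministic given the spec's
#' seed.
#'
#' @param spec a \linkS4class{SimulationSpec}. When its
#'   \code{plantedEdges} table is empty, pairs are auto-planted per
#'   tissue via \code{\link{samplePlantedEdges}} with the spec's
#'   planting profile.
#' @param scaffold the \linkS4class{BackgroundNetwork} from
#'   \code{\link{simulateScaffold}}.
#' @return named list (per tissue) of \linkS4class{TissueExpression}
#'   objects; the realized planted-edge table is attached as attribute
#'   \code{"plantedEdges"}.
#' @export
simulateExpression <- function(spec, scaffold) {
    stopifnot(is(spec, "SimulationSpec"), is(scaffold, "BackgroundNetwork"))
    pe <- spec@plantedEdges
    auto <- attr(pe, "autoPlant")
    if (!nrow(pe) && !is.null(auto) && auto$nPlanted > 0L) {
        pe <- do.call(rbind, lapply(seq_along(spec@tissues), function(t)
            samplePlantedEdges(scaffold, auto$nPlanted, auto$rHigh,
                               auto$rLow, auto$highCondition,
                               tissue = spec@tissues[t],
                               seed = spec@seed + 1000L * t,
                               exclude = moduleGenes(spec))))
    }
    scafKeys <- edgeKeys(scaffold)
    if (nrow(pe)) {
        cp <- .canonicalPairs(pe$u, pe$v)
        pe$u <- cp[, 1L]; pe$v <- cp[, 2L]
        bad <- !(.pairKey(pe$u, pe$v) %in% scafKeys)
        if (any(bad))
            stop("planted pair(s) not in the scaffold: ",
                 paste(.pairKey(pe$u[bad], pe$v[bad]), collapse = ", "))
    }
    genes <- .csort(union(.specGeneNames(spec), nodeNames(scaffold)))

    nS <- spec@nSamples
    condRole <- c(rep("disease", nS), rep("normal", nS))
    condLab <- unname(spec@conditions[condRole])
    sampleIds <- sprintf("S%0*d", nchar(2 * nS), seq_len(2 * nS))

    out <- stats::setNames(vector("list", length(spec@tissues)), spec@tissues)
    for (t in seq_along(spec@tissues)) {
        tis <- spec@tissues[t]
        pet <- pe[pe$tissue == tis, , drop = FALSE]
        shared <- c(pet$u, pet$v)
        if (anyDuplicated(shared))
            stop("conflicting planted pairs share gene(s): ",
                 paste(unique(shared[duplicated(shared)]), collapse = ", "))
        mg <- moduleGenes(spec)
        if (length(clash <- intersect(shared, mg)))
            stop("planted pair(s) conflict with the planted module at gene(s): ",
                 paste(clash, collapse = ", "))
        if (spec@backgroundR != 0) {
            bgPairs <- scaffold@edges[
                !(edgeKeys(scaffold) %in% .pairKey(pet$u, pet$v)), ,
                drop = FALSE]
            if (anyDuplicated(c(as.vector(bgPairs), shared)))
                stop("nonzero backgroundR requires gene-disjoint scaffold pairs")
        } else bgPairs <- matrix(character(0), ncol = 2L)

        vals <- .withSeed(spec@seed + 7919L * t, {
            m <- matrix(stats::rnorm(length(genes) * 2L * nS),
                        nrow = length(genes),
                        dimnames = list(genes, sampleIds))
            drawPair <- function(u, v, rD, rN) {
                xy <- rbind(.bvn(nS, rD), .bvn(nS, rN))
                m[u, ] <<- xy[, 1L]
                m[v, ] <<- xy[, 2L]
            }
            if (nrow(pet)) for (i in seq_len(nrow(pet))) {
                rD <- if (pet$highCondition[i] == "disease") pet$rHigh[i]
                      else pet$rLow[i]
                rN <- if (pet$highCondition[i] == "disease") pet$rLow[i]
                      else pet$rHigh[i]
                drawPair(pet$u[i], pet$v[i], rD, rN)
            }
            if (nrow(bgPairs)) for (i in seq_len(nrow(bgPairs)))
                drawPair(bgPairs[i, 1L], bgPairs[i, 2L],
                         spec@backgroundR, spec@backgroundR)
            if (length(mg)) {
                ## latent-factor module: pairwise correlation moduleR in
                ## the high condition, independence in the other
                highCols <- if (spec@moduleHighCondition == "disease")
                    seq_len(nS) else nS + seq_len(nS)
                f <- stats::rnorm(nS)
                for (g in mg)
                    m[g, highCols] <- sqrt(spec@moduleR) * f +
                        sqrt(1 - spec@moduleR) * stats::rnorm(nS)
            }
            m * spec@noiseSd
        })
        out[[tis]] <- TissueExpressionFromMatrix(vals, condLab, tissue = tis)
    }
    attr(out, "plantedEdges") <- pe
    out
}

#' Score diverse-edge recovery against the planted truth
#'
#' @param wdin a \linkS4class{WDIN} built on simulated data.
#' @param planted the planted-edge table for the WDIN's tissue (rows of
#'   the \code{"plantedEdges"} attribute of
#'   \code{\link{simulateExpression}}).
#' @return list with \code{recall}, \code{precision}, \code{nRecovered},
#'   and \code{signAccuracy} — the fraction of recovered planted edges
#'   whose status matches the planted direction (high condition =
#'   disease should come back active).
#' @export
scoreRecovery <- function(wdin, planted) {
    truth <- .pairKey(planted$u, planted$v)
    got <- edgeKeys(wdin)
    tp <- intersect(got, truth)
    recall <- length(tp) / length(truth)
    precision <- if (length(got)) length(tp) / length(got) else 0
    e <- wdin@edges
    hit <- match(tp, .pairKey(e$u, e$v))
    expStatus <- ifelse(
        planted$highCondition[match(tp, truth)] == "disease",
        "active", "inactive")
    signAcc <- if (length(tp)) mean(e$status[hit] == expStatus) else NA_real_
    list(recall = recall, precision = precision, nRecovered = length(tp),
         signAccuracy = signAcc)
}
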