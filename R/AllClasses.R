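#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' TissueExpression: a two-condition expression matrix for one tissue
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are gene symbols
#' (unique), columns are samples, and \code{colData(x)$condition} assigns
#' each sample one of exactly two phenotype labels (e.g. disease strain
#' \code{"GK"} vs control \code{"WK"}). Both conditions must carry at least
#' three samples so that within-condition correlations are defined.
#'
#' The same container holds raw expression values and the per-sample
#' rank z-scores produced by \code{\link{rankNormalize}}; the two states
#' are distinguished by \code{metadata(x)$normalized}.
#'
#' @slot tissue character(1), free-text tissue label.
#' @export
setClass("TissueExpression",
    contains = "SummarizedExperiment",
    representation(tissue = "character"))

setValidity("TissueExpression", function(object) {
    msg <- character()
    g <- rownames(object)
    if (is.null(g) || anyDuplicated(g))
        msg <- c(msg, "gene symbols (rownames) must be present and unique")
    if (any(is.na(assay(object))))
        msg <- c(msg, "expression values must not contain missing cells")
    cd <- colData(object)
    if (!"condition" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'condition' column")
    } else {
        tab <- table(as.character(cd$condition))
        if (length(tab) != 2L)
            msg <- c(msg, sprintf(
                "exactly two condition labels required, found %d", length(tab)))
        if (any(tab < 3L))
            msg <- c(msg, "each condition needs >= 3 samples")
    }
    if (length(object@tissue) != 1L)
        msg <- c(msg, "tissue must be a single label")
    if (length(msg)) msg else TRUE
})

#' BackgroundNetwork: undirected background interactome
#'
#' An undirected, simple (no self-loops, no multi-edges) interaction
#' network over gene symbols, typically assembled from pathway and
#' protein-protein interaction databases. Edges are stored canonically
#' with \code{u < v} lexicographically.
#'
#' @slot edges two-column character matrix of gene pairs, canonical order.
#' @export
setClass("BackgroundNetwork",
    representation(edges = "matrix"))

setValidity("BackgroundNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    if (nrow(e)) {
        if (!is.character(e)) msg <- c(msg, "edges must be character")
        if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
        if (any(e[, 1L] > e[, 2L]))
            msg <- c(msg, "edges must be canonically ordered (u < v)")
        if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
            msg <- c(msg, "duplicate edges are not allowed")
    }
    if (length(msg)) msg else TRUE
})

#' WDIN: weighted diverse interaction network for one tissue
#'
#' Holds the background-network edges whose within-condition Spearman
#' correlation passes the diverse-interaction screen: high magnitude in
#' one phenotype, low in the other. Each edge carries the two
#' within-condition correlations, its weight (disease minus normal
#' correlation) and its status: \code{"active"} (weight > 0, correlation
#' gained under disease) or \code{"inactive"} (weight < 0, lost).
#'
#' @slot tissue character(1) tissue label.
#' @slot edges data.frame with columns u, v (canonical order), rNormal,
#'   rDisease, weight, status.
#' @slot params list recording the screening thresholds (hi, lo,
#'   useAbsolute) and condition labels used.
#' @export
setClass("WDIN",
    representation(tissue = "character", edges = "data.frame",
                   params = "list"))

setValidity("WDIN", function(object) {
    e <- object@edges
    msg <- character()
    need <- c("u", "v", "rNormal", "rDisease", "weight", "status")
    if (!all(need %in% names(e)))
        return(paste("edges must have columns:", paste(need, collapse = ", ")))
    if (nrow(e)) {
        if (any(e$u >= e$v)) msg <- c(msg, "edges must be canonical (u < v)")
        if (max(abs(e$weight - (e$rDisease - e$rNormal))) > 1e-12)
            msg <- c(msg, "weight must equal rDisease - rNormal")
        if (any(e$weight == 0)) msg <- c(msg, "zero-weight edges are not allowed")
        ok <- ifelse(e$weight > 0, "active", "inactive")
        if (!identical(as.character(e$status), ok))
            msg <- c(msg, "status must follow the weight sign")
    }
    if (length(msg)) msg else TRUE
})

#' NodeRanking: random-walk-with-restart gene prioritization
#'
#' Steady-state visiting probabilities of a restart random walk seeded at
#' known disease genes, plus the derived candidate ranking (rank 1 = most
#' disease-associated candidate). Seeds are excluded from the ranking.
#'
#' @slot scores named numeric, steady-state probability per candidate gene.
#' @slot ranks named integer, rank per candidate (permutation of 1..n).
#' @slot seeds character, seed genes present in the network.
#' @slot steadyState named numeric, probabilities over all network nodes.
#' @slot iterations integer(1), iterations to convergence (0 for a direct
#'   linear solve).
#' @slot probabilitySums numeric, total probability mass after each
#'   iteration (diagnostic; equals 1 throughout when eta = 0).
#' @export
setClass("NodeRanking",
    representation(scores = "numeric", ranks = "integer",
                   seeds = "character", steadyState = "numeric",
                   iterations = "integer", probabilitySums = "numeric"))

setValidity("NodeRanking", function(object) {
    msg <- character()
    if (!identical(names(object@scores), names(object@ranks)))
        msg <- c(msg, "scores and ranks must cover the same genes")
    n <- length(object@ranks)
    if (n && !identical(sort(as.integer(object@ranks)), seq_len(n)))
        msg <- c(msg, "ranks must be a permutation of 1..n")
    if (any(names(object@scores) %in% object@seeds))
        msg <- c(msg, "seed genes must not be ranked")
    if (length(msg)) msg else TRUE
})

#' EdgeRanking: prioritized WDIN edges
#'
#' Edges ordered by their index, the mean of the two endpoint ranks;
#' smaller index = more disease-associated. Ties are broken by the
#' lexicographic gene pair so runs are reproducible.
#'
#' @slot table data.frame with columns u, v, index, sorted ascending.
#' @slot policy character(1), how seed genes entered the edge index
#'   ("seeds_first" assigns seeds rank 0; "drop_seed_edges" removes
#'   seed-incident edges).
#' @export
setClass("EdgeRanking",
    representation(table = "data.frame", policy = "character"))

#' CoreModule: clustering-coefficient-maximizing prioritized subnetwork
#'
#' The maximum connected component, over a sweep of top-fraction
#' prioritized-edge subnetworks, with the largest average clustering
#' coefficient. The full sweep table is retained for reporting.
#'
#' @slot tissue character(1).
#' @slot fraction numeric(1), selected top-edge fraction.
#' @slot edges data.frame, WDIN edge subset (with weights).
#' @slot clusteringCoefficient numeric(1).
#' @slot sweep data.frame with one row per swept fraction.
#' @export
setClass("CoreModule",
    representation(tissue = "character", fraction = "numeric",
                   edges = "data.frame", clusteringCoefficient = "numeric",
                   sweep = "data.frame"))

#' MergedCoreModule: cross-tissue merge of core modules
#'
#' Union-style merge of tissue core modules admitting the interactions
#' whose cross-module Jaccard index exceeds alpha in at least one module
#' pair. Each edge carries one weight column per source tissue (NA where
#' the tissue's core module lacks the edge) and, after
#' \code{\link{classifyEdges}}, a category label.
#'
#' @slot tissues character, source tissue labels.
#' @slot alpha numeric(1), merge threshold.
#' @slot method character(1), per-interaction Jaccard strategy used.
#' @slot edges data.frame: u, v, one numeric column per tissue, category.
#' @export
setClass("MergedCoreModule",
    representation(tissues = "character", alpha = "numeric",
                   method = "character", edges = "data.frame"))

setValidity("MergedCoreModule", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("u", "v", object@tissues, "category") %in% names(e)))
        return("edges must have u, v, one column per tissue, and category")
    if (nrow(e)) {
        w <- as.matrix(e[, object@tissues, drop = FALSE])
        if (any(rowSums(!is.na(w)) == 0L))
            msg <- c(msg, "every edge must be present in >= 1 tissue")
    }
    if (length(object@alpha) == 1L && (object@alpha <= 0 || object@alpha >= 1))
        msg <- c(msg, "alpha must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' SimulationSpec: parameters of the synthetic two-condition study
#'
#' Describes an Erdős–Rényi scaffold interactome and, per tissue, a set
#' of planted gene pairs that are strongly correlated in one phenotype
#' and weakly in the other — the ground truth against which
#' diverse-interaction recovery is scored.
#'
#' @slot nGenes integer(1), scaffold size.
#' @slot meanDegree numeric(1), expected scaffold degree.
#' @slot nSamples integer(1), samples per condition per tissue.
#' @slot plantedEdges data.frame: tissue, u, v, rHigh, rLow,
#'   highCondition ("disease" or "normal").
#' @slot backgroundR numeric(1), correlation of non-planted scaffold
#'   pairs in both conditions (0 = independent).
#' @slot noiseSd numeric(1), marginal standard deviation.
#' @slot nModuleGenes integer(1), size of an optional planted
#'   co-expression module: a gene clique added to the scaffold whose
#'   members share a latent factor (pairwise correlation
#'   \code{moduleR}) in the module's high condition and are independent
#'   in the other. 0 disables it.
#' @slot moduleR numeric(1), within-module pairwise Pearson correlation
#'   in the high condition.
#' @slot moduleHighCondition character(1), "disease" or "normal".
#' @slot conditions named character, labels for c(normal=, disease=).
#' @slot tissues character, tissue labels.
#' @slot seed integer(1), master RNG seed; all randomness derives from it.
#' @export
setClass("SimulationSpec",
    representation(nGenes = "integer", meanDegree = "numeric",
                   nSamples = "integer", plantedEdges = "data.frame",
                   backgroundR = "numeric", noiseSd = "numeric",
                   nModuleGenes = "integer", moduleR = "numeric",
                   moduleHighCondition = "character",
                   conditions = "character", tissues = "character",
                   seed = "integer"))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    if (object@nGenes < 2L) msg <- c(msg, "nGenes must be >= 2")
    if (object@meanDegree <= 0) msg <- c(msg, "meanDegree must be > 0")
    if (object@nSamples < 3L) msg <- c(msg, "nSamples per condition must be >= 3")
    pe <- object@plantedEdges
    if (nrow(pe)) {
        if (any(abs(pe$rHigh) > 1) || any(abs(pe$rLow) > 1))
            msg <- c(msg, "planted correlations must lie in [-1, 1]")
        if (!all(pe$highCondition %in% c("disease", "normal")))
            msg <- c(msg, "highCondition must be 'disease' or 'normal'")
    }
    if (!identical(sort(names(object@conditions)), c("disease", "normal")))
        msg <- c(msg, "conditions must be named 'normal' and 'disease'")
    if (abs(object@backgroundR) >= 1)
        msg <- c(msg, "backgroundR must lie in (-1, 1)")
    if (object@nModuleGenes < 0L ||
        (object@nModuleGenes > 0L && object@nModuleGenes < 3L))
        msg <- c(msg, "nModuleGenes must be 0 or >= 3")
    if (object@nModuleGenes > object@nGenes)
        msg <- c(msg, "nModuleGenes cannot exceed nGenes")
    if (object@moduleR < 0 || object@moduleR >= 1)
        msg <- c(msg, "moduleR must lie in [0, 1)")
    if (!object@moduleHighCondition %in% c("disease", "normal"))
        msg <- c(msg, "moduleHighCondition must be 'disease' or 'normal'")
    if (length(msg)) msg else TRUE
})
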