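#' Classify merged-core-module edges across tissues
#'
#' Assigns each edge of the merged core module exactly one category from
#' its per-tissue presence and weight signs:
#' \itemize{
#'   \item \code{specific:<tissue>} — the edge is present in exactly one
#'     tissue's core module;
#'   \item \code{differential} — present in two or more tissues with
#'     both weight signs occurring (the interaction is active in one
#'     tissue and inactive in another);
#'   \item \code{common} — present in two or more tissues with all
#'     weight signs equal (consistently active or consistently
#'     inactive).
#' }
#' An edge present in three tissues with mixed signs is differential
#' (at least one discordant pair).
#'
#' @param mcm a \linkS4class{MergedCoreModule}.
#' @return the same object with the \code{category} column filled.
#' @seealso \code{\link{categoryCounts}} for per-category and
#'   per-tissue-pair summaries.
#' @export
classifyEdges <- function(mcm) {
    e <- mcm@edges
    if (!nrow(e)) return(mcm)
    w <- as.matrix(e[, mcm@tissues, drop = FALSE])
    present <- !is.na(w)
    nPresent <- rowSums(present)
    if (any(nPresent == 0L))
        stop("edge(s) present in zero tissues violate the merged-module invariant")
    if (any(w[present] == 0))
        stop("zero per-tissue weight encountered; WDIN weights must be nonzero")
    cat <- character(nrow(e))
    single <- nPresent == 1L
    cat[single] <- paste0("specific:",
                          mcm@tissues[apply(present[single, , drop = FALSE],
                                            1L, which)])
    multi <- which(!single)
    for (i in multi) {
        s <- sign(w[i, present[i, ]])
        cat[i] <- if (length(unique(s)) == 1L) "common" else "differential"
    }
    mcm@edges$category <- cat
    validObject(mcm)
    mcm
}

#' Category and tissue-pair summaries of a classified merged module
#'
#' Counts edges per category, and for every tissue pair counts the
#' edges present in both tissues split into concordant (same weight
#' sign) and discordant (opposite sign) — the pairwise common and
#' differential tallies.
#'
#' @param mcm a classified \linkS4class{MergedCoreModule}.
#' @return list with \code{byCategory} (named integer vector) and
#'   \code{byPair} (data.frame: tissueA, tissueB, nShared, nCommon,
#'   nDifferential).
#' @export
categoryCounts <- function(mcm) {
    e <- mcm@edges
    if (nrow(e) && any(is.na(e$category)))
        stop("run classifyEdges() first")
    byCat <- table(factor(e$category,
                          levels = c(paste0("specific:", mcm@tissues),
                                     "differential", "common")))
    w <- as.matrix(e[, mcm@tissues, drop = FALSE])
    pairIdx <- utils::combn(seq_along(mcm@tissues), 2L)
    rows <- lapply(seq_len(ncol(pairIdx)), function(p) {
        a <- pairIdx[1L, p]; b <- pairIdx[2L, p]
        both <- !is.na(w[, a]) & !is.na(w[, b])
        conc <- both & sign(w[, a]) == sign(w[, b])
        data.frame(tissueA = mcm@tissues[a], tissueB = mcm@tissues[b],
                   nShared = sum(both), nCommon = sum(conc),
                   nDifferential = sum(both & !conc))
    })
    list(byCategory = stats::setNames(as.integer(byCat), names(byCat)),
         byPair = do.call(rbind, rows))
}
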