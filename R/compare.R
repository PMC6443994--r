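.asEdgeSet <- function(x) {
    if (is.character(x)) return(unique(x))
    unique(edgeKeys(x))
}

.asNodeSet <- function(x) {
    if (is.character(x)) return(unique(x))
    nodeNames(x)
}

#' Edge-overlap S-score between two networks
#'
#' With \eqn{N_1, N_2} the two edge counts and \eqn{n} the number of
#' edges present in both networks, the directional overlap ratios are
#' \eqn{x_1 = n / N_1} and \eqn{x_2 = n / N_2}, and the S-score is their
#' harmonic mean \eqn{2 x_1 x_2 / (x_1 + x_2)}. Disjoint networks
#' (\eqn{n = 0}) score 0 by convention; identical networks score 1. Edge
#' identity is the unordered gene pair; weights and status are ignored.
#'
#' @param a,b networks (\linkS4class{WDIN}, \linkS4class{CoreModule},
#'   \linkS4class{BackgroundNetwork}, two-column pair table, or a
#'   character vector of \code{edgeKeys}).
#' @return list with \code{n}, \code{N1}, \code{N2}, \code{x1},
#'   \code{x2}, \code{sScore}.
#' @export
sScore <- function(a, b) {
    ea <- .asEdgeSet(a); eb <- .asEdgeSet(b)
    if (!length(ea) || !length(eb)) stop("both edge sets must be nonempty")
    n <- length(intersect(ea, eb))
    x1 <- n / length(ea)
    x2 <- n / length(eb)
    s <- if (n > 0) 2 * x1 * x2 / (x1 + x2) else 0
    list(n = n, N1 = length(ea), N2 = length(eb), x1 = x1, x2 = x2,
         sScore = s)
}

#' Venn region counts for two or three node sets
#'
#' Partitions the union of the supplied gene sets into the 3 (pairwise)
#' or 7 (triple) Venn regions and counts each.
#'
#' @param sets a named list of 2 or 3 character vectors (or network
#'   objects, whose node sets are used). Unnamed lists get names
#'   \code{A, B, C}.
#' @return named integer vector; region names join set names with
#'   \code{"&"} (e.g. \code{"A&B"} = in A and B only).
#' @export
vennNodes <- function(sets) {
    if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
        stop("vennNodes needs a list of 2 or 3 sets")
    sets <- lapply(sets, .asNodeSet)
    if (is.null(names(sets)))
        names(sets) <- LETTERS[seq_along(sets)]
    universe <- unique(unlist(sets))
    memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
    pattern <- apply(memb, 1L, function(row)
        paste(names(sets)[row], collapse = "&"))
    k <- length(sets)
    regions <- unlist(lapply(seq_len(k), function(m)
        utils::combn(names(sets), m, paste, collapse = "&")))
    counts <- stats::setNames(integer(length(regions)), regions)
    tab <- table(pattern)
    counts[names(tab)] <- as.integer(tab)
    counts
}

#' Jaccard index of two sets
#'
#' \eqn{|a \cap b| / |a \cup b|}; at least one set must be nonempty.
#'
#' @param a,b character vectors (or objects with node sets).
#' @return numeric in [0, 1].
#' @export
jaccardIndex <- function(a, b) {
    a <- unique(as.character(a)); b <- unique(as.character(b))
    u <- length(union(a, b))
    if (u == 0L) stop("Jaccard index undefined: both sets empty")
    length(intersect(a, b)) / u
}
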