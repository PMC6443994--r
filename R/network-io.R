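#' Construct a BackgroundNetwork from gene pairs
#'
#' Edges are canonicalized (unordered pairs), deduplicated, and
#' self-loops dropped with a message.
#'
#' @param u,v character vectors of endpoint gene symbols, or \code{u} a
#'   two-column matrix/data.frame of pairs with \code{v} missing.
#' @return a \linkS4class{BackgroundNetwork}.
#' @export
backgroundNetwork <- function(u, v = NULL) {
    if (is.null(v)) {
        v <- if (is.data.frame(u)) as.character(u[[2L]]) else as.character(u[, 2L])
        u <- if (is.data.frame(u)) as.character(u[[1L]]) else as.character(u[, 1L])
    }
    loops <- u == v
    if (any(loops)) {
        message(sum(loops), " self-loop(s) dropped")
        u <- u[!loops]; v <- v[!loops]
    }
    p <- .canonicalPairs(u, v)
    p <- p[!duplicated(.pairKey(p[, 1L], p[, 2L])), , drop = FALSE]
    p <- p[.corder(p[, 1L], p[, 2L]), , drop = FALSE]
    new("BackgroundNetwork", edges = p)
}

#' Read an undirected background interaction network
#'
#' Accepts a whitespace- or tab-delimited two-column edge list, or SIF
#' lines (\code{node relation node}); duplicate edges (in either
#' orientation) are collapsed and self-loops dropped.
#'
#' @param path path to the edge-list file.
#' @return a \linkS4class{BackgroundNetwork}.
#' @export
readNetwork <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("network file is empty: ", path)
    parts <- strsplit(lines, "[\t ]+")
    n <- lengths(parts)
    if (any(n < 2L))
        stop("malformed network line: ", lines[which(n < 2L)[1L]])
    u <- vapply(parts, `[`, character(1), 1L)
    ## SIF has the relation type in column 2 and the partner in column 3
    v <- ifelse(n >= 3L, vapply(parts, `[`, character(1), 3L),
                vapply(parts, `[`, character(1), 2L))
    backgroundNetwork(u, v)
}

#' Read a gene list (one symbol per line)
#' @param path file path.
#' @return character vector, blanks and comment lines removed.
#' @export
readGeneList <- function(path) {
    x <- trimws(readLines(path, warn = FALSE))
    unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Write / read a WDIN as a weighted edge-list TSV
#'
#' Columns: gene_u, gene_v, r_normal, r_disease, weight, status. The
#' screening parameters are stored as header comment lines so a
#' round-trip preserves provenance.
#'
#' @param wdin a \linkS4class{WDIN}.
#' @param path output path.
#' @return \code{writeWDIN} returns \code{path} invisibly;
#'   \code{readWDIN} returns a \linkS4class{WDIN}.
#' @export
writeWDIN <- function(wdin, path) {
    p <- wdin@params
    hdr <- c(sprintf("# tissue=%s", wdin@tissue),
             sprintf("# hi=%s lo=%s useAbsolute=%s",
                     format(p$hi), format(p$lo), isTRUE(p$useAbsolute)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    e <- wdin@edges
    out <- data.frame(gene_u = e$u, gene_v = e$v,
                      r_normal = e$rNormal, r_disease = e$rDisease,
                      weight = e$weight, status = e$status)
    utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeWDIN
#' @export
readWDIN <- function(path) {
    lines <- readLines(path, warn = FALSE)
    hdr <- lines[startsWith(lines, "#")]
    tissue <- sub("^# tissue=", "", hdr[startsWith(hdr, "# tissue=")])
    if (!length(tissue)) tissue <- "unspecified"
    params <- list()
    pl <- hdr[startsWith(hdr, "# hi=")]
    if (length(pl)) {
        m <- regmatches(pl, regexec(
            "hi=([0-9.eE+-]+) lo=([0-9.eE+-]+) useAbsolute=(TRUE|FALSE)", pl))[[1L]]
        if (length(m) == 4L)
            params <- list(hi = as.numeric(m[2L]), lo = as.numeric(m[3L]),
                           useAbsolute = as.logical(m[4L]))
    }
    d <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                           sep = "\t", header = TRUE)
    edges <- data.frame(u = as.character(d$gene_u), v = as.character(d$gene_v),
                        rNormal = d$r_normal, rDisease = d$r_disease,
                        weight = d$r_disease - d$r_normal,
                        status = as.character(d$status),
                        stringsAsFactors = FALSE)
    new("WDIN", tissue = tissue, edges = edges, params = params)
}

#' Write a node ranking as TSV (gene, score, rank)
#' @param nr a \linkS4class{NodeRanking}.
#' @param path output path.
#' @export
writeNodeRanking <- function(nr, path) {
    ord <- order(nr@ranks)
    out <- data.frame(gene = names(nr@ranks)[ord],
                      score = unname(nr@scores[ord]),
                      rank = unname(nr@ranks[ord]))
    utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write an edge ranking as TSV (gene_u, gene_v, edge_index, order)
#' @param er an \linkS4class{EdgeRanking}.
#' @param path output path.
#' @export
writeEdgeRanking <- function(er, path) {
    t <- er@table
    out <- data.frame(gene_u = t$u, gene_v = t$v, edge_index = t$index,
                      order = seq_len(nrow(t)))
    utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a (classified) merged core module as TSV
#'
#' Columns: gene_u, gene_v, weight_<tissue> per source tissue (empty
#' where the tissue's core module lacks the edge), category.
#'
#' @param mcm a \linkS4class{MergedCoreModule}.
#' @param path output path.
#' @export
writeMCM <- function(mcm, path) {
    e <- mcm@edges
    out <- data.frame(gene_u = e$u, gene_v = e$v, check.names = FALSE)
    for (tis in mcm@tissues)
        out[[paste0("weight_", tis)]] <- e[[tis]]
    out$category <- e$category
    utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    invisible(path)
}

#' Write the rank-normalized (or raw) expression assay as TSV
#' @param x a \linkS4class{TissueExpression}.
#' @param path output path.
#' @export
writeExpressionTSV <- function(x, path) {
    m <- assay(x)
    out <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
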