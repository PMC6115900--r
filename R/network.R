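#' Load an undirected molecular interaction network
#'
#' Reads a protein-protein interaction (or any molecular) network from a
#' 2-3 column edge list. Tab-separated files are read as
#' `node_a<TAB>node_b[<TAB>weight]`; files ending in `.sif` use the SIF
#' convention `node_a<TAB>relation<TAB>node_b`. Edges are undirected:
#' duplicate pairs (in either orientation) are collapsed to a single edge and
#' self-loops are dropped, each with a reported count. Node order is
#' lexicographic so that every matrix built from the network is reproducible.
#'
#' @param path Path to the edge-list file.
#' @param header Logical; does the file carry a header line? Default `FALSE`
#'   (the usual convention for raw edge lists).
#' @return A `phyto_network` object: list with `nodes` (sorted character
#'   vector), `edges` (data.frame `from`, `to`, `weight` with `from < to`),
#'   and counts of dropped self-loops / duplicates.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tC", "C\tA"), f)
#' net <- load_network(f)
#' net$nodes
#' @export
load_network <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network file: ", path, call. = FALSE)
  is_sif <- grepl("\\.sif$", path, ignore.case = TRUE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < if (is_sif) 3L else 2L)
  if (length(bad)) {
    stop("malformed network line ", bad[1L] + as.integer(header), " in ",
         path, ": ", lines[bad[1L]], call. = FALSE)
  }
  a <- vapply(parts, `[[`, "", 1L)
  if (is_sif) {
    b <- vapply(parts, `[[`, "", 3L)
    w <- rep(1, length(a))
  } else {
    b <- vapply(parts, `[[`, "", 2L)
    w <- vapply(parts, function(p) {
      if (length(p) >= 3L) suppressWarnings(as.numeric(p[[3L]])) else 1
    }, 1.0)
    w[is.na(w)] <- 1
  }
  if (any(w <= 0)) stop("non-positive edge weight in ", path, call. = FALSE)
  molecular_network(data.frame(from = a, to = b, weight = w,
                               stringsAsFactors = FALSE))
}

#' Build a molecular network from an in-memory edge table
#'
#' @param edges A data.frame with columns `from`, `to` and optionally
#'   `weight` (default 1).
#' @return A `phyto_network` object (see [load_network()]).
#' @export
molecular_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  if (is.null(edges$weight)) edges$weight <- 1
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)

  loops <- edges$from == edges$to
  n_loops <- sum(loops)
  if (n_loops) {
    message("dropped ", n_loops, " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("network has no edges after cleaning",
                              call. = FALSE)
  # canonical orientation so A-B and B-A collapse
  lo <- pmin(edges$from, edges$to)
  hi <- pmax(edges$from, edges$to)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup) message("collapsed ", n_dup, " duplicate edge(s)")
  edges <- data.frame(from = lo[!dup], to = hi[!dup],
                      weight = edges$weight[!dup], stringsAsFactors = FALSE)
  o <- order(edges$from, edges$to)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges,
                 n_self_loops_dropped = n_loops,
                 n_duplicates_dropped = n_dup),
            class = "phyto_network")
}

#' @export
print.phyto_network <- function(x, ...) {
  cat("Molecular network:", length(x$nodes), "nodes,",
      nrow(x$edges), "undirected edges\n")
  if (x$n_self_loops_dropped)
    cat("  (", x$n_self_loops_dropped, "self-loops dropped at load )\n")
  invisible(x)
}

#' Row-stochastic transition matrix of a molecular network
#'
#' Returns the normalized adjacency matrix W used by the random walk with
#' restart: `W[i, j]` is the probability of stepping from node i to its
#' neighbour j, i.e. the edge weight divided by the weighted degree of i.
#' Every row of a node with at least one neighbour sums to 1. Isolated nodes
#' (possible when a node list is supplied explicitly) receive a self
#' transition of 1 so that probability mass is conserved.
#'
#' @param network A `phyto_network`.
#' @return A sparse `dgCMatrix` with `dimnames` equal to the node order.
#' @export
build_transition <- function(network) {
  stopifnot(inherits(network, "phyto_network"))
  nodes <- network$nodes
  n <- length(nodes)
  i <- match(network$edges$from, nodes)
  j <- match(network$edges$to, nodes)
  w <- network$edges$weight
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n), dimnames = list(nodes, nodes))
  deg <- Matrix::rowSums(A)
  isolated <- which(deg == 0)
  if (length(isolated)) {
    A <- A + Matrix::sparseMatrix(i = isolated, j = isolated,
                                  x = rep(1, length(isolated)),
                                  dims = c(n, n))
    deg[isolated] <- 1
  }
  W <- Matrix::Diagonal(x = 1 / deg) %*% A
  dimnames(W) <- list(nodes, nodes)
  methods::as(W, "CsparseMatrix")
}
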