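#' Virtual root concept ID
#'
#' UMLS-style concept hierarchies have many roots; all parentless concepts
#' are attached to this virtual root so that depth and lowest-common-subsumer
#' queries are always defined. Similarity between concepts whose only common
#' ancestor is the virtual root is 0.
#' @export
PHYTO_ROOT <- "__ROOT__"

#' Load concept relation triples from a TSV file
#'
#' Expects columns `cui1`, `cui2`, `rel` with relation codes `RB` (cui2 is
#' broader than cui1), `RN` (cui2 is narrower) or `RO` (other-related).
#'
#' @param path Path to the triples TSV.
#' @param allowlist Optional character vector of concept IDs; triples with
#'   either endpoint outside the allowlist are discarded.
#' @return Data.frame of triples.
#' @export
load_ontology_triples <- function(path, allowlist = NULL) {
  df <- read_tsv(path)
  need <- c("cui1", "cui2", "rel")
  if (!all(need %in% names(df)))
    stop("triples table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(allowlist))
    df <- df[df$cui1 %in% allowlist & df$cui2 %in% allowlist, , drop = FALSE]
  df
}

#' Build a rooted phenotype concept hierarchy
#'
#' Relations follow the UMLS MRREL convention: `RB(a, b)` states that `b` is
#' broader than `a`, so `b` is stored as a parent of `a`; `RN(a, b)` is the
#' inverse; `RO` edges are non-hierarchical and are kept separately — they
#' take no part in depth, subsumer or path computations. Users holding dumps
#' of the opposite polarity can set `orientation = "inverted"`.
#'
#' Hierarchical edges are inserted in lexicographic (child, parent) order and
#' an edge that would close a cycle is dropped with a warning, which makes
#' cycle breaking deterministic. Every concept without a parent is attached
#' to the virtual root [PHYTO_ROOT], whose depth is 0.
#'
#' @param triples Data.frame with columns `cui1`, `cui2`, `rel` (see
#'   [load_ontology_triples()]).
#' @param orientation `"umls"` (default) or `"inverted"` to flip the RB/RN
#'   polarity.
#' @return A `phyto_ontology`: list with `concepts`, `parents` (named list),
#'   `children` (named list), `depth` (named integer, shortest ancestor chain
#'   from the root), `ro_edges`.
#' @export
build_ontology <- function(triples, orientation = c("umls", "inverted")) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(triples),
            all(c("cui1", "cui2", "rel") %in% names(triples)))
  if (nrow(triples) == 0L) stop("no triples supplied", call. = FALSE)
  bad <- setdiff(unique(triples$rel), c("RB", "RN", "RO"))
  if (length(bad))
    stop("unknown relation code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  concepts <- sort(unique(c(triples$cui1, triples$cui2)))
  hier <- triples[triples$rel != "RO", , drop = FALSE]
  # orient to (child, parent)
  child <- ifelse(hier$rel == "RB", hier$cui1, hier$cui2)
  parent <- ifelse(hier$rel == "RB", hier$cui2, hier$cui1)
  if (orientation == "inverted") { tmp <- child; child <- parent; parent <- tmp }
  keep <- !duplicated(paste(child, parent, sep = "\r")) & child != parent
  child <- child[keep]; parent <- parent[keep]
  o <- order(child, parent)
  child <- child[o]; parent <- parent[o]

  parents <- stats::setNames(vector("list", length(concepts)), concepts)
  dropped <- character()
  for (k in seq_along(child)) {
    # adding child -> parent closes a cycle iff child is an ancestor of parent
    if (is_ancestor(parents, child[k], parent[k])) {
      dropped <- c(dropped, paste0(child[k], "->", parent[k]))
    } else {
      parents[[child[k]]] <- c(parents[[child[k]]], parent[k])
    }
  }
  if (length(dropped))
    warning("dropped ", length(dropped), " cycle-closing edge(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)

  roots <- concepts[vapply(parents[concepts], length, 1L) == 0L]
  for (r in roots) parents[[r]] <- PHYTO_ROOT

  children <- list()
  for (cpt in concepts) {
    for (p in parents[[cpt]]) children[[p]] <- c(children[[p]], cpt)
  }

  # breadth-first depths from the virtual root (min over parents)
  depth <- stats::setNames(rep(NA_integer_, length(concepts)), concepts)
  frontier <- children[[PHYTO_ROOT]] %||% character()
  d <- 1L
  while (length(frontier)) {
    new <- frontier[is.na(depth[frontier])]
    depth[new] <- d
    frontier <- unique(unlist(children[new], use.names = FALSE))
    frontier <- frontier[!is.na(frontier) & is.na(depth[frontier])]
    d <- d + 1L
  }

  ro <- triples[triples$rel == "RO", c("cui1", "cui2"), drop = FALSE]
  structure(list(concepts = concepts, parents = parents, children = children,
                 depth = depth, ro_edges = ro,
                 n_cycle_edges_dropped = length(dropped)),
            class = "phyto_ontology")
}

# TRUE if `anc` is a (proper or improper) hierarchical ancestor of `node`.
is_ancestor <- function(parents, anc, node) {
  if (anc == node) return(TRUE)
  seen <- character()
  stack <- parents[[node]]
  while (length(stack)) {
    p <- stack[[1L]]; stack <- stack[-1L]
    if (p == anc) return(TRUE)
    if (p %in% seen || p == PHYTO_ROOT) next
    seen <- c(seen, p)
    stack <- c(stack, parents[[p]])
  }
  FALSE
}

#' @export
print.phyto_ontology <- function(x, ...) {
  cat("Phenotype ontology:", length(x$concepts), "concepts, max depth",
      max(x$depth, na.rm = TRUE), "\n")
  invisible(x)
}

check_concept <- function(ontology, cpt) {
  if (!cpt %in% ontology$concepts && cpt != PHYTO_ROOT)
    stop("unknown concept: ", cpt, call. = FALSE)
}

#' Depth of a concept
#'
#' Length of the shortest ancestor chain from the virtual root; the root
#' itself has depth 0. With multiple parents the minimum applies.
#'
#' @param ontology A `phyto_ontology`.
#' @param concept Concept ID.
#' @return Integer depth.
#' @export
concept_depth <- function(ontology, concept) {
  stopifnot(inherits(ontology, "phyto_ontology"))
  if (concept == PHYTO_ROOT) return(0L)
  check_concept(ontology, concept)
  ontology$depth[[concept]]
}

# All hierarchical ancestors of a concept, itself included.
ancestor_set <- function(ontology, concept) {
  seen <- concept
  stack <- ontology$parents[[concept]]
  while (length(stack)) {
    p <- stack[[1L]]; stack <- stack[-1L]
    if (p %in% seen) next
    seen <- c(seen, p)
    if (p != PHYTO_ROOT) stack <- c(stack, ontology$parents[[p]])
  }
  seen
}

#' Lowest common subsumer of two concepts
#'
#' The common hierarchical ancestor of maximal depth; ties are broken
#' lexicographically. The virtual root is returned when the concepts share no
#' other ancestor.
#'
#' @param ontology A `phyto_ontology`.
#' @param c1,c2 Concept IDs.
#' @return Concept ID of the subsumer (possibly [PHYTO_ROOT]).
#' @export
lcs <- function(ontology, c1, c2) {
  stopifnot(inherits(ontology, "phyto_ontology"))
  check_concept(ontology, c1); check_concept(ontology, c2)
  common <- intersect(ancestor_set(ontology, c1), ancestor_set(ontology, c2))
  common <- setdiff(common, PHYTO_ROOT)
  if (!length(common)) return(PHYTO_ROOT)
  d <- ontology$depth[common]
  cands <- sort(common[d == max(d)])
  cands[[1L]]
}

# Shortest path length between two concepts over undirected hierarchical
# parent-child edges (breadth-first search).
hier_path_length <- function(ontology, from, to) {
  if (from == to) return(0L)
  neighbours <- function(cpt) {
    unique(c(if (cpt == PHYTO_ROOT) character() else ontology$parents[[cpt]],
             ontology$children[[cpt]] %||% character()))
  }
  dist <- stats::setNames(0L, from)
  frontier <- from
  while (length(frontier)) {
    nxt <- character()
    for (cpt in frontier) {
      for (nb in neighbours(cpt)) {
        if (!nb %in% names(dist)) {
          dist[[nb]] <- dist[[cpt]] + 1L
          if (nb == to) return(dist[[nb]])
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  NA_integer_  # unreachable: distinct trees (possible only via the root)
}

#' Wu-Palmer semantic similarity between two concepts
#'
#' `sim(c1, c2) = 2 d / (path(c1, lcs) + path(c2, lcs) + 2 d)` where `d` is
#' the depth of the lowest common subsumer and `path` is the shortest
#' hierarchical path length to it. Identical non-root concepts score 1;
#' concepts whose only common ancestor is the virtual root score 0. RO
#' ("other-related") edges never contribute to paths or depths.
#'
#' @param ontology A `phyto_ontology`.
#' @param c1,c2 Concept IDs.
#' @return Similarity in `[0, 1]`.
#' @export
wup_similarity <- function(ontology, c1, c2) {
  stopifnot(inherits(ontology, "phyto_ontology"))
  check_concept(ontology, c1); check_concept(ontology, c2)
  sub <- lcs(ontology, c1, c2)
  if (sub == PHYTO_ROOT) return(0)
  d <- concept_depth(ontology, sub)
  p1 <- hier_path_length(ontology, c1, sub)
  p2 <- hier_path_length(ontology, c2, sub)
  2 * d / (p1 + p2 + 2 * d)
}

#' Wu-Palmer similarity for a table of concept pairs
#'
#' @param ontology A `phyto_ontology`.
#' @param pairs Data.frame with two character columns of concept IDs.
#' @return The input with an appended `similarity` column.
#' @export
wup_similarity_batch <- function(ontology, pairs) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2L)
  pairs$similarity <- vapply(seq_len(nrow(pairs)), function(k) {
    wup_similarity(ontology, pairs[[1L]][k], pairs[[2L]][k])
  }, 1.0)
  pairs
}
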