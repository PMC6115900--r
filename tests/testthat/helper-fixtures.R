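# Shared builders and independent oracles used across the suite.

# Write an edge list to a temp file and load it.
make_network <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  suppressMessages(load_network(f))
}

triangle_network <- function() make_network(c("A\tB", "B\tC", "C\tA"))

# Random connected undirected graph on n nodes (spanning tree + extras).
random_graph <- function(n, extra = n) {
  nodes <- sprintf("N%02d", seq_len(n))
  from <- nodes[2:n]
  to <- nodes[vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L)]
  for (k in seq_len(extra)) {
    ab <- sample(nodes, 2L)
    from <- c(from, ab[1L]); to <- c(to, ab[2L])
  }
  suppressMessages(molecular_network(data.frame(from = from, to = to)))
}

# Independent RWR oracle: direct solve of the fixed point
# p = r (I - (1 - r) W^T)^{-1} p0 with dense linear algebra.
rwr_direct_solve <- function(W, p0, restart) {
  n <- nrow(W)
  A <- diag(n) - (1 - restart) * t(as.matrix(W))
  as.numeric(restart * solve(A, p0))
}

# Build a literature corpus in memory (list of character-vector lists).
corpus_from <- function(...) {
  sent_lists <- list(...)
  abstracts <- lapply(seq_along(sent_lists), function(i)
    list(id = sprintf("A%03d", i), sentences = sent_lists[[i]]))
  structure(abstracts, class = "literature_corpus")
}

# Ontology used by several tests: root -> X1 -> L, with A two levels below L
# and B one level below L (the worked similarity example shape).
example_ontology <- function() {
  build_ontology(data.frame(
    cui1 = c("L", "A1", "A", "B"),
    cui2 = c("X1", "L", "A1", "L"),
    rel = "RB"))
}

# Random rooted DAG ontology on <= n concepts; some nodes get two parents.
random_ontology <- function(n) {
  ids <- sprintf("C%02d", seq_len(n))
  rows <- list()
  for (i in 2:n) {
    parent <- ids[sample.int(i - 1L, 1L)]
    rows[[length(rows) + 1L]] <- data.frame(cui1 = ids[i], cui2 = parent,
                                            rel = "RB")
    if (i > 3 && stats::runif(1) < 0.3) {  # occasional second parent
      p2 <- ids[sample.int(i - 1L, 1L)]
      if (p2 != parent)
        rows[[length(rows) + 1L]] <- data.frame(cui1 = ids[i], cui2 = p2,
                                                rel = "RB")
    }
  }
  build_ontology(do.call(rbind, rows))
}

# Brute-force ancestor set (recursive, independent of the package's walk).
brute_ancestors <- function(ont, cpt) {
  out <- cpt
  for (p in ont$parents[[cpt]]) {
    if (p == PHYTO_ROOT) next
    out <- union(out, brute_ancestors(ont, p))
  }
  out
}

# Brute-force LCS: intersect full ancestor sets, take max depth, then
# lexicographic order.
brute_lcs <- function(ont, c1, c2) {
  common <- intersect(brute_ancestors(ont, c1), brute_ancestors(ont, c2))
  if (!length(common)) return(PHYTO_ROOT)
  d <- ont$depth[common]
  sort(common[d == max(d)])[1L]
}

# A small fixture spec that keeps test runtimes low while preserving the
# default generator structure.
small_spec <- function(seed = 11L) {
  fixture_spec(rng_seed = seed, n_nodes = 60L, n_phytochemicals = 6L,
               n_phenotypes = 12L, genes_per_phenotype = 5L,
               n_plants = 6L, n_abstracts = 120L, ontology_depth = 3L,
               branching = 3L)
}

fixture_dir <- function(spec) {
  d <- tempfile("fx")
  suppressMessages(generate_fixtures(spec, d))
  d
}

fixture_config <- function(d, ...) {
  pipeline_config(
    network = file.path(d, "network.tsv"),
    targets = file.path(d, "targets.tsv"),
    gene_phenotype = file.path(d, "gene_phenotype.tsv"),
    ontology = file.path(d, "ontology.tsv"),
    plant_compounds = file.path(d, "plant_compounds.tsv"),
    plant_uses = file.path(d, "plant_uses.tsv"),
    chemicals = file.path(d, "chemicals.tsv"),
    corpus = file.path(d, "corpus.jsonl"), ...)
}
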