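#' Specification for the synthetic fixture generator
#'
#' Describes a complete synthetic study: a degree-heterogeneous molecular
#' network, phytochemical target profiles with planted true phenotype
#' associations, a gene-phenotype map, a rooted phenotype concept tree,
#' plants with ethnopharmacological uses echoing the planted associations,
#' a chemical descriptor table with mixed rule-of-five outcomes, and an
#' annotated abstract corpus in which true pairs co-occur
#' `enrichment_strength` times more often than background pairs. The same
#' spec and seed always reproduce byte-identical files.
#'
#' Signal is planted by construction: direct targets of each compound are
#' drawn from the gene sets of its true phenotypes and indirect targets from
#' their one-hop network neighbourhoods, so propagation concentrates mass on
#' the genes of the true phenotypes; plant-use concepts include the true
#' phenotypes so ethnopharmacological matching can confirm them.
#'
#' @param rng_seed Master seed.
#' @param n_nodes Network size; default 150.
#' @param edge_density Fraction of possible node pairs joined by an edge;
#'   default 0.04 (mean degree about 6).
#' @param n_phytochemicals Number of compounds; default 20.
#' @param targets_per_compound Integer pair `c(direct, indirect)`; default
#'   `c(6, 6)`.
#' @param n_phenotypes Number of phenotype concepts; default 30.
#' @param genes_per_phenotype Genes associated with each phenotype; default 8.
#' @param ontology_depth Depth of the concept tree below the root; default 4.
#' @param branching Children per internal concept; default 3.
#' @param n_plants Number of plants; default 15.
#' @param uses_per_plant Traditional-use concepts per plant; default 4.
#' @param n_abstracts Corpus size; default 500.
#' @param enrichment_strength Multiplier on the background co-occurrence
#'   rate for true pairs; default 10 (1 = no planted signal).
#' @param true_pairs_per_compound Planted true phenotypes per compound;
#'   default 2.
#' @param background_cooccurrence Per-abstract probability that any given
#'   pair is planted in one sentence; default 0.002.
#' @return A `fixture_spec` object (validated list).
#' @export
fixture_spec <- function(rng_seed = 1L, n_nodes = 150L, edge_density = 0.04,
                         n_phytochemicals = 20L,
                         targets_per_compound = c(6L, 6L),
                         n_phenotypes = 30L, genes_per_phenotype = 8L,
                         ontology_depth = 4L, branching = 3L,
                         n_plants = 15L, uses_per_plant = 4L,
                         n_abstracts = 500L, enrichment_strength = 10,
                         true_pairs_per_compound = 2L,
                         background_cooccurrence = 0.002) {
  spec <- list(rng_seed = as.integer(rng_seed), n_nodes = as.integer(n_nodes),
               edge_density = edge_density,
               n_phytochemicals = as.integer(n_phytochemicals),
               targets_per_compound = as.integer(targets_per_compound),
               n_phenotypes = as.integer(n_phenotypes),
               genes_per_phenotype = as.integer(genes_per_phenotype),
               ontology_depth = as.integer(ontology_depth),
               branching = as.integer(branching),
               n_plants = as.integer(n_plants),
               uses_per_plant = as.integer(uses_per_plant),
               n_abstracts = as.integer(n_abstracts),
               enrichment_strength = enrichment_strength,
               true_pairs_per_compound = as.integer(true_pairs_per_compound),
               background_cooccurrence = background_cooccurrence)
  counts <- c(spec$n_nodes, spec$n_phytochemicals, spec$targets_per_compound,
              spec$n_phenotypes, spec$genes_per_phenotype,
              spec$ontology_depth, spec$branching, spec$n_plants,
              spec$uses_per_plant, spec$n_abstracts,
              spec$true_pairs_per_compound)
  if (any(counts < 1L)) stop("all fixture counts must be >= 1", call. = FALSE)
  if (edge_density <= 0 || edge_density > 1)
    stop("edge_density must lie in (0, 1]", call. = FALSE)
  if (background_cooccurrence <= 0 || background_cooccurrence > 1)
    stop("background_cooccurrence must lie in (0, 1]", call. = FALSE)
  if (enrichment_strength < 1 ||
      background_cooccurrence * enrichment_strength > 1)
    stop("enrichment_strength out of range", call. = FALSE)
  if (length(spec$targets_per_compound) != 2L)
    stop("targets_per_compound must be c(direct, indirect)", call. = FALSE)
  if (spec$ontology_depth < 2L)
    stop("ontology_depth must be >= 2", call. = FALSE)
  if (spec$branching ^ spec$ontology_depth < spec$n_phenotypes)
    stop("concept tree too small for n_phenotypes: increase branching ",
         "or ontology_depth", call. = FALSE)
  structure(spec, class = "fixture_spec")
}

# Build every fixture object in memory, deterministically from the seed.
fixture_build <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$rng_seed, {
    nodes <- sprintf("G%03d", seq_len(spec$n_nodes))
    edges <- fixture_edges(nodes, spec$edge_density)
    adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))

    phen <- sprintf("P%02d", seq_len(spec$n_phenotypes))
    gp <- do.call(rbind, lapply(phen, function(p)
      data.frame(phenotype_id = p,
                 gene_id = sample(nodes, spec$genes_per_phenotype))))
    genes_of <- split(gp$gene_id, gp$phenotype_id)

    compounds <- sprintf("C%02d", seq_len(spec$n_phytochemicals))
    nd <- spec$targets_per_compound[1L]
    ni <- spec$targets_per_compound[2L]
    k <- spec$true_pairs_per_compound
    truth_rows <- list(); target_rows <- list()
    for (i in seq_along(compounds)) {
      # round-robin so every phenotype collects roughly equal planted pairs
      ph_idx <- ((i - 1L) * k + seq_len(k) - 1L) %% spec$n_phenotypes + 1L
      planted <- phen[unique(ph_idx)]
      # direct slots allocated round-robin over the planted phenotypes so
      # each gets an even share of seed genes sitting inside its gene set
      alloc <- planted[(seq_len(nd) - 1L) %% length(planted) + 1L]
      direct <- character()
      for (p in planted) {
        take <- min(sum(alloc == p), spec$genes_per_phenotype)
        direct <- c(direct, sample(genes_of[[p]], take))
      }
      direct <- unique(direct)
      hop <- setdiff(unique(unlist(adj[direct], use.names = FALSE)), direct)
      indirect <- if (length(hop)) sample(hop, min(ni, length(hop))) else
        character()
      if (length(indirect) < ni) {
        rest <- setdiff(nodes, c(direct, indirect))
        indirect <- c(indirect, sample(rest, ni - length(indirect)))
      }
      truth_rows[[i]] <- data.frame(phytochemical_id = compounds[i],
                                    phenotype_id = planted)
      target_rows[[i]] <- data.frame(
        phytochemical_id = compounds[i],
        target_id = c(direct, indirect),
        association = c(rep("direct", length(direct)),
                        rep("indirect", length(indirect))))
    }
    truth <- do.call(rbind, truth_rows)
    targets <- do.call(rbind, target_rows)

    onto <- fixture_ontology(phen, spec$ontology_depth, spec$branching)

    plant_ids <- sprintf("PL%02d", seq_len(spec$n_plants))
    pc_rows <- data.frame(
      plant_id = plant_ids[(seq_along(compounds) - 1L) %% spec$n_plants + 1L],
      phytochemical_id = compounds)
    # a second, shuffled membership so most compounds sit in two plants
    pc_rows <- rbind(pc_rows, data.frame(
      plant_id = plant_ids[sample.int(spec$n_plants, length(compounds),
                                      replace = TRUE)],
      phytochemical_id = compounds))
    pc_rows <- pc_rows[!duplicated(pc_rows), ]
    true_of <- split(truth$phenotype_id, truth$phytochemical_id)
    use_rows <- lapply(plant_ids, function(pl) {
      members <- pc_rows$phytochemical_id[pc_rows$plant_id == pl]
      echoed <- unique(unlist(true_of[members], use.names = FALSE))
      echoed <- echoed[stats::runif(length(echoed)) < 0.9]
      filler <- sample(onto$leaf_concepts,
                       max(0L, spec$uses_per_plant - length(echoed)))
      uses <- unique(c(echoed, filler))
      if (!length(uses)) uses <- sample(onto$leaf_concepts, 1L)
      data.frame(plant_id = pl, use_concept_id = uses)
    })
    uses <- do.call(rbind, use_rows)

    chem <- fixture_chemicals(compounds)
    corpus <- fixture_corpus(compounds, phen, truth, spec)
    list(nodes = nodes, edges = edges, gene_phenotype = gp,
         targets = targets, truth = truth, triples = onto$triples,
         plant_compounds = pc_rows, plant_uses = uses, chemicals = chem,
         corpus = corpus)
  })
}

# Spanning tree with preferential attachment, then extra degree-weighted
# edges up to the requested density.
fixture_edges <- function(nodes, density) {
  n <- length(nodes)
  ord <- sample(n)
  deg <- rep(0L, n)
  from <- integer(); to <- integer()
  for (i in 2:n) {
    prev <- ord[seq_len(i - 1L)]
    j <- if (i == 2L) prev else sample(prev, 1L, prob = deg[prev] + 1)
    from <- c(from, ord[i]); to <- c(to, j)
    deg[ord[i]] <- deg[ord[i]] + 1L; deg[j] <- deg[j] + 1L
  }
  m_target <- max(n - 1L, round(density * n * (n - 1L) / 2))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seen <- key(from, to)
  guard <- 0L
  while (length(from) < m_target && guard < 50L * m_target) {
    guard <- guard + 1L
    a <- sample.int(n, 1L, prob = deg + 1)
    b <- sample.int(n, 1L)
    if (a == b || key(a, b) %in% seen) next
    from <- c(from, a); to <- c(to, b); seen <- c(seen, key(a, b))
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
  }
  data.frame(from = nodes[from], to = nodes[to], weight = 1)
}

# Complete `branching`-ary concept tree of the given depth; the first
# n_phenotypes leaves are the phenotype concepts, remaining leaves are
# filler. Most edges are written as RB(child, parent); every fifth as the
# equivalent RN(parent, child); two RO cross-links exercise the
# non-hierarchical path.
fixture_ontology <- function(phen, depth, branching) {
  rows <- list()
  # level 1: `branching` root concepts attached to the virtual root, so
  # phenotype leaves end up exactly `depth` levels down
  level <- sprintf("H01_%03d", seq_len(branching))
  leaf_pool <- character()
  for (d in 2:depth) {
    counter <- 0L
    nxt <- character()
    for (parent in level) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        child <- if (d == depth) {
          if (counter <= length(phen)) phen[counter] else
            sprintf("U%03d", counter)
        } else sprintf("H%02d_%03d", d, counter)
        rows[[length(rows) + 1L]] <-
          if (length(rows) %% 5L == 4L)
            data.frame(cui1 = parent, cui2 = child, rel = "RN")
          else data.frame(cui1 = child, cui2 = parent, rel = "RB")
        nxt <- c(nxt, child)
      }
    }
    if (d == depth) leaf_pool <- nxt
    level <- nxt
  }
  triples <- do.call(rbind, rows)
  triples <- rbind(triples,
                   data.frame(cui1 = leaf_pool[1L],
                              cui2 = leaf_pool[min(4L, length(leaf_pool))],
                              rel = "RO"),
                   data.frame(cui1 = leaf_pool[2L],
                              cui2 = leaf_pool[min(7L, length(leaf_pool))],
                              rel = "RO"))
  list(triples = triples, leaf_concepts = leaf_pool)
}

# Descriptor table with a mix of rule-of-five outcomes and tri-state flags;
# key column doubles as the table-backend key.
fixture_chemicals <- function(compounds) {
  n <- length(compounds)
  mw <- round(stats::runif(n, 150, 700), 1)
  alogp <- round(stats::rnorm(n, 2.5, 1.8), 2)
  hbd <- stats::rpois(n, 3)
  hba <- stats::rpois(n, 6)
  rotb <- stats::rpois(n, 5)
  flag <- function(p_true, p_na = 0.15) {
    u <- stats::runif(n)
    out <- u < (1 - p_na) * p_true
    out[u >= 1 - p_na] <- NA
    out
  }
  data.frame(phytochemical_id = compounds, smiles = NA_character_,
             mw = mw, alogp = alogp, hbd = hbd, hba = hba, rotb = rotb,
             hia = flag(0.75), caco2 = flag(0.65), bbb = flag(0.55))
}

# Abstract corpus: background mentions scattered over sentences plus planted
# same-sentence pairs. Every compound-phenotype pair is planted at rate
# background_cooccurrence; true pairs at that rate times
# enrichment_strength, so strength 1 is an exact null.
fixture_corpus <- function(compounds, phen, truth, spec) {
  n_abs <- spec$n_abstracts
  truth_key <- paste(truth$phytochemical_id, truth$phenotype_id)
  pairs <- expand.grid(chem = compounds, pheno = phen,
                       stringsAsFactors = FALSE)
  rate <- ifelse(paste(pairs$chem, pairs$pheno) %in% truth_key,
                 spec$background_cooccurrence * spec$enrichment_strength,
                 spec$background_cooccurrence)
  abstracts <- vector("list", n_abs)
  for (a in seq_len(n_abs)) {
    sentences <- replicate(3L, character(), simplify = FALSE)
    for (term in c(sample(compounds, 2L), sample(phen, 2L))) {
      s <- sample.int(3L, 1L)
      sentences[[s]] <- c(sentences[[s]], term)
    }
    hit <- which(stats::runif(nrow(pairs)) < rate)
    for (h in hit)
      sentences[[length(sentences) + 1L]] <- c(pairs$chem[h], pairs$pheno[h])
    abstracts[[a]] <- list(id = sprintf("A%05d", a),
                           sentences = sentences[lengths(sentences) > 0L])
  }
  structure(abstracts, class = "literature_corpus")
}

#' Generate every pipeline input as files
#'
#' Writes `network.tsv`, `targets.tsv`, `gene_phenotype.tsv`,
#' `ontology.tsv`, `plant_compounds.tsv`, `plant_uses.tsv`,
#' `chemicals.tsv`, `corpus.jsonl` and `truth.tsv` into `out_dir`.
#' Byte-identical for identical spec and seed.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the files written (invisibly).
#' @export
generate_fixtures <- function(spec, out_dir) {
  fx <- fixture_build(spec)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("cannot write to ", out_dir, call. = FALSE)
  paths <- c(
    network = file.path(out_dir, "network.tsv"),
    targets = file.path(out_dir, "targets.tsv"),
    gene_phenotype = file.path(out_dir, "gene_phenotype.tsv"),
    ontology = file.path(out_dir, "ontology.tsv"),
    plant_compounds = file.path(out_dir, "plant_compounds.tsv"),
    plant_uses = file.path(out_dir, "plant_uses.tsv"),
    chemicals = file.path(out_dir, "chemicals.tsv"),
    corpus = file.path(out_dir, "corpus.jsonl"),
    truth = file.path(out_dir, "truth.tsv"))
  net <- fx$edges
  names(net) <- c("node_a", "node_b", "weight")
  write_tsv(net, paths["network"])
  write_tsv(fx$targets, paths["targets"])
  write_tsv(fx$gene_phenotype, paths["gene_phenotype"])
  write_tsv(fx$triples, paths["ontology"])
  write_tsv(fx$plant_compounds, paths["plant_compounds"])
  write_tsv(fx$plant_uses, paths["plant_uses"])
  write_tsv(fx$chemicals, paths["chemicals"])
  write_corpus(fx$corpus, paths["corpus"])
  write_tsv(fx$truth, paths["truth"])
  invisible(paths)
}

#' Ground-truth planted associations of a fixture spec
#'
#' Recomputes (deterministically) the compound-phenotype pairs that
#' [generate_fixtures()] planted, for use as the positive set in
#' parameter-recovery evaluations.
#'
#' @param spec A [fixture_spec()].
#' @return Data.frame `phytochemical_id`, `phenotype_id`.
#' @export
planted_truth <- function(spec) {
  fx <- fixture_build(spec)
  rownames(fx$truth) <- NULL
  fx$truth
}
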