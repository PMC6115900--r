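#' Pipeline configuration
#'
#' Bundles the input paths and every numeric parameter of the three-stage
#' pipeline. Defaults are the reference settings: restart 0.7, convergence
#' 1e-8, seed weights 1.0 / 0.3, 1000 random profiles, alpha 0.01,
#' similarity threshold 0.8, skews 1:1 / 1:10 / all with 10 repeats.
#'
#' @param network,targets,gene_phenotype,ontology,plant_compounds,plant_uses,chemicals
#'   Input file paths (see the loaders of each module for the formats).
#' @param corpus Optional JSONL corpus path for literature validation.
#' @param restart,tol Propagation parameters.
#' @param direct_weight,indirect_weight Seed weights.
#' @param n_random,alpha Permutation-null parameters.
#' @param wup_threshold Evidence similarity threshold.
#' @param skews,repeats Evaluation settings.
#' @param seed Master seed; per-compound streams are derived from it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(network, targets, gene_phenotype, ontology,
                            plant_compounds, plant_uses, chemicals,
                            corpus = NULL,
                            restart = 0.7, tol = 1e-8,
                            direct_weight = 1.0, indirect_weight = 0.3,
                            n_random = 1000L, alpha = 0.01,
                            wup_threshold = 0.8,
                            skews = c("1:1", "1:10", "all"),
                            repeats = 10L, seed = 1L) {
  cfg <- list(paths = list(network = network, targets = targets,
                           gene_phenotype = gene_phenotype,
                           ontology = ontology,
                           plant_compounds = plant_compounds,
                           plant_uses = plant_uses, chemicals = chemicals,
                           corpus = corpus),
              restart = restart, tol = tol,
              direct_weight = direct_weight,
              indirect_weight = indirect_weight,
              n_random = as.integer(n_random), alpha = alpha,
              wup_threshold = wup_threshold, skews = skews,
              repeats = as.integer(repeats), seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; paths may be given
#' relative to the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  do.call(pipeline_config, c(
    lapply(y[intersect(names(y),
                       c("network", "targets", "gene_phenotype", "ontology",
                         "plant_compounds", "plant_uses", "chemicals",
                         "corpus"))], fix),
    y[intersect(names(y),
                c("restart", "tol", "direct_weight", "indirect_weight",
                  "n_random", "alpha", "wup_threshold", "skews", "repeats",
                  "seed"))]))
}

#' Run the integrated prediction pipeline
#'
#' Three stages per phytochemical: (1) molecular-network propagation of the
#' target profile with permutation-null selection of significant phenotypes
#' (the binary PVP); (2) chemical availability annotation (rule of five plus
#' HIA / Caco-2 / BBB flags, surrogate-filled where unknown) and the
#' co-satisfaction table; (3) ethnopharmacological evidence matching and
#' ranking against the uses of the plants containing the compound. When
#' `out_dir` is given, per-stage TSV outputs, a resolved-config snapshot and
#' an input-hash manifest are written beside each other.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional output directory.
#' @return A `phyto_pipeline` bundle: `pvps`, `evidence`, `effects` (ranked
#'   supported phenotypes per compound), `chemicals` (annotated records),
#'   `cosatisfaction`, `summary`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  network <- stage("load_network",
                   load_network(config$paths$network, header = TRUE))
  W <- build_transition(network)
  gpmap <- stage("gene_phenotype",
                 load_gene_phenotype_map(config$paths$gene_phenotype, network))
  profiles <- stage("targets", load_target_profiles(config$paths$targets))
  ontology <- stage("ontology",
                    build_ontology(load_ontology_triples(config$paths$ontology)))
  plants <- stage("plants",
                  load_plant_records(config$paths$plant_compounds,
                                     config$paths$plant_uses, ontology))

  pvps <- stage("netprop", lapply(profiles, function(pr) {
    compute_pvp(pr, W, gpmap, n_random = config$n_random,
                rng_seed = derive_seed(config$seed, pr$phytochemical_id),
                alpha = config$alpha, restart = config$restart,
                tol = config$tol, direct_weight = config$direct_weight,
                indirect_weight = config$indirect_weight)
  }))

  chem <- stage("chemprops", {
    records <- read_chemical_table(config$paths$chemicals)
    annotate_availability(records)
  })
  cosat <- cosatisfaction_table(chem)

  evidence <- stage("evidence", lapply(pvps, function(pvp)
    match_evidence(pvp, plants, ontology, threshold = config$wup_threshold)))
  effects <- lapply(names(pvps), function(id)
    filter_by_evidence(pvps[[id]], evidence[[id]]))
  names(effects) <- names(pvps)

  summary <- summarize_pipeline(pvps, effects)
  bundle <- structure(list(pvps = pvps, evidence = evidence,
                           effects = effects, chemicals = chem,
                           cosatisfaction = cosat, summary = summary,
                           config = config),
                      class = "phyto_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  bundle
}

#' Summary statistics of a pipeline run
#'
#' Mean number of predicted effects per compound with a 95 percent Student-t
#' confidence half-width, the mean number of evidence-supported effects, and
#' the overall supported fraction.
#'
#' @param pvps Named list of `phyto_pvp` objects.
#' @param effects Named list of [filter_by_evidence()] tables.
#' @return List of summary numbers.
#' @export
summarize_pipeline <- function(pvps, effects) {
  n_pred <- vapply(pvps, function(p) sum(p$binary), 1L)
  n_supp <- vapply(effects, nrow, 1L)
  ci_half <- function(x) {
    if (length(x) < 2L || stats::sd(x) == 0) return(0)
    stats::qt(0.975, length(x) - 1L) * stats::sd(x) / sqrt(length(x))
  }
  list(n_compounds = length(pvps),
       mean_predicted = mean(n_pred), ci95_predicted = ci_half(n_pred),
       mean_supported = mean(n_supp), ci95_supported = ci_half(n_supp),
       supported_fraction = if (sum(n_pred) > 0)
         sum(n_supp) / sum(n_pred) else 0)
}

#' @export
print.phyto_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Phytochemical health-effect pipeline:", s$n_compounds, "compounds\n")
  cat(sprintf("  predicted effects per compound: %.1f +/- %.1f (95%% CI)\n",
              s$mean_predicted, s$ci95_predicted))
  cat(sprintf("  evidence-supported: %.1f per compound (%.0f%% of predictions)\n",
              s$mean_supported, 100 * s$supported_fraction))
  invisible(x)
}

write_pipeline_outputs <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pvp_tab <- do.call(rbind, lapply(bundle$pvps, function(p)
    data.frame(phytochemical_id = p$phytochemical_id,
               phenotype_id = names(p$binary),
               raw_score = unname(p$raw_scores[names(p$binary)]),
               empirical_p = unname(p$empirical_p[names(p$binary)]),
               selected = unname(p$binary))))
  write_tsv(pvp_tab, file.path(out_dir, "pvp.tsv"))
  eff_tab <- do.call(rbind, lapply(names(bundle$effects), function(id) {
    d <- bundle$effects[[id]]
    if (!nrow(d)) return(NULL)
    cbind(phytochemical_id = id, d)
  }))
  if (is.null(eff_tab))
    eff_tab <- data.frame(phytochemical_id = character(),
                          phenotype_id = character(), n_e = integer(),
                          rank = integer())
  write_tsv(eff_tab, file.path(out_dir, "effects.tsv"))
  write_tsv(bundle$chemicals, file.path(out_dir, "chemical_flags.tsv"))
  cosat <- as.data.frame(bundle$cosatisfaction)
  cosat <- cbind(property = rownames(cosat), cosat)
  write_tsv(cosat, file.path(out_dir, "cosatisfaction.tsv"))
  cfg <- bundle$config
  snapshot <- c(cfg["paths"], cfg[setdiff(names(cfg), "paths")],
                list(summary = bundle$summary))
  jsonlite::write_json(snapshot, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  inputs <- unlist(Filter(Negate(is.null), cfg$paths))
  manifest <- data.frame(input = names(inputs), path = unname(inputs),
                         md5 = unname(tools::md5sum(unname(inputs))))
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
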