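# phytonet

Network-based prediction of the potential health effects of phytochemicals,
with chemical-availability filtering, ethnopharmacological evidence matching
and literature-based validation.

## The problem

Phytochemicals — plant secondary metabolites such as quercetin or choline —
are promising leads for drugs and functional foods, but in vitro screening of
their health effects is slow and expensive. `phytonet` implements an
integrated in silico screen that combines three complementary information
sources:

1. **Molecular propagation.** A compound's protein targets (direct binding
   partners, weight 1, and indirect targets such as expression-level
   interactions, weight 0.3) seed a random walk with restart on a
   protein–protein interaction network,

   p_{t+1} = (1 − r) Wᵀ p_t + r p₀,  r = 0.7,

   iterated until ‖p_{t+1} − p_t‖₁ < 10⁻⁸, where W is the row-normalized
   adjacency matrix. Steady-state node scores are summed over each
   phenotype's associated genes to give raw phenotype scores. Because raw
   scores inflate with target and gene-set sizes, each score is compared
   against 1000 random target profiles of the same size; the empirical
   p-value p = (n_exceed + 1)/(n_random + 1) < 0.01 selects the compound's
   **phenotype vector (PVP)**, a binary profile of predicted effects.
2. **Chemical availability.** Molecular weight, AlogP, hydrogen-bond
   donors/acceptors and rotatable bonds feed Lipinski's rule of five;
   intestinal absorption (HIA), Caco-2 and blood–brain-barrier flags
   arrive precomputed (or from a clearly-labelled surrogate rule) and are
   summarized in a co-satisfaction table.
3. **Ethnopharmacological evidence.** Predicted phenotypes are matched
   against the traditional uses of the plants containing the compound via
   Wu–Palmer similarity on a rooted phenotype concept hierarchy,
   sim(c₁, c₂) = 2·depth(lcs) / (path₁ + path₂ + 2·depth(lcs)); a plant
   supports a prediction when its best-matching use exceeds 0.8, and the
   supporting-plant count n_e ranks the predictions.

A literature module validates association sets against an annotated abstract
corpus (sentence-level co-occurrence, Jaccard index, one-sided Fisher
enrichment, Benjamini–Hochberg FDR, Mann–Whitney comparisons) and evaluates
precision/recall under controlled class skew. A deterministic fixture
generator produces all seven inputs synthetically, so the entire pipeline is
testable offline.

## Worked example

```r
library(phytonet)

spec <- fixture_spec(rng_seed = 1)          # a complete synthetic study
dir <- tempfile(); generate_fixtures(spec, dir)

cfg <- pipeline_config(
  network        = file.path(dir, "network.tsv"),
  targets        = file.path(dir, "targets.tsv"),
  gene_phenotype = file.path(dir, "gene_phenotype.tsv"),
  ontology       = file.path(dir, "ontology.tsv"),
  plant_compounds = file.path(dir, "plant_compounds.tsv"),
  plant_uses     = file.path(dir, "plant_uses.tsv"),
  chemicals      = file.path(dir, "chemicals.tsv"),
  corpus         = file.path(dir, "corpus.jsonl"),
  seed = 1)
bundle <- run_pipeline(cfg)
print(bundle)
#> Phytochemical health-effect pipeline: 20 compounds
#>   predicted effects per compound: 2.2 +/- 0.2 (95% CI)
#>   evidence-supported: 2.0 per compound (89% of predictions)
```

Each of the 20 synthetic compounds carries 2 planted true phenotypes; the
permutation null selects on average ~2 phenotypes per compound (the planted
ones plus an occasional neighbour), and most survive the ethnopharmacological
filter because the generator echoes the planted phenotypes into plant-use
records. Per-compound detail:

```r
bundle$effects[["C01"]]
#>   phenotype_id n_e rank
#> 1          P01   1    1
#> 2          P02   1    1
```

Here `n_e` is the number of plants containing C01 whose traditional use
matches the predicted phenotype with Wu–Palmer similarity above 0.8, and
`rank` orders the compound's predictions by that evidence.

Single components work standalone, e.g.

```r
ont <- build_ontology(data.frame(cui1 = c("L","M","stroke","nephrosis"),
                                 cui2 = c("top","L","M","L"), rel = "RB"))
wup_similarity(ont, "stroke", "nephrosis")   # lcs depth 2, paths 2 and 1
#> [1] 0.5714286
```

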