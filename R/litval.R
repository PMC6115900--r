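#' Read an annotated abstract corpus from JSONL
#'
#' One JSON object per line: `{"id": "...", "sentences": [["TERM", ...],
#' ...]}`. Mentions are already-normalized identifiers (phytochemical or
#' phenotype IDs), not raw text.
#'
#' @param path Path to the JSONL file.
#' @return A `literature_corpus`: list of abstracts, each a list with `id`
#'   and `sentences` (list of character vectors).
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  abstracts <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    list(id = x$id,
         sentences = lapply(x$sentences, function(s)
           as.character(unlist(s, use.names = FALSE))))
  })
  ids <- vapply(abstracts, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate abstract id(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "),
         call. = FALSE)
  structure(abstracts, class = "literature_corpus")
}

#' Write a corpus to JSONL
#'
#' @param corpus A `literature_corpus`.
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (a in corpus) {
    writeLines(jsonlite::toJSON(
      list(id = a$id, sentences = lapply(a$sentences, as.list)),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

# Index: term -> integer vector of abstract positions mentioning it anywhere.
corpus_index <- function(corpus) {
  terms_per_abs <- lapply(corpus, function(a)
    unique(unlist(a$sentences, use.names = FALSE)))
  split(rep(seq_along(corpus), lengths(terms_per_abs)),
        unlist(terms_per_abs, use.names = FALSE))
}

#' Sentence-level co-occurrence and abstract-level occurrence counts
#'
#' `n_c` counts abstracts containing at least one sentence that mentions
#' both terms; `n_o` counts abstracts mentioning either or both terms
#' anywhere (so `n_c <= n_o` always).
#'
#' @param corpus A `literature_corpus`.
#' @param chem_id,pheno_id Term identifiers.
#' @return Named integer vector `c(n_c = ..., n_o = ...)`.
#' @export
cooccurrence <- function(corpus, chem_id, pheno_id) {
  stopifnot(inherits(corpus, "literature_corpus"))
  n_c <- 0L; n_o <- 0L
  for (a in corpus) {
    has_chem <- FALSE; has_pheno <- FALSE; together <- FALSE
    for (s in a$sentences) {
      ic <- chem_id %in% s; ip <- pheno_id %in% s
      has_chem <- has_chem || ic
      has_pheno <- has_pheno || ip
      if (ic && ip) together <- TRUE
    }
    if (has_chem || has_pheno) n_o <- n_o + 1L
    if (together) n_c <- n_c + 1L
  }
  c(n_c = n_c, n_o = n_o)
}

#' Jaccard index of a term pair
#'
#' The sentence-level co-mention abstract count divided by the either-or-both
#' abstract count, with the convention 0 when the pair never occurs.
#'
#' @param n_c Co-occurrence abstract count.
#' @param n_o Occurrence (either-or-both) abstract count.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(n_c, n_o) {
  if (any(n_c > n_o)) stop("n_c cannot exceed n_o", call. = FALSE)
  ifelse(n_o == 0, 0, n_c / n_o)
}

#' One-sided Fisher enrichment of a term pair in the corpus
#'
#' Builds the 2x2 abstract-count table (mentions the phytochemical: yes/no x
#' mentions the phenotype: yes/no, anywhere in the abstract) and returns the
#' exact one-sided hypergeometric over-representation p-value. Only
#' over-representation is meaningful for literature support, hence the
#' one-sided test. A degenerate table (a zero margin) yields p = 1.
#'
#' @param corpus A `literature_corpus`.
#' @param chem_id,pheno_id Term identifiers.
#' @return P-value in `(0, 1]`.
#' @export
fisher_enrichment <- function(corpus, chem_id, pheno_id) {
  stopifnot(inherits(corpus, "literature_corpus"), length(corpus) >= 1L)
  idx <- corpus_index(corpus)
  in_chem <- idx[[chem_id]] %||% integer()
  in_pheno <- idx[[pheno_id]] %||% integer()
  hyper_enrichment_p(length(intersect(in_chem, in_pheno)),
                     length(in_chem), length(in_pheno), length(corpus))
}

# P(X >= a) for X ~ Hypergeometric: `a` successes out of k draws (abstracts
# with the chemical) from n_pheno successes in a population of N abstracts.
hyper_enrichment_p <- function(a, n_chem, n_pheno, N) {
  if (n_chem == 0L || n_pheno == 0L || n_chem == N || n_pheno == N) return(1)
  stats::phyper(a - 1, n_pheno, N - n_pheno, n_chem, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment of a p-value list.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration of the U distribution when `length(x) * length(y) <=
#' exact_limit` and the data carry no ties; otherwise the tie-corrected
#' normal approximation with continuity correction. The mode actually used
#' is attached as the `"method"` attribute.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Product-of-sizes limit for the exact mode; default 400.
#' @return Two-sided p-value with attribute `method` (`"exact"` or
#'   `"approximate"`).
#' @export
mann_whitney <- function(x, y, exact_limit = 400L) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  if (length(unique(c(x, y))) == 1L)  # fully degenerate: no evidence of shift
    return(structure(1, method = "degenerate"))
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !has_ties && length(x) * length(y) <= exact_limit
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  structure(min(p, 1), method = if (exact) "exact" else "approximate")
}

#' Literature association statistics for a set of term pairs
#'
#' For each phytochemical-phenotype pair: the sentence-level co-occurrence
#' count `n_c`, the abstract-level occurrence count `n_o`, the Jaccard index,
#' the one-sided Fisher enrichment p-value, and the Benjamini-Hochberg
#' q-value computed across the supplied list (one family per list).
#'
#' @param corpus A `literature_corpus`.
#' @param pairs Data.frame with columns `phytochemical_id`, `phenotype_id`.
#' @return Data.frame of class `association_stats` with columns
#'   `phytochemical_id`, `phenotype_id`, `n_c`, `n_o`, `ji`, `fisher_p`, `q`.
#' @export
association_stats <- function(corpus, pairs) {
  stopifnot(inherits(corpus, "literature_corpus"), is.data.frame(pairs),
            all(c("phytochemical_id", "phenotype_id") %in% names(pairs)))
  idx <- corpus_index(corpus)
  N <- length(corpus)
  # sentence-level pair index built once: abstract sets per co-mentioned pair
  n_c_of <- new.env(parent = emptyenv())
  want <- paste(pairs$phytochemical_id, pairs$phenotype_id, sep = "\r")
  want_set <- unique(want)
  for (ai in seq_along(corpus)) {
    seen_here <- character()
    for (s in corpus[[ai]]$sentences) {
      s <- unique(s)
      if (length(s) < 2L) next
      combos <- utils::combn(sort(s), 2L)
      keys <- c(paste(combos[1L, ], combos[2L, ], sep = "\r"),
                paste(combos[2L, ], combos[1L, ], sep = "\r"))
      for (key in intersect(setdiff(keys, seen_here), want_set)) {
        n_c_of[[key]] <- (n_c_of[[key]] %||% 0L) + 1L
        seen_here <- c(seen_here, key)
      }
    }
  }
  out <- pairs[, c("phytochemical_id", "phenotype_id")]
  stats_rows <- lapply(seq_len(nrow(pairs)), function(k) {
    in_chem <- idx[[pairs$phytochemical_id[k]]] %||% integer()
    in_pheno <- idx[[pairs$phenotype_id[k]]] %||% integer()
    n_o <- length(union(in_chem, in_pheno))
    n_c <- n_c_of[[want[k]]] %||% 0L
    both <- length(intersect(in_chem, in_pheno))
    c(n_c = n_c, n_o = n_o,
      fisher_p = hyper_enrichment_p(both, length(in_chem), length(in_pheno), N))
  })
  sm <- do.call(rbind, stats_rows)
  out$n_c <- as.integer(sm[, "n_c"])
  out$n_o <- as.integer(sm[, "n_o"])
  out$ji <- jaccard(out$n_c, out$n_o)
  out$fisher_p <- sm[, "fisher_p"]
  out$q <- bh_fdr(out$fisher_p)
  class(out) <- c("association_stats", "data.frame")
  out
}

#' Skew-controlled precision/recall evaluation
#'
#' True negatives are unknown in phytochemical-effect prediction, so the
#' negative set is sampled: per repeat, `ratio x |positives|` pairs are drawn
#' without replacement from `universe \ positives` (or the whole complement
#' for skew `"all"`). Precision is computed on predictions restricted to the
#' evaluation set (positives plus sampled negatives); recall is
#' `TP / |positives|` and does not depend on the skew.
#'
#' @param predictions,positives,universe Data.frames with columns
#'   `phytochemical_id`, `phenotype_id`; `positives` must be a subset of
#'   `universe`.
#' @param skew `"1:1"`, `"1:10"` or `"all"`.
#' @param repeats Number of negative-set draws; default 10.
#' @param rng_seed Integer seed.
#' @return An `evaluation_report`: list with `skew`, `precision_mean`,
#'   `precision_sd`, `recall`, `repeats`, `rng_seed`.
#' @export
evaluate_predictions <- function(predictions, positives, universe,
                                 skew = c("1:1", "1:10", "all"),
                                 repeats = 10L, rng_seed = 1L) {
  skew <- match.arg(skew)
  pk <- pair_keys(predictions)
  gk <- pair_keys(positives)
  uk <- pair_keys(universe)
  if (!all(gk %in% uk))
    stop("positives must be a subset of the universe", call. = FALSE)
  candidates <- setdiff(uk, gk)
  tp <- length(intersect(pk, gk))
  recall <- if (length(gk)) tp / length(gk) else 0
  n_neg <- switch(skew, "1:1" = length(gk), "1:10" = 10L * length(gk),
                  "all" = length(candidates))
  if (n_neg > length(candidates))
    stop("not enough candidate negatives: need ", n_neg, ", have ",
         length(candidates), call. = FALSE)
  precisions <- with_seed(rng_seed, vapply(seq_len(repeats), function(i) {
    negs <- if (skew == "all") candidates else sample(candidates, n_neg)
    fp <- length(intersect(pk, negs))
    if (tp + fp == 0L) 0 else tp / (tp + fp)
  }, 1.0))
  structure(list(skew = skew, precision_mean = mean(precisions),
                 precision_sd = stats::sd(precisions), recall = recall,
                 repeats = as.integer(repeats),
                 rng_seed = as.integer(rng_seed)),
            class = "evaluation_report")
}

pair_keys <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("phytochemical_id", "phenotype_id") %in% names(df)))
  unique(paste(df$phytochemical_id, df$phenotype_id, sep = "\r"))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation (skew %s, %d repeats): precision %.3f +/- %.3f, recall %.3f\n",
              x$skew, x$repeats, x$precision_mean, x$precision_sd, x$recall))
  invisible(x)
}

#' Compare literature statistics of predicted vs random association sets
#'
#' Summarizes each set by its mean co-occurrence `n_c`, mean Jaccard index,
#' the number of pairs with Fisher p < `p_cut` (`n_p`) and the number with
#' BH q < `q_cut` (`n_q`), and tests the per-pair `n_c`, Jaccard and Fisher-p
#' columns for a distributional difference with the Mann-Whitney U test.
#'
#' @param predicted_stats,random_stats `association_stats` data.frames.
#' @param p_cut Fisher significance cut; default 0.001.
#' @param q_cut FDR cut; default 0.05.
#' @return List with `summary` (two-row data.frame) and `mw_p` (named vector
#'   of Mann-Whitney p-values for `n_c`, `ji`, `fisher_p`).
#' @export
compare_sets <- function(predicted_stats, random_stats,
                         p_cut = 0.001, q_cut = 0.05) {
  stopifnot(nrow(predicted_stats) > 0L, nrow(random_stats) > 0L)
  summ <- function(s, label) {
    data.frame(set = label, n_pairs = nrow(s), mean_n_c = mean(s$n_c),
               mean_ji = mean(s$ji), n_p = sum(s$fisher_p < p_cut),
               n_q = sum(s$q < q_cut))
  }
  mw <- c(n_c = as.numeric(mann_whitney(predicted_stats$n_c,
                                        random_stats$n_c)),
          ji = as.numeric(mann_whitney(predicted_stats$ji, random_stats$ji)),
          fisher_p = as.numeric(mann_whitney(predicted_stats$fisher_p,
                                             random_stats$fisher_p)))
  list(summary = rbind(summ(predicted_stats, "predicted"),
                       summ(random_stats, "random")),
       mw_p = mw)
}
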