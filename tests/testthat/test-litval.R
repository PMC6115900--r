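test_that("co-occurrence is sentence-level, occurrence abstract-level", {
  corpus <- corpus_from(
    list(c("chemX", "phenoY")),                 # same sentence
    list("chemX", "phenoY"),                    # same abstract, apart
    list("chemX"),                              # chem only
    list(c("other", "terms")))                  # neither
  cc <- cooccurrence(corpus, "chemX", "phenoY")
  expect_equal(cc[["n_c"]], 1L)
  expect_equal(cc[["n_o"]], 3L)

  # brute-force scan oracle on a random corpus
  set.seed(601)
  vocab <- c("c1", "c2", "p1", "p2", "x1")
  rnd <- do.call(corpus_from, replicate(30, {
    replicate(sample(1:3, 1), sample(vocab, sample(1:3, 1)),
              simplify = FALSE)
  }, simplify = FALSE))
  for (pair in list(c("c1", "p1"), c("c2", "p2"))) {
    got <- cooccurrence(rnd, pair[1L], pair[2L])
    nc <- sum(vapply(rnd, function(a)
      any(vapply(a$sentences,
                 function(s) pair[1L] %in% s && pair[2L] %in% s, TRUE)),
      TRUE))
    no <- sum(vapply(rnd, function(a) {
      terms <- unlist(a$sentences)
      pair[1L] %in% terms || pair[2L] %in% terms
    }, TRUE))
    expect_equal(unname(got), c(nc, no))
  }
})

test_that("the Jaccard index divides co-mentions by either-or-both mentions", {
  expect_equal(jaccard(50, 200), 0.25)
  expect_equal(jaccard(7, 7), 1)
  expect_equal(jaccard(0, 0), 0)
  expect_error(jaccard(5, 4), "exceed")
})

test_that("Fisher enrichment matches the hypergeometric closed form and fisher.test", {
  # 10 abstracts with both terms, 10 with neither: p = 1 / C(20, 10)
  corpus <- do.call(corpus_from, c(
    rep(list(list(c("chem", "pheno"))), 10),
    rep(list(list("filler")), 10)))
  p <- fisher_enrichment(corpus, "chem", "pheno")
  expect_equal(p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(p, stats::fisher.test(matrix(c(10, 0, 0, 10), 2),
                                     alternative = "greater")$p.value,
               tolerance = 1e-12)

  # absent term -> zero margin -> p = 1
  expect_equal(fisher_enrichment(corpus, "chem", "ghost"), 1)
})

test_that("Fisher enrichment equals full enumeration over fixed margins", {
  # enumeration oracle: P(table) = C(R1, a) C(R2, c) / C(N, C1)
  enum_p <- function(a, b, c, d) {
    R1 <- a + b; R2 <- c + d; C1 <- a + c; N <- R1 + R2
    xs <- max(0, C1 - R2):min(R1, C1)
    probs <- choose(R1, xs) * choose(R2, C1 - xs) / choose(N, C1)
    sum(probs[xs >= a])
  }
  set.seed(602)
  for (rep in 1:50) {
    tab <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    N <- sum(tab)
    got <- phytonet:::hyper_enrichment_p(a, a + b, a + c, N)
    if ((a + b) %in% c(0, N) || (a + c) %in% c(0, N)) {
      expect_equal(got, 1)
    } else {
      expect_equal(got, enum_p(a, b, c, d), tolerance = 1e-10)
    }
  }
})

test_that("Fisher p-values are super-uniform under independent margins", {
  set.seed(603)
  N <- 60L
  ps <- replicate(300, {
    chem <- sample.int(N, 20L); pheno <- sample.int(N, 15L)
    phytonet:::hyper_enrichment_p(length(intersect(chem, pheno)), 20L, 15L, N)
  })
  for (alpha in c(0.05, 0.2, 0.5))
    expect_lte(mean(ps < alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 300))
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(604)
  p <- stats::runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone after sorting
  expect_true(all(q >= 0 & q <= 1))
})

test_that("Mann-Whitney switches between exact enumeration and approximation", {
  expect_equal(as.numeric(mann_whitney(c(1, 2, 3), c(1, 2, 3))), 1)
  p <- mann_whitney(c(1, 2), c(10, 20))
  expect_equal(as.numeric(p), 1 / 3)
  expect_equal(attr(p, "method"), "exact")

  set.seed(605)
  big <- mann_whitney(stats::rnorm(40), stats::rnorm(40) + 3)
  expect_lt(as.numeric(big), 1e-3)
  expect_equal(attr(big, "method"), "approximate")

  # enumeration oracle: all group assignments of the pooled sample
  enum_mw <- function(x, y) {
    pooled <- c(x, y); n <- length(x)
    u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
    mu <- n * length(y) / 2
    combos <- utils::combn(length(pooled), n)
    us <- apply(combos, 2, function(ix)
      sum(rank(pooled)[ix]) - n * (n + 1) / 2)
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  for (sizes in list(c(2, 3), c(4, 4), c(5, 6), c(6, 6))) {
    x <- sample(seq_len(100), sizes[1L])
    y <- sample(setdiff(seq_len(100), x), sizes[2L])
    expect_equal(as.numeric(mann_whitney(x, y)), enum_mw(x, y),
                 tolerance = 1e-9, label = paste(sizes, collapse = "x"))
  }
  expect_error(mann_whitney(numeric(), 1), "empty")
})

test_that("association statistics agree with the single-pair primitives", {
  set.seed(606)
  vocab_c <- c("c1", "c2"); vocab_p <- c("p1", "p2")
  rnd <- do.call(corpus_from, replicate(40, {
    replicate(sample(1:2, 1),
              sample(c(vocab_c, vocab_p, "x"), sample(1:4, 1)),
              simplify = FALSE)
  }, simplify = FALSE))
  pairs <- expand.grid(phytochemical_id = vocab_c, phenotype_id = vocab_p,
                       stringsAsFactors = FALSE)
  st <- association_stats(rnd, pairs)
  for (k in seq_len(nrow(st))) {
    cc <- cooccurrence(rnd, st$phytochemical_id[k], st$phenotype_id[k])
    expect_equal(st$n_c[k], cc[["n_c"]])
    expect_equal(st$n_o[k], cc[["n_o"]])
    expect_equal(st$ji[k], jaccard(cc[["n_c"]], cc[["n_o"]]))
    expect_equal(st$fisher_p[k],
                 fisher_enrichment(rnd, st$phytochemical_id[k],
                                   st$phenotype_id[k]))
  }
  expect_equal(st$q, bh_fdr(st$fisher_p))
  expect_true(all(st$n_c <= st$n_o))
  expect_true(all(st$ji >= 0 & st$ji <= 1))
})

test_that("evaluation handles perfect, disjoint and planted prediction sets", {
  pairs <- function(ids) data.frame(
    phytochemical_id = sub("\\|.*", "", ids),
    phenotype_id = sub(".*\\|", "", ids))
  universe <- pairs(as.vector(outer(paste0("c", 1:6), paste0("p", 1:10),
                                    paste, sep = "|")))
  positives <- universe[1:5, ]

  for (skew in c("1:1", "1:10", "all")) {
    r <- evaluate_predictions(positives, positives, universe, skew = skew,
                              rng_seed = 1)
    expect_equal(r$precision_mean, 1)
    expect_equal(r$recall, 1)
  }
  disjoint <- universe[6:10, ]
  r0 <- evaluate_predictions(disjoint, positives, universe, skew = "1:1",
                             rng_seed = 1)
  expect_lte(r0$recall, 0)
  # planted overlap: 3 of 5 positives predicted, plus 2 known negatives
  pred <- rbind(positives[1:3, ], universe[8:9, ])
  r_all <- evaluate_predictions(pred, positives, universe, skew = "all",
                                rng_seed = 1)
  expect_equal(r_all$recall, 3 / 5)
  expect_equal(r_all$precision_mean, 3 / 5)  # both false pairs in eval set
  expect_equal(r_all$precision_sd, 0)
})

test_that("recall ignores skew while precision decays with negative load", {
  set.seed(607)
  universe <- expand.grid(phytochemical_id = paste0("c", 1:20),
                          phenotype_id = paste0("p", 1:20),
                          stringsAsFactors = FALSE)
  positives <- universe[sample(nrow(universe), 25L), ]
  pred <- rbind(positives[1:15, ],
                universe[sample(nrow(universe), 60L), ])
  rs <- lapply(c("1:1", "1:10", "all"), function(s)
    evaluate_predictions(pred, positives, universe, skew = s, rng_seed = 3))
  recalls <- vapply(rs, `[[`, 1.0, "recall")
  expect_true(all(abs(recalls - recalls[1L]) < 1e-12))
  precisions <- vapply(rs, `[[`, 1.0, "precision_mean")
  expect_true(all(diff(precisions) < 0))
  expect_error(evaluate_predictions(pred, positives, universe[1:30, ],
                                    skew = "1:1"), "subset")
  expect_error(evaluate_predictions(pred, universe[1:30, ], universe[1:30, ],
                                    skew = "1:10"), "negatives")
})

test_that("set comparison reports means, significance counts and MW p-values", {
  mk_stats <- function(n_c, fisher_p) {
    df <- data.frame(phytochemical_id = paste0("c", seq_along(n_c)),
                     phenotype_id = "p", n_c = n_c, n_o = pmax(n_c, 10L),
                     fisher_p = fisher_p)
    df$ji <- df$n_c / df$n_o
    df$q <- bh_fdr(df$fisher_p)
    class(df) <- c("association_stats", "data.frame")
    df
  }
  a <- mk_stats(c(5L, 8L, 6L, 9L), c(1e-5, 1e-4, 2e-3, 0.5))
  same <- compare_sets(a, a)
  expect_true(all(same$mw_p == 1))
  expect_equal(same$summary$mean_n_c, rep(mean(a$n_c), 2))
  expect_equal(same$summary$n_p, rep(2L, 2))  # fisher_p < 0.001

  b <- mk_stats(c(0L, 1L, 0L, 0L), c(0.4, 0.6, 0.9, 0.8))
  cmp <- compare_sets(a, b)
  expect_gt(cmp$summary$mean_n_c[1L], cmp$summary$mean_n_c[2L])
  expect_gt(cmp$summary$mean_ji[1L], cmp$summary$mean_ji[2L])
  expect_true(all(cmp$summary$n_p <= cmp$summary$n_pairs))
  expect_true(all(cmp$summary$n_q <= cmp$summary$n_pairs))
})

test_that("JSONL corpora round-trip through write and read", {
  corpus <- corpus_from(list(c("a", "b"), "c"), list("d"))
  f <- tempfile(fileext = ".jsonl")
  write_corpus(corpus, f)
  back <- read_corpus(f)
  expect_equal(length(back), 2L)
  expect_equal(back[[1L]]$sentences, list(c("a", "b"), "c"))
  dup <- c(readLines(f), readLines(f)[1L])
  writeLines(dup, f)
  expect_error(read_corpus(f), "duplicate")
})
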