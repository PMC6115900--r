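#' Random walk with restart on the molecular network
#'
#' Iterates the propagation `p_{t+1} = (1 - r) W^T p_t + r p0` until the L1
#' change between successive iterates falls below `tol`, where `W` is the
#' row-stochastic transition matrix from [build_transition()] and `r` is the
#' restart probability. Because `W^T` is column-stochastic and `p0` sums to
#' one, total probability mass is conserved at every step; the fixed point
#' scores each node's network proximity to the seed set.
#'
#' @param W Row-stochastic transition matrix (sparse, from
#'   [build_transition()]).
#' @param p0 Initial probability vector (from [make_seed_vector()]); must sum
#'   to 1.
#' @param restart Restart probability `r` in (0, 1]; default 0.7.
#' @param tol L1 convergence tolerance; default 1e-8.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return A `propagation_result`: list with `node_scores` (named, aligned to
#'   the node order), `iterations`, `converged`.
#' @export
run_rwr <- function(W, p0, restart = 0.7, tol = 1e-8, max_iter = 10000L) {
  stopifnot(restart > 0, restart <= 1)
  if (abs(sum(p0) - 1) > 1e-6)
    stop("p0 must sum to 1 (got ", format(sum(p0)), ")", call. = FALSE)
  Wt <- Matrix::t(W)
  res <- rwr_iterate(Wt, matrix(p0, ncol = 1L), restart, tol, max_iter)
  structure(list(node_scores = stats::setNames(res$P[, 1L], rownames(W)),
                 iterations = res$iterations, converged = res$converged),
            class = "propagation_result")
}

# Batched fixed-point iteration: each column of P0 is one walk. Shared by
# run_rwr and the permutation null (which propagates hundreds of random
# profiles at once; the per-column maths is identical to the single-vector
# case).
rwr_iterate <- function(Wt, P0, restart, tol, max_iter) {
  if (restart == 1) {
    return(list(P = as.matrix(P0), iterations = 1L, converged = TRUE))
  }
  P <- as.matrix(P0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    P_new <- as.matrix((1 - restart) * (Wt %*% P)) + restart * as.matrix(P0)
    delta <- max(colSums(abs(P_new - P)))
    P <- P_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("RWR did not converge within ", max_iter, " iterations",
            call. = FALSE)
  list(P = P, iterations = iter, converged = converged)
}

#' @export
print.propagation_result <- function(x, ...) {
  cat("RWR propagation over", length(x$node_scores), "nodes:",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  top <- sort(x$node_scores, decreasing = TRUE)[seq_len(min(5, length(x$node_scores)))]
  cat("  top nodes:", paste(sprintf("%s=%.4g", names(top), top),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Load a gene-phenotype association map
#'
#' Expects a TSV with columns `phenotype_id`, `gene_id`. Every phenotype must
#' have at least one gene; genes outside the network namespace are retained
#' (they simply contribute zero to phenotype scores) and counted in a
#' message when a network is supplied.
#'
#' @param path Path to the TSV file.
#' @param network Optional `phyto_network` used only to report how many
#'   genes fall outside the network.
#' @return A named list (`gene_phenotype_map`): phenotype ID -> character
#'   vector of gene IDs.
#' @export
load_gene_phenotype_map <- function(path, network = NULL) {
  df <- read_tsv(path)
  need <- c("phenotype_id", "gene_id")
  if (!all(need %in% names(df)))
    stop("gene-phenotype table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  gpmap <- lapply(split(df$gene_id, df$phenotype_id), unique)
  gpmap <- gpmap[order(names(gpmap))]
  if (!is.null(network)) {
    unmatched <- sum(!unique(df$gene_id) %in% network$nodes)
    if (unmatched)
      message(unmatched, " gene(s) in the phenotype map are absent from ",
              "the network and will contribute 0")
  }
  structure(gpmap, class = "gene_phenotype_map")
}

# Sparse phenotype x node indicator matrix; row phi sums node scores of the
# genes associated with phi.
phenotype_indicator <- function(gpmap, nodes) {
  phen <- names(gpmap)
  ij <- do.call(rbind, lapply(seq_along(gpmap), function(k) {
    j <- match(gpmap[[k]], nodes)
    j <- j[!is.na(j)]
    if (length(j)) cbind(k, j) else NULL
  }))
  if (is.null(ij)) ij <- matrix(integer(), ncol = 2L)
  Matrix::sparseMatrix(i = ij[, 1L], j = ij[, 2L], x = 1,
                       dims = c(length(phen), length(nodes)),
                       dimnames = list(phen, nodes))
}

#' Aggregate propagated node scores to phenotype scores
#'
#' The raw score of a phenotype is the sum of the steady-state scores of its
#' associated genes that are present in the network; a gene shared by several
#' phenotypes contributes to each of them, and a phenotype with no in-network
#' gene scores 0.
#'
#' @param result A `propagation_result` from [run_rwr()].
#' @param gpmap A `gene_phenotype_map` from [load_gene_phenotype_map()] (or a
#'   plain named list phenotype -> genes).
#' @return Named numeric vector of raw phenotype scores.
#' @export
map_to_phenotypes <- function(result, gpmap) {
  stopifnot(inherits(result, "propagation_result"))
  if (length(gpmap) == 0L) stop("empty gene-phenotype map", call. = FALSE)
  M <- phenotype_indicator(gpmap, names(result$node_scores))
  stats::setNames(as.numeric(M %*% result$node_scores), names(gpmap))
}

#' Empirical permutation null for phenotype scores
#'
#' High raw phenotype scores do not by themselves indicate a specific
#' phytochemical-phenotype relationship: compounds with many targets, and
#' phenotypes with many genes, inflate scores for purely combinatorial
#' reasons. This null keeps the observed numbers of direct and indirect
#' targets fixed, redraws the target identities uniformly from the network
#' nodes (direct and indirect sets disjoint, sampled without replacement),
#' re-propagates each random profile, and scores each phenotype by
#' `p = (n_exceed + 1) / (n_random + 1)` where `n_exceed` counts random
#' profiles whose raw score is strictly greater than the observed one (ties
#' do not count as exceeding).
#'
#' All random profiles are propagated in one batched iteration, which is
#' mathematically identical to `n_random` independent [run_rwr()] calls.
#'
#' @param profile A [target_profile()].
#' @param W Transition matrix from [build_transition()].
#' @param gpmap Gene-phenotype map.
#' @param n_random Number of random profiles; default 1000.
#' @param rng_seed Integer seed; required for reproducibility.
#' @param restart,tol,max_iter Propagation parameters, as in [run_rwr()].
#' @param direct_weight,indirect_weight Seed weights, as in
#'   [make_seed_vector()].
#' @return List with `empirical_p` and `raw_scores` (named numeric vectors
#'   over phenotypes), plus `n_random` and `rng_seed`.
#' @export
empirical_null <- function(profile, W, gpmap, n_random = 1000L, rng_seed,
                           restart = 0.7, tol = 1e-8, max_iter = 10000L,
                           direct_weight = 1.0, indirect_weight = 0.3) {
  stopifnot(inherits(profile, "target_profile"))
  if (n_random < 1L) stop("n_random must be >= 1", call. = FALSE)
  if (missing(rng_seed)) stop("rng_seed is required", call. = FALSE)
  nodes <- rownames(W)
  n <- length(nodes)
  nd <- sum(profile$direct_targets %in% nodes)
  ni <- sum(profile$indirect_targets %in% nodes)
  if (nd + ni == 0L)
    stop("no in-network targets for ", profile$phytochemical_id,
         call. = FALSE)
  net_stub <- structure(list(nodes = nodes), class = "phyto_network")
  p0_obs <- suppressMessages(
    make_seed_vector(profile, net_stub, direct_weight, indirect_weight))

  # one seed column per random profile; draw order is part of the contract
  # (tests replay the identical stream)
  draws <- with_seed(rng_seed, {
    lapply(seq_len(n_random), function(i) sample.int(n, nd + ni))
  })
  total <- nd * direct_weight + ni * indirect_weight
  i_idx <- unlist(draws)
  j_idx <- rep(seq_len(n_random), each = nd + ni)
  x_val <- rep(c(rep(direct_weight, nd), rep(indirect_weight, ni)) / total,
               times = n_random)
  P0 <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x_val,
                             dims = c(n, n_random))
  Wt <- Matrix::t(W)
  res <- rwr_iterate(Wt, cbind(p0_obs, as.matrix(P0)), restart, tol, max_iter)
  M <- phenotype_indicator(gpmap, nodes)
  scores <- as.matrix(M %*% res$P)  # phenotypes x (1 + n_random)
  observed <- scores[, 1L]
  n_exceed <- rowSums(scores[, -1L, drop = FALSE] > observed)
  list(empirical_p = stats::setNames((n_exceed + 1) / (n_random + 1),
                                     names(gpmap)),
       raw_scores = stats::setNames(observed, names(gpmap)),
       n_random = as.integer(n_random), rng_seed = as.integer(rng_seed))
}

#' Assemble a binary phenotype vector of a phytochemical (PVP)
#'
#' Phenotypes whose empirical p-value is strictly below `alpha` are marked 1;
#' all raw values are replaced by this binary indicator. Provenance
#' (`n_random`, `rng_seed`, `alpha`) travels with the object.
#'
#' @param phytochemical_id Character scalar.
#' @param raw_scores,empirical_p Named numeric vectors over the same
#'   phenotype set (a mismatch is an error naming the differing keys).
#' @param alpha Significance level; default 0.01, strict inequality.
#' @param n_random,rng_seed Provenance of the permutation null.
#' @return A `phyto_pvp` object.
#' @export
build_pvp <- function(phytochemical_id, raw_scores, empirical_p,
                      alpha = 0.01, n_random = NA_integer_,
                      rng_seed = NA_integer_) {
  k1 <- names(raw_scores); k2 <- names(empirical_p)
  if (!setequal(k1, k2)) {
    diff <- c(setdiff(k1, k2), setdiff(k2, k1))
    stop("raw_scores / empirical_p key mismatch: ",
         paste(utils::head(diff, 10L), collapse = ", "), call. = FALSE)
  }
  empirical_p <- empirical_p[k1]
  structure(list(phytochemical_id = phytochemical_id,
                 raw_scores = raw_scores,
                 empirical_p = empirical_p,
                 binary = stats::setNames(as.integer(empirical_p < alpha), k1),
                 n_random = as.integer(n_random), alpha = alpha,
                 rng_seed = as.integer(rng_seed)),
            class = "phyto_pvp")
}

#' @export
print.phyto_pvp <- function(x, ...) {
  cat("PVP for", x$phytochemical_id, "-", sum(x$binary), "of",
      length(x$binary), "phenotypes selected (alpha =", x$alpha,
      ", n_random =", x$n_random, ")\n")
  invisible(x)
}

#' Predicted phenotypes of a PVP
#'
#' @param pvp A `phyto_pvp`.
#' @return Character vector of phenotype IDs with binary indicator 1.
#' @export
predicted_effects <- function(pvp) {
  stopifnot(inherits(pvp, "phyto_pvp"))
  names(pvp$binary)[pvp$binary == 1L]
}

#' Compute the PVP of one phytochemical end to end
#'
#' Convenience wrapper: seed vector, propagation, phenotype mapping,
#' permutation null and binarization in one call.
#'
#' @inheritParams empirical_null
#' @param alpha Significance level for selection; default 0.01.
#' @return A `phyto_pvp`.
#' @export
compute_pvp <- function(profile, W, gpmap, n_random = 1000L, rng_seed,
                        alpha = 0.01, restart = 0.7, tol = 1e-8,
                        max_iter = 10000L, direct_weight = 1.0,
                        indirect_weight = 0.3) {
  nul <- empirical_null(profile, W, gpmap, n_random = n_random,
                        rng_seed = rng_seed, restart = restart, tol = tol,
                        max_iter = max_iter, direct_weight = direct_weight,
                        indirect_weight = indirect_weight)
  build_pvp(profile$phytochemical_id, nul$raw_scores, nul$empirical_p,
            alpha = alpha, n_random = nul$n_random, rng_seed = nul$rng_seed)
}
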