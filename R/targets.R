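#' Create a phytochemical target profile
#'
#' A target profile holds the molecular seeds of one phytochemical, split
#' into direct targets (physical binding) and indirect targets (expression
#' change, phosphorylation, active metabolites). A node listed in both sets
#' is kept as direct — the stronger association wins.
#'
#' @param phytochemical_id Character scalar.
#' @param direct Character vector of direct target node IDs.
#' @param indirect Character vector of indirect target node IDs.
#' @return A `target_profile` object.
#' @export
target_profile <- function(phytochemical_id, direct = character(),
                           indirect = character()) {
  direct <- unique(as.character(direct))
  indirect <- unique(as.character(indirect))
  both <- intersect(direct, indirect)
  if (length(both)) {
    message(phytochemical_id, ": ", length(both),
            " target(s) listed as both direct and indirect; kept as direct")
    indirect <- setdiff(indirect, both)
  }
  if (length(direct) + length(indirect) == 0L)
    stop("target profile for ", phytochemical_id, " is empty", call. = FALSE)
  structure(list(phytochemical_id = phytochemical_id,
                 direct_targets = direct, indirect_targets = indirect),
            class = "target_profile")
}

#' Load target profiles from a TSV table
#'
#' Expects columns `phytochemical_id`, `target_id`, `association` with
#' association values `direct` or `indirect`.
#'
#' @param path Path to the TSV file.
#' @return Named list of [target_profile()] objects.
#' @export
load_target_profiles <- function(path) {
  df <- read_tsv(path)
  need <- c("phytochemical_id", "target_id", "association")
  if (!all(need %in% names(df)))
    stop("target table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$association), c("direct", "indirect"))
  if (length(bad))
    stop("unknown association type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  profiles <- lapply(split(df, df$phytochemical_id), function(d) {
    target_profile(d$phytochemical_id[1L],
                   direct = d$target_id[d$association == "direct"],
                   indirect = d$target_id[d$association == "indirect"])
  })
  profiles[order(names(profiles))]
}

#' Initial probability vector for the random walk
#'
#' Assigns `direct_weight` to direct targets and `indirect_weight` to
#' indirect targets present in the network, zero elsewhere, then normalizes
#' the vector to sum to one so the propagation stays a probability iteration.
#' The relative direct:indirect weighting (1 : 0.3 by default) is preserved
#' by the normalization. Targets absent from the network are dropped with a
#' message.
#'
#' @param profile A [target_profile()].
#' @param network A `phyto_network`.
#' @param direct_weight,indirect_weight Raw seed weights before
#'   normalization; defaults 1.0 and 0.3.
#' @return Named numeric vector over `network$nodes`, summing to 1.
#' @export
make_seed_vector <- function(profile, network,
                             direct_weight = 1.0, indirect_weight = 0.3) {
  stopifnot(inherits(profile, "target_profile"),
            inherits(network, "phyto_network"))
  nodes <- network$nodes
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  d_in <- intersect(profile$direct_targets, nodes)
  i_in <- intersect(profile$indirect_targets, nodes)
  n_off <- (length(profile$direct_targets) - length(d_in)) +
    (length(profile$indirect_targets) - length(i_in))
  if (n_off)
    message(profile$phytochemical_id, ": dropped ", n_off,
            " target(s) absent from the network")
  if (length(d_in) + length(i_in) == 0L)
    stop("no in-network targets for ", profile$phytochemical_id,
         call. = FALSE)
  p0[d_in] <- direct_weight
  p0[i_in] <- indirect_weight
  p0 / sum(p0)
}
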