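#' Load plant records (constituents and ethnopharmacological uses)
#'
#' @param compounds_path TSV with columns `plant_id`, `phytochemical_id`.
#' @param uses_path TSV with columns `plant_id`, `use_concept_id`.
#' @param ontology Optional `phyto_ontology`; use concepts absent from it
#'   are dropped with a message.
#' @return A `plant_records` object: named list of plants, each with
#'   `phytochemical_ids` and `use_concepts` (both deduplicated).
#' @export
load_plant_records <- function(compounds_path, uses_path, ontology = NULL) {
  comp <- read_tsv(compounds_path)
  uses <- read_tsv(uses_path)
  if (!all(c("plant_id", "phytochemical_id") %in% names(comp)))
    stop("plant-compound table needs plant_id, phytochemical_id",
         call. = FALSE)
  if (!all(c("plant_id", "use_concept_id") %in% names(uses)))
    stop("plant-use table needs plant_id, use_concept_id", call. = FALSE)
  plant_records(comp, uses, ontology)
}

#' Assemble plant records from in-memory tables
#'
#' @param compounds Data.frame `plant_id`, `phytochemical_id`.
#' @param uses Data.frame `plant_id`, `use_concept_id`.
#' @param ontology Optional `phyto_ontology` to validate use concepts.
#' @return A `plant_records` object.
#' @export
plant_records <- function(compounds, uses, ontology = NULL) {
  if (!is.null(ontology)) {
    known <- uses$use_concept_id %in% ontology$concepts
    if (any(!known)) {
      message("dropped ", sum(!known),
              " plant use(s) with concepts absent from the ontology")
      uses <- uses[known, , drop = FALSE]
    }
  }
  ids <- sort(unique(comp_ids <- compounds$plant_id))
  comp_by <- split(compounds$phytochemical_id, compounds$plant_id)
  use_by <- split(uses$use_concept_id, uses$plant_id)
  plants <- lapply(ids, function(p) {
    list(plant_id = p,
         phytochemical_ids = sort(unique(comp_by[[p]] %||% character())),
         use_concepts = sort(unique(use_by[[p]] %||% character())))
  })
  names(plants) <- ids
  empty <- vapply(plants, function(p) length(p$phytochemical_ids) == 0L, TRUE)
  if (any(empty)) {
    message("dropped ", sum(empty), " plant(s) with no phytochemicals")
    plants <- plants[!empty]
  }
  structure(plants, class = "plant_records")
}

#' Plants containing a given phytochemical
#'
#' @param phytochemical_id Character scalar.
#' @param plants A `plant_records` object.
#' @return A `plant_records` subset (possibly empty).
#' @export
plants_of <- function(phytochemical_id, plants) {
  stopifnot(inherits(plants, "plant_records"))
  keep <- vapply(plants,
                 function(p) phytochemical_id %in% p$phytochemical_ids, TRUE)
  structure(plants[keep], class = "plant_records")
}

#' Match predicted effects against ethnopharmacological plant uses
#'
#' For each phenotype predicted by the PVP, a plant containing the compound
#' supports the prediction when the best Wu-Palmer similarity between the
#' phenotype and any of the plant's traditional-use concepts strictly
#' exceeds `threshold`. The count of supporting plants is the
#' ethnopharmacological evidence `n_e` of that phenotype.
#'
#' @param pvp A `phyto_pvp` (binarized).
#' @param plants A `plant_records` object.
#' @param ontology A `phyto_ontology` covering phenotypes and use concepts.
#' @param threshold Similarity threshold; default 0.8, strict inequality.
#' @return An `evidence_result`: list with `phytochemical_id`, `n_e` (named
#'   integer over predicted phenotypes) and `supporting_plants` (named list
#'   of data.frames `plant_id`, `use_concept`, `similarity`).
#' @export
match_evidence <- function(pvp, plants, ontology, threshold = 0.8) {
  stopifnot(inherits(pvp, "phyto_pvp"), inherits(plants, "plant_records"),
            inherits(ontology, "phyto_ontology"))
  mine <- plants_of(pvp$phytochemical_id, plants)
  predicted <- predicted_effects(pvp)
  unknown <- setdiff(predicted, ontology$concepts)
  if (length(unknown)) {
    warning("skipping ", length(unknown),
            " predicted phenotype(s) absent from the ontology: ",
            paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    predicted <- setdiff(predicted, unknown)
  }
  sim_cache <- new.env(parent = emptyenv())
  sim <- function(a, b) {
    key <- paste(a, b, sep = "\r")
    got <- sim_cache[[key]]
    if (is.null(got)) {
      got <- wup_similarity(ontology, a, b)
      sim_cache[[key]] <- got
    }
    got
  }
  n_e <- stats::setNames(integer(length(predicted)), predicted)
  supporting <- stats::setNames(vector("list", length(predicted)), predicted)
  for (phi in predicted) {
    rows <- list()
    for (p in mine) {
      uses <- p$use_concepts[p$use_concepts %in% ontology$concepts]
      if (!length(uses)) next
      sims <- vapply(uses, function(u) sim(phi, u), 1.0)
      best <- which.max(sims)
      if (sims[best] > threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          plant_id = p$plant_id, use_concept = uses[best],
          similarity = sims[best], stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(plant_id = character(), use_concept = character(),
                 similarity = numeric())
    rownames(df) <- NULL
    supporting[[phi]] <- df
    n_e[[phi]] <- nrow(df)
  }
  structure(list(phytochemical_id = pvp$phytochemical_id,
                 threshold = threshold, n_e = n_e,
                 supporting_plants = supporting),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat("Ethnopharmacological evidence for", x$phytochemical_id, "-",
      sum(x$n_e >= 1L), "of", length(x$n_e),
      "predicted phenotypes supported (threshold", x$threshold, ")\n")
  invisible(x)
}

#' Keep predicted effects with ethnopharmacological support, ranked
#'
#' Retains exactly the predicted phenotypes with at least one supporting
#' plant and ranks them by descending evidence count `n_e` (dense ranking;
#' equal counts share a rank, rows ordered lexicographically within a rank).
#'
#' @param pvp A `phyto_pvp`.
#' @param evidence An `evidence_result` for the same phytochemical.
#' @return Data.frame `phenotype_id`, `n_e`, `rank`, ordered by rank.
#' @export
filter_by_evidence <- function(pvp, evidence) {
  stopifnot(inherits(pvp, "phyto_pvp"), inherits(evidence, "evidence_result"))
  if (!identical(pvp$phytochemical_id, evidence$phytochemical_id))
    stop("PVP and evidence refer to different phytochemicals", call. = FALSE)
  keep <- evidence$n_e[evidence$n_e >= 1L]
  keep <- keep[names(keep) %in% predicted_effects(pvp)]
  if (!length(keep))
    return(data.frame(phenotype_id = character(), n_e = integer(),
                      rank = integer()))
  o <- order(-keep, names(keep))
  keep <- keep[o]
  lvls <- sort(unique(unname(keep)), decreasing = TRUE)
  data.frame(phenotype_id = names(keep), n_e = unname(keep),
             rank = match(unname(keep), lvls), row.names = NULL)
}
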