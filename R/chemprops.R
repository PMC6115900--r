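#' Read a chemical descriptor and availability-flag table
#'
#' Expects a TSV with columns `phytochemical_id`, `smiles`, `mw`, `alogp`,
#' `hbd`, `hba`, `rotb`, `hia`, `caco2`, `bbb`; any of the last six may be
#' `NA`. Flags are tri-state (TRUE / FALSE / unknown) and unknowns are
#' excluded from co-satisfaction denominators rather than counted as
#' failures.
#'
#' @param path Path to the TSV file.
#' @return Data.frame of `chemical_records`: descriptors numeric, flags
#'   logical with NA for unknown.
#' @export
read_chemical_table <- function(path) {
  df <- read_tsv(path)
  if (!"phytochemical_id" %in% names(df))
    stop("chemical table needs a phytochemical_id column", call. = FALSE)
  for (col in c("mw", "alogp", "hbd", "hba", "rotb"))
    if (col %in% names(df)) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  for (col in c("hia", "caco2", "bbb"))
    if (col %in% names(df)) df[[col]] <- parse_flag(df[[col]])
  if (any(!is.na(df$mw) & df$mw <= 0))
    stop("molecular weight must be positive", call. = FALSE)
  cnt <- c("hbd", "hba", "rotb")
  for (col in intersect(cnt, names(df)))
    if (any(!is.na(df[[col]]) & df[[col]] < 0))
      stop(col, " must be a non-negative count", call. = FALSE)
  class(df) <- c("chemical_records", "data.frame")
  df
}

#' Descriptor backend backed by a precomputed table
#'
#' The default descriptor source: a table of precomputed values (e.g. from an
#' external descriptor calculator) keyed by SMILES or compound ID. Always
#' available; a missing row is an error, mirroring an unparseable structure.
#'
#' @param table Data.frame with a `key` column plus `mw`, `alogp`, `hbd`,
#'   `hba`, `rotb`.
#' @return A descriptor backend object.
#' @export
descriptor_table_backend <- function(table) {
  stopifnot(is.data.frame(table), "key" %in% names(table))
  need <- c("mw", "alogp", "hbd", "hba", "rotb")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("descriptor table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(list(name = "table", version = "1", table = table),
            class = c("descriptor_backend_table", "descriptor_backend"))
}

#' Descriptor backend using Open Babel (via ChemmineR/ChemmineOB)
#'
#' Computes molecular weight, logP, hydrogen-bond donors/acceptors and
#' rotatable bonds from SMILES. Requires the suggested ChemmineR and
#' ChemmineOB packages. Descriptor conventions (e.g. which atoms count as
#' acceptors) are Open Babel's; the backend name and version are recorded so
#' outputs carry their provenance.
#'
#' @return A descriptor backend object.
#' @export
descriptor_openbabel_backend <- function() {
  for (pkg in c("ChemmineR", "ChemmineOB"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("the openbabel backend needs the ", pkg, " package", call. = FALSE)
  structure(list(name = "openbabel",
                 version = as.character(utils::packageVersion("ChemmineOB"))),
            class = c("descriptor_backend_openbabel", "descriptor_backend"))
}

#' Compute physicochemical descriptors for SMILES strings
#'
#' @param smiles Character vector of SMILES (or table keys for the table
#'   backend).
#' @param backend A descriptor backend; see [descriptor_table_backend()] and
#'   [descriptor_openbabel_backend()].
#' @return Data.frame with columns `key`, `mw`, `alogp`, `hbd`, `hba`,
#'   `rotb`, and attribute `backend` recording name/version.
#' @export
compute_descriptors <- function(smiles, backend) {
  UseMethod("compute_descriptors", backend)
}

#' @export
compute_descriptors.descriptor_backend_table <- function(smiles, backend) {
  idx <- match(smiles, backend$table$key)
  if (anyNA(idx))
    stop("no precomputed descriptors for: ",
         paste(utils::head(smiles[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  out <- backend$table[idx, c("key", "mw", "alogp", "hbd", "hba", "rotb")]
  rownames(out) <- NULL
  attr(out, "backend") <- paste0(backend$name, "/", backend$version)
  out
}

# SMARTS for single, acyclic, non-terminal bonds not adjacent to a triple
# bond; matched both directions, hence the division by two.
ROTB_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' @export
compute_descriptors.descriptor_backend_openbabel <- function(smiles, backend) {
  out <- data.frame(key = smiles, mw = NA_real_, alogp = NA_real_,
                    hbd = NA_real_, hba = NA_real_, rotb = NA_real_)
  for (k in seq_along(smiles)) {
    rec <- tryCatch({
      sdf <- suppressWarnings(
        ChemmineR::smiles2sdf(stats::setNames(smiles[k], "q")))
      props <- ChemmineR::propOB(sdf)
      rb <- ChemmineR::smartsSearchOB(sdf, ROTB_SMARTS,
                                      uniqueMatches = FALSE) / 2
      c(props$MW[1L], props$logP[1L], props$HBD[1L], props$HBA2[1L], rb[[1L]])
    }, error = function(e) {
      message("skipping unparseable SMILES '", smiles[k], "': ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) out[k, 2:6] <- rec
  }
  attr(out, "backend") <- paste0(backend$name, "/", backend$version)
  out
}

#' Count Lipinski rule-of-five violations
#'
#' The four Lipinski criteria: molecular weight <= 500 Da, AlogP <= 5,
#' hydrogen-bond donors <= 5, hydrogen-bond acceptors <= 10.
#'
#' @param mw,alogp,hbd,hba Numeric vectors (recycled).
#' @return Integer vector of violation counts (NA if any input is NA).
#' @export
ro5_violations <- function(mw, alogp, hbd, hba) {
  as.integer(mw > 500) + as.integer(alogp > 5) +
    as.integer(hbd > 5) + as.integer(hba > 10)
}

#' Lipinski rule-of-five compliance
#'
#' A compound satisfies the rule of five when it violates at most one of the
#' four criteria — Lipinski's published convention; stricter readings
#' (zero violations) can be requested via `max_violations = 0`. A record
#' with any missing descriptor is `NA` (unknown), never `FALSE`.
#'
#' @param records A `chemical_records` data.frame (or any data.frame with
#'   `mw`, `alogp`, `hbd`, `hba`).
#' @param max_violations Maximum violations still counted as compliant;
#'   default 1.
#' @return Logical vector (with NA for unknown), one element per record.
#' @export
ro5_compliant <- function(records, max_violations = 1L) {
  stopifnot(all(c("mw", "alogp", "hbd", "hba") %in% names(records)))
  ro5_violations(records$mw, records$alogp, records$hbd, records$hba) <=
    max_violations
}

#' Surrogate physiological-availability predictor
#'
#' A deliberately simple logistic rule on molecular weight and AlogP that
#' stands in for external absorption/permeability classifiers so the
#' pipeline can run end to end on synthetic fixtures. It is a synthetic
#' surrogate for demonstration — not a validated ADMET model — and real
#' analyses should supply precomputed flags instead.
#'
#' @param records Data.frame with `mw` and `alogp`.
#' @param property One of `"hia"`, `"caco2"`, `"bbb"`.
#' @return Logical vector (NA where descriptors are missing).
#' @export
predict_availability <- function(records, property = c("hia", "caco2", "bbb")) {
  property <- match.arg(property)
  stopifnot(all(c("mw", "alogp") %in% names(records)))
  # intercept / mw / alogp coefficients per property: smaller, moderately
  # lipophilic molecules absorb and permeate more readily; BBB is strictest
  # on size and favours higher lipophilicity
  coefs <- switch(property,
                  hia = c(6.0, -0.012, 0.30),
                  caco2 = c(4.5, -0.010, 0.25),
                  bbb = c(4.0, -0.012, 0.50))
  score <- coefs[1L] + coefs[2L] * records$mw + coefs[3L] * records$alogp
  stats::plogis(score) > 0.5
}

#' Fill unknown availability flags with surrogate predictions
#'
#' Only unknown (NA) `hia`, `caco2`, `bbb` entries are filled; supplied flags
#' are never overwritten. RO5 compliance is (re)computed from descriptors
#' into a `ro5` column.
#'
#' @param records A `chemical_records` data.frame.
#' @return The records with `ro5` added and flag gaps filled.
#' @export
annotate_availability <- function(records) {
  records$ro5 <- ro5_compliant(records)
  for (prop in c("hia", "caco2", "bbb")) {
    if (is.null(records[[prop]])) records[[prop]] <- NA
    gap <- is.na(records[[prop]])
    if (any(gap))
      records[[prop]][gap] <- predict_availability(records[gap, , drop = FALSE],
                                                   prop)
  }
  records
}

#' Co-satisfaction counts of availability properties
#'
#' Counts how many compounds satisfy each of RO5, HIA, Caco-2 and BBB
#' (diagonal) and each pair of them jointly (off-diagonal). Records with an
#' unknown flag are excluded from every cell involving that property, so an
#' unknown is neither a pass nor a failure.
#'
#' @param records Data.frame with logical columns `ro5`, `hia`, `caco2`,
#'   `bbb` (see [annotate_availability()]).
#' @return Symmetric 4x4 integer matrix with dimnames
#'   `RO5, HIA, Caco-2, BBB`.
#' @export
cosatisfaction_table <- function(records) {
  cols <- c(RO5 = "ro5", HIA = "hia", `Caco-2` = "caco2", BBB = "bbb")
  miss <- setdiff(unname(cols), names(records))
  if (length(miss))
    stop("records lack flag column(s): ", paste(miss, collapse = ", "),
         " — run annotate_availability() first", call. = FALSE)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  m <- matrix(0L, 4L, 4L, dimnames = list(names(cols), names(cols)))
  for (a in 1:4) {
    for (b in a:4) {
      fa <- records[[cols[[a]]]]
      fb <- records[[cols[[b]]]]
      m[a, b] <- m[b, a] <- sum(fa & fb, na.rm = TRUE)
    }
  }
  m
}
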