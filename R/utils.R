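# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-entity seed from a master seed
#'
#' Hashes an identifier string into the master seed so that every
#' phytochemical gets its own deterministic RNG stream while the whole run is
#' controlled by a single integer. The result always fits in a 32-bit signed
#' integer.
#'
#' @param master_seed Integer master seed for the run.
#' @param id Character scalar, e.g. a phytochemical identifier.
#' @return A positive integer seed, strictly below 2^31.
#' @export
derive_seed <- function(master_seed, id) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(id), length(id) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime: good modulus for a rolling hash
  h <- as.double(master_seed) %% m
  for (code in utf8ToInt(id)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# user's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Read a TSV with stable types; no factor conversion, keeps "" as NA.
read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""), ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Tri-state logical parser: "TRUE"/"T"/"1"/"yes" -> TRUE, analogous FALSE,
# anything missing -> NA.
parse_flag <- function(x) {
  out <- rep(NA, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[lx %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}
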