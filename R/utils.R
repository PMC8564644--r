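# Internal helpers shared across modules.

#' Derive a reproducible 31-bit seed from a master seed and a string key
#'
#' Used so that every sample gets its own deterministic random stream derived
#' from one master seed: results for a sample do not depend on the order in
#' which samples are processed.
#'
#' @param master integer master seed.
#' @param key character scalar (e.g. a sample id).
#' @return an integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master), length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- (abs(as.numeric(master)) * 48271) %% m
  for (cp in utf8ToInt(as.character(key))) {
    h <- (h * 131 + cp) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` with a temporary RNG state seeded by `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Canonical timepoint labels in study order; unknown labels keep their
# first-appearance order after the known ones.
TIMEPOINT_LEVELS <- c("baseline", "radiotherapy", "cycle7", "cycle18", "progression")

#' Order timepoint labels
#'
#' Sorts labels by the canonical study schedule (baseline, radiotherapy,
#' cycle7, cycle18, progression); labels outside the schedule follow in
#' first-appearance order.
#'
#' @param x character vector of timepoint labels.
#' @return `x` reordered.
#' @export
order_timepoints <- function(x) {
  x <- as.character(x)
  known <- x[x %in% TIMEPOINT_LEVELS]
  known <- known[order(match(known, TIMEPOINT_LEVELS))]
  c(known, unique(x[!x %in% TIMEPOINT_LEVELS]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
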