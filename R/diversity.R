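# Renyi diversity profiles and Shannon diversity, with depth-normalizing
# read subsampling (rarefaction) and the per-patient diversity-change rule.
#
# H(alpha) = 1/(1 - alpha) * ln sum_i p_i^alpha for alpha not in {1, Inf};
# H(1) is the Shannon index -sum p_i ln p_i (the alpha -> 1 limit);
# H(0) = ln S (log richness); H(Inf) = -ln max p_i (dominance).
# All values are in natural-log units (nats). Frequencies p_i are over
# amino-acid clonotypes: nucleotide variants sharing an amino-acid CDR3 are
# summed first.

#' Default Rényi order grid
#'
#' The conventional diversity-profile scale `{0, 0.25, 0.5, 1, 2, 4, 8, 16,
#' 32, 64, Inf}` used by ecological diversity software.
#'
#' @return a numeric vector of alpha values.
#' @export
renyi_alphas <- function() c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, Inf)

# Renyi entropy of a frequency vector for one alpha, computed stably:
# ln sum p^a = a*ln(pmax) + ln sum (p/pmax)^a avoids underflow at large alpha.
renyi_h <- function(p, alpha) {
  p <- p[p > 0]
  if (length(p) == 0) stop("no positive frequencies", call. = FALSE)
  if (alpha == 0) return(log(length(p)))
  if (alpha == 1) return(-sum(p * log(p)))
  if (is.infinite(alpha)) return(-log(max(p)))
  pmax <- max(p)
  lse <- alpha * log(pmax) + log(sum((p / pmax)^alpha))
  lse / (1 - alpha)
}

renyi_from_counts <- function(counts, alphas) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  vapply(alphas, renyi_h, numeric(1), p = p)
}

new_renyi_profile <- function(alphas, H, depth, permutations, sample_id) {
  structure(
    tibble::tibble(alpha = alphas, H = H),
    depth = depth, permutations = permutations, sample_id = sample_id,
    class = c("renyi_profile", class(tibble::tibble())))
}

#' Rényi diversity profile of a repertoire
#'
#' Computes the full-sample Rényi diversity H(alpha) over a grid of orders,
#' on amino-acid clonotype frequencies (nucleotide variants aggregated
#' first). alpha = 0 gives log richness ln S, alpha = 1 the Shannon index,
#' and alpha = Inf the negative log frequency of the most abundant clone;
#' increasing alpha weights abundant clones more heavily, so H(alpha) is
#' non-increasing in alpha.
#'
#' @param rep a [repertoire()] (or a bare numeric count vector).
#' @param alphas ordered grid of Rényi orders; default [renyi_alphas()].
#' @param level clonotype level: `"aa"` (default) or `"nt"`.
#' @return a `renyi_profile`: a tibble with columns `alpha`, `H` (nats) and
#'   attributes `depth` (`"full"` here), `permutations`, `sample_id`.
#' @export
renyi_profile <- function(rep, alphas = renyi_alphas(), level = "aa") {
  counts <- if (is.numeric(rep)) rep else clone_counts(rep, level = level)
  if (sum(counts > 0) == 0) stop("empty repertoire", call. = FALSE)
  alphas <- sort(unique(as.numeric(alphas)))
  new_renyi_profile(alphas, renyi_from_counts(counts, alphas),
                    depth = "full", permutations = NA_integer_,
                    sample_id = if (is_repertoire(rep)) rep$sample_id else NA_character_)
}

# One multivariate-hypergeometric draw of `depth` reads from integer counts:
# sample read indices without replacement, map them back to clones via the
# cumulative count boundaries.
subsample_counts <- function(counts, depth) {
  total <- sum(counts)
  if (depth == total) return(counts)
  reads <- sample.int(total, depth)
  cum <- cumsum(counts)
  tabulate(findInterval(reads - 1L, cum) + 1L, nbins = length(counts))
}

#' Depth-normalized Rényi profile by read subsampling
#'
#' Controls for library-size differences between samples: each permutation
#' draws exactly `depth` reads without replacement from the sample's read
#' pool (a multivariate hypergeometric draw on clone counts), a Rényi profile
#' is computed on the drawn counts, and the profiles are averaged
#' arithmetically over permutations. Defaults follow common practice for
#' bulk TCR-beta repertoires: 70 000 reads and 500 permutations.
#'
#' @inheritParams renyi_profile
#' @param depth number of reads per permutation (default 70000).
#' @param permutations number of repetitions averaged (default 500).
#' @param seed master seed; the sample's stream is derived deterministically
#'   from `(seed, sample_id)`, so results do not depend on processing order.
#' @param on_short what to do when `total_count < depth`: `"error"` (default)
#'   or `"full"` (compute on the full sample, with a warning).
#' @return a `renyi_profile` tibble with `depth` and `permutations`
#'   attributes set.
#' @export
subsampled_renyi <- function(rep, depth = 70000, permutations = 500,
                             seed = 1, alphas = renyi_alphas(), level = "aa",
                             on_short = c("error", "full")) {
  on_short <- match.arg(on_short)
  counts <- if (is.numeric(rep)) rep else clone_counts(rep, level = level)
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty repertoire", call. = FALSE)
  stopifnot(depth >= 1, permutations >= 1)
  alphas <- sort(unique(as.numeric(alphas)))
  sample_id <- if (is_repertoire(rep)) rep$sample_id else "counts"
  total <- sum(counts)
  if (total < depth) {
    if (on_short == "error") {
      stop("sample '", sample_id, "' has ", total,
           " reads, fewer than the subsampling depth ", depth,
           " (set on_short = \"full\" to compute on the full sample)",
           call. = FALSE)
    }
    warning("sample '", sample_id, "' has ", total, " < ", depth,
            " reads; computing on the full sample", call. = FALSE)
    out <- renyi_profile(counts, alphas = alphas)
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  H <- with_seed(derive_seed(seed, sample_id), {
    acc <- numeric(length(alphas))
    for (r in seq_len(permutations)) {
      drawn <- subsample_counts(counts, depth)
      acc <- acc + renyi_from_counts(drawn, alphas)
    }
    acc / permutations
  })
  new_renyi_profile(alphas, H, depth = depth, permutations = permutations,
                    sample_id = sample_id)
}

#' Shannon diversity index
#'
#' `-sum(p_i * log(p_i))` over amino-acid clonotype frequencies; identical to
#' the Rényi profile at alpha = 1.
#'
#' @inheritParams renyi_profile
#' @return a single numeric value in nats.
#' @export
shannon <- function(rep, level = "aa") {
  counts <- if (is.numeric(rep)) rep else clone_counts(rep, level = level)
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty repertoire", call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Classify a diversity change against baseline
#'
#' A follow-up Shannon value is called `unchanged` when its relative
#' deviation from baseline, `|current - baseline| / baseline`, is within the
#' threshold (default 1%); otherwise the sign of the difference gives
#' `increased` or `decreased`. Both values should come from
#' [subsampled_renyi()] at alpha = 1 with identical depth and permutations so
#' that library size cannot masquerade as a diversity change.
#'
#' @param baseline_H,current_H Shannon diversity values (nats).
#' @param threshold relative-deviation threshold (default 0.01). A deviation
#'   exactly at the threshold is called unchanged.
#' @return a one-row tibble of class `diversity_change` with columns
#'   `baseline_H`, `current_H`, `relative_deviation`, `call`.
#' @export
classify_diversity_change <- function(baseline_H, current_H, threshold = 0.01) {
  stopifnot(is.finite(baseline_H), is.finite(current_H), threshold > 0)
  if (baseline_H <= 0) {
    stop("undefined relative change: baseline Shannon diversity is ",
         baseline_H, call. = FALSE)
  }
  rel <- abs(current_H - baseline_H) / baseline_H
  call <- if (rel <= threshold) "unchanged"
          else if (current_H > baseline_H) "increased" else "decreased"
  structure(
    tibble::tibble(baseline_H = baseline_H, current_H = current_H,
                   relative_deviation = rel,
                   call = factor(call, levels = c("decreased", "unchanged", "increased"))),
    class = c("diversity_change", class(tibble::tibble())))
}
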