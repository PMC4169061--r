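# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a root seed
#'
#' All randomness in the package flows from a single root seed. Each named
#' stage draws its own sub-seed as `(root + 104729 * stream) mod (2^31 - 1)`
#' (104729 is the 10,000th prime), so stages are decoupled: changing the
#' number of random draws in one stage does not perturb any other stage.
#'
#' @param seed integer root seed.
#' @param stream integer stream index (each pipeline stage has a fixed one).
#' @return An integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((as.numeric(seed) + 104729 * as.numeric(stream)) %% (2^31 - 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around [stats::p.adjust()] with the missing-value policy used
#' throughout the pipeline: `NA`/`NaN` inputs propagate as `NA` and are
#' excluded from the number of tests `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# match subject ids between two tables, erroring informatively
.match_ids <- function(x, y, what) {
  idx <- match(x, y)
  if (anyNA(idx)) {
    stop(sprintf("%d %s ids have no match (first: %s)",
                 sum(is.na(idx)), what, x[which(is.na(idx))[1L]]))
  }
  idx
}
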