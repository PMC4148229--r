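# Internal helpers shared across modules.

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans into a recombination
#' fraction under the Haldane (no-interference) model,
#' r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM Numeric vector of genetic distances in centimorgans.
#' @return Recombination fractions in `[0, 0.5)`.
#' @examples
#' haldane(c(0, 1, 10, 1000))
#' @export
haldane <- function(d_cM) {
  if (any(d_cM < 0)) stop("genetic distances must be non-negative")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's
#' RNG state afterwards. Every stochastic operation in the package
#' routes its `seed` argument through this helper, so nothing perturbs
#' or depends on global RNG state.
#'
#' @param seed Single integer, or `NULL` to run unseeded.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Hashes a stage label together with a master seed into a stable 31-bit
#' integer, so a single pipeline seed fans out to independent, reproducible
#' per-stage seeds.
#'
#' @param master Master seed (single integer).
#' @param stage Character stage label.
#' @return A single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- as.double(master) %% 2147483647
  for (k in utf8ToInt(stage)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

# -log10 of an F-test upper tail, computed in log space so that very
# strong signals do not underflow to Inf/0. A perfect fit (infinite F)
# maps to +Inf; callers cap at their own ceiling.
neglog10_pf <- function(f, df1, df2) {
  out <- rep(0, length(f))
  ok <- is.finite(f) & df1 > 0 & df2 > 0
  out[ok] <- -stats::pf(f[ok], df1[ok], df2[ok],
                        lower.tail = FALSE, log.p = TRUE) / log(10)
  out[is.infinite(f) & f > 0 & df1 > 0 & df2 > 0] <- Inf
  out
}

# Split line indices by family, preserving family level order.
family_indices <- function(families) {
  f <- as.factor(families)
  split(seq_along(f), f)
}
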