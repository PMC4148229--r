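# Parent-of-origin calling with Viterbi error correction.
#
# Low-coverage genotyping-by-sequencing data miscalls most heterozygous
# sites as homozygotes and leaves many sites missing. Calls are therefore
# re-scored against a three-state hidden Markov model along each
# chromosome (reference homozygote, heterozygote, alternate homozygote)
# whose transitions follow the genetic map and whose emissions model
# per-allele call errors and heterozygote dropout.

#' Construct a parent-of-origin HMM
#'
#' @param eps Per-allele call error rate (default 0.005).
#' @param het_dropout Probability that a true heterozygote is scored as a
#'   homozygote (default 0.8, the dropout level typical of ~0.5x coverage
#'   data).
#' @param selfing Selfing depth of the lines; sets the stationary
#'   heterozygote frequency `0.5^selfing` and the distance decay of
#'   heterozygous tracts.
#' @return A `parent_hmm` object.
#' @export
parent_hmm <- function(eps = 0.005, het_dropout = 0.8, selfing = 6) {
  if (eps < 0 || eps > 1 || het_dropout < 0 || het_dropout > 1) {
    stop("eps and het_dropout must be in [0, 1]")
  }
  structure(list(eps = eps, het_dropout = het_dropout, selfing = selfing,
                 p_het = 0.5 ^ selfing),
            class = "parent_hmm")
}

#' Emission matrix of a parent-of-origin HMM
#'
#' Rows are hidden states (REF, HET, ALT), columns observed calls
#' (0, 1, 2). A homozygous state emits the correct call with probability
#' `1 - eps` and either wrong call with probability `eps/2`; a
#' heterozygous state drops out to one of the homozygous calls with
#' probability `het_dropout` (split evenly). Each row sums to one;
#' missing observations are handled by the decoder with likelihood 1 in
#' every state.
#'
#' @param hmm A [parent_hmm()].
#' @return A 3 x 3 probability matrix.
#' @export
hmm_emission <- function(hmm) {
  e <- hmm$eps
  d <- hmm$het_dropout
  mat <- rbind(REF = c(1 - e, e / 2, e / 2),
               HET = c(d / 2, 1 - d, d / 2),
               ALT = c(e / 2, e / 2, 1 - e))
  colnames(mat) <- c("0", "1", "2")
  mat
}

#' Transition matrix between two markers of an HMM
#'
#' Parent-of-origin switches follow the Haldane recombination fraction of
#' the inter-marker distance; heterozygous tracts persist with probability
#' `(1-r)^(2*selfing)` and are entered so that the chain's stationary
#' heterozygote frequency is `0.5^selfing`.
#'
#' @param hmm A [parent_hmm()].
#' @param d_cM Inter-marker distance in centimorgans.
#' @return A 3 x 3 row-stochastic matrix over states (REF, HET, ALT).
#' @export
hmm_transition <- function(hmm, d_cM) {
  r <- haldane(d_cM)
  p <- hmm$p_het
  a <- (1 - r) ^ (2 * hmm$selfing)
  stay_het <- a + (1 - a) * p
  enter_het <- (1 - a) * p
  mat <- rbind(REF = c((1 - enter_het) * (1 - r), enter_het,
                       (1 - enter_het) * r),
               HET = c((1 - stay_het) / 2, stay_het, (1 - stay_het) / 2),
               ALT = c((1 - enter_het) * r, enter_het,
                       (1 - enter_het) * (1 - r)))
  colnames(mat) <- rownames(mat)
  mat
}

# Viterbi decode one observation sequence (values 0/1/2/NA).
# log_em: 3 x 3 log emission; log_tr: list of 3 x 3 log transitions per
# interval; log_init: length-3 log initial distribution.
# Ties in the backtrack are broken toward staying in the same state.
viterbi_path <- function(obs, log_em, log_tr, log_init) {
  m <- length(obs)
  delta <- matrix(-Inf, 3, m)
  ptr <- matrix(0L, 3, m)
  emit <- function(t) if (is.na(obs[t])) c(0, 0, 0) else log_em[, obs[t] + 1L]
  delta[, 1L] <- log_init + emit(1L)
  if (m > 1L) {
    for (t in 2:m) {
      et <- emit(t)
      A <- log_tr[[t - 1L]]
      for (j in 1:3) {
        v <- delta[, t - 1L] + A[, j]
        best <- max(v)
        cand <- which(v >= best - 1e-12)
        ptr[j, t] <- if (j %in% cand) j else cand[1L]
        delta[j, t] <- best + et[j]
      }
    }
  }
  path <- integer(m)
  v <- delta[, m]
  cand <- which(v >= max(v) - 1e-12)
  path[m] <- cand[1L]
  if (m > 1L) for (t in (m - 1L):1L) path[t] <- ptr[path[t + 1L], t + 1L]
  path - 1L   # dosage coding 0/1/2
}

#' Correct raw genotype calls with the Viterbi algorithm
#'
#' Decodes, per line and chromosome, the maximum a-posteriori state path
#' under the parent-of-origin HMM. Missing calls contribute likelihood 1
#' in every state; computation is in the log domain.
#'
#' @param raw Matrix of raw calls in {0, 1, 2, NA}, lines x markers,
#'   columns aligned with `map`.
#' @param map A [genetic_map()] sorted within chromosomes.
#' @param hmm A [parent_hmm()].
#' @return List with `states` (lines x markers dosage matrix in {0,1,2})
#'   and `all_missing` (logical lines x chromosomes flag matrix: those
#'   paths are the prior-most-likely states).
#' @export
viterbi_correct <- function(raw, map, hmm = parent_hmm()) {
  stopifnot(ncol(raw) == nrow(map))
  chrom_idx <- map_chrom_index(map)
  log_em <- log(hmm_emission(hmm))
  p <- hmm$p_het
  log_init <- log(c((1 - p) / 2, p, (1 - p) / 2))
  states <- matrix(0L, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  all_missing <- matrix(FALSE, nrow(raw), length(chrom_idx),
                        dimnames = list(rownames(raw), names(chrom_idx)))
  for (ci in seq_along(chrom_idx)) {
    idx <- chrom_idx[[ci]]
    d <- diff(map$cM[idx])
    log_tr <- lapply(d, function(x) log(hmm_transition(hmm, x)))
    for (i in seq_len(nrow(raw))) {
      obs <- raw[i, idx]
      if (all(is.na(obs))) {
        all_missing[i, ci] <- TRUE
      }
      states[i, idx] <- viterbi_path(obs, log_em, log_tr, log_init)
    }
  }
  if (any(all_missing)) {
    warning(sum(all_missing),
            " line-chromosome(s) had no non-missing calls; their paths ",
            "are the prior-most-likely states")
  }
  list(states = states, all_missing = all_missing)
}
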