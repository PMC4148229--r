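# Digenic epistasis scan over a thinned marker grid.

#' Select a marker subset at uniform genetic spacing
#'
#' Picks, per chromosome, the marker nearest to each multiple of
#' `spacing_cM`, without duplicates; mirrors the thinning used to make an
#' all-pairs interaction scan tractable.
#'
#' @param map A [genetic_map()].
#' @param spacing_cM Target spacing in cM (default 1).
#' @return Integer vector of marker column indices.
#' @export
thin_markers <- function(map, spacing_cM = 1) {
  out <- integer(0)
  for (idx in map_chrom_index(map)) {
    cm <- map$cM[idx]
    targets <- seq(min(cm), max(cm), by = spacing_cM)
    pick <- vapply(targets, function(t) idx[which.min(abs(cm - t))],
                   integer(1))
    out <- c(out, unique(pick))
  }
  out
}

#' Scan marker pairs for digenic epistasis
#'
#' For every pair of subset markers, tests the family-nested
#' marker-by-marker interaction on top of a model with family main
#' effects and the two markers' nested main effects. Pairs whose
#' interaction beats `scan_threshold` are then each added (with their
#' main effects) to the final additive joint-linkage model, and the
#' interaction is re-tested there; the full-model p decides whether the
#' epistatic term improves on the additive model.
#'
#' @inheritParams joint_stepwise
#' @param subset Marker column indices to pair up (e.g. from
#'   [thin_markers()]).
#' @param scan_threshold Initial filter on the scan -log10 p (a
#'   permutation threshold in the original analysis).
#' @param model Final additive `jl_model` (or `NULL` for a bare family
#'   model) for the confirmation test.
#' @param full_alpha Significance level for the full-model interaction
#'   test.
#' @return Data frame: `m1`, `m2` (column indices), `scan_nlp`,
#'   `full_nlp` (`NA` unless the pair passed the initial filter), and
#'   `pass` (interaction significant in the full model).
#' @export
epistasis_scan <- function(y, G, families, subset, scan_threshold,
                           model = NULL, full_alpha = 0.05) {
  subset <- unique(subset)
  if (length(subset) < 2L) stop("need at least two subset markers")
  pairs <- utils::combn(subset, 2L)
  n <- length(y)
  fidx <- family_indices(families)
  # residualise y and the subset dosages on family intercepts once
  ry <- numeric(n)
  Gc <- G[, subset, drop = FALSE]
  for (idx in fidx) {
    ry[idx] <- y[idx] - mean(y[idx])
    Gc[idx, ] <- sweep(Gc[idx, , drop = FALSE], 2L,
                       colMeans(Gc[idx, , drop = FALSE]))
  }
  scan_nlp <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- match(pairs[1L, k], subset)
    j <- match(pairs[2L, k], subset)
    x12 <- G[, pairs[1L, k]] * G[, pairs[2L, k]]
    scan_nlp[k] <- nested_interaction_nlp(ry, Gc[, i], Gc[, j], x12,
                                          fidx, n)
  }
  full_nlp <- rep(NA_real_, ncol(pairs))
  cand <- which(scan_nlp > scan_threshold)
  base <- if (is.null(model)) integer(0) else model$selected
  for (k in cand) {
    full_nlp[k] <- interaction_full_nlp(y, G, families, base,
                                        pairs[1L, k], pairs[2L, k])
  }
  data.frame(m1 = pairs[1L, ], m2 = pairs[2L, ],
             scan_nlp = scan_nlp, full_nlp = full_nlp,
             pass = !is.na(full_nlp) & full_nlp >= -log10(full_alpha))
}

# Interaction test given family-centred main-effect columns: compares the
# family-nested [x1, x2] model to [x1, x2, x1*x2], per-family slopes with
# pooled error (Frisch-Waugh on the family intercepts).
nested_interaction_nlp <- function(ry, x1c, x2c, x12, fidx, n) {
  sse_add <- 0; sse_full <- 0
  df_add <- 0; df_full <- 0
  for (idx in fidx) {
    Xa <- cbind(x1c[idx], x2c[idx])
    Xf <- cbind(Xa, x12[idx] - mean(x12[idx]))
    qa <- qr(Xa); qf <- qr(Xf)
    sse_add <- sse_add + sum(qr.resid(qa, ry[idx])^2)
    sse_full <- sse_full + sum(qr.resid(qf, ry[idx])^2)
    df_add <- df_add + qa$rank + 1L        # +1 for the family intercept
    df_full <- df_full + qf$rank + 1L
  }
  q <- df_full - df_add
  df2 <- n - df_full
  if (q <= 0 || df2 <= 0) return(0)
  f <- ((sse_add - sse_full) / q) / pmax(sse_full / df2,
                                         .Machine$double.xmin)
  pmin(neglog10_pf(f, q, df2), 350)
}

# Full-model confirmation: interaction nested in families, added together
# with both markers' nested main effects to the final additive model.
interaction_full_nlp <- function(y, G, families, base, m1, m2) {
  extra <- cbind(G[, m1], G[, m2], G[, m1] * G[, m2])
  rs <- jl_residualise(y, extra, G, families, base)
  fidx <- family_indices(families)
  n <- length(y)
  sse_add <- 0; sse_full <- 0; rank_add <- rs$rank_base
  rank_full <- rs$rank_base
  for (idx in fidx) {
    Xa <- rs$RX[idx, 1:2, drop = FALSE]
    Xf <- rs$RX[idx, , drop = FALSE]
    qa <- qr(Xa); qf <- qr(Xf)
    sse_add <- sse_add + sum(qr.resid(qa, rs$ry[idx])^2)
    sse_full <- sse_full + sum(qr.resid(qf, rs$ry[idx])^2)
    rank_add <- rank_add + qa$rank
    rank_full <- rank_full + qf$rank
  }
  q <- rank_full - rank_add
  df2 <- n - rank_full
  if (q <= 0 || df2 <= 0) return(0)
  f <- ((sse_add - sse_full) / q) / pmax(sse_full / df2,
                                         .Machine$double.xmin)
  pmin(neglog10_pf(f, q, df2), 350)
}
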