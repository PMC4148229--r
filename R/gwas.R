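# Residual-based genome-wide association with subagging and RMIP.

#' Chromosome-wise residual phenotypes
#'
#' Refits the joint linkage model omitting every selected marker on the
#' focal chromosome (family effects retained) and returns the residuals.
#' These residuals are orthogonal to all retained model columns, so dense
#' variants on the focal chromosome are tested free of background QTL on
#' other chromosomes.
#'
#' @inheritParams joint_stepwise
#' @param model A `jl_model`.
#' @param chrom Focal chromosome label.
#' @return Named numeric vector of residuals (family means removed).
#' @export
chromosome_residuals <- function(model, y, G, map, families, chrom) {
  keep <- model$selected[map$chrom[model$selected] != as.character(chrom)]
  fidx <- family_indices(families)
  res <- numeric(length(y))
  for (idx in fidx) {
    Xb <- cbind(rep(1, length(idx)), if (length(keep)) G[idx, keep, drop = FALSE])
    res[idx] <- qr.resid(qr(Xb), y[idx])
  }
  names(res) <- names(y)
  res
}

#' Forward selection over dense projected variants
#'
#' Forward regression of residual phenotypes on dense-variant dosages,
#' one across-population slope per variant on top of family main effects
#' (projected dosages already encode founder origin). A variant enters
#' while its p-value is below `p_enter`; selection stops otherwise.
#'
#' @param residuals Residual phenotypes (family effects already removed,
#'   as from [chromosome_residuals()]).
#' @param dense Lines x variants projected dosage matrix (focal
#'   chromosome).
#' @param families Family label per line.
#' @param p_enter Entry p-value threshold (default 1e-6).
#' @param max_steps Cap on selected variants.
#' @return Data frame `variant` (column index), `nlp` (-log10 p at
#'   entry), `effect` (slope in the final model).
#' @export
forward_select_dense <- function(residuals, dense, families,
                                 p_enter = 1e-6, max_steps = 25) {
  fidx <- family_indices(families)
  n <- length(residuals)
  nfam <- length(fidx)
  r <- residuals
  for (idx in fidx) r[idx] <- r[idx] - mean(r[idx])
  # family-centred column sums of squares without materialising the
  # centred matrix: ssxx_j = sum x^2 - sum_f n_f mean_f^2
  fam <- factor(as.character(families))
  fam_sums <- rowsum(dense, fam)
  fam_n <- as.numeric(table(fam))
  ssxx <- colSums(dense^2) - colSums(fam_sums^2 / fam_n)
  ssxx <- pmax(ssxx, 0)
  sel <- integer(0)
  nlp_at_entry <- numeric(0)
  # running centred copies of selected columns for orthogonalisation
  Vc <- matrix(0, n, 0)
  repeat {
    ssxy <- as.numeric(crossprod(dense, r))   # r is family-centred
    ok <- ssxx > SEG_TOL * n
    ok[sel] <- FALSE
    if (!any(ok)) break
    num <- ssxy^2 / pmax(ssxx, .Machine$double.xmin)
    sse <- sum(r^2)
    df2 <- n - nfam - length(sel) - 1L
    if (df2 <= 0) break
    f <- num / pmax((sse - num) / df2, .Machine$double.xmin)
    nlp <- rep(-Inf, length(f))
    nlp[ok] <- pmin(neglog10_pf(f[ok], rep(1, sum(ok)),
                                rep(df2, sum(ok))), 350)
    best <- which.max(nlp)
    if (nlp[best] < -log10(p_enter) || length(sel) >= max_steps) break
    # centre the chosen column within families, orthogonalise against
    # previously selected ones, then sweep it out of the residual
    v <- dense[, best]
    for (idx in fidx) v[idx] <- v[idx] - mean(v[idx])
    if (ncol(Vc)) {
      for (k in seq_len(ncol(Vc))) {
        vk <- Vc[, k]
        v <- v - vk * sum(vk * v) / sum(vk^2)
      }
    }
    vss <- sum(v^2)
    if (vss <= SEG_TOL * n) break
    r <- r - v * sum(v * r) / vss
    # downdate remaining variants' centred sums of squares
    proj <- as.numeric(crossprod(dense, v))
    ssxx <- pmax(ssxx - proj^2 / vss, 0)
    Vc <- cbind(Vc, v)
    sel <- c(sel, best)
    nlp_at_entry <- c(nlp_at_entry, nlp[best])
  }
  effect <- rep(NA_real_, length(sel))
  if (length(sel)) {
    # joint refit of the selected variants for final effect estimates
    X <- dense[, sel, drop = FALSE]
    for (idx in fidx) {
      X[idx, ] <- sweep(X[idx, , drop = FALSE], 2L,
                        colMeans(X[idx, , drop = FALSE]))
    }
    rr <- residuals
    for (idx in fidx) rr[idx] <- rr[idx] - mean(rr[idx])
    effect <- as.numeric(qr.coef(qr(X), rr))
  }
  data.frame(variant = sel, nlp = nlp_at_entry, effect = effect)
}

#' Subagging GWAS with resample model inclusion probabilities
#'
#' Draws `n_subsamples` stratified subsamples of `fraction` of each
#' family's lines (without replacement), recomputes the focal
#' chromosome's residual phenotypes on each subsample, runs
#' [forward_select_dense()], and aggregates: RMIP is the proportion of
#' subsamples in which a variant entered the model; the reported p-value
#' and effect are means over the selecting subsamples. Records with RMIP
#' above `rmip_floor` are returned; the `robust` flag marks the
#' reporting threshold (0.25).
#'
#' @inheritParams joint_stepwise
#' @param model Final additive `jl_model` fitted on the full data.
#' @param dense Lines x variants projected dosage matrix with a
#'   `map`-like attribute or accompanying `dense_pos` data.frame
#'   (`variant`, `chrom`, `bp`) describing its columns.
#' @param dense_pos Data frame describing `dense` columns: `variant`,
#'   `chrom`, `bp`.
#' @param chroms Chromosomes to scan (default: all with dense variants).
#' @param n_subsamples Number of subsamples (default 100).
#' @param fraction Per-family subsampling fraction (default 0.8, rounded
#'   down, minimum 2 lines; smaller families are dropped for that
#'   subsample with a warning).
#' @param p_enter Forward-selection entry threshold (default 1e-6).
#' @param rmip_floor Retention floor on RMIP (default 0.05).
#' @param seed Integer seed; subsample memberships are derived from it
#'   and shared across chromosomes.
#' @return Data frame of association records: `variant`, `chrom`, `bp`,
#'   `rmip`, `mean_nlp`, `mean_effect`, `robust`.
#' @export
subagging_rmip <- function(y, model, G, map, families, dense, dense_pos,
                           chroms = unique(dense_pos$chrom),
                           n_subsamples = 100, fraction = 0.8,
                           p_enter = 1e-6, rmip_floor = 0.05, seed = 1) {
  stopifnot(nrow(dense_pos) == ncol(dense))
  fidx <- family_indices(families)
  subs <- with_seed(seed, {
    lapply(seq_len(n_subsamples), function(k) {
      take <- lapply(fidx, function(idx) {
        sz <- floor(fraction * length(idx))
        if (sz < 2L) {
          warning("family smaller than 2 after subsampling; dropped")
          return(integer(0))
        }
        sort(sample(idx, sz))
      })
      sort(unlist(take))
    })
  })
  count <- numeric(ncol(dense))
  sum_nlp <- numeric(ncol(dense))
  sum_eff <- numeric(ncol(dense))
  for (ch in chroms) {
    vcols <- which(dense_pos$chrom == as.character(ch))
    if (!length(vcols)) next
    for (k in seq_len(n_subsamples)) {
      rows <- subs[[k]]
      res <- chromosome_residuals(model, y[rows], G[rows, , drop = FALSE],
                                  map, families[rows], ch)
      hits <- forward_select_dense(res, dense[rows, vcols, drop = FALSE],
                                   families[rows], p_enter = p_enter)
      if (nrow(hits)) {
        cols <- vcols[hits$variant]
        count[cols] <- count[cols] + 1
        sum_nlp[cols] <- sum_nlp[cols] + hits$nlp
        sum_eff[cols] <- sum_eff[cols] + hits$effect
      }
    }
  }
  rmip <- count / n_subsamples
  keep <- which(rmip > rmip_floor)
  out <- data.frame(variant = dense_pos$variant[keep],
                    chrom = dense_pos$chrom[keep],
                    bp = dense_pos$bp[keep],
                    rmip = rmip[keep],
                    mean_nlp = sum_nlp[keep] / pmax(count[keep], 1),
                    mean_effect = sum_eff[keep] / pmax(count[keep], 1),
                    stringsAsFactors = FALSE)
  out$robust <- out$rmip >= 0.25
  out[order(match(out$chrom, unique(dense_pos$chrom)), out$bp), ]
}

#' Collapse clustered association records
#'
#' Single-linkage clustering of associated variants within `window_bp`
#' on each chromosome; nearby hits are assumed to tag the same causative
#' gene and the most significant member (highest RMIP, ties broken by
#' larger mean -log10 p then smaller bp) represents the cluster.
#'
#' @param records Association records from [subagging_rmip()].
#' @param window_bp Linkage window in bp (default 2000).
#' @return Data frame of clusters: representative `variant`, `chrom`,
#'   `bp`, `rmip`, `mean_nlp`, `mean_effect`, `n_members`, `span_bp`.
#' @export
collapse_clusters <- function(records, window_bp = 2000) {
  if (!nrow(records)) {
    return(data.frame(variant = character(0), chrom = character(0),
                      bp = numeric(0), rmip = numeric(0),
                      mean_nlp = numeric(0), mean_effect = numeric(0),
                      n_members = integer(0), span_bp = numeric(0)))
  }
  out <- list()
  for (ch in unique(records$chrom)) {
    sub <- records[records$chrom == ch, ]
    sub <- sub[order(sub$bp), ]
    cluster_id <- cumsum(c(1, diff(sub$bp) > window_bp))
    for (cl in unique(cluster_id)) {
      mem <- sub[cluster_id == cl, ]
      o <- order(-mem$rmip, -mem$mean_nlp, mem$bp)
      rep_row <- mem[o[1L], ]
      rep_row$n_members <- nrow(mem)
      rep_row$span_bp <- diff(range(mem$bp))
      out[[length(out) + 1L]] <- rep_row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
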