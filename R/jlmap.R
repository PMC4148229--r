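# Joint multi-family linkage mapping.

#' Family-nested single-marker test
#'
#' Partial F-test for adding one marker's family-nested term (one slope
#' per segregating family, relative to the common parent) to a model
#' containing family main effects and any `base` markers. A marker
#' monomorphic in every family returns p = 1 with a flag.
#'
#' @param y Named numeric vector of line trait values.
#' @param G Lines x markers dosage matrix in `[0, 2]`.
#' @param families Family label per line.
#' @param marker Column index of the marker to test.
#' @param base Column indices of markers already in the model.
#' @return List with `F`, `df1`, `df2`, `p`, `nlp` (-log10 p) and
#'   `monomorphic`.
#' @export
nested_marker_test <- function(y, G, families, marker, base = integer(0)) {
  sc <- jl_scan(y, G, families, base = base, candidates = marker)
  p <- if (sc$monomorphic) 1 else 10^(-sc$nlp)
  list(F = sc$F, df1 = sc$df1, df2 = sc$df2, p = p, nlp = sc$nlp,
       monomorphic = sc$monomorphic)
}

#' Permutation threshold for the joint linkage scan
#'
#' Permutes trait values within families (preserving the family main
#' effect structure of the null model), scans all markers with the
#' family-nested test, records the minimum p per permutation, and returns
#' the empirical `(1 - alpha)` quantile of the -log10 minimum-p
#' distribution as the genome-wide entry threshold.
#'
#' @inheritParams nested_marker_test
#' @param n_perm Number of permutations (1000 in the original analyses).
#' @param alpha Genome-wide type-I level (default 0.05).
#' @param seed Integer seed.
#' @return Object of class `permutation_result`: list with `threshold`
#'   (-log10 p units), `minp_nlp` (per-permutation maxima of -log10 p),
#'   `n_perm`, `alpha`.
#' @export
permutation_threshold <- function(y, G, families, n_perm = 1000,
                                  alpha = 0.05, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 20) warning("n_perm < 20: threshold quantile is unstable")
  fidx <- family_indices(families)
  maxnlp <- with_seed(seed, {
    Y <- matrix(0, length(y), n_perm)
    for (idx in fidx) {
      for (k in seq_len(n_perm)) Y[idx, k] <- y[sample(idx)]
    }
    jl_scan_multi_max(Y, G, families)
  })
  structure(list(threshold = as.numeric(stats::quantile(maxnlp, 1 - alpha)),
                 minp_nlp = maxnlp, n_perm = n_perm, alpha = alpha),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation threshold:", round(x$threshold, 3), "(-log10 p),",
      x$n_perm, "permutations, alpha =", x$alpha, "\n")
  invisible(x)
}

#' Joint stepwise QTL selection
#'
#' Forward selection over markers: at each step the marker with the
#' largest -log10 p of its family-nested term (given the current model)
#' enters if it exceeds the threshold; selection stops otherwise. Family
#' main effects are always in the model. Ties are broken by smaller p,
#' then chromosome order, then cM.
#'
#' @inheritParams nested_marker_test
#' @param map [genetic_map()] aligned with the columns of `G`.
#' @param threshold Entry threshold in -log10 p units (from
#'   [permutation_threshold()] or user-supplied).
#' @param max_qtl Safety cap on model size.
#' @return A `jl_model`: list with `selected` (marker column indices, in
#'   entry order), `peaks` (data.frame marker/chrom/cM/nlp_entry),
#'   `threshold`, `r2`, `sse`, `df_resid`, and the fitting inputs' key
#'   dimensions.
#' @export
joint_stepwise <- function(y, G, map, families, threshold, max_qtl = 40) {
  stopifnot(nrow(map) == ncol(G))
  selected <- integer(0)
  entry_nlp <- numeric(0)
  repeat {
    sc <- jl_scan(y, G, families, base = selected)
    sc$nlp[selected] <- -Inf
    ord <- order(-sc$nlp,
                 match(map$chrom, unique(map$chrom)),
                 map$cM)
    best <- ord[1L]
    if (!is.finite(sc$nlp[best]) || sc$nlp[best] <= threshold ||
        length(selected) >= max_qtl) break
    selected <- c(selected, best)
    entry_nlp <- c(entry_nlp, sc$nlp[best])
  }
  jl_model(y, G, map, families, selected, threshold, entry_nlp)
}

# Assemble a fitted jl_model object for a given marker selection.
jl_model <- function(y, G, map, families, selected, threshold,
                     entry_nlp = rep(NA_real_, length(selected))) {
  fit <- jl_sse(y, G, families, selected)
  tss <- sum((y - mean(y))^2)
  marg_r2 <- vapply(seq_along(selected), function(i) {
    drop1 <- jl_sse(y, G, families, selected[-i])
    (drop1$sse - fit$sse) / tss
  }, numeric(1))
  peaks <- data.frame(marker = map$marker[selected],
                      chrom = map$chrom[selected],
                      cM = map$cM[selected],
                      col = selected,
                      nlp_entry = entry_nlp,
                      r2_marginal = marg_r2,
                      stringsAsFactors = FALSE)
  structure(list(selected = selected, peaks = peaks,
                 threshold = threshold,
                 r2 = 1 - fit$sse / tss, sse = fit$sse,
                 df_resid = fit$n - fit$rank,
                 n = fit$n, n_families = length(unique(families))),
            class = "jl_model")
}

#' @export
print.jl_model <- function(x, ...) {
  cat("joint linkage model:", length(x$selected), "QTL, model R2 =",
      round(x$r2, 3), ", threshold =", round(x$threshold, 2), "\n")
  if (length(x$selected)) print(x$peaks[, c("marker", "chrom", "cM",
                                            "nlp_entry", "r2_marginal")])
  invisible(x)
}

#' Refine a joint linkage model over local marker windows
#'
#' For each selected marker in turn, with the rest of the model fixed,
#' all markers within `window` map-adjacent positions on the same
#' chromosome are evaluated and the best-fitting one replaces the
#' original if it improves the partial p. Sweeps repeat until no marker
#' moves or `max_sweeps` is reached. Each retained marker's fit is never
#' worse than before refinement.
#'
#' @inheritParams joint_stepwise
#' @param model A `jl_model`.
#' @param window Number of adjacent markers scanned either side
#'   (default 8).
#' @param max_sweeps Sweep cap.
#' @return The refined `jl_model`.
#' @export
refine_model <- function(model, y, G, map, families, window = 8,
                         max_sweeps = 10) {
  if (!length(model$selected)) return(model)
  selected <- model$selected
  chrom_idx <- map_chrom_index(map)
  for (sweep_i in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_along(selected)) {
      s <- selected[i]
      on_chr <- chrom_idx[[as.character(map$chrom[s])]]
      pos <- match(s, on_chr)
      cand <- on_chr[max(1, pos - window):min(length(on_chr), pos + window)]
      cand <- setdiff(cand, selected[-i])
      sc <- jl_scan(y, G, families, base = selected[-i], candidates = cand)
      best <- cand[order(-sc$nlp, abs(map$cM[cand] - map$cM[s]))][1L]
      if (best != s && sc$nlp[match(best, cand)] >
            sc$nlp[match(s, cand)] + 1e-9) {
        selected[i] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  jl_model(y, G, map, families, selected, model$threshold)
}

#' Estimate founder allele effects at the selected QTL
#'
#' All effects are estimated simultaneously by least squares in the full
#' family-nested model; each effect is the deviation of the founder's
#' allele from the common parent (positive = the non-reference allele
#' increases the trait). t-tests use the pooled residual variance of the
#' joint fit. A family not segregating at a marker gets `NA` (not
#' estimable).
#'
#' @inheritParams joint_stepwise
#' @param model A `jl_model`.
#' @return List of QTL x family matrices `effect`, `se`, `t`, `p`, plus
#'   `mse` and `df_resid`.
#' @export
estimate_allele_effects <- function(model, y, G, families) {
  sel <- model$selected
  if (!length(sel)) stop("model has no selected markers")
  fidx <- family_indices(families)
  fam_names <- names(fidx)
  k <- length(sel)
  eff <- se <- matrix(NA_real_, k, length(fidx),
                      dimnames = list(model$peaks$marker, fam_names))
  sse <- 0; rank_tot <- 0
  per_fam <- vector("list", length(fidx))
  for (fi in seq_along(fidx)) {
    idx <- fidx[[fi]]
    Xs <- G[idx, sel, drop = FALSE]
    seg <- apply(Xs, 2L, function(col) stats::var(col) > SEG_TOL)
    X <- cbind(1, Xs[, seg, drop = FALSE])
    qrx <- qr(X)
    res <- qr.resid(qrx, y[idx])
    sse <- sse + sum(res^2)
    rank_tot <- rank_tot + qrx$rank
    per_fam[[fi]] <- list(idx = idx, X = X, seg = seg, qr = qrx)
  }
  df_resid <- length(y) - rank_tot
  mse <- sse / df_resid
  for (fi in seq_along(fidx)) {
    pf <- per_fam[[fi]]
    if (!any(pf$seg)) next
    co <- qr.coef(pf$qr, y[pf$idx])
    xtxi <- tryCatch(chol2inv(qr.R(pf$qr)), error = function(e) NULL)
    if (is.null(xtxi)) next
    which_seg <- which(pf$seg)
    eff[which_seg, fi] <- co[-1L]
    se[which_seg, fi] <- sqrt(mse * diag(xtxi)[-1L])
  }
  tmat <- eff / se
  pmat <- 2 * stats::pt(abs(tmat), df_resid, lower.tail = FALSE)
  list(effect = eff, se = se, t = tmat, p = pmat, mse = mse,
       df_resid = df_resid)
}

#' QTL support interval
#'
#' Scans outward from a QTL peak in map order (0.2 cM steps on a
#' grid-imputed map), adding each flanking marker to the full model one
#' at a time and re-testing the peak marker's nested term. A flank close
#' to the peak absorbs its signal, so the peak term is non-significant;
#' the interval boundary on each side is the first position at which the
#' peak regains significance at `alpha` despite the added flank (the
#' flank can no longer substitute for the QTL). If the peak never
#' regains significance before the chromosome end, the interval is
#' one-sided to that end.
#'
#' @inheritParams joint_stepwise
#' @param model A `jl_model`.
#' @param qtl Index into `model$selected`.
#' @param alpha Significance level for the peak term (default 0.05).
#' @return Numeric `c(lo, hi)` in cM; always contains the peak.
#' @export
support_interval <- function(model, qtl, y, G, map, families,
                             alpha = 0.05) {
  sel <- model$selected
  peak <- sel[qtl]
  on_chr <- map_chrom_index(map)[[as.character(map$chrom[peak])]]
  pos <- match(peak, on_chr)
  nlp_alpha <- -log10(alpha)
  others <- setdiff(sel, peak)
  scan_side <- function(step) {
    j <- pos + step
    end_cM <- map$cM[on_chr[if (step < 0) 1L else length(on_chr)]]
    while (j >= 1L && j <= length(on_chr)) {
      flank <- on_chr[j]
      if (!flank %in% sel) {
        sc <- jl_scan(y, G, families, base = c(others, flank),
                      candidates = peak)
        if (sc$nlp >= nlp_alpha) return(map$cM[flank])
      }
      j <- j + step
    }
    end_cM
  }
  c(lo = min(scan_side(-1L), map$cM[peak]),
    hi = max(scan_side(+1L), map$cM[peak]))
}

#' Single-family marker scan
#'
#' Simple one-marker regression within a single family, a lightweight
#' stand-in for composite interval mapping: per-marker p-values,
#' additive effects, and (optionally) a within-family permutation
#' threshold on the minimum p.
#'
#' @param y Trait values of the family's lines.
#' @param G Family lines x markers dosage matrix.
#' @param n_perm Number of permutations for the family threshold; 0
#'   skips it.
#' @param alpha Threshold level.
#' @param seed Integer seed.
#' @return List with `scan` (data.frame marker index, effect, F, nlp)
#'   and `threshold` (-log10 p, or `NA` if `n_perm = 0`).
#' @export
single_family_scan <- function(y, G, n_perm = 0, alpha = 0.05, seed = 1) {
  n <- length(y)
  scan_one <- function(yy) {
    yc <- yy - mean(yy)
    Xc <- sweep(G, 2L, colMeans(G))
    ssxx <- colSums(Xc^2)
    ssxy <- as.numeric(crossprod(Xc, yc))
    seg <- ssxx > SEG_TOL * n
    num <- ifelse(seg, ssxy^2 / pmax(ssxx, .Machine$double.xmin), 0)
    sse <- sum(yc^2) - num
    f <- ifelse(seg, num / pmax(sse / (n - 2), .Machine$double.xmin), NA)
    nlp <- numeric(ncol(G))
    nlp[seg] <- pmin(neglog10_pf(f[seg], rep(1, sum(seg)),
                                 rep(n - 2, sum(seg))), 350)
    list(effect = ifelse(seg, ssxy / ssxx, NA_real_), F = f, nlp = nlp)
  }
  sc <- scan_one(y)
  threshold <- NA_real_
  if (n_perm > 0) {
    maxes <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(k) max(scan_one(y[sample(n)])$nlp), numeric(1))
    })
    threshold <- as.numeric(stats::quantile(maxes, 1 - alpha))
  }
  list(scan = data.frame(marker = seq_len(ncol(G)), effect = sc$effect,
                         F = sc$F, nlp = sc$nlp),
       threshold = threshold)
}
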