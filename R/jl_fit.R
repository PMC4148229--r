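# Internal fitting machinery for the joint multi-family linkage model.
#
# The joint model contains family main effects and marker effects nested
# within families, so its design matrix is block-diagonal by family: every
# fit decomposes into per-family regressions sharing a single pooled
# residual variance. All scans below exploit this, which is what makes
# permutation thresholds and stepwise selection tractable at full
# population sizes.

SEG_TOL <- 1e-8

# Residual sum of squares and rank of the family-nested model with the
# given marker columns (family intercepts always included).
jl_sse <- function(y, G, families, cols) {
  fidx <- family_indices(families)
  sse <- 0; rank <- 0
  for (idx in fidx) {
    Xb <- cbind(rep(1, length(idx)), if (length(cols)) G[idx, cols, drop = FALSE])
    qrb <- qr(Xb)
    sse <- sse + sum(qr.resid(qrb, y[idx])^2)
    rank <- rank + qrb$rank
  }
  list(sse = sse, rank = rank, n = length(y))
}

# Partial F-test scan: for each candidate marker, the test of adding its
# family-nested term (one slope per segregating family) to the model that
# already contains family intercepts and the `base` markers' nested terms.
# Returns F statistics, numerator df (number of segregating families),
# denominator df, and -log10 p (capped at 350 so perfect fits stay finite).
jl_scan <- function(y, G, families, base = integer(0),
                    candidates = seq_len(ncol(G))) {
  fidx <- family_indices(families)
  n <- length(y)
  m <- length(candidates)
  num <- numeric(m)
  q <- integer(m)
  sse_base <- 0; rank_base <- 0
  for (idx in fidx) {
    Xb <- cbind(rep(1, length(idx)), if (length(base)) G[idx, base, drop = FALSE])
    qrb <- qr(Xb)
    ry <- qr.resid(qrb, y[idx])
    RX <- qr.resid(qrb, G[idx, candidates, drop = FALSE])
    ssxx <- colSums(RX^2)
    seg <- ssxx > SEG_TOL * length(idx)
    if (any(seg)) {
      ssxy <- colSums(RX * ry)
      num[seg] <- num[seg] + ssxy[seg]^2 / ssxx[seg]
      q <- q + as.integer(seg)
    }
    sse_base <- sse_base + sum(ry^2)
    rank_base <- rank_base + qrb$rank
  }
  sse_full <- pmax(sse_base - num, 0)
  df2 <- n - rank_base - q
  f <- rep(NA_real_, m)
  ok <- q > 0 & df2 > 0
  f[ok] <- (num[ok] / q[ok]) / pmax(sse_full[ok] / df2[ok],
                                    .Machine$double.xmin)
  nlp <- numeric(m)
  nlp[ok] <- pmin(neglog10_pf(f[ok], q[ok], df2[ok]), 350)
  data.frame(marker = candidates, F = f, df1 = q, df2 = df2,
             nlp = nlp, monomorphic = q == 0)
}

# Scan of many (permuted) trait vectors at once against all markers, with
# family intercepts as the base model. Y is an n x n_perm matrix. Returns
# the per-column maximum -log10 p over markers.
jl_scan_multi_max <- function(Y, G, families) {
  fidx <- family_indices(families)
  n <- nrow(Y)
  m <- ncol(G)
  n_perm <- ncol(Y)
  num <- matrix(0, m, n_perm)
  q <- integer(m)
  sse_base <- numeric(n_perm)
  for (idx in fidx) {
    Yc <- Y[idx, , drop = FALSE]
    Yc <- sweep(Yc, 2L, colMeans(Yc))
    Xc <- G[idx, , drop = FALSE]
    Xc <- sweep(Xc, 2L, colMeans(Xc))
    ssxx <- colSums(Xc^2)
    seg <- ssxx > SEG_TOL * length(idx)
    ssxy <- crossprod(Xc, Yc)                       # m x n_perm
    num[seg, ] <- num[seg, , drop = FALSE] +
      ssxy[seg, , drop = FALSE]^2 / ssxx[seg]
    q <- q + as.integer(seg)
    sse_base <- sse_base + colSums(Yc^2)
  }
  df2 <- n - length(fidx) - q
  out <- numeric(n_perm)
  sse_full <- pmax(-sweep(num, 2L, sse_base), 0)
  for (k in seq_len(n_perm)) {
    ok <- q > 0 & df2 > 0
    f <- (num[ok, k] / q[ok]) / pmax(sse_full[ok, k] / df2[ok],
                                     .Machine$double.xmin)
    out[k] <- max(pmin(neglog10_pf(f, q[ok], df2[ok]), 350))
  }
  out
}

# Frisch-Waugh residualisation of y and a set of extra columns on the
# family-nested base model; used by the epistasis tests.
jl_residualise <- function(y, X_extra, G, families, base) {
  fidx <- family_indices(families)
  ry <- numeric(length(y))
  RX <- matrix(0, nrow(X_extra), ncol(X_extra))
  rank_base <- 0
  for (idx in fidx) {
    Xb <- cbind(rep(1, length(idx)), if (length(base)) G[idx, base, drop = FALSE])
    qrb <- qr(Xb)
    ry[idx] <- qr.resid(qrb, y[idx])
    RX[idx, ] <- qr.resid(qrb, X_extra[idx, , drop = FALSE])
    rank_base <- rank_base + qrb$rank
  }
  list(ry = ry, RX = RX, rank_base = rank_base)
}
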