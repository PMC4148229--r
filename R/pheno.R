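# Trait derivation and quantitative-genetic summaries.

#' Standardized area under the disease progress curve
#'
#' Trapezoid-integrates repeated severity ratings over time and divides
#' by the total span of days, yielding a time-weighted average severity:
#' `sum_i ((s_i + s_{i+1})/2) * (t_{i+1} - t_i) / (t_last - t_first)`.
#' The result always lies within the range of the scores, is invariant to
#' uniform time shifts, and handles seasons with different numbers of
#' ratings on a common footing.
#'
#' @param days Strictly increasing rating days (since planting).
#' @param scores Severity scores on the 1-10 lesion scale.
#' @return The sAUDPC, a real on the score scale.
#' @examples
#' saudpc(c(0, 10, 30), c(1, 5, 9))  # (3*10 + 7*20)/30 = 5.6667
#' @export
saudpc <- function(days, scores) {
  if (length(days) != length(scores)) stop("days and scores must align")
  if (length(days) < 2L) stop("at least two ratings required")
  if (anyDuplicated(days)) stop("duplicate rating days")
  o <- order(days)
  days <- days[o]; scores <- scores[o]
  dt <- diff(days)
  sum((scores[-length(scores)] + scores[-1]) / 2 * dt) / sum(dt)
}

#' Mutant to wild-type ratio trait
#'
#' @param mutant_mean Mean over mutant-class plants (the paper's design
#'   uses three representative plants per class).
#' @param wildtype_mean Mean over wild-type plants; must be positive.
#' @return `mutant_mean / wildtype_mean`.
#' @export
ratio_trait <- function(mutant_mean, wildtype_mean) {
  if (any(wildtype_mean <= 0)) stop("wildtype mean must be positive")
  mutant_mean / wildtype_mean
}

#' Environment-adjusted least-squares line means
#'
#' Fits, by ordinary least squares, line (fixed) plus environment and
#' family-by-environment adjustment terms, and returns each line's
#' estimate averaged over all environments. On balanced data this reduces
#' exactly to the raw line mean; line contrasts are invariant to adding
#' environment-specific constants.
#'
#' @param plots Data frame with columns `line`, `family`, `env`, `value`.
#' @return Data frame `line`, `family`, `lsmean`.
#' @export
ls_means <- function(plots) {
  need <- c("line", "family", "env", "value")
  if (!all(need %in% names(plots))) stop("plots must have columns ",
                                         paste(need, collapse = ", "))
  plots <- plots[!is.na(plots$value), ]
  line <- factor(plots$line)
  env <- factor(plots$env)
  fam <- factor(plots$family)
  X <- stats::model.matrix(~ 0 + line)
  adj_form <- if (nlevels(fam) > 1L) ~ env + fam:env else ~ env
  if (nlevels(env) > 1L) {
    Z <- stats::model.matrix(adj_form)[, -1, drop = FALSE]
    X <- cbind(X, Z)
  }
  fit <- stats::lm.fit(X, plots$value)
  beta <- fit$coefficients
  if (anyNA(beta[seq_len(nlevels(line))])) {
    stop("singular design: line effects aliased for ",
         paste(levels(line)[is.na(beta[seq_len(nlevels(line))])][1:3],
               collapse = ", "))
  }
  beta[is.na(beta)] <- 0   # standard treatment of aliased adjustment terms
  lsm <- beta[seq_len(nlevels(line))]
  if (nlevels(env) > 1L) {
    # average the environment and family:env adjustments over environments
    fam_of <- fam[match(levels(line), line)]
    grid <- expand.grid(env = factor(levels(env), levels(env)),
                        fam = factor(levels(fam), levels(fam)))
    Zg <- stats::model.matrix(adj_form, data = grid)[, -1, drop = FALSE]
    adj <- as.vector(Zg %*% beta[-seq_len(nlevels(line))])
    adj_by_fam <- tapply(adj, grid$fam, mean)
    lsm <- lsm + adj_by_fam[as.character(fam_of)]
  }
  out <- data.frame(line = levels(line),
                    family = as.character(fam[match(levels(line), line)]),
                    lsmean = as.numeric(lsm),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate variance components by expected mean squares
#'
#' Method-of-moments estimates from the line x environment ANOVA, with
#' all factors treated as random. With replicates within environments the
#' line-by-environment and residual components separate; with a single
#' replicate they are confounded and returned as their sum in
#' `s2_line_env` (flagged). Negative solutions are truncated at zero and
#' flagged.
#'
#' @param plots Data frame with `line`, `env`, `value` and optionally
#'   `rep`.
#' @return Object of class `variance_components`: list with `s2_line`,
#'   `s2_env`, `s2_line_env`, `s2_resid`, `n_env`, `n_rep`, `flags`.
#' @export
estimate_variance_components <- function(plots) {
  stopifnot(all(c("line", "env", "value") %in% names(plots)))
  plots <- plots[!is.na(plots$value), ]
  line <- factor(plots$line); env <- factor(plots$env)
  a <- nlevels(line); b <- nlevels(env)
  if (b < 2L) {
    stop("at least two environments needed to separate line from noise")
  }
  n_rep <- nrow(plots) / (a * b)
  flags <- character(0)
  if (abs(n_rep - round(n_rep)) > 1e-8) {
    flags <- c(flags, "unbalanced: using average replicate count")
  }
  # two-way ANOVA sums of squares from cell means (exact on balanced
  # data, O(N); aov() would materialise a lines x cells design matrix)
  gm <- mean(plots$value)
  ss_of <- function(f) {
    m <- tapply(plots$value, f, mean)
    n_g <- tapply(plots$value, f, length)
    sum(n_g * (m - gm)^2)
  }
  ss_line <- ss_of(line)
  ss_env <- ss_of(env)
  cell <- interaction(line, env, drop = TRUE)
  ss_cell <- ss_of(cell)
  ss_total <- sum((plots$value - gm)^2)
  ss_le <- max(ss_cell - ss_line - ss_env, 0)
  ss_resid <- max(ss_total - ss_cell, 0)
  df_line <- a - 1; df_env <- b - 1; df_le <- (a - 1) * (b - 1)
  df_resid <- nrow(plots) - nlevels(cell)
  ms <- c(line = ss_line / df_line, env = ss_env / df_env,
          le = ss_le / df_le)
  single_rep <- df_resid <= 0
  if (single_rep) {
    # the cell stratum is the error stratum; s2_le and s2_e confounded
    s2_e <- 0
    s2_le <- ms[["le"]]
    n <- 1
    flags <- c(flags, "single replicate: s2_line_env holds s2_le + s2_e")
  } else {
    n <- n_rep
    s2_e <- ss_resid / df_resid
    s2_le <- (ms[["le"]] - s2_e) / n
  }
  s2_l <- (ms[["line"]] - ifelse(single_rep, s2_le, ms[["le"]])) / (b * n)
  s2_env <- (ms[["env"]] - ifelse(single_rep, s2_le, ms[["le"]])) / (a * n)
  comps <- c(s2_line = s2_l, s2_env = s2_env, s2_line_env = s2_le,
             s2_resid = s2_e)
  if (any(comps < 0)) {
    flags <- c(flags, paste("negative estimate truncated:",
                            paste(names(comps)[comps < 0], collapse = ", ")))
    comps <- pmax(comps, 0)
  }
  structure(list(s2_line = comps[["s2_line"]], s2_env = comps[["s2_env"]],
                 s2_line_env = comps[["s2_line_env"]],
                 s2_resid = comps[["s2_resid"]],
                 n_env = b, n_rep = round(n), flags = flags),
            class = "variance_components")
}

#' Line-mean heritability
#'
#' `H2 = s2_line / (s2_line + s2_line_env/nE + s2_resid/(nE * nR))`,
#' the fraction of variance among line means across `nE` environments
#' with `nR` replicates that is genetic.
#'
#' @param vc A [estimate_variance_components()] result, or a list with
#'   the same fields.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc) {
  if (vc$n_env < 1 || vc$n_rep < 1) stop("n_env and n_rep must be >= 1")
  denom <- vc$s2_line + vc$s2_line_env / vc$n_env +
    vc$s2_resid / (vc$n_env * vc$n_rep)
  if (denom == 0) stop("all variance components are zero; H2 undefined")
  vc$s2_line / denom
}

#' Partial correlation adjusting for group structure
#'
#' Pearson correlation of two traits after removing group (e.g. NAM
#' family) means from both, with the significance test on
#' `n - g - 1` degrees of freedom. Listwise deletion is applied; groups
#' with fewer than two complete pairs are dropped with a warning.
#'
#' @param x,y Trait vectors.
#' @param groups Group labels (same length).
#' @return List with `r`, `p`, `n` (pairs used), `df`.
#' @export
partial_correlation <- function(x, y, groups) {
  ok <- stats::complete.cases(x, y, groups)
  x <- x[ok]; y <- y[ok]; g <- factor(as.character(groups[ok]))
  sizes <- table(g)
  if (any(sizes < 2L)) {
    warning(sum(sizes < 2L), " group(s) with < 2 members dropped")
    keep <- g %in% names(sizes)[sizes >= 2L]
    x <- x[keep]; y <- y[keep]; g <- droplevels(g[keep])
  }
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete pairs")
  xr <- x - stats::ave(x, g)
  yr <- y - stats::ave(y, g)
  if (stats::sd(xr) == 0 || stats::sd(yr) == 0) {
    stop("a trait is constant within groups; correlation undefined")
  }
  r <- stats::cor(xr, yr)
  df <- n - nlevels(g) - 1L
  t <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(r = r, p = p, n = n, df = df)
}

#' Correlation between allele-effect estimates of two traits
#'
#' Pearson correlation over all founder-by-QTL cells of two matched
#' allele-effect matrices at QTL shared between traits (e.g. 24 founders
#' x 15 shared QTL = 360 paired effect estimates).
#'
#' @param effA,effB Founder x QTL matrices of allele effects, matched
#'   cell-for-cell.
#' @return List with `r`, `p`, `n` (cells used).
#' @export
effect_correlation <- function(effA, effB) {
  effA <- as.matrix(effA); effB <- as.matrix(effB)
  if (!length(effA)) stop("no shared QTL: empty effect matrices")
  if (!all(dim(effA) == dim(effB))) stop("effect matrices must match")
  ok <- is.finite(effA) & is.finite(effB)
  a <- effA[ok]; b <- effB[ok]
  if (length(a) < 3L) stop("fewer than 3 paired effect estimates")
  r <- stats::cor(a, b)
  df <- length(a) - 2L
  t <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(r = r, p = p, n = length(a))
}

#' Invert a lesion-score trait for sign-consistent correlations
#'
#' Reflects a score on the 1-10 lesion scale as `11 - x` (generally
#' `scale_max + scale_min - x`), so that larger values mean a weaker HR
#' and correlation signs line up across traits. Any affine inversion
#' leaves the magnitude of correlations unchanged; only the sign
#' convention is affected.
#'
#' @param x Scores.
#' @param scale_min,scale_max Ends of the rating scale.
#' @export
invert_scale <- function(x, scale_min = 1, scale_max = 10) {
  scale_max + scale_min - x
}

#' Derive per-line HR trait values from plot records
#'
#' Computes per-plot sAUDPC from the rating series (per environment
#' first, as the trial design dictates), then environment-adjusted LS
#' means per line; direct-valued traits are LS-mean adjusted as they are.
#'
#' @param ratings Rating series data frame (`line`, `family`, `env`,
#'   `rep`, `day`, `score`), or `NULL`.
#' @param plots Named list of plot-record data frames (one per trait,
#'   each with `line`, `family`, `env`, `value`), or `NULL`.
#' @return Trait table: `line`, `family`, one column per trait (the
#'   rating-derived trait is named `LES`).
#' @export
derive_traits <- function(ratings = NULL, plots = NULL) {
  tabs <- list()
  if (!is.null(ratings)) {
    key <- interaction(ratings$line, ratings$env, ratings$rep, drop = TRUE)
    sp <- split(ratings, key)
    aud <- vapply(sp, function(df) saudpc(df$day, df$score), numeric(1))
    meta <- do.call(rbind, lapply(sp, function(df) {
      df[1L, c("line", "family", "env", "rep")]
    }))
    per_plot <- cbind(meta, value = as.numeric(aud))
    tabs$LES <- ls_means(per_plot)
  }
  if (!is.null(plots)) {
    for (tr in names(plots)) tabs[[tr]] <- ls_means(plots[[tr]])
  }
  if (!length(tabs)) stop("nothing to derive")
  out <- tabs[[1]][, c("line", "family")]
  for (tr in names(tabs)) {
    out[[tr]] <- tabs[[tr]]$lsmean[match(out$line, tabs[[tr]]$line)]
  }
  out
}
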