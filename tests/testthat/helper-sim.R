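# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; no stored data.

# Small multi-family population with an additive allelic-series trait.
# Returns y (named), G, map, families, plus the truth used to build it.
make_nam_fixture <- function(n_families = 6, n_rils = 100, n_chrom = 3,
                             spacing = 2, qtl_marker = NULL,
                             effect_sd = 0.6, h2 = 0.85, seed = 1) {
  map <- uniform_map(n_chrom, 100, spacing)
  panel <- simulate_founders(n_families + 1, map, nrow(map) + 50,
                             seed = derive_seed(seed, "panel"))
  pop <- simulate_population(panel, map, n_rils,
                             seed = derive_seed(seed, "pop"))
  if (is.null(qtl_marker)) {
    qtl_marker <- round(seq(10, nrow(map) - 10, length.out = 4))
  }
  eff <- with_seed(derive_seed(seed, "eff"), {
    matrix(stats::rnorm(n_families * length(qtl_marker), 0, effect_sd),
           n_families, length(qtl_marker),
           dimnames = list(pop$families$founder, NULL))
  })
  tm <- trait_model(qtl = data.frame(chrom = map$chrom[qtl_marker],
                                     cM = map$cM[qtl_marker]),
                    effects = eff, h2_line = h2, n_env = 4)
  pop <- assign_genetic_values(pop, tm)
  ph <- simulate_phenotypes(pop, tm, seed = derive_seed(seed, "ph"))
  lsm <- ls_means(ph$plots)
  y <- stats::setNames(lsm$lsmean, lsm$line)
  list(y = y, G = pop$geno[lsm$line, , drop = FALSE], map = map,
       families = lsm$family, pop = pop, panel = panel, tm = tm,
       qtl_marker = qtl_marker, plots = ph$plots)
}

# Independent brute-force Viterbi oracle: enumerate all 3^m state paths
# and return the log-likelihood maximum (and one argmax path).
enumerate_best_path <- function(obs, hmm, d_cM) {
  m <- length(obs)
  log_em <- log(hmm_emission(hmm))
  p <- hmm$p_het
  log_init <- log(c((1 - p) / 2, p, (1 - p) / 2))
  log_tr <- lapply(d_cM, function(d) log(hmm_transition(hmm, d)))
  paths <- as.matrix(expand.grid(rep(list(0:2), m)))
  ll <- log_init[paths[, 1] + 1]
  for (t in seq_len(m)) {
    if (!is.na(obs[t])) ll <- ll + log_em[cbind(paths[, t] + 1, obs[t] + 1)]
    if (t > 1) {
      ll <- ll + log_tr[[t - 1]][cbind(paths[, t - 1] + 1, paths[, t] + 1)]
    }
  }
  best <- which.max(ll)
  list(loglik = ll[best], path = unname(paths[best, ]),
       n_ties = sum(ll > ll[best] - 1e-9))
}

# Log-likelihood of a specific state path under the HMM (for comparing a
# decoded path against the enumeration maximum).
path_loglik <- function(path, obs, hmm, d_cM) {
  log_em <- log(hmm_emission(hmm))
  p <- hmm$p_het
  log_init <- log(c((1 - p) / 2, p, (1 - p) / 2))
  ll <- log_init[path[1] + 1]
  for (t in seq_along(path)) {
    if (!is.na(obs[t])) ll <- ll + log_em[path[t] + 1, obs[t] + 1]
    if (t > 1) {
      ll <- ll + log(hmm_transition(hmm, d_cM[t - 1]))[path[t - 1] + 1,
                                                       path[t] + 1]
    }
  }
  ll
}

# Generic least-squares oracle via explicit normal equations.
normal_equations_fit <- function(X, y) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# Independent nested-marker F test built on lm(): family intercepts plus
# per-family marker slopes, compared by anova().
lm_nested_test <- function(y, g, families, base_g = NULL) {
  fam <- factor(families)
  df <- data.frame(y = y, g = g, fam = fam)
  rhs0 <- "fam"
  if (!is.null(base_g)) {
    base_g <- as.matrix(base_g)
    for (k in seq_len(ncol(base_g))) df[[paste0("b", k)]] <- base_g[, k]
    rhs0 <- paste(c("fam", paste0("fam:b", seq_len(ncol(base_g)))),
                  collapse = " + ")
  }
  f0 <- stats::lm(stats::as.formula(paste("y ~", rhs0)), data = df)
  f1 <- stats::lm(stats::as.formula(paste("y ~", rhs0, "+ fam:g")),
                  data = df)
  an <- stats::anova(f0, f1)
  list(F = an$F[2], p = an$`Pr(>F)`[2], df1 = an$Df[2], df2 = an$Res.Df[2])
}
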