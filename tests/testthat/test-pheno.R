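test_that("sAUDPC reproduces hand-computed trapezoid sums", {
  expect_equal(saudpc(c(0, 7, 14), c(3, 3, 3)), 3.0)
  expect_equal(saudpc(c(0, 10), c(2, 4)), 3.0)
  expect_equal(saudpc(c(0, 10, 30), c(1, 5, 9)), (3 * 10 + 7 * 20) / 30,
               tolerance = 1e-12)
  expect_error(saudpc(c(0, 0, 5), c(1, 2, 3)), "duplicate")
  expect_error(saudpc(5, 3), "two ratings")
})

test_that("sAUDPC is bounded by the scores and shift-invariant", {
  set.seed(5)
  for (i in 1:50) {
    k <- sample(3:7, 1)
    days <- sort(sample(0:90, k))
    scores <- runif(k, 1, 10)
    v <- saudpc(days, scores)
    expect_true(v >= min(scores) - 1e-12 && v <= max(scores) + 1e-12)
    expect_equal(saudpc(days + 17, scores), v, tolerance = 1e-12)
  }
})

test_that("ratio traits divide class means", {
  expect_equal(ratio_trait(150, 150), 1)
  expect_equal(ratio_trait(75, 150), 0.5)
  expect_equal(ratio_trait(mean(c(60, 62, 64)), mean(c(120, 121, 119))),
               0.5167, tolerance = 1e-4)
  expect_error(ratio_trait(100, 0), "positive")
})

test_that("LS means equal raw means on balanced data", {
  set.seed(11)
  d <- expand.grid(line = paste0("l", 1:6), env = c("e1", "e2"),
                   stringsAsFactors = FALSE)
  d$family <- rep(c("fA", "fB"), each = 3)[match(d$line, paste0("l", 1:6))]
  d$value <- rnorm(nrow(d))
  lsm <- ls_means(d)
  raw <- tapply(d$value, d$line, mean)
  expect_equal(lsm$lsmean, as.numeric(raw[lsm$line]), tolerance = 1e-10)
})

test_that("unbalanced LS means match the normal-equations oracle", {
  set.seed(12)
  d <- expand.grid(line = paste0("l", 1:3), env = c("e1", "e2"),
                   stringsAsFactors = FALSE)
  d$family <- "fA"
  d$value <- rnorm(nrow(d))
  d <- d[-4, ]                       # one missing cell
  lsm <- ls_means(d)
  # oracle: explicit normal equations for line + env effects, then the
  # line estimate averaged over both environments
  X <- cbind(stats::model.matrix(~ 0 + factor(d$line)),
             env2 = as.numeric(d$env == "e2"))
  beta <- normal_equations_fit(X, d$value)
  oracle <- beta[1:3] + 0.5 * beta[4]
  expect_equal(lsm$lsmean, oracle, tolerance = 1e-9)
})

test_that("line contrasts ignore environment-wide shifts", {
  set.seed(13)
  d <- expand.grid(line = paste0("l", 1:8), env = c("e1", "e2", "e3"),
                   stringsAsFactors = FALSE)
  d$family <- rep(c("fA", "fB"), each = 4)[match(d$line, paste0("l", 1:8))]
  d$value <- rnorm(nrow(d))
  lsm1 <- ls_means(d)
  d2 <- d
  d2$value[d2$env == "e2"] <- d2$value[d2$env == "e2"] + 100
  lsm2 <- ls_means(d2)
  expect_equal(diff(lsm1$lsmean), diff(lsm2$lsmean), tolerance = 1e-9)
})

test_that("variance components are recovered by expected mean squares", {
  set.seed(14)
  a <- 400; b <- 4; n <- 2
  truth <- c(line = 1.0, env = 0.2, le = 0.3, resid = 0.5)
  line_eff <- rnorm(a, 0, sqrt(truth["line"]))
  env_eff <- rnorm(b, 0, sqrt(truth["env"]))
  le_eff <- matrix(rnorm(a * b, 0, sqrt(truth["le"])), a, b)
  d <- expand.grid(line = seq_len(a), env = seq_len(b), rep = seq_len(n))
  d$value <- line_eff[d$line] + env_eff[d$env] +
    le_eff[cbind(d$line, d$env)] + rnorm(nrow(d), 0, sqrt(truth["resid"]))
  d$line <- paste0("l", d$line); d$env <- paste0("e", d$env)
  vc <- estimate_variance_components(d)
  expect_lt(abs(vc$s2_line - 1.0), 0.15)
  expect_lt(abs(vc$s2_line_env - 0.3), 0.3 * 0.5)
  expect_lt(abs(vc$s2_resid - 0.5), 0.5 * 0.15)
  # zero-noise data give zero residual
  d0 <- d; d0$value <- line_eff[as.integer(sub("l", "", d0$line))]
  vc0 <- estimate_variance_components(d0)
  expect_equal(vc0$s2_resid, 0, tolerance = 1e-20)
  # permuting line labels within env kills the line component
  dp <- d
  set.seed(15)
  for (e in unique(dp$env)) {
    i <- dp$env == e
    dp$value[i] <- dp$value[i][sample(sum(i))]
  }
  vcp <- estimate_variance_components(dp)
  expect_lt(vcp$s2_line, 0.05 * vc$s2_line + 0.05)
  expect_error(estimate_variance_components(d[d$env == "e1", ]),
               "two environments")
})

test_that("mean-square computation agrees with the aov oracle", {
  set.seed(20)
  d <- expand.grid(line = paste0("l", 1:12), env = paste0("e", 1:3),
                   rep = 1:2, stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  vc <- estimate_variance_components(d)
  tab <- summary(stats::aov(value ~ line + env + line:env, data = d))[[1]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  s2_e <- ms[["Residuals"]]
  s2_le <- (ms[["line:env"]] - s2_e) / 2
  s2_l <- (ms[["line"]] - ms[["line:env"]]) / (3 * 2)
  expect_equal(vc$s2_resid, s2_e, tolerance = 1e-10)
  expect_equal(vc$s2_line_env, max(s2_le, 0), tolerance = 1e-8)
  expect_equal(vc$s2_line, max(s2_l, 0), tolerance = 1e-8)
})

test_that("heritability follows its formula and monotonicities", {
  vc <- list(s2_line = 2, s2_env = 1, s2_line_env = 0.5, s2_resid = 1,
             n_env = 4, n_rep = 2)
  expect_equal(heritability(vc), 2 / (2 + 0.5 / 4 + 1 / 8))
  vc0 <- vc; vc0$s2_line <- 0
  expect_equal(heritability(vc0), 0)
  vc1 <- list(s2_line = 3, s2_env = 0, s2_line_env = 0, s2_resid = 0,
              n_env = 1, n_rep = 1)
  expect_equal(heritability(vc1), 1)
  # monotone in s2_line and in nE, nR
  h <- vapply(seq(0.5, 5, by = 0.5), function(s) {
    v <- vc; v$s2_line <- s; heritability(v)
  }, numeric(1))
  expect_true(all(diff(h) > 0))
  h2 <- vapply(1:6, function(k) {
    v <- vc; v$n_env <- k; heritability(v)
  }, numeric(1))
  expect_true(all(diff(h2) > 0))
  expect_error(heritability(list(s2_line = 0, s2_line_env = 0,
                                 s2_resid = 0, n_env = 2, n_rep = 1)),
               "undefined")
})

test_that("partial correlation removes group structure", {
  set.seed(16)
  x <- rnorm(100)
  expect_equal(partial_correlation(x, x, rep(c("a", "b"), 50))$r, 1)
  # group-constant traits are degenerate
  g <- rep(c("a", "b"), each = 10)
  expect_error(partial_correlation(as.numeric(g == "a") * 2,
                                   as.numeric(g == "a") * 5, g),
               "constant within groups")
  # invariant to group-specific offsets
  g2 <- rep(paste0("f", 1:5), each = 30)
  xx <- rnorm(150); yy <- 0.5 * xx + rnorm(150, 0, sqrt(0.75))
  r0 <- partial_correlation(xx, yy, g2)
  shift <- stats::setNames(rnorm(5, 0, 50), paste0("f", 1:5))
  r1 <- partial_correlation(xx + shift[g2], yy - shift[g2], g2)
  expect_equal(r0$r, r1$r, tolerance = 1e-12)
  # recovery of the within-group correlation
  set.seed(17)
  g3 <- rep(sprintf("f%02d", 1:24), each = 140)
  mu <- stats::setNames(rnorm(24, 0, 3), unique(g3))
  x3 <- mu[g3] + rnorm(length(g3))
  y3 <- -mu[g3] + 0.5 * (x3 - mu[g3]) + rnorm(length(g3), 0, sqrt(0.75))
  est <- partial_correlation(x3, y3, g3)
  expect_lt(abs(est$r - 0.5), 0.05)
  expect_lt(est$p, 1e-10)
  expect_equal(est$df, length(g3) - 24 - 1)
})

test_that("effect correlations behave at the extremes and under the null", {
  set.seed(18)
  A <- matrix(rnorm(24 * 15), 24, 15)
  expect_equal(effect_correlation(A, 2 * A)$r, 1)
  expect_equal(effect_correlation(A, -A)$r, -1)
  B <- matrix(rnorm(24 * 15), 24, 15)
  expect_lt(abs(effect_correlation(A, B)$r), 0.15)
  expect_error(effect_correlation(matrix(numeric(0), 0, 0), B),
               "no shared QTL")
})

test_that("scale inversion flips correlation signs only", {
  set.seed(19)
  x <- runif(60, 1, 10); y <- 0.6 * x + rnorm(60)
  g <- rep(c("a", "b", "c"), 20)
  r <- partial_correlation(x, y, g)$r
  ri <- partial_correlation(invert_scale(x), y, g)$r
  expect_equal(ri, -r, tolerance = 1e-12)
  expect_equal(invert_scale(3), 8)
})

test_that("derive_traits turns rating series into LES line means", {
  fx <- make_nam_fixture(n_families = 3, n_rils = 40, seed = 23)
  ph <- simulate_phenotypes(fx$pop, fx$tm, seed = 3, ratings = TRUE)
  tt <- derive_traits(ratings = ph$ratings,
                      plots = list(VAL = ph$plots))
  expect_true(all(c("line", "family", "LES", "VAL") %in% names(tt)))
  expect_equal(nrow(tt), nrow(fx$pop$lines))
  # LES line means track the underlying genetic values
  expect_gt(cor(tt$LES, fx$pop$genetic_values[tt$line]), 0.5)
})
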