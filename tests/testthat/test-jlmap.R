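test_that("nested marker test matches the lm/anova oracle", {
  fx <- make_nam_fixture(n_families = 4, n_rils = 60, seed = 31)
  set.seed(32)
  for (m in sample(ncol(fx$G), 5)) {
    ours <- nested_marker_test(fx$y, fx$G, fx$families, m)
    oracle <- lm_nested_test(fx$y, fx$G[, m], fx$families)
    expect_equal(ours$F, oracle$F, tolerance = 1e-8)
    expect_equal(ours$p, oracle$p, tolerance = 1e-6)
    expect_equal(ours$df1, oracle$df1)
    expect_equal(ours$df2, oracle$df2)
  }
  # with base markers in the model
  base <- sample(ncol(fx$G), 2)
  m <- setdiff(sample(ncol(fx$G), 3), base)[1]
  ours <- nested_marker_test(fx$y, fx$G, fx$families, m, base = base)
  oracle <- lm_nested_test(fx$y, fx$G[, m], fx$families,
                           base_g = fx$G[, base])
  expect_equal(ours$F, oracle$F, tolerance = 1e-8)
  expect_equal(ours$df2, oracle$df2)
})

test_that("single-family data reduce to the one-marker regression F test", {
  set.seed(33)
  map <- uniform_map(1, 40, 2)
  G <- simulate_family(80, map, seed = 34)
  y <- stats::setNames(G[, 7] * 0.4 + rnorm(80), rownames(G))
  fam <- rep("f1", 80)
  ours <- nested_marker_test(y, G, fam, 7)
  ref <- summary(stats::lm(y ~ G[, 7]))$fstatistic
  expect_equal(ours$F, unname(ref[1]), tolerance = 1e-8)
  # perfect fit underflows to the numerical floor, not NaN/Inf
  y2 <- stats::setNames(as.numeric(G[, 7]), rownames(G))
  perfect <- nested_marker_test(y2, G, fam, 7)
  expect_true(is.finite(perfect$nlp) && perfect$nlp >= 300)
  # monomorphic marker flags p = 1
  G2 <- G; G2[, 3] <- 2
  mono <- nested_marker_test(y, G2, fam, 3)
  expect_true(mono$monomorphic)
  expect_equal(mono$p, 1)
})

test_that("null nested-test p-values are uniform", {
  set.seed(35)
  map <- uniform_map(2, 100, 1)
  panel <- simulate_founders(6, map, nrow(map) + 10, seed = 36)
  pop <- simulate_population(panel, map, 200, seed = 37)
  y <- stats::setNames(rnorm(nrow(pop$lines)), pop$lines$line)
  # 500 independent null markers: permute each column's rows within family
  sc <- jl_scan(y, pop$geno, pop$lines$family)
  pvals <- 10^(-sc$nlp)
  # markers are correlated along chromosomes; thin to near-independence
  thin <- pvals[seq(1, length(pvals), by = 10)]
  ks <- stats::ks.test(thin, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation thresholds are quantiles with expected behaviour", {
  fx <- make_nam_fixture(n_families = 4, n_rils = 60, seed = 41)
  expect_warning(p1 <- permutation_threshold(fx$y, fx$G, fx$families,
                                             n_perm = 1, seed = 5),
                 "unstable")
  expect_equal(p1$threshold, p1$minp_nlp)   # single permutation
  p2 <- permutation_threshold(fx$y, fx$G, fx$families, n_perm = 60,
                              seed = 6)
  th <- vapply(c(0.01, 0.05, 0.2, 0.5), function(a) {
    as.numeric(stats::quantile(p2$minp_nlp, 1 - a))
  }, numeric(1))
  expect_true(all(diff(th) <= 0))            # monotone in alpha
  # determinism
  p3 <- permutation_threshold(fx$y, fx$G, fx$families, n_perm = 60,
                              seed = 6)
  expect_identical(p2$minp_nlp, p3$minp_nlp)
})

test_that("threshold agrees with the order-statistic approximation", {
  # independent null markers: threshold ~ -log10(1 - (1-alpha)^(1/m))
  set.seed(43)
  n <- 300; m <- 80
  fam <- rep(c("fA", "fB"), each = n / 2)
  G <- matrix(2 * rbinom(n * m, 1, 0.5), n, m)
  y <- stats::setNames(rnorm(n), paste0("l", 1:n))
  p <- permutation_threshold(y, G, fam, n_perm = 400, alpha = 0.05,
                             seed = 44)
  approx_th <- -log10(1 - 0.95^(1 / m))
  expect_lt(abs(p$threshold - approx_th), 0.35)
})

test_that("stepwise selection starts at the exhaustive-scan argmax", {
  fx <- make_nam_fixture(n_families = 5, n_rils = 80, seed = 51)
  sc <- jl_scan(fx$y, fx$G, fx$families)
  model <- joint_stepwise(fx$y, fx$G, fx$map, fx$families, threshold = 3)
  expect_equal(model$selected[1], which.max(sc$nlp))
  # model R2 non-decreasing as markers enter, every entry above threshold
  expect_true(all(model$peaks$nlp_entry > 3))
  fit_partial <- vapply(seq_along(model$selected), function(k) {
    1 - namhr:::jl_sse(fx$y, fx$G, fx$families,
                       model$selected[seq_len(k)])$sse /
      sum((fx$y - mean(fx$y))^2)
  }, numeric(1))
  expect_true(all(diff(c(0, fit_partial)) > -1e-12))
})

test_that("a displaced peak is pulled back by refinement", {
  fx <- make_nam_fixture(n_families = 6, n_rils = 120, seed = 52,
                         qtl_marker = c(25, 80, 130))
  model <- joint_stepwise(fx$y, fx$G, fx$map, fx$families, threshold = 4)
  # displace each selected marker by two map positions (same chromosome)
  displaced <- model$selected
  for (i in seq_along(displaced)) {
    on_chr <- which(fx$map$chrom == fx$map$chrom[displaced[i]])
    pos <- match(displaced[i], on_chr)
    displaced[i] <- on_chr[max(1, pos - 2)]
  }
  bad <- namhr:::jl_model(fx$y, fx$G, fx$map, fx$families, displaced,
                          model$threshold)
  ref <- refine_model(bad, fx$y, fx$G, fx$map, fx$families)
  expect_gte(ref$r2, bad$r2)
  # refinement returns to (at least as good as) the stepwise peaks
  expect_true(mean(ref$selected %in% model$selected) >= 2 / 3)
  # a local optimum is a fixed point
  ref2 <- refine_model(ref, fx$y, fx$G, fx$map, fx$families)
  expect_identical(ref2$selected, ref$selected)
})

test_that("allele effects are recovered with honest t-tests", {
  set.seed(53)
  map <- uniform_map(1, 60, 2)
  fams <- c("fA", "fB", "fC")
  G <- do.call(rbind, lapply(1:3, function(i) {
    simulate_family(400, map, seed = 60 + i)
  }))
  rownames(G) <- paste0("l", seq_len(nrow(G)))
  fam <- rep(fams, each = 400)
  true_eff <- c(fA = 0, fB = 0.5, fC = 1.0)
  qm <- 15
  y <- stats::setNames(true_eff[fam] * G[, qm] / 2 + rnorm(1200),
                       rownames(G))
  model <- namhr:::jl_model(y, G, map, fam, qm, threshold = 3)
  est <- estimate_allele_effects(model, y, G, fam)
  for (f in fams) {
    # slope on dosage is half the homozygote-contrast effect
    expect_lt(abs(est$effect[1, f] - true_eff[f] / 2), 2 * est$se[1, f])
  }
  # doubling the trait doubles every estimate
  est2 <- estimate_allele_effects(model, 2 * y, G, fam)
  expect_equal(est2$effect, 2 * est$effect, tolerance = 1e-9)
  # zero-effect family rejects at ~alpha over repeated noise draws
  rej <- vapply(1:60, function(k) {
    yk <- stats::setNames(true_eff[fam] * G[, qm] / 2 + rnorm(1200),
                          rownames(G))
    ek <- estimate_allele_effects(model, yk, G, fam)
    ek$p[1, "fA"] < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 60))
})

test_that("support intervals contain the peak and shrink with effect size", {
  covered <- logical(0)
  widths <- matrix(NA_real_, 6, 2)
  for (s in 1:6) {
    eff_scale <- rep(c(0.4, 1.2), 3)[s]
    fx <- make_nam_fixture(n_families = 6, n_rils = 120,
                           qtl_marker = 60, effect_sd = eff_scale,
                           seed = 100 + s)
    model <- joint_stepwise(fx$y, fx$G, fx$map, fx$families, threshold = 4)
    if (!length(model$selected)) next
    i <- which.max(model$peaks$r2_marginal)
    si <- support_interval(model, i, fx$y, fx$G, fx$map, fx$families)
    expect_true(si[1] <= model$peaks$cM[i] && si[2] >= model$peaks$cM[i])
    true_pos <- fx$map$cM[fx$qtl_marker]
    if (as.character(model$peaks$chrom[i]) ==
          as.character(fx$map$chrom[fx$qtl_marker])) {
      covered <- c(covered, true_pos >= si[1] && true_pos <= si[2])
    }
    widths[s, ] <- c(eff_scale, si[2] - si[1])
  }
  expect_gt(mean(covered), 0.5)
  w <- stats::na.omit(as.data.frame(widths))
  expect_lte(mean(w$V2[w$V1 > 1]), mean(w$V2[w$V1 < 1]))
})

test_that("single-family scans find family-private QTL the joint scan dilutes", {
  set.seed(55)
  map <- uniform_map(1, 80, 2)
  n_fam <- 8; n_rils <- 100
  G <- do.call(rbind, lapply(seq_len(n_fam), function(i) {
    simulate_family(n_rils, map, seed = 70 + i)
  }))
  rownames(G) <- paste0("l", seq_len(nrow(G)))
  fam <- rep(sprintf("f%02d", seq_len(n_fam)), each = n_rils)
  qm <- 20
  # private QTL: only family f01 carries a non-zero allele
  y <- stats::setNames(ifelse(fam == "f01", 0.9, 0) * G[, qm] / 2 +
                         rnorm(n_fam * n_rils), rownames(G))
  f1 <- fam == "f01"
  sf <- single_family_scan(y[f1], G[f1, ], n_perm = 100, seed = 56)
  expect_gt(max(sf$scan$nlp), sf$threshold)
  expect_equal(sf$scan$marker[which.max(sf$scan$nlp)], qm,
               tolerance = 3)
  # effect sign matches the simulated sign
  expect_gt(sf$scan$effect[which.max(sf$scan$nlp)], 0)
  # null family scan stays below its threshold most of the time
  below <- vapply(1:20, function(k) {
    yk <- rnorm(n_rils)
    sk <- single_family_scan(yk, G[f1, ], n_perm = 60, seed = 200 + k)
    max(sk$scan$nlp) <= sk$threshold
  }, logical(1))
  expect_gt(mean(below), 0.75)
})
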