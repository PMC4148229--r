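test_that("founder panels respect the reference parent and MAF window", {
  map <- uniform_map(2, 50, 5)
  p1 <- simulate_founders(25, map, 10000, maf_range = c(0.1, 0.5), seed = 3)
  p2 <- simulate_founders(25, map, 10000, maf_range = c(0.1, 0.5), seed = 3)
  expect_identical(p1, p2)                       # determinism
  expect_true(all(p1$alleles[p1$reference, ] == 0))
  # realized frequencies across the 24 non-reference founders stay inside
  # the sampling envelope of the target window
  freq <- colMeans(p1$alleles[-1, ])
  expect_true(all(freq > 0.05 - 1e-12 & freq < 0.55 + 1e-12))
  # two founders: only the non-reference one may carry alternate alleles
  p3 <- simulate_founders(2, map, 60, seed = 1)
  expect_true(all(p3$alleles[1, ] == 0))
  expect_error(simulate_founders(5, map, 60, maf_range = c(0, 0.5)),
               "maf_range")
})

test_that("RIL families follow the Haldane model and selfing depth", {
  # markers at identical cM are perfectly correlated
  map0 <- genetic_map(c("a", "b"), c(1, 1), c(10, 10), c(5e6, 5e6 + 1))
  g0 <- simulate_family(300, map0, seed = 2)
  expect_identical(g0[, 1], g0[, 2])
  # unlinked markers approach recombinant fraction 1/2
  map1 <- genetic_map(c("a", "b"), c(1, 1), c(0, 1200), c(1, 2e9))
  g1 <- simulate_family(2000, map1, seed = 4)
  hom <- g1[, 1] != 1 & g1[, 2] != 1
  rec <- mean(g1[hom, 1] != g1[hom, 2])
  expect_lt(abs(rec - 0.5), 3 * sqrt(0.25 / sum(hom)))
  # residual heterozygosity ~ (1/2)^selfing
  map2 <- uniform_map(1, 100, 1)
  g2 <- simulate_family(2000, map2, selfing = 6, seed = 5)
  p_het <- mean(g2 == 1)
  se <- sqrt((1 / 64) * (63 / 64) / length(g2))
  expect_lt(abs(p_het - 1 / 64), 4 * se)
  # adjacent-marker recombinant fraction matches Haldane r(d)
  rec_all <- vapply(seq_len(ncol(g2) - 1), function(j) {
    ok <- g2[, j] != 1 & g2[, j + 1] != 1
    mean(g2[ok, j] != g2[ok, j + 1])
  }, numeric(1))
  r <- haldane(1)
  expect_lt(abs(mean(rec_all) - r), 3 * sqrt(r * (1 - r) / 2000) / 2)
  # within-family allele frequency ~ 0.5 at every marker
  freq <- colMeans(g2 / 2)
  expect_true(all(abs(freq - 0.5) < 4 * sqrt(0.25 / nrow(g2))))
  expect_error(simulate_family(10, map2, selfing = 0), "selfing")
})

test_that("genetic values equal the brute-force truth-registry sum", {
  fx <- make_nam_fixture(n_families = 4, n_rils = 30, seed = 9)
  pop <- fx$pop
  tm <- fx$tm
  founder_of <- pop$families$founder[match(pop$lines$family,
                                           pop$families$family)]
  # independent re-summation over 20 hand-picked RILs
  idx <- seq(1, nrow(pop$lines), length.out = 20)
  for (i in round(idx)) {
    v <- 0
    for (q in seq_along(pop$truth$qtl_marker)) {
      dose <- pop$geno[i, pop$truth$qtl_marker[q]]
      v <- v + tm$effects[founder_of[i], q] * dose / 2
    }
    expect_equal(unname(pop$genetic_values[i]), unname(v))
  }
  # all-zero effects give all-zero values
  tm0 <- trait_model(tm$qtl, tm$effects * 0, h2_line = 0.5)
  pop0 <- assign_genetic_values(pop, tm0)
  expect_true(all(pop0$genetic_values == 0))
  # homozygous non-reference single-QTL line scores the full effect
  expect_error(assign_genetic_values(pop,
    trait_model(data.frame(chrom = "1", cM = 5000),
                tm$effects[, 1, drop = FALSE])), "outside|QTL")
})

test_that("epistatic terms use centred-dosage products", {
  fx <- make_nam_fixture(n_families = 3, n_rils = 25, seed = 13)
  pop <- fx$pop
  qtl <- data.frame(chrom = c("1", "2"), cM = c(20, 40))
  eff <- matrix(0, 3, 2, dimnames = list(pop$families$founder, NULL))
  epi <- data.frame(q1 = 1, q2 = 2, effect = 0.7)
  tm <- trait_model(qtl, eff, epistasis = epi, h2_line = 0.5)
  pop <- assign_genetic_values(pop, tm)
  m1 <- pop$truth$qtl_marker[1]; m2 <- pop$truth$qtl_marker[2]
  expect_equal(unname(pop$genetic_values),
               unname(0.7 * (pop$geno[, m1] - 1) * (pop$geno[, m2] - 1)))
})

test_that("phenotype noise hits the target line-mean heritability", {
  fx <- make_nam_fixture(n_families = 8, n_rils = 130, h2 = 0.85, seed = 21)
  vc <- estimate_variance_components(fx$plots)
  expect_lt(abs(heritability(vc) - 0.85), 0.05)
  # h2 = 1 gives zero residual noise and H2 = 1
  tm1 <- trait_model(fx$tm$qtl, fx$tm$effects, h2_line = 1, n_env = 3)
  ph1 <- simulate_phenotypes(fx$pop, tm1, seed = 2)
  vc1 <- estimate_variance_components(ph1$plots)
  expect_equal(heritability(vc1), 1)
  # determinism
  ph_a <- simulate_phenotypes(fx$pop, fx$tm, seed = 33, ratings = TRUE)
  ph_b <- simulate_phenotypes(fx$pop, fx$tm, seed = 33, ratings = TRUE)
  expect_identical(ph_a, ph_b)
  expect_true(all(ph_a$ratings$score >= 1 & ph_a$ratings$score <= 10))
})

test_that("corrupt_calls reproduces the configured error processes", {
  map <- uniform_map(1, 50, 1)
  g <- simulate_family(400, map, seed = 6)
  expect_identical(corrupt_calls(g, 0, 0, 0, seed = 1), g)  # identity
  # 80% of true heterozygotes scored homozygous
  all_het <- matrix(1L, 200, 300)
  cc <- corrupt_calls(all_het, missing_rate = 0, allele_error_rate = 0,
                      het_dropout = 0.8, seed = 2)
  hom_rate <- mean(cc != 1)
  expect_lt(abs(hom_rate - 0.8), 4 * sqrt(0.8 * 0.2 / length(cc)))
  # 50% missingness
  cm <- corrupt_calls(g, missing_rate = 0.5, allele_error_rate = 0,
                      het_dropout = 0, seed = 3)
  expect_lt(abs(mean(is.na(cm)) - 0.5), 4 * sqrt(0.25 / length(g)))
  expect_error(corrupt_calls(g, missing_rate = 1.5), "rates")
})
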