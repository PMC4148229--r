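# Synthetic NAM population generator.
#
# Emulates the structure the downstream analyses assume: a panel of diverse
# founders crossed to one common reference parent, biparental RIL families
# segregating two parental alleles, founder-specific allelic series at QTL,
# repeated lesion ratings over a season, and genotyping error processes
# (heterozygote dropout, allele flips, missing data) for the HMM stage.

#' Simulate a founder panel with dense variants
#'
#' Generates `n_founders` founders (the first is the common reference
#' parent, all-0 by construction) genotyped at `n_dense` dense biallelic
#' variants placed uniformly along the mapped genome. Alternate-allele
#' frequencies among the non-reference founders are drawn per variant from
#' `maf_range`.
#'
#' @param n_founders Number of founders including the reference parent
#'   (>= 2).
#' @param map A [genetic_map()] giving the mapped-marker span per
#'   chromosome; dense variants are placed within it.
#' @param n_dense Total number of dense variants (>= number of mapped
#'   markers).
#' @param maf_range Interval in (0, 1) from which each variant's target
#'   alternate-allele frequency is drawn.
#' @param seed Integer seed.
#' @return A `founder_panel`: list with `founder_ids` (reference parent
#'   first), `alleles` (founder x variant 0/1 matrix) and `positions`
#'   (data.frame variant/chrom/bp).
#' @export
simulate_founders <- function(n_founders, map, n_dense,
                              maf_range = c(0.1, 0.5), seed = 1) {
  if (n_founders < 2) stop("need at least two founders")
  if (any(maf_range <= 0) || any(maf_range >= 1) || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie inside (0, 1)")
  }
  validate_map(map)
  if (n_dense < nrow(map)) stop("n_dense must be >= number of mapped markers")
  with_seed(seed, {
    chroms <- unique(map$chrom)
    span <- vapply(chroms, function(ch) {
      b <- map$bp[map$chrom == ch]
      diff(range(b)) + 1
    }, numeric(1))
    n_per <- pmax(1L, round(n_dense * span / sum(span)))
    # adjust so counts total n_dense
    while (sum(n_per) != n_dense) {
      i <- if (sum(n_per) > n_dense) which.max(n_per) else which.min(n_per)
      n_per[i] <- n_per[i] + sign(n_dense - sum(n_per))
    }
    pos_list <- lapply(seq_along(chroms), function(i) {
      b <- map$bp[map$chrom == chroms[i]]
      p <- sort(sample(seq(min(b), max(b)), n_per[i], replace = FALSE))
      data.frame(chrom = chroms[i], bp = p, stringsAsFactors = FALSE)
    })
    positions <- do.call(rbind, pos_list)
    positions$variant <- sprintf("dv_%s_%d", positions$chrom, positions$bp)
    positions <- positions[, c("variant", "chrom", "bp")]
    m <- nrow(positions)
    freq <- stats::runif(m, maf_range[1], maf_range[2])
    # draw exact alternate-allele counts so realized frequencies stay
    # inside the target window (up to count rounding)
    n_alt <- pmin(pmax(round(freq * (n_founders - 1L)), 1L),
                  n_founders - 1L)
    alleles <- matrix(0L, nrow = n_founders, ncol = m)
    for (j in seq_len(m)) {
      carriers <- sample(n_founders - 1L, n_alt[j])
      alleles[1L + carriers, j] <- 1L
    }
    founder_ids <- c("REF", sprintf("F%02d", seq_len(n_founders - 1L)))
    dimnames(alleles) <- list(founder_ids, positions$variant)
    structure(list(founder_ids = founder_ids,
                   reference = founder_ids[1],
                   alleles = alleles,
                   positions = positions),
              class = "founder_panel")
  })
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("founder_panel:", length(x$founder_ids), "founders (reference:",
      x$reference, "),", nrow(x$positions), "dense variants\n")
  invisible(x)
}

#' Simulate one biparental RIL family
#'
#' Draws `n_rils` recombinant inbred lines from a cross between the common
#' reference parent and one diverse founder. Each RIL's parent-of-origin
#' mosaic is a two-state Markov chain along the chromosome whose switch
#' probability between adjacent markers is the Haldane recombination
#' fraction of their map distance; residual heterozygosity is overlaid as a
#' second two-state chain with stationary frequency `(1/2)^selfing`.
#' Genotypes are returned as dosage of the non-reference allele: 0
#' (reference homozygote), 1 (heterozygote) or 2 (founder homozygote).
#'
#' @param n_rils Number of lines.
#' @param map A sorted [genetic_map()].
#' @param selfing Number of selfing generations (>= 1); expected residual
#'   heterozygote frequency per locus is `0.5^selfing`.
#' @param seed Integer seed.
#' @return Integer matrix `n_rils` x `nrow(map)` with values in {0, 1, 2};
#'   columns named by marker.
#' @export
simulate_family <- function(n_rils, map, selfing = 6, seed = 1) {
  if (selfing < 1) stop("selfing must be >= 1")
  validate_map(map)
  for (ch in unique(map$chrom)) {
    if (is.unsorted(map$cM[map$chrom == ch])) {
      stop("map is not sorted by cM within chromosome ", ch)
    }
  }
  p_het <- 0.5 ^ selfing
  with_seed(seed, {
    geno <- matrix(0L, nrow = n_rils, ncol = nrow(map),
                   dimnames = list(sprintf("RIL%04d", seq_len(n_rils)),
                                   map$marker))
    for (idx in map_chrom_index(map)) {
      m <- length(idx)
      r <- haldane(diff(map$cM[idx]))
      # parent-of-origin mosaic, vectorised per RIL via switch parity
      for (i in seq_len(n_rils)) {
        start <- stats::rbinom(1L, 1L, 0.5)
        sw <- if (m > 1L) stats::rbinom(m - 1L, 1L, r) else integer(0)
        geno[i, idx] <- (start + c(0L, cumsum(sw))) %% 2L
      }
      # heterozygosity chain: stationary p_het, distance-driven persistence
      a <- if (m > 1L) (1 - r) ^ (2 * selfing) else numeric(0)
      het <- matrix(0L, n_rils, m)
      het[, 1L] <- stats::rbinom(n_rils, 1L, p_het)
      if (m > 1L) {
        for (j in 2:m) {
          stay <- a[j - 1L] + (1 - a[j - 1L]) * p_het
          enter <- (1 - a[j - 1L]) * p_het
          pr <- ifelse(het[, j - 1L] == 1L, stay, enter)
          het[, j] <- stats::rbinom(n_rils, 1L, pr)
        }
      }
      block <- 2L * geno[, idx, drop = FALSE]
      block[het == 1L] <- 1L
      geno[, idx] <- block
    }
    geno
  })
}

#' Specify a trait's genetic architecture
#'
#' @param qtl Data frame with columns `chrom` and `cM` giving QTL
#'   positions on the map.
#' @param effects Founder x QTL matrix of additive allele effects in trait
#'   units, relative to the common reference parent (whose row, if present,
#'   must be zero). Row names are founder ids; unnamed effects apply to all
#'   non-reference founders.
#' @param epistasis Optional data.frame with columns `q1`, `q2` (QTL row
#'   indices) and `effect`; interactions use the product of centered
#'   dosages (Cockerham coding), keeping additive and epistatic terms
#'   orthogonal in expectation.
#' @param h2_line Target line-mean heritability in `[0, 1]`.
#' @param n_env Number of environments.
#' @param n_reps Replicates per environment.
#' @param rating_days Day offsets (since planting) of repeated lesion
#'   ratings within a season.
#' @return A `trait_model` list.
#' @export
trait_model <- function(qtl, effects, epistasis = NULL, h2_line = 0.85,
                        n_env = 4, n_reps = 1,
                        rating_days = c(30, 42, 54, 66, 78)) {
  if (h2_line < 0 || h2_line > 1) stop("h2_line must be in [0, 1]")
  qtl <- as.data.frame(qtl)
  stopifnot(all(c("chrom", "cM") %in% names(qtl)))
  effects <- as.matrix(effects)
  if (ncol(effects) != nrow(qtl)) stop("one effect column per QTL required")
  if (!is.null(epistasis)) {
    epistasis <- as.data.frame(epistasis)
    stopifnot(all(c("q1", "q2", "effect") %in% names(epistasis)))
    if (any(epistasis$q1 == epistasis$q2)) stop("epistatic loci must differ")
  }
  structure(list(qtl = qtl, effects = effects, epistasis = epistasis,
                 h2_line = h2_line, n_env = n_env, n_reps = n_reps,
                 rating_days = sort(rating_days)),
            class = "trait_model")
}

#' Simulate a complete NAM population
#'
#' Crosses each non-reference founder to the common parent and simulates a
#' RIL family from each, producing truth-registered genotypes at the mapped
#' markers.
#'
#' @param panel A [simulate_founders()] panel.
#' @param map Mapped-marker [genetic_map()].
#' @param n_rils_per_family Lines per family (recycled across families).
#' @param selfing Selfing generations.
#' @param seed Integer seed.
#' @return A `nam_population`: list with `lines` (data.frame line/family),
#'   `families` (data.frame family/founder), `geno` (line x marker dosage
#'   matrix), and `map`.
#' @export
simulate_population <- function(panel, map, n_rils_per_family = 150,
                                selfing = 6, seed = 1) {
  stopifnot(inherits(panel, "founder_panel"))
  founders <- setdiff(panel$founder_ids, panel$reference)
  n_rils <- rep_len(n_rils_per_family, length(founders))
  blocks <- vector("list", length(founders))
  lines <- vector("list", length(founders))
  for (i in seq_along(founders)) {
    fam <- sprintf("fam%02d", i)
    g <- simulate_family(n_rils[i], map, selfing = selfing,
                         seed = derive_seed(seed, paste0("family_", fam)))
    rownames(g) <- sprintf("%s_%s", fam, rownames(g))
    blocks[[i]] <- g
    lines[[i]] <- data.frame(line = rownames(g), family = fam,
                             stringsAsFactors = FALSE)
  }
  structure(list(lines = do.call(rbind, lines),
                 families = data.frame(family = sprintf("fam%02d",
                                                        seq_along(founders)),
                                       founder = founders,
                                       stringsAsFactors = FALSE),
                 geno = do.call(rbind, blocks),
                 map = map),
            class = "nam_population")
}

#' @export
print.nam_population <- function(x, ...) {
  cat("nam_population:", nrow(x$lines), "RILs in", nrow(x$families),
      "families,", nrow(x$map), "mapped markers\n")
  invisible(x)
}

#' Assign true genetic values under a trait model
#'
#' The genetic value of a line is the sum over QTL of the founder-specific
#' additive effect scaled by half the dosage of the non-reference allele
#' (so a founder homozygote contributes the full effect, a heterozygote
#' half), plus any epistatic terms on centered dosages `(g - 1)`.
#'
#' @param pop A [simulate_population()] object.
#' @param tm A [trait_model()].
#' @return `pop` with elements `genetic_values` (named numeric) and
#'   `truth` (QTL marker indices and the trait model) added.
#' @export
assign_genetic_values <- function(pop, tm) {
  stopifnot(inherits(pop, "nam_population"), inherits(tm, "trait_model"))
  map <- pop$map
  qidx <- integer(nrow(tm$qtl))
  for (q in seq_len(nrow(tm$qtl))) {
    on_chr <- which(map$chrom == as.character(tm$qtl$chrom[q]))
    if (!length(on_chr)) stop("QTL ", q, " lies on a chromosome not in the map")
    d <- abs(map$cM[on_chr] - tm$qtl$cM[q])
    if (min(d) > max(diff(range(map$cM[on_chr])), 1)) {
      stop("QTL ", q, " lies outside the map")
    }
    if (tm$qtl$cM[q] < min(map$cM[on_chr]) - 1e-9 ||
        tm$qtl$cM[q] > max(map$cM[on_chr]) + 1e-9) {
      stop("QTL ", q, " position outside mapped span of chromosome ",
           tm$qtl$chrom[q])
    }
    qidx[q] <- on_chr[which.min(d)]
  }
  fam_of <- pop$lines$family
  founder_of <- pop$families$founder[match(fam_of, pop$families$family)]
  eff <- tm$effects
  if (is.null(rownames(eff))) {
    eff <- matrix(rep(t(eff), 1), nrow = length(unique(founder_of)),
                  ncol = ncol(eff), byrow = TRUE,
                  dimnames = list(unique(founder_of), NULL))
  }
  g <- numeric(nrow(pop$lines))
  for (q in seq_along(qidx)) {
    dose <- pop$geno[, qidx[q]]
    e <- eff[founder_of, q]
    g <- g + e * dose / 2
  }
  if (!is.null(tm$epistasis)) {
    for (k in seq_len(nrow(tm$epistasis))) {
      w1 <- pop$geno[, qidx[tm$epistasis$q1[k]]] - 1
      w2 <- pop$geno[, qidx[tm$epistasis$q2[k]]] - 1
      g <- g + tm$epistasis$effect[k] * w1 * w2
    }
  }
  names(g) <- pop$lines$line
  pop$genetic_values <- g
  pop$truth <- list(qtl_marker = qidx, model = tm,
                    qtl_cM = map$cM[qidx], qtl_chrom = map$chrom[qidx])
  pop
}

#' Simulate plot-level phenotypes and lesion rating series
#'
#' Adds environment, line-by-environment and residual noise around the
#' true genetic values, with variance components chosen so the line-mean
#' heritability `H2 = s2_L / (s2_L + s2_LE/nE + s2_e/(nE nR))` matches the
#' trait model's target. Lesion ratings follow a logistic disease-progress
#' curve whose asymptote reflects the plot's phenotypic value, with bounded
#' noise, clipped and rounded to the 1-10 integer scale.
#'
#' @param pop Population with genetic values assigned.
#' @param tm A [trait_model()].
#' @param seed Integer seed.
#' @param ratings If `TRUE`, also simulate the repeated rating series.
#' @return List with `plots` (data.frame line/family/env/rep/value) and,
#'   if requested, `ratings` (line/family/env/rep/day/score).
#' @export
simulate_phenotypes <- function(pop, tm, seed = 1, ratings = FALSE) {
  stopifnot(!is.null(pop$genetic_values))
  g <- pop$genetic_values
  s2_g <- stats::var(g)
  h2 <- tm$h2_line
  nE <- tm$n_env
  nR <- tm$n_reps
  if (h2 <= 0 && s2_g == 0) stop("h2_line = 0 with a degenerate trait model")
  if (s2_g == 0 && h2 > 0) stop("no genetic variance but h2_line > 0 requested")
  if (h2 == 1) {
    s2_le <- 0; s2_e <- 0
  } else {
    s2_le <- 0.25 * s2_g
    s2_e <- nE * nR * (s2_g / h2 - s2_g - s2_le / nE)
    if (s2_e < 0) {               # target so high the LE share must shrink
      s2_le <- max(0, nE * (s2_g / h2 - s2_g))
      s2_e <- 0
    }
  }
  s2_env <- 0.5 * s2_g
  n <- length(g)
  with_seed(seed, {
    env_eff <- stats::rnorm(nE, 0, sqrt(s2_env))
    le <- matrix(stats::rnorm(n * nE, 0, sqrt(s2_le)), n, nE)
    rows <- vector("list", nE * nR)
    k <- 0
    for (e in seq_len(nE)) {
      for (r in seq_len(nR)) {
        k <- k + 1
        val <- g + env_eff[e] + le[, e] + stats::rnorm(n, 0, sqrt(s2_e))
        rows[[k]] <- data.frame(line = pop$lines$line,
                                family = pop$lines$family,
                                env = sprintf("env%d", e),
                                rep = r, value = val,
                                stringsAsFactors = FALSE)
      }
    }
    plots <- do.call(rbind, rows)
    out <- list(plots = plots,
                components = c(s2_line = s2_g, s2_env = s2_env,
                               s2_line_env = s2_le, s2_resid = s2_e))
    if (ratings) {
      days <- tm$rating_days
      rng <- range(plots$value)
      sev <- if (diff(rng) > 0) {
        1 + 9 * (plots$value - rng[1]) / diff(rng)
      } else rep(5, nrow(plots))
      t_mid <- mean(range(days))
      tau <- diff(range(days)) / 6
      rl <- vector("list", length(days))
      for (i in seq_along(days)) {
        mu <- 1 + (sev - 1) / (1 + exp(-(days[i] - t_mid) / tau))
        sc <- round(pmin(10, pmax(1, mu + stats::rnorm(length(mu), 0, 0.3))))
        rl[[i]] <- data.frame(plots[, c("line", "family", "env", "rep")],
                              day = days[i], score = sc,
                              stringsAsFactors = FALSE)
      }
      out$ratings <- do.call(rbind, rl)
    }
    out
  })
}

#' Corrupt true genotype calls with realistic error processes
#'
#' Applies, in order: heterozygote dropout (a heterozygous site is scored
#' as one of the two homozygotes, side at random), independent per-allele
#' flip errors, and missingness.
#'
#' @param geno Integer dosage matrix with values in {0, 1, 2}.
#' @param missing_rate,allele_error_rate,het_dropout Rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return Matrix of raw calls in {0, 1, 2, NA}.
#' @export
corrupt_calls <- function(geno, missing_rate = 0.5,
                          allele_error_rate = 0.002, het_dropout = 0.8,
                          seed = 1) {
  rates <- c(missing_rate, allele_error_rate, het_dropout)
  if (any(rates < 0) || any(rates > 1)) stop("rates must be in [0, 1]")
  with_seed(seed, {
    out <- geno
    n <- length(out)
    # het dropout
    is_het <- which(out == 1L)
    drop <- is_het[stats::runif(length(is_het)) < het_dropout]
    out[drop] <- 2L * stats::rbinom(length(drop), 1L, 0.5)
    # independent allele flips: each of the two alleles flips w.p. e
    e <- allele_error_rate
    if (e > 0) {
      flips <- matrix(stats::runif(2 * n) < e, ncol = 2)
      nflip <- rowSums(flips)
      cur <- as.integer(out)
      # flipping k alleles moves dosage toward the opposite homozygote
      new <- cur
      one <- which(nflip == 1)
      new[one] <- ifelse(cur[one] == 1L,
                         2L * stats::rbinom(length(one), 1L, 0.5),
                         1L)
      two <- which(nflip == 2)
      new[two] <- 2L - cur[two]
      out[] <- new
    }
    miss <- stats::runif(n) < missing_rate
    out[miss] <- NA_integer_
    out
  })
}
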