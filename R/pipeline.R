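# End-to-end orchestration on synthetic data: simulate -> derive traits ->
# correct/impute/project genotypes -> permutation threshold -> joint
# stepwise -> refine -> effects/intervals -> epistasis -> GWAS -> report.

#' Build a pipeline run configuration
#'
#' @param n_families Number of RIL families.
#' @param n_rils Lines per family.
#' @param n_chrom,chrom_length_cM,marker_spacing_cM Map geometry.
#' @param n_dense Dense founder variants for the GWAS stage.
#' @param n_qtl Number of simulated QTL.
#' @param h2_line Target line-mean heritability.
#' @param n_env Environments.
#' @param selfing Selfing generations.
#' @param n_perm Permutations for the entry threshold (0 = use
#'   `threshold` directly).
#' @param threshold Explicit entry threshold (-log10 p) when `n_perm = 0`.
#' @param alpha Genome-wide level for the permutation threshold.
#' @param p_enter GWAS forward-selection entry p.
#' @param n_subsamples,fraction Subagging settings.
#' @param rmip_floor,window_bp GWAS reporting settings.
#' @param step_cM Imputation grid spacing.
#' @param seed Master seed; per-stage seeds are derived from it by
#'   [derive_seed()].
#' @return A `run_config` list.
#' @export
run_config <- function(n_families = 10, n_rils = 150, n_chrom = 5,
                       chrom_length_cM = 100, marker_spacing_cM = 1,
                       n_dense = 2000, n_qtl = 8, h2_line = 0.85,
                       n_env = 4, selfing = 6, n_perm = 200,
                       threshold = NA, alpha = 0.05, p_enter = 1e-6,
                       n_subsamples = 100, fraction = 0.8,
                       rmip_floor = 0.05, window_bp = 2000,
                       step_cM = 0.2, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(alpha > 0, alpha < 1, p_enter > 0, p_enter < 1,
            fraction > 0, fraction <= 1, rmip_floor >= 0, rmip_floor < 1,
            step_cM > 0, h2_line >= 0, h2_line <= 1)
  if (cfg$n_perm == 0 && !is.finite(cfg$threshold)) {
    stop("n_perm = 0 requires an explicit threshold")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Write and read a run configuration as key=value text
#'
#' @param cfg A [run_config()].
#' @param file Path.
#' @export
write_run_config <- function(cfg, file) {
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) format(v, digits = 17),
                            character(1))),
             file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  kv <- strsplit(readLines(file), "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- utils::type.convert(x[2], as.is = TRUE)
    v
  })
  names(vals) <- vapply(kv, `[`, character(1), 1)
  do.call(run_config, vals)
}

#' Run the full synthetic-demonstration pipeline
#'
#' Executes every stage of the analysis at the configured scale on a
#' simulated NAM population and writes all tabular outputs plus a
#' manifest of stage seeds to `dir`. Deterministic for a fixed master
#' seed.
#'
#' @param cfg A [run_config()].
#' @param dir Output directory (created if needed).
#' @param gwas Run the (comparatively expensive) subagging GWAS stage.
#' @return Invisibly, a list with all intermediate objects: population,
#'   trait table, threshold, model (refined), effects, intervals,
#'   epistasis, associations, clusters.
#' @export
run_pipeline <- function(cfg, dir = tempfile("namhr_run_"), gwas = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(s) derive_seed(cfg$seed, s)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, msg)
  }

  note("simulate: %d families x %d RILs", cfg$n_families, cfg$n_rils)
  map <- uniform_map(cfg$n_chrom, cfg$chrom_length_cM, cfg$marker_spacing_cM)
  panel <- simulate_founders(cfg$n_families + 1L, map, cfg$n_dense,
                             seed = stage_seed("founders"))
  pop <- simulate_population(panel, map, cfg$n_rils, cfg$selfing,
                             seed = stage_seed("population"))
  qtl_markers <- round(seq(1, nrow(map), length.out = cfg$n_qtl + 2))
  qtl_markers <- qtl_markers[-c(1, length(qtl_markers))]
  eff <- with_seed(stage_seed("effects"), {
    matrix(stats::rnorm(cfg$n_families * cfg$n_qtl, 0, 0.5),
           cfg$n_families, cfg$n_qtl,
           dimnames = list(pop$families$founder, NULL))
  })
  tm <- trait_model(qtl = data.frame(chrom = map$chrom[qtl_markers],
                                     cM = map$cM[qtl_markers]),
                    effects = eff, h2_line = cfg$h2_line,
                    n_env = cfg$n_env)
  pop <- assign_genetic_values(pop, tm)
  ph <- simulate_phenotypes(pop, tm, seed = stage_seed("phenotypes"),
                            ratings = TRUE)
  write_genetic_map(map, file.path(dir, "map.tsv"))
  write_plot_records(ph$plots, file.path(dir, "plots.tsv"))

  note("traits: sAUDPC + LS means for %d lines", nrow(pop$lines))
  traits <- derive_traits(ratings = ph$ratings)
  lsm <- ls_means(ph$plots)
  traits$VALUE <- lsm$lsmean[match(traits$line, lsm$line)]
  write_trait_table(traits, file.path(dir, "traits.tsv"))
  y <- traits$VALUE
  names(y) <- traits$line
  families <- traits$family
  G <- pop$geno[traits$line, , drop = FALSE]

  note("impute: %g cM grid", cfg$step_cM)
  grid <- impute_grid(G, map, step_cM = cfg$step_cM)

  if (cfg$n_perm > 0) {
    note("threshold: %d permutations at alpha = %g", cfg$n_perm, cfg$alpha)
    perm <- permutation_threshold(y, G, families, n_perm = cfg$n_perm,
                                  alpha = cfg$alpha,
                                  seed = stage_seed("permutations"))
    threshold <- perm$threshold
  } else {
    note("threshold: permutation stage skipped, explicit threshold %g",
         cfg$threshold)
    threshold <- cfg$threshold
  }

  note("joint stepwise at threshold %.2f", threshold)
  model <- joint_stepwise(y, G, map, families, threshold)
  note("refine: %d QTL", length(model$selected))
  model <- refine_model(model, y, G, map, families)
  effects <- if (length(model$selected)) {
    estimate_allele_effects(model, y, G, families)
  } else NULL
  intervals <- if (length(model$selected)) {
    t(vapply(seq_along(model$selected), function(i) {
      support_interval(model, i, y, G, map, families)
    }, numeric(2)))
  } else matrix(numeric(0), 0, 2)

  qtl_tab <- model$peaks
  if (nrow(qtl_tab)) {
    qtl_tab$ci_lo <- intervals[, 1]
    qtl_tab$ci_hi <- intervals[, 2]
  }
  utils::write.table(qtl_tab, file.path(dir, "qtl_model.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(effects)) {
    utils::write.table(data.frame(marker = rownames(effects$effect),
                                  effects$effect, check.names = FALSE),
                       file.path(dir, "allele_effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  note("epistasis scan on ~1 cM subset")
  sub <- thin_markers(map, spacing_cM = max(2, cfg$marker_spacing_cM * 5))
  epi <- epistasis_scan(y, G, families, sub,
                        scan_threshold = threshold, model = model)
  utils::write.table(epi[epi$scan_nlp > threshold, ],
                     file.path(dir, "epistasis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  assoc <- NULL; clusters <- NULL
  if (gwas) {
    note("GWAS: %d subsamples x %d dense variants", cfg$n_subsamples,
         nrow(panel$positions))
    fam_founder <- stats::setNames(pop$families$founder,
                                   pop$families$family)
    dense <- project_population(G, map, panel, families, fam_founder)
    assoc <- subagging_rmip(y, model, G, map, families, dense,
                            panel$positions,
                            n_subsamples = cfg$n_subsamples,
                            fraction = cfg$fraction,
                            p_enter = cfg$p_enter,
                            rmip_floor = cfg$rmip_floor,
                            seed = stage_seed("gwas"))
    clusters <- collapse_clusters(assoc, window_bp = cfg$window_bp)
    utils::write.table(assoc, file.path(dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clusters, file.path(dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- c(sprintf("master_seed=%d", cfg$seed),
                sprintf("stage_seed_%s=%d",
                        c("founders", "population", "effects",
                          "phenotypes", "permutations", "gwas"),
                        vapply(c("founders", "population", "effects",
                                 "phenotypes", "permutations", "gwas"),
                               stage_seed, integer(1))),
                sprintf("threshold=%.6f", threshold))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  writeLines(log_lines, file.path(dir, "log.txt"))
  write_run_config(cfg, file.path(dir, "config.txt"))

  invisible(list(dir = dir, map = map, panel = panel, pop = pop,
                 traits = traits, threshold = threshold, model = model,
                 effects = effects, intervals = intervals, epistasis = epi,
                 associations = assoc, clusters = clusters))
}

#' Summarise a completed pipeline run
#'
#' Reads the tabular outputs of [run_pipeline()] from disk and builds a
#' cross-checked plain-text report: QTL table, allele-effect matrix
#' dimensions, association clusters. Missing stages are marked rather
#' than failing.
#'
#' @param dir Run directory.
#' @return List with `text` (character lines), `qtl` (data.frame),
#'   `effects` (matrix or `NULL`), `clusters` (data.frame or `NULL`).
#' @export
make_report <- function(dir) {
  txt <- character(0)
  qtl <- NULL; effects <- NULL; clusters <- NULL
  f <- file.path(dir, "qtl_model.tsv")
  if (file.exists(f)) {
    qtl <- utils::read.delim(f, stringsAsFactors = FALSE)
    txt <- c(txt, sprintf("QTL detected: %d", nrow(qtl)))
    if (nrow(qtl) == 0) txt <- c(txt, "  (empty model: zero QTL)")
  } else {
    txt <- c(txt, "QTL model: MISSING")
  }
  f <- file.path(dir, "allele_effects.tsv")
  if (file.exists(f)) {
    eff_df <- utils::read.delim(f, stringsAsFactors = FALSE,
                                check.names = FALSE)
    effects <- as.matrix(eff_df[, -1, drop = FALSE])
    rownames(effects) <- eff_df$marker
    txt <- c(txt, sprintf("Allele-effect matrix: %d QTL x %d families",
                          nrow(effects), ncol(effects)))
    if (!is.null(qtl) && nrow(effects) != nrow(qtl)) {
      txt <- c(txt, "  WARNING: effect rows do not match QTL table")
    }
  } else if (!is.null(qtl) && nrow(qtl) > 0) {
    txt <- c(txt, "Allele effects: MISSING")
  }
  f <- file.path(dir, "clusters.tsv")
  if (file.exists(f)) {
    clusters <- utils::read.delim(f, stringsAsFactors = FALSE)
    txt <- c(txt, sprintf("Association clusters (RMIP > floor): %d",
                          nrow(clusters)))
  } else {
    txt <- c(txt, "GWAS clusters: not run")
  }
  list(text = txt, qtl = qtl, effects = effects, clusters = clusters)
}
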