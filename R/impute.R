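# Grid imputation and dense-variant projection.

#' Impute dosages onto a uniform centimorgan grid
#'
#' Places grid points every `step_cM` from 0 to the end of each
#' chromosome and imputes the expected dosage of the non-reference allele
#' at each point from the corrected marker states: a point flanked by
#' markers carrying the same parental dosage gets that dosage exactly
#' (0 or 2 for homozygous tracts); between markers of different dosage the
#' value is the linear interpolation in genetic distance; beyond the
#' terminal markers the nearest marker's dosage is carried.
#'
#' @param states Lines x markers dosage matrix (from [viterbi_correct()]
#'   or true genotypes), columns aligned with `map`.
#' @param map A [genetic_map()].
#' @param step_cM Grid spacing in centimorgans (default 0.2).
#' @return List with `dosage` (lines x grid points, values in `[0, 2]`)
#'   and `grid` (a [genetic_map()] of the grid points; bp positions are
#'   interpolated linearly between mapped markers).
#' @export
impute_grid <- function(states, map, step_cM = 0.2) {
  stopifnot(ncol(states) == nrow(map))
  chrom_idx <- map_chrom_index(map)
  grids <- list(); blocks <- list()
  for (ci in seq_along(chrom_idx)) {
    idx <- chrom_idx[[ci]]
    ch <- names(chrom_idx)[ci]
    if (!length(idx)) next
    x <- map$cM[idx]
    gx <- seq(0, max(x), by = step_cM)
    bp <- stats::approx(x, map$bp[idx], xout = gx, rule = 2,
                        ties = mean)$y
    grids[[ci]] <- data.frame(marker = sprintf("grid_%s_%05.1f", ch, gx),
                              chrom = ch, cM = gx, bp = round(bp),
                              stringsAsFactors = FALSE)
    if (length(unique(x)) == 1L) {
      blk <- matrix(rep(rowMeans(states[, idx, drop = FALSE]), length(gx)),
                    ncol = length(gx))
    } else {
      blk <- t(apply(states[, idx, drop = FALSE], 1L, function(y) {
        stats::approx(x, y, xout = gx, rule = 2, ties = mean)$y
      }))
    }
    blocks[[ci]] <- blk
  }
  grid <- do.call(rbind, grids)
  rownames(grid) <- NULL
  class(grid) <- c("genetic_map", "data.frame")
  dosage <- do.call(cbind, blocks)
  dimnames(dosage) <- list(rownames(states), grid$marker)
  list(dosage = dosage, grid = grid)
}

#' Project a dense variant from flanking mapped markers
#'
#' The expected dosage of the non-reference allele at a dense founder
#' variant is the physical-distance-weighted average of the dosages at
#' the flanking mapped markers, `(d2*G1 + d1*G2) / (d1 + d2)`, where `d1`
#' and `d2` are the distances to the left and right flanking markers.
#' When the family's founder carries the reference allele at the variant,
#' the projected dosage is 0 regardless of the flanking genotypes; a
#' heterozygous founder call (allele content 0.5) halves the projection.
#'
#' @param d1,d2 Non-negative physical distances (bp) to the left and
#'   right flanking mapped markers; `d1 + d2 > 0`.
#' @param G1,G2 Dosages in `[0, 2]` at the left and right markers.
#' @param founder_allele Founder's allele content at the variant: 0
#'   (reference), 1 (alternate) or 0.5 (heterozygous call).
#' @return Projected dosage in `[0, 2]`. All arguments are vectorised.
#' @examples
#' project_dense(d1 = 3000, d2 = 1000, G1 = 2, G2 = 0)  # 0.5
#' @export
project_dense <- function(d1, d2, G1, G2, founder_allele = 1) {
  if (any(d1 < 0) || any(d2 < 0)) stop("distances must be non-negative")
  if (any(d1 + d2 == 0)) stop("degenerate position: d1 = d2 = 0")
  if (any(G1 < 0 | G1 > 2 | G2 < 0 | G2 > 2)) {
    stop("flanking dosages must lie in [0, 2]")
  }
  (d2 * G1 + d1 * G2) / (d1 + d2) * founder_allele
}

#' Project dense founder variants onto a RIL population
#'
#' For every line and dense variant, applies [project_dense()] using the
#' family founder's allele and the line's dosages at the mapped markers
#' physically flanking the variant. Variants at exactly a mapped marker's
#' bp take that marker's dosage directly; variants outside the mapped
#' span use the nearest single marker.
#'
#' @param dosages Lines x mapped-marker dosage matrix in `[0, 2]`.
#' @param map Mapped-marker [genetic_map()] aligned with `dosages`.
#' @param panel A `founder_panel` with dense variant positions and
#'   founder alleles.
#' @param line_family Character vector: family of each line (rows of
#'   `dosages`).
#' @param family_founder Named character vector mapping family to founder
#'   id in `panel`.
#' @return Lines x dense-variant matrix of projected dosages in `[0, 2]`.
#' @export
project_population <- function(dosages, map, panel, line_family,
                               family_founder) {
  stopifnot(inherits(panel, "founder_panel"),
            ncol(dosages) == nrow(map),
            length(line_family) == nrow(dosages))
  if (any(!line_family %in% names(family_founder))) {
    stop("family with unknown founder mapping")
  }
  if (any(!family_founder %in% panel$founder_ids)) {
    stop("family founder not present in panel")
  }
  pos <- panel$positions
  out <- matrix(0, nrow(dosages), nrow(pos),
                dimnames = list(rownames(dosages), pos$variant))
  for (ch in unique(pos$chrom)) {
    vi <- which(pos$chrom == ch)
    mi <- which(map$chrom == ch)
    if (!length(mi)) stop("dense variants on chromosome ", ch,
                          " but no mapped markers there")
    mbp <- map$bp[mi]
    vbp <- pos$bp[vi]
    left <- findInterval(vbp, mbp)
    li <- pmax(left, 1L)
    ri <- pmin(left + 1L, length(mbp))
    exact <- match(vbp, mbp)
    d1 <- vbp - mbp[li]
    d2 <- mbp[ri] - vbp
    d1[left == 0L] <- 0          # before first marker: use right marker only
    d2[left == 0L] <- 1
    d2[left == length(mbp)] <- 0 # beyond last marker: use left marker only
    d1[left == length(mbp)] <- 1
    w1 <- d2 / (d1 + d2)
    w2 <- d1 / (d1 + d2)
    G1 <- dosages[, mi[li], drop = FALSE]
    G2 <- dosages[, mi[ri], drop = FALSE]
    proj <- sweep(G1, 2L, w1, `*`) + sweep(G2, 2L, w2, `*`)
    hit <- which(!is.na(exact))
    if (length(hit)) proj[, hit] <- dosages[, mi[exact[hit]], drop = FALSE]
    # founder allele content per family per variant
    fam_lev <- unique(line_family)
    for (fam in fam_lev) {
      rows <- which(line_family == fam)
      al <- panel$alleles[family_founder[[fam]], pos$variant[vi]]
      out[rows, vi] <- proj[rows, , drop = FALSE] *
        rep(al, each = length(rows))
    }
  }
  out
}
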