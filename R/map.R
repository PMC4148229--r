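#' Construct a genetic linkage map
#'
#' A genetic map records, for each mapped marker, its chromosome, genetic
#' position (centimorgans) and physical position (base pairs, 1-based).
#' Both coordinates must be non-decreasing within a chromosome and marker
#' identifiers must be unique.
#'
#' @param marker Character vector of unique marker identifiers.
#' @param chrom Chromosome labels (coerced to character).
#' @param cM Genetic positions in centimorgans (non-negative).
#' @param bp Physical positions in base pairs (positive integers).
#' @return A `data.frame` of class `genetic_map` with columns
#'   `marker`, `chrom`, `cM`, `bp`, ordered by chromosome then position.
#' @examples
#' genetic_map(c("m1", "m2"), c(1, 1), c(0, 5), c(1e5, 9e5))
#' @export
genetic_map <- function(marker, chrom, cM, bp) {
  map <- data.frame(marker = as.character(marker),
                    chrom = as.character(chrom),
                    cM = as.numeric(cM),
                    bp = as.numeric(bp),
                    stringsAsFactors = FALSE)
  validate_map(map)
  map <- map[order(match(map$chrom, unique(map$chrom)), map$cM, map$bp), ]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

validate_map <- function(map) {
  req <- c("marker", "chrom", "cM", "bp")
  if (!all(req %in% names(map))) {
    stop("map must have columns marker, chrom, cM, bp")
  }
  if (anyDuplicated(map$marker)) {
    stop("duplicated marker ids in map: ",
         paste(unique(map$marker[duplicated(map$marker)])[1:3], collapse = ", "))
  }
  if (any(map$cM < 0)) stop("cM positions must be non-negative")
  if (any(map$bp < 1)) stop("bp positions must be >= 1")
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    sub <- sub[order(sub$cM), ]
    if (is.unsorted(sub$cM)) stop("cM not sortable on chromosome ", ch)
    if (is.unsorted(sub$bp)) {
      stop("bp positions not non-decreasing within chromosome ", ch)
    }
  }
  invisible(map)
}

#' Build a uniformly spaced marker map
#'
#' Convenience constructor for simulation studies: `n_chrom` chromosomes of
#' equal genetic length with markers every `spacing_cM`, and physical
#' positions laid out at `bp_per_cM` (default 1 Mb per cM, the genome-wide
#' average scale for maize).
#'
#' @param n_chrom Number of chromosomes.
#' @param length_cM Genetic length of each chromosome in cM.
#' @param spacing_cM Marker spacing in cM.
#' @param bp_per_cM Physical bases per centimorgan.
#' @return A [genetic_map()].
#' @export
uniform_map <- function(n_chrom = 10, length_cM = 100, spacing_cM = 1,
                        bp_per_cM = 1e6) {
  pos <- seq(0, length_cM, by = spacing_cM)
  chrom <- rep(seq_len(n_chrom), each = length(pos))
  cM <- rep(pos, n_chrom)
  genetic_map(marker = sprintf("c%d_%06.1fcM", chrom, cM),
              chrom = chrom, cM = cM, bp = round(cM * bp_per_cM) + 1)
}

# List of per-chromosome marker index vectors, in map row order.
map_chrom_index <- function(map) {
  split(seq_len(nrow(map)), factor(map$chrom, levels = unique(map$chrom)))
}
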