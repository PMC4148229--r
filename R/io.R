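# Readers and writers for the tab-separated genotype, map, dense-variant
# and trait-table formats. All writers round-trip bit-exactly (dosages are
# formatted to 4 decimals, and read back as written).

#' Read a genetic map TSV
#'
#' Expected columns: `marker`, `chrom`, `cM`, `bp` (header required).
#'
#' @param file Path to a tab-separated file.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  req <- c("marker", "chrom", "cM", "bp")
  if (!all(req %in% names(df))) {
    stop("malformed map header in ", file, ": need columns ",
         paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$marker)) {
    line <- which(duplicated(df$marker))[1] + 1L
    stop("duplicated marker at line ", line, " of ", file)
  }
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    o <- order(sub$cM)
    if (is.unsorted(sub$bp[o])) {
      stop("bp positions not sorted within chromosome ", ch, " in ", file)
    }
  }
  genetic_map(df$marker, df$chrom, df$cM, df$bp)
}

#' @rdname read_genetic_map
#' @param map A [genetic_map()] to write.
#' @export
write_genetic_map <- function(map, file) {
  utils::write.table(as.data.frame(map)[, c("marker", "chrom", "cM", "bp")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read and write dosage matrices
#'
#' Genotype TSVs have one row per line and one column per marker, with the
#' line identifier in the first column (`line`). Dosages are written to 4
#' decimal places.
#'
#' @param file Path to a tab-separated file.
#' @return `read_dosage_matrix()`: numeric matrix with line row names.
#' @export
read_dosage_matrix <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "line") {
    stop("malformed genotype header in ", file, ": first column must be 'line'")
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicated marker column in ", file)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line
  if (any(!is.na(m) & (m < 0 | m > 2))) {
    stop("dosages outside [0, 2] in ", file)
  }
  m
}

#' @rdname read_dosage_matrix
#' @param x Numeric lines x markers matrix in `[0, 2]`.
#' @export
write_dosage_matrix <- function(x, file) {
  df <- data.frame(line = rownames(x),
                   apply(x, 2L, function(col) sprintf("%.4f", col)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("line", colnames(x))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a HapMap-dialect dense founder table
#'
#' Tab-separated with columns `rs`, `alleles` (e.g. `A/G`, reference
#' allele first), `chrom`, `pos`, then one column per founder holding
#' nucleotide calls (or `H` for a heterozygous call, `N` for missing).
#' Calls are recoded to allele content of the non-reference allele with
#' the common parent set to 0 everywhere: 0 for the reference parent's
#' allele, 1 for the alternate, 0.5 for `H`, `NA` for `N`.
#'
#' @param file Path to the table.
#' @param reference Column name of the common reference parent.
#' @return A `founder_panel` (heterozygous calls are carried as 0.5 in
#'   the allele matrix and flagged via the `any_het` attribute).
#' @export
read_hapmap_founders <- function(file, reference) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("rs", "alleles", "chrom", "pos")
  if (!all(req %in% names(df))) {
    stop("malformed HapMap header in ", file, ": need ",
         paste(req, collapse = ", "))
  }
  if (!reference %in% names(df)) {
    stop("reference parent column '", reference, "' absent from ", file)
  }
  if (anyDuplicated(df$rs)) {
    stop("duplicated variant at line ",
         which(duplicated(df$rs))[1] + 1L, " of ", file)
  }
  for (ch in unique(df$chrom)) {
    if (is.unsorted(df$pos[df$chrom == ch])) {
      stop("unsorted bp positions within chromosome ", ch, " in ", file)
    }
  }
  founder_cols <- setdiff(names(df), req)
  ref_call <- df[[reference]]
  alt <- vapply(strsplit(df$alleles, "/", fixed = TRUE), function(a) {
    if (length(a) != 2L) stop("malformed alleles field")
    a
  }, character(2))
  alleles <- matrix(NA_real_, length(founder_cols), nrow(df),
                    dimnames = list(founder_cols, df$rs))
  for (fc in founder_cols) {
    call <- df[[fc]]
    v <- ifelse(call == "N", NA_real_,
                ifelse(call == "H", 0.5,
                       ifelse(call == ref_call, 0, 1)))
    alleles[fc, ] <- v
  }
  alleles[reference, ] <- 0
  structure(list(founder_ids = c(reference,
                                 setdiff(founder_cols, reference)),
                 reference = reference,
                 alleles = alleles[c(reference,
                                     setdiff(founder_cols, reference)), ,
                                   drop = FALSE],
                 positions = data.frame(variant = df$rs, chrom = df$chrom,
                                        bp = df$pos,
                                        stringsAsFactors = FALSE)),
            class = "founder_panel")
}

#' Read and write plot-level phenotype records
#'
#' Long format: `line`, `family`, `env`, `rep`, and either `value` (one
#' measurement per plot) or `day`/`score` (repeated rating series).
#'
#' @param file Path to a tab-separated file.
#' @export
read_plot_records <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("line", "family", "env")
  if (!all(need %in% names(df))) {
    stop("malformed plot-record header in ", file)
  }
  df
}

#' @rdname read_plot_records
#' @param x Data frame of plot records.
#' @export
write_plot_records <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a per-line trait table
#'
#' One row per line with family label and derived trait values (LES,
#' HTR, SWR, DTAR or any subset), mirroring the layout of published
#' line-mean supplements.
#'
#' @param x Data frame with columns `line`, `family` and trait columns.
#' @param file Output path.
#' @export
write_trait_table <- function(x, file) {
  stopifnot(all(c("line", "family") %in% names(x)))
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(col) sprintf("%.4f", col))
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("line", "family") %in% names(df))) {
    stop("malformed trait-table header in ", file)
  }
  df
}
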