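#' Construct a genotype matrix
#'
#' The central container of the pipeline: per-site, per-sample diploid
#' alternate-allele dosages together with per-site metadata (position,
#' alleles, site quality, aggregate depth).
#'
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (1-based integer), `ref` and `alt` (allele strings; `alt` may hold a
#'   comma-separated list for multiallelic records), and optionally `qual`
#'   (phred-scaled site quality) and `dp` (aggregate site depth). Extra
#'   columns are kept.
#' @param geno integer matrix, `nrow(sites)` rows by one column per sample,
#'   holding dosages in \{0, 1, 2\} with `NA` for missing genotypes. Column
#'   names are the sample identifiers.
#' @param chrom_lengths named integer vector of sequence lengths in bp; when
#'   `NULL`, the maximum observed position per chromosome is used.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sites`, `geno`, `samples`, `chrom_lengths`. Sites are sorted by
#'   (chrom, pos); duplicated coordinates are an error.
#' @export
genotype_matrix <- function(sites, geno, chrom_lengths = NULL) {
  stopifnot(is.data.frame(sites), is.matrix(geno))
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols))
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(sites) != nrow(geno))
    stop("sites and geno disagree on the number of variant records")
  if (is.null(colnames(geno)))
    stop("geno must carry sample identifiers as column names")
  if (!"qual" %in% names(sites)) sites$qual <- NA_real_
  if (!"dp" %in% names(sites)) sites$dp <- NA_integer_
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  bad <- sites$ref == sites$alt
  if (any(bad)) stop("ref and alt alleles identical at ", sum(bad), " site(s)")

  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(sites) <- NULL
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) stop("duplicated (chrom, pos) coordinates in sites")

  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosages must lie in {0, 1, 2} or be NA")

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(sites$pos, sites$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }
  structure(
    list(sites = sites, geno = geno, samples = colnames(geno),
         chrom_lengths = chrom_lengths),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on %d sequence(s)\n",
              nrow(x$sites), length(x$samples), length(x$chrom_lengths)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by site index
#'
#' @param gm a [genotype_matrix()].
#' @param i integer or logical index over sites.
#' @return A `genotype_matrix` restricted to the selected sites, order
#'   preserved; `chrom_lengths` unchanged.
#' @export
subset_sites <- function(gm, i) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- gm
  out$sites <- gm$sites[i, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$geno <- gm$geno[i, , drop = FALSE]
  out
}

#' Read or construct a sample-to-population map
#'
#' @param x either the path to a two-column headerless TSV (sample,
#'   population) or a data.frame with columns `sample` and `population`.
#' @return A `popmap`: data.frame with character columns `sample` and
#'   `population`, one row per sample.
#' @export
read_popmap <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    df <- utils::read.table(x, header = FALSE, sep = "\t",
                            col.names = c("sample", "population"),
                            colClasses = "character")
  } else {
    df <- as.data.frame(x)
    if (!all(c("sample", "population") %in% names(df)))
      stop("popmap needs columns 'sample' and 'population'")
    df <- df[c("sample", "population")]
  }
  if (anyDuplicated(df$sample))
    stop("popmap assigns some sample more than one population")
  class(df) <- c("popmap", "data.frame")
  df
}

# samples of one population, checked against the matrix
pop_samples <- function(gm, popmap, population) {
  s <- popmap$sample[popmap$population == population]
  s <- intersect(gm$samples, s)
  if (!length(s)) stop("population '", population, "' has no samples in the matrix")
  s
}

check_popmap <- function(gm, popmap) {
  popmap <- read_popmap(popmap)
  absent <- setdiff(gm$samples, popmap$sample)
  if (length(absent))
    stop("samples missing from popmap: ", paste(absent, collapse = ", "))
  popmap[match(gm$samples, popmap$sample), , drop = FALSE]
}
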