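#' LD-decay configuration
#'
#' @param max_dist maximum pair distance in bp (default 500000, i.e. all
#'   marker pairs within a 500-kb window).
#' @param maf_min minor-allele-frequency floor applied before pairing
#'   (default 0.05); rare variants make r2 noisy.
#' @param bin_width distance bin width in bp for the decay curve
#'   (default 1000).
#' @return An `ld_config` list.
#' @export
ld_config <- function(max_dist = 500000L, maf_min = 0.05, bin_width = 1000L) {
  stopifnot(max_dist > 0, maf_min >= 0, maf_min < 0.5, bin_width > 0)
  structure(list(max_dist = as.integer(max_dist), maf_min = maf_min,
                 bin_width = as.integer(bin_width)), class = "ld_config")
}

#' Composite (genotype-correlation) r-squared between two SNPs
#'
#' The squared Pearson correlation of diploid dosages over the samples
#' genotyped at both loci (Rogers-Huff composite LD) - the standard
#' phase-free surrogate for haplotype r2. Missing when fewer than two
#' complete pairs exist or either locus is monomorphic among them.
#'
#' @param dosages_a,dosages_b equal-length dosage vectors in \{0, 1, 2, NA\}.
#' @return r-squared in `[0, 1]`, or NA.
#' @export
pair_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b))
    stop("dosage vectors differ in length")
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' LD decay curve from a genotype matrix
#'
#' All same-chromosome SNP pairs with distance at most `max_dist` and both
#' minor-allele frequencies at least `maf_min` contribute their composite
#' r2; pairs are binned by distance into `(lo, hi]` bins of width
#' `bin_width` and bins without pairs are omitted. Missing genotypes are
#' handled by pairwise-complete deletion.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap optional population map; with `population` set, only that
#'   population's samples are used.
#' @param population population label, or `NULL` for all samples.
#' @param cfg an [ld_config()].
#' @return data.frame with columns `dist_lo`, `dist_hi`, `mean_r2`,
#'   `n_pairs`, ordered by distance.
#' @export
decay_curve <- function(gm, popmap = NULL, population = NULL,
                        cfg = ld_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "ld_config"))
  G <- gm$geno
  if (!is.null(population)) {
    popmap <- read_popmap(popmap)
    G <- G[, pop_samples(gm, popmap, population), drop = FALSE]
  }
  if (ncol(G) < 2L) stop("need at least two samples")
  nonmiss <- rowSums(!is.na(G))
  p <- rowSums(G, na.rm = TRUE) / (2 * nonmiss)
  maf <- pmin(p, 1 - p)
  keep <- nonmiss >= 2L & !is.na(maf) & maf >= cfg$maf_min
  G <- G[keep, , drop = FALSE]
  chrom <- gm$sites$chrom[keep]
  pos <- gm$sites$pos[keep]

  breaks <- seq.int(0L, cfg$max_dist + cfg$bin_width, by = cfg$bin_width)
  r2_sum <- numeric(length(breaks) - 1L)
  n_pair <- integer(length(breaks) - 1L)
  use <- if (anyNA(G)) "pairwise.complete.obs" else "everything"

  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) < 2L) next
    cp <- pos[i]
    cm <- suppressWarnings(stats::cor(t(G[i, , drop = FALSE]), use = use))^2
    d <- abs(outer(cp, cp, "-"))
    sel <- upper.tri(d) & d <= cfg$max_dist & d >= 1L & !is.na(cm)
    if (!any(sel)) next
    bin <- findInterval(d[sel] - 1L, breaks) # (lo, hi] bins
    for (b in unique(bin)) {
      inb <- bin == b
      r2_sum[b] <- r2_sum[b] + sum(cm[sel][inb])
      n_pair[b] <- n_pair[b] + sum(inb)
    }
  }
  nz <- which(n_pair > 0L)
  data.frame(dist_lo = breaks[nz], dist_hi = breaks[nz + 1L],
             mean_r2 = r2_sum[nz] / n_pair[nz], n_pairs = n_pair[nz])
}
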