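#' Sliding-window specification
#'
#' @param size window size in bp (default 40000).
#' @param step distance between window starts in bp (default 20000, i.e.
#'   adjacent 40-kb windows overlap by 20 kb).
#' @return A `window_spec` list.
#' @export
window_spec <- function(size = 40000L, step = 20000L) {
  size <- as.integer(size); step <- as.integer(step)
  stopifnot(step > 0L, step <= size)
  structure(list(size = size, step = step), class = "window_spec")
}

#' Tile chromosomes with sliding windows
#'
#' Windows start at 1, 1 + step, 1 + 2*step, ... and are truncated at the
#' chromosome end. A trailing truncated window is emitted only when it
#' covers at least one bp beyond the previous window, so chromosome ends are
#' never silently dropped and no fully redundant window appears.
#'
#' @param chrom_lengths named vector of sequence lengths in bp.
#' @param spec a [window_spec()].
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), sorted by chromosome then start.
#' @export
make_windows <- function(chrom_lengths, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"), all(chrom_lengths >= 1))
  res <- lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(1L, L, by = spec$step)
    ends <- pmin(starts + spec$size - 1L, L)
    keep <- ends >= cummax(c(0L, utils::head(ends, -1L))) + 1L
    keep[1] <- TRUE
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Tajima (1989) constants for a sample of n chromosomes
tajima_constants <- function(n) {
  if (n < 2) stop("need at least 2 chromosomes")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# per-site heterozygosity 2a(n-a)/(n(n-1)); 0 where n < 2
pi_site <- function(alt, n) {
  out <- numeric(length(alt))
  ok <- n >= 2L
  out[ok] <- 2 * alt[ok] * (n[ok] - alt[ok]) / (n[ok] * (n[ok] - 1))
  out
}

#' Within-window diversity statistics for one population
#'
#' Computes the segregating-site count S, per-bp nucleotide diversity
#' (theta-pi), the per-bp Watterson estimator `S / (a1 * L)`, and Tajima's D
#' for the sites of one population falling in one window. Per-site sample
#' sizes may vary through missingness; the Tajima constants are evaluated at
#' the window-median chromosome count. Both per-bp estimators normalize by
#' the full window length.
#'
#' @param counts an `allele_counts` object from [population_allele_counts()].
#' @param window list or one-row data.frame with `chrom`, `start`, `end`.
#' @param population population label present in `counts`.
#' @return list with `n_snps`, `theta_pi`, `theta_w`, `tajimas_d` (NA when
#'   S = 0 or the median chromosome count is below 4, with a warning in the
#'   latter case).
#' @export
window_diversity <- function(counts, window, population) {
  stopifnot(inherits(counts, "allele_counts"))
  L <- window$end - window$start + 1L
  if (L <= 0L) stop("window has non-positive length")
  idx <- which(counts$sites$chrom == window$chrom &
                 counts$sites$pos >= window$start &
                 counts$sites$pos <= window$end)
  n <- counts$n_chrom[idx, population]
  a <- counts$alt[idx, population]
  seg <- a > 0L & a < n
  S <- sum(seg)
  sum_pi <- sum(pi_site(a, n))
  nbar <- if (length(n)) as.integer(stats::median(n)) else 0L
  d <- window_tajima_d(S, sum_pi, nbar)
  list(n_snps = S, theta_pi = sum_pi / L, theta_w = watterson_theta(S, nbar, L),
       tajimas_d = d)
}

watterson_theta <- function(S, nbar, L) {
  if (S == 0L) return(0)
  if (nbar < 2L) return(NA_real_)
  S / (tajima_constants(nbar)$a1 * L)
}

window_tajima_d <- function(S, sum_pi, nbar, warn = TRUE) {
  if (S == 0L) return(NA_real_)
  if (nbar < 4L) {
    if (warn) warning("median chromosome count below 4; Tajima's D set to NA")
    return(NA_real_)
  }
  k <- tajima_constants(nbar)
  (sum_pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Within-window FST between two populations
#'
#' Per-site variance components are summed across the window before the
#' ratio is taken ("ratio of sums"). The default estimator is the
#' Weir-Cockerham (1984) allele-count form (random union of gametes);
#' Hudson's estimator as formulated by Bhatia et al. (2013) is selectable.
#' Sites where either population has fewer than two genotyped chromosomes
#' are skipped; monomorphic sites contribute nothing. Windows with no usable
#' polymorphic site return NA.
#'
#' @param counts an `allele_counts` object.
#' @param window list with `chrom`, `start`, `end`.
#' @param pop_a,pop_b population labels.
#' @param estimator `"weir_cockerham"` (default) or `"hudson"`.
#' @return A single FST value (possibly negative; never clamped).
#' @export
window_fst <- function(counts, window, pop_a, pop_b,
                       estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  idx <- which(counts$sites$chrom == window$chrom &
                 counts$sites$pos >= window$start &
                 counts$sites$pos <= window$end)
  comp <- fst_components(counts$alt[idx, pop_a], counts$n_chrom[idx, pop_a],
                         counts$alt[idx, pop_b], counts$n_chrom[idx, pop_b],
                         estimator)
  if (comp$den == 0) return(NA_real_)
  comp$num / comp$den
}

# per-site numerator/denominator sums for ratio-of-sums FST
fst_components <- function(a1, n1, a2, n2, estimator) {
  ok <- n1 >= 2L & n2 >= 2L
  a1 <- a1[ok]; n1 <- n1[ok]; a2 <- a2[ok]; n2 <- n2[ok]
  p1 <- a1 / n1; p2 <- a2 / n2
  poly <- (a1 + a2) > 0L & (a1 + a2) < (n1 + n2)
  p1 <- p1[poly]; p2 <- p2[poly]; n1 <- n1[poly]; n2 <- n2[poly]
  if (!length(p1)) return(list(num = 0, den = 0))
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
    a <- nbar / nc * (s2 - b / nbar)
    num <- a
    den <- a + b
  }
  list(num = sum(num), den = sum(den))
}

#' log2 diversity ratio between two matched window tables
#'
#' `log2(theta_pi_a / theta_pi_b)`: positive values mark diversity loss in
#' the `b` (e.g. domestic) group relative to the `a` (e.g. wild) group.
#' Windows where either diversity is zero yield NA and are excluded from
#' downstream quantiles.
#'
#' @param stats_a,stats_b data.frames with columns `chrom`, `start`, `end`,
#'   `theta_pi`, row-matched window for window.
#' @return numeric vector of log2 ratios, one per window.
#' @export
log2_pi_ratio <- function(stats_a, stats_b) {
  if (nrow(stats_a) != nrow(stats_b) ||
      !all(stats_a$chrom == stats_b$chrom) ||
      !all(stats_a$start == stats_b$start) ||
      !all(stats_a$end == stats_b$end))
    stop("window coordinates of the two tables do not match")
  ratio <- rep(NA_real_, nrow(stats_a))
  ok <- stats_a$theta_pi > 0 & stats_b$theta_pi > 0
  ratio[ok] <- log2(stats_a$theta_pi[ok] / stats_b$theta_pi[ok])
  ratio
}

#' Sliding-window statistics table
#'
#' The main per-window driver: computes, for every window, the pooled
#' segregating-site count and per-population theta-pi, Watterson's theta
#' and Tajima's D, plus FST and the log2 diversity ratio for one population
#' pair. Column order is fixed: `chrom`, `start`, `end`, `n_snps`, then
#' `theta_pi_<pop>`, `theta_w_<pop>`, `tajimas_d_<pop>` per population in
#' popmap order, then `fst` and `log2_ratio` when a pair is given.
#'
#' @param gm a [genotype_matrix()] (or an `allele_counts` object, in which
#'   case `popmap` is ignored).
#' @param popmap population map covering every sample.
#' @param spec a [window_spec()], or a precomputed window data.frame with
#'   `chrom`/`start`/`end` columns.
#' @param pair character of length 2: the (numerator, denominator)
#'   populations for FST and the log2 theta-pi ratio, e.g.
#'   `c("wild", "domestic")`. Defaults to the two populations of the popmap
#'   when exactly two exist; set `NULL` to skip pair statistics.
#' @param estimator FST estimator, see [window_fst()].
#' @return data.frame of class `window_stats`.
#' @export
windowed_stats <- function(gm, popmap = NULL, spec = window_spec(),
                           pair = NULL,
                           estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  if (inherits(gm, "allele_counts")) {
    counts <- gm
    chrom_lengths <- tapply(counts$sites$pos, counts$sites$chrom, max)
  } else {
    counts <- population_allele_counts(gm, popmap)
    chrom_lengths <- gm$chrom_lengths
  }
  pops <- counts$pops
  if (is.null(pair) && length(pops) == 2L) pair <- pops
  if (!is.null(pair)) stopifnot(length(pair) == 2L, all(pair %in% pops))

  windows <- if (is.data.frame(spec)) spec else make_windows(chrom_lengths, spec)
  sites <- counts$sites
  n_win <- nrow(windows)

  # per-population per-site quantities and their cumulative sums, so each
  # window is an O(log S) range query
  pos_by_chrom <- split(seq_len(nrow(sites)), sites$chrom)
  per_pop <- lapply(pops, function(p) {
    n <- counts$n_chrom[, p]; a <- counts$alt[, p]
    list(n = n, seg = as.numeric(a > 0L & a < n), pi = pi_site(a, n))
  })
  names(per_pop) <- pops
  pooled_n <- rowSums(counts$n_chrom)
  pooled_a <- rowSums(counts$alt)
  pooled_seg <- as.numeric(pooled_a > 0L & pooled_a < pooled_n)

  out <- windows
  out$n_snps <- 0L
  for (p in pops) {
    out[[paste0("theta_pi_", p)]] <- NA_real_
    out[[paste0("theta_w_", p)]] <- NA_real_
    out[[paste0("tajimas_d_", p)]] <- NA_real_
  }
  if (!is.null(pair)) { out$fst <- NA_real_; out$log2_ratio <- NA_real_ }

  low_n_warned <- FALSE
  for (ch in unique(windows$chrom)) {
    sidx <- pos_by_chrom[[ch]]
    wr <- which(windows$chrom == ch)
    pos <- if (length(sidx)) sites$pos[sidx] else integer(0)
    lo <- findInterval(windows$start[wr] - 1L, pos) + 1L
    hi <- findInterval(windows$end[wr], pos)
    for (k in seq_along(wr)) {
      w <- wr[k]
      rows <- if (hi[k] >= lo[k]) sidx[lo[k]:hi[k]] else integer(0)
      L <- windows$end[w] - windows$start[w] + 1L
      out$n_snps[w] <- as.integer(sum(pooled_seg[rows]))
      for (p in pops) {
        pp <- per_pop[[p]]
        S <- as.integer(sum(pp$seg[rows]))
        sum_pi <- sum(pp$pi[rows])
        nbar <- if (length(rows)) as.integer(stats::median(pp$n[rows])) else 0L
        out[[paste0("theta_pi_", p)]][w] <- sum_pi / L
        out[[paste0("theta_w_", p)]][w] <- watterson_theta(S, nbar, L)
        d <- window_tajima_d(S, sum_pi, nbar, warn = FALSE)
        if (S > 0L && nbar < 4L && !low_n_warned) {
          warning("some windows have median chromosome count below 4; ",
                  "Tajima's D set to NA there")
          low_n_warned <- TRUE
        }
        out[[paste0("tajimas_d_", p)]][w] <- d
      }
      if (!is.null(pair)) {
        comp <- fst_components(counts$alt[rows, pair[1]],
                               counts$n_chrom[rows, pair[1]],
                               counts$alt[rows, pair[2]],
                               counts$n_chrom[rows, pair[2]], estimator)
        out$fst[w] <- if (comp$den == 0) NA_real_ else comp$num / comp$den
      }
    }
  }
  if (!is.null(pair)) {
    a <- out[[paste0("theta_pi_", pair[1])]]
    b <- out[[paste0("theta_pi_", pair[2])]]
    ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
    out$log2_ratio[ok] <- log2(a[ok] / b[ok])
  }
  attr(out, "pair") <- pair
  attr(out, "estimator") <- if (is.null(pair)) NULL else estimator
  class(out) <- c("window_stats", "data.frame")
  out
}
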