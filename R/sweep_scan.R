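#' Sweep-scan configuration
#'
#' @param fst_quantile upper empirical quantile for the FST arm
#'   (default 0.95, i.e. the top 5 percent).
#' @param ratio_quantile upper empirical quantile for the log2
#'   diversity-ratio arm (default 0.95).
#' @return A `sweep_scan_config` list.
#' @export
sweep_scan_config <- function(fst_quantile = 0.95, ratio_quantile = 0.95) {
  stopifnot(fst_quantile > 0, fst_quantile < 1,
            ratio_quantile > 0, ratio_quantile < 1)
  structure(list(fst_quantile = fst_quantile, ratio_quantile = ratio_quantile),
            class = "sweep_scan_config")
}

#' Joint FST / diversity-ratio outlier windows
#'
#' Thresholds are the empirical quantiles (type-7 linear interpolation) of
#' FST and the log2 theta-pi ratio, both computed over the windows where the
#' two statistics are non-missing. A window is an outlier when it reaches or
#' exceeds both realized thresholds simultaneously. The realized cutoffs are
#' data-dependent quantities and are always reported alongside the outliers.
#'
#' @param stats a `window_stats` data.frame with `fst` and `log2_ratio`
#'   columns (see [windowed_stats()]).
#' @param cfg a [sweep_scan_config()].
#' @return list with `outliers` (the outlier rows of `stats`), `fst_cutoff`,
#'   `ratio_cutoff`, and `n_windows_used`.
#' @export
joint_outlier_windows <- function(stats, cfg = sweep_scan_config()) {
  stopifnot(all(c("fst", "log2_ratio") %in% names(stats)))
  ok <- !is.na(stats$fst) & !is.na(stats$log2_ratio)
  if (!any(ok)) stop("no window has both FST and log2 ratio defined")
  fst_cutoff <- unname(stats::quantile(stats$fst[ok], cfg$fst_quantile, type = 7))
  ratio_cutoff <- unname(stats::quantile(stats$log2_ratio[ok],
                                         cfg$ratio_quantile, type = 7))
  out <- ok & stats$fst >= fst_cutoff & stats$log2_ratio >= ratio_cutoff
  list(outliers = stats[out, , drop = FALSE],
       fst_cutoff = fst_cutoff, ratio_cutoff = ratio_cutoff,
       n_windows_used = sum(ok))
}

#' Merge outlier windows into candidate selected regions
#'
#' Overlapping or book-ended (zero-gap adjacent) outlier windows on the same
#' chromosome are merged into one region spanning their union; the number of
#' contributing windows and the per-region maxima of FST and the log2 ratio
#' are recorded. Merging is idempotent and order-invariant.
#'
#' @param outliers data.frame of outlier windows (`chrom`, `start`, `end`,
#'   optionally `fst` and `log2_ratio`), e.g.
#'   `joint_outlier_windows(...)$outliers`.
#' @return data.frame of class `cdr_set` with columns `chrom`, `start`,
#'   `end`, `n_windows`, `max_fst`, `max_log2_ratio`, sorted and pairwise
#'   non-overlapping.
#' @export
merge_to_cdrs <- function(outliers) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      max_fst = numeric(0), max_log2_ratio = numeric(0))
  class(empty) <- c("cdr_set", "data.frame")
  if (nrow(outliers) == 0L) return(empty)
  res <- lapply(sort(unique(outliers$chrom)), function(ch) {
    w <- outliers[outliers$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = w$start, end = w$end)
    red <- IRanges::reduce(ir, min.gapwidth = 1L, with.revmap = TRUE)
    rv <- S4Vectors::mcols(red)$revmap
    data.frame(
      chrom = ch,
      start = IRanges::start(red),
      end = IRanges::end(red),
      n_windows = lengths(rv),
      max_fst = vapply(rv, function(i)
        if ("fst" %in% names(w)) max(w$fst[i]) else NA_real_, numeric(1)),
      max_log2_ratio = vapply(rv, function(i)
        if ("log2_ratio" %in% names(w)) max(w$log2_ratio[i]) else NA_real_,
        numeric(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("cdr_set", "data.frame")
  out
}

#' Genes overlapping candidate selected regions
#'
#' A gene is selected when its transcript span overlaps a region by at least
#' one bp (book-ended gene/region pairs do not count). A gene overlapping
#' several regions is counted once in the unique total.
#'
#' @param cdrs a `cdr_set` data.frame from [merge_to_cdrs()].
#' @param genes gene models: a list from [read_gene_models()] or a
#'   data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return list with `per_cdr` (the `cdrs` table plus a `genes`
#'   comma-joined column and `n_genes`), `genes` (unique gene ids), and
#'   `n_genes` (unique total).
#' @export
genes_in_cdrs <- function(cdrs, genes) {
  gdf <- gene_spans(genes)
  hits_by_cdr <- vector("list", nrow(cdrs))
  for (ch in unique(cdrs$chrom)) {
    ci <- which(cdrs$chrom == ch)
    gi <- which(gdf$chrom == ch)
    if (!length(gi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(cdrs$start[ci], cdrs$end[ci]),
      IRanges::IRanges(gdf$start[gi], gdf$end[gi]),
      minoverlap = 1L)
    for (k in seq_along(ci)) {
      hit <- gi[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]]
      hits_by_cdr[[ci[k]]] <- gdf$gene_id[hit]
    }
  }
  per_cdr <- cdrs
  per_cdr$genes <- vapply(hits_by_cdr, function(g)
    paste(sort(unique(g)), collapse = ","), character(1))
  per_cdr$n_genes <- vapply(hits_by_cdr, function(g)
    length(unique(g)), integer(1))
  uniq <- sort(unique(as.character(unlist(hits_by_cdr))))
  list(per_cdr = per_cdr, genes = uniq, n_genes = length(uniq))
}

# normalize gene models to a span data.frame
gene_spans <- function(genes) {
  if (is.data.frame(genes)) {
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
    return(genes)
  }
  data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0L, "tx_start"),
    end = vapply(genes, `[[`, 0L, "tx_end"),
    stringsAsFactors = FALSE)
}

#' Mann-Whitney contrast of Tajima's D: selected genes vs the genome
#'
#' Each gene's D is the mean Tajima's D of the windows overlapping its span
#' (at least 1 bp). Selected genes are compared with all remaining genes by
#' a two-sided Mann-Whitney U test: exact enumeration when both groups have
#' at most 8 genes and no ties, otherwise the normal approximation with tie
#' correction (no continuity correction).
#'
#' @param selected_genes character vector of selected gene ids.
#' @param stats a `window_stats` data.frame.
#' @param genes gene models (list or span data.frame, see
#'   [genes_in_cdrs()]).
#' @param population which population's Tajima's D column to use, i.e.
#'   column `tajimas_d_<population>`.
#' @return list with `median_selected`, `median_genome`, `U`, `p_value`,
#'   `n_selected`, `n_genome`.
#' @export
tajima_d_contrast <- function(selected_genes, stats, genes, population) {
  col <- paste0("tajimas_d_", population)
  if (!col %in% names(stats)) stop("no column ", col, " in stats")
  gdf <- gene_spans(genes)
  d_gene <- rep(NA_real_, nrow(gdf))
  for (ch in unique(gdf$chrom)) {
    gi <- which(gdf$chrom == ch)
    wi <- which(stats$chrom == ch)
    if (!length(wi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(gdf$start[gi], gdf$end[gi]),
      IRanges::IRanges(stats$start[wi], stats$end[wi]),
      minoverlap = 1L)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    for (k in seq_along(gi)) {
      v <- stats[[col]][wi[s[q == k]]]
      if (length(v)) d_gene[gi[k]] <- mean(v, na.rm = TRUE)
    }
  }
  sel <- gdf$gene_id %in% selected_genes
  x <- d_gene[sel & !is.na(d_gene)]
  y <- d_gene[!sel & !is.na(d_gene)]
  if (!length(x) || !length(y))
    stop("a contrast group is empty after dropping genes without windows")
  mw <- mann_whitney_u(x, y)
  list(median_selected = stats::median(x), median_genome = stats::median(y),
       U = mw$U, p_value = mw$p_value,
       n_selected = length(x), n_genome = length(y))
}

#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()]: exact when both groups have
#' at most 8 observations and the pooled sample is tie-free, otherwise the
#' normal approximation with tie correction and no continuity correction.
#' The reported U is the number of (x, y) pairs with x > y (the
#' `wilcox.test` W statistic).
#'
#' @param x,y numeric vectors.
#' @param alternative as in [stats::wilcox.test()] (default two-sided).
#' @return list with `U` and `p_value`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 8L && length(y) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
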