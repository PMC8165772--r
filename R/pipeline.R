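#' Run the analysis pipeline
#'
#' Orchestrates the stages in dependency order (filter, annotate, stats,
#' then sweep / ld / tree) from a configuration list or YAML file. Outputs
#' are written atomically (tempfile + rename) into `outdir`; a run log
#' records the seed, counts and realized sweep-scan cutoffs - the cutoffs
#' are realized quantiles of the data, never constants, so they are always
#' logged.
#'
#' Configuration keys: `vcf`, `popmap` (paths; required), optional `gff`
#' (gene models, GFF3 or BED12), `fasta` (reference), `outdir` (default
#' `"."`), `seed`, `pair` (two population labels, numerator first),
#' `fst_estimator`, and nested `window` (size, step), `filter` (min_qual,
#' min_depth, max_depth, biallelic_only), `sweep` (fst_quantile,
#' ratio_quantile), `ld` (max_dist, maf_min, bin_width).
#'
#' @param config list or path to a YAML file.
#' @param stages subset of `c("filter", "annotate", "stats", "sweep", "ld",
#'   "tree")`; requesting a stage without its prerequisite is an error
#'   naming the missing stage.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config,
                         stages = c("filter", "stats", "sweep", "ld", "tree")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$vcf), !is.null(config$popmap))
  known <- c("filter", "annotate", "stats", "sweep", "ld", "tree")
  stages <- match.arg(stages, known, several.ok = TRUE)
  needs <- list(annotate = "filter", stats = "filter", sweep = "stats",
                ld = "filter", tree = "filter")
  for (s in stages) {
    miss <- setdiff(needs[[s]], stages)
    if (length(miss))
      stop("stage '", s, "' requires stage '", miss[1], "' to run first")
  }
  outdir <- config$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  if (!is.null(config$seed)) {
    set.seed(as.integer(config$seed))
    logmsg("seed: ", config$seed)
  }
  artifacts <- list(log = log_path)

  popmap <- read_popmap(config$popmap)
  gm <- read_vcf(config$vcf, popmap = popmap)
  logmsg("input: ", nrow(gm$sites), " SNP records, ",
         length(gm$samples), " samples")

  fcfg <- do.call(site_filter_config, config$filter %||% list())
  gm <- apply_site_filters(gm, fcfg)
  logmsg("filtered: ", nrow(gm$sites), " sites pass (QUAL >= ", fcfg$min_qual,
         ", ", fcfg$min_depth, " <= DP <= ", fcfg$max_depth, ")")
  artifacts$filtered_vcf <- file.path(outdir, "filtered.vcf")
  atomic_write(function(p) write_vcf(gm, p), artifacts$filtered_vcf)

  genes <- if (!is.null(config$gff)) read_gene_models(config$gff) else NULL

  if ("annotate" %in% stages) {
    if (is.null(genes)) stop("stage 'annotate' needs a 'gff' entry in config")
    reference <- if (!is.null(config$fasta)) read_reference(config$fasta) else NULL
    ann <- annotate_sites(gm, genes, reference)
    artifacts$annotation <- file.path(outdir, "annotation.tsv")
    atomic_write(function(p) utils::write.table(
      ann, p, sep = "\t", quote = FALSE, row.names = FALSE),
      artifacts$annotation)
    sm <- annotation_summary(ann)
    logmsg("annotation: ",
           paste(names(sm$category_counts), sm$category_counts,
                 sep = "=", collapse = " "),
           "; nonsyn/syn = ", format(sm$nonsyn_syn_ratio, digits = 4))
  }

  stats_tab <- NULL
  if ("stats" %in% stages) {
    wcfg <- do.call(window_spec, config$window %||% list())
    pair <- config$pair %||% NULL
    est <- config$fst_estimator %||% "weir_cockerham"
    stats_tab <- windowed_stats(gm, popmap, spec = wcfg,
                                pair = unlist(pair), estimator = est)
    artifacts$window_stats <- file.path(outdir, "window_stats.tsv")
    atomic_write(function(p) utils::write.table(
      as.data.frame(stats_tab), p, sep = "\t", quote = FALSE,
      row.names = FALSE), artifacts$window_stats)
    logmsg("stats: ", nrow(stats_tab), " windows (size ", wcfg$size,
           ", step ", wcfg$step, "), FST estimator ", est)
  }

  if ("sweep" %in% stages) {
    scfg <- do.call(sweep_scan_config, config$sweep %||% list())
    sc <- joint_outlier_windows(stats_tab, scfg)
    cdrs <- merge_to_cdrs(sc$outliers)
    logmsg("sweep: realized cutoffs FST >= ",
           format(sc$fst_cutoff, digits = 4), ", log2 ratio >= ",
           format(sc$ratio_cutoff, digits = 4), "; ",
           nrow(sc$outliers), " outlier windows -> ", nrow(cdrs), " regions")
    artifacts$cdrs <- file.path(outdir, "cdrs.bed")
    atomic_write(function(p) write_cdr_bed(cdrs, p), artifacts$cdrs)
    if (!is.null(genes)) {
      hit <- genes_in_cdrs(cdrs, genes)
      logmsg("sweep: ", hit$n_genes, " unique genes overlap a region")
      artifacts$selected_genes <- file.path(outdir, "selected_genes.tsv")
      atomic_write(function(p) writeLines(hit$genes, p),
                   artifacts$selected_genes)
    }
  }

  if ("ld" %in% stages) {
    lcfg <- do.call(ld_config, config$ld %||% list())
    pops <- unique(popmap$population)
    for (p in pops) {
      curve <- decay_curve(gm, popmap, p, lcfg)
      path <- file.path(outdir, paste0("ld_decay_", p, ".tsv"))
      atomic_write(function(pp) utils::write.table(
        curve, pp, sep = "\t", quote = FALSE, row.names = FALSE), path)
      artifacts[[paste0("ld_", p)]] <- path
    }
    logmsg("ld: decay curves for ", length(pops), " population(s)")
  }

  if ("tree" %in% stages) {
    B <- config$bootstrap %||% 0L
    tree <- if (B >= 1L)
      bootstrap_support(gm, B = B, seed = config$seed)
    else
      nj_tree(p_distance_matrix(gm))
    artifacts$tree <- file.path(outdir, "nj_tree.nwk")
    atomic_write(function(p) write_newick(tree, p), artifacts$tree)
    logmsg("tree: ", length(tree$tip.label), " tips",
           if (B >= 1L) paste0(", ", B, " bootstrap replicates") else "")
  }
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

# CDR table as 0-based half-open BED with score columns
write_cdr_bed <- function(cdrs, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%.6g\t%.6g",
                   cdrs$chrom, cdrs$start - 1L, cdrs$end, cdrs$n_windows,
                   cdrs$max_fst, cdrs$max_log2_ratio)
  writeLines(lines, path)
  invisible(path)
}
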