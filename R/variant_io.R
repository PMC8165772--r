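#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain text or gzipped) and keeps every record whose
#' REF and all ALT alleles are single bases (SNPs). Indel records are skipped
#' with a message. Multiallelic SNP records are retained as-is (dosage =
#' count of non-reference alleles) and can be removed later with
#' [apply_site_filters()]. Site depth is taken from the INFO `DP` field when
#' present. Sequence lengths come from `##contig` header lines when present,
#' otherwise from the maximum observed position per chromosome.
#'
#' @param path VCF file path.
#' @param popmap optional population map (path or data.frame, see
#'   [read_popmap()]); when given, every mapped sample must appear in the VCF
#'   header or an error lists the missing ones.
#' @return A [genotype_matrix()]. The `sites` data.frame carries `qual`,
#'   `dp` and `n_alt` (number of ALT alleles) columns.
#' @export
read_vcf <- function(path, popmap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  if (!"FORMAT" %in% colnames(v@gt))
    stop("VCF has no FORMAT/genotype columns: ", path)
  no_gt <- !grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])
  if (any(no_gt))
    stop("record without GT field at ", fix[which(no_gt)[1], "CHROM"], ":",
         fix[which(no_gt)[1], "POS"])

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_alleles <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  is_snp <- nchar(ref) == 1L & !is.na(alt) &
    vapply(alt_alleles, function(a) length(a) >= 1L && all(nchar(a) == 1L), logical(1))
  n_skip <- sum(!is_snp)
  if (n_skip > 0L)
    message("read_vcf: skipped ", n_skip, " non-SNP record(s)")
  if (!any(is_snp)) stop("no SNP records in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  geno <- gt_to_dosage(gt)

  dp <- suppressWarnings(vcfR::extract.info(v, element = "DP", as.numeric = TRUE))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  sites <- data.frame(
    chrom = fix[is_snp, "CHROM"],
    pos = as.integer(fix[is_snp, "POS"]),
    ref = ref[is_snp],
    alt = alt[is_snp],
    qual = qual[is_snp],
    dp = as.integer(dp[is_snp]),
    n_alt = lengths(alt_alleles)[is_snp],
    stringsAsFactors = FALSE
  )

  chrom_lengths <- contig_lengths(v@meta)
  gm <- genotype_matrix(sites, geno, chrom_lengths = chrom_lengths)
  if (!is.null(popmap)) {
    popmap <- read_popmap(popmap)
    absent <- setdiff(popmap$sample, gm$samples)
    if (length(absent))
      stop("popmap samples absent from VCF header: ",
           paste(absent, collapse = ", "))
  }
  gm
}

# "0/1", "0|1", "./." etc. -> dosage 0/1/2/NA (any non-ref allele counts)
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  dos <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == "." | a == "")) return(NA_integer_)
    sum(as.integer(a) > 0L)
  }, integer(1))
  out <- matrix(dos[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  storage.mode(out) <- "integer"
  out
}

contig_lengths <- function(meta) {
  m <- regmatches(meta, regexec("##contig=<ID=([^,>]+),.*length=([0-9]+)", meta))
  m <- m[lengths(m) == 3L]
  if (!length(m)) return(NULL)
  stats::setNames(as.integer(vapply(m, `[`, "", 3L)),
                  vapply(m, `[`, "", 2L))
}

#' Write a genotype matrix as an uncompressed VCF
#'
#' Emits a minimal, deterministic VCF 4.2 with `##contig` lines, the site
#' QUAL column, INFO `DP`, and unphased GT genotypes. Dosage 1 is written as
#' `0/1`; phase is not represented. Round-tripping through [read_vcf()]
#' preserves chrom, pos, alleles and dosages exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  s <- gm$sites
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    sprintf("##contig=<ID=%s,length=%d>",
            names(gm$chrom_lengths), as.integer(gm$chrom_lengths)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  qual <- ifelse(is.na(s$qual), ".", formatC(s$qual, format = "g", digits = 8))
  info <- ifelse(is.na(s$dp), ".", paste0("DP=", s$dp))
  code <- c("0/0", "0/1", "1/1")
  gts <- matrix("./.", nrow = nrow(s), ncol = length(gm$samples))
  ok <- !is.na(gm$geno)
  gts[ok] <- code[gm$geno[ok] + 1L]
  if (nrow(s) == 0L) {
    body <- character(0)
  } else {
    gt_str <- do.call(paste, c(lapply(seq_len(ncol(gts)), function(j) gts[, j]),
                               list(sep = "\t")))
    body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, qual, "PASS", info, "GT",
                  gt_str, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Site filter configuration
#'
#' Defaults mirror a resequencing-style hard filter: phred site quality at
#' least 20 and aggregate depth between 2 and 1000, keeping biallelic
#' records only.
#'
#' @param min_qual minimum phred-scaled site quality (default 20).
#' @param min_depth minimum aggregate site depth (default 2).
#' @param max_depth maximum aggregate site depth (default 1000).
#' @param biallelic_only drop records with more than one ALT allele
#'   (default TRUE).
#' @return A `site_filter_config` list.
#' @export
site_filter_config <- function(min_qual = 20, min_depth = 2, max_depth = 1000,
                               biallelic_only = TRUE) {
  stopifnot(min_qual >= 0, min_depth <= max_depth)
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 max_depth = max_depth, biallelic_only = isTRUE(biallelic_only)),
            class = "site_filter_config")
}

#' Apply hard site filters to a genotype matrix
#'
#' Retains exactly the sites with `qual >= min_qual`, `min_depth <= dp <=
#' max_depth` and, when `biallelic_only`, a single ALT allele. Sites with
#' missing `qual` or `dp` pass the corresponding test (nothing to filter
#' on). Order is preserved and the operation is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [site_filter_config()].
#' @return The filtered `genotype_matrix`; a warning (not an error) is
#'   raised when no site survives.
#' @export
apply_site_filters <- function(gm, cfg = site_filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "site_filter_config"))
  if (nrow(gm$sites) == 0L) stop("empty genotype matrix")
  s <- gm$sites
  keep <- (is.na(s$qual) | s$qual >= cfg$min_qual) &
    (is.na(s$dp) | (s$dp >= cfg$min_depth & s$dp <= cfg$max_depth))
  if (cfg$biallelic_only) {
    n_alt <- if ("n_alt" %in% names(s)) s$n_alt else
      lengths(strsplit(s$alt, ",", fixed = TRUE))
    keep <- keep & n_alt == 1L
  }
  if (!any(keep)) warning("no sites pass the filters")
  subset_sites(gm, keep)
}

#' Per-population allele counts
#'
#' For every site and population, counts the non-missing chromosomes
#' (`2 x` genotyped samples) and the observed alternate alleles (sum of
#' dosages). Missing genotypes are excluded, not imputed.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a population map covering every sample of `gm`.
#' @return An `allele_counts` object: list with `sites` (chrom/pos
#'   data.frame), `pops`, and site-by-population integer matrices `n_chrom`
#'   and `alt`.
#' @export
population_allele_counts <- function(gm, popmap) {
  popmap <- check_popmap(gm, popmap)
  pops <- unique(popmap$population)
  n_chrom <- alt <- matrix(0L, nrow = nrow(gm$sites), ncol = length(pops),
                           dimnames = list(NULL, pops))
  for (p in pops) {
    cols <- popmap$sample[popmap$population == p]
    g <- gm$geno[, cols, drop = FALSE]
    n_chrom[, p] <- 2L * as.integer(rowSums(!is.na(g)))
    alt[, p] <- as.integer(rowSums(g, na.rm = TRUE))
  }
  structure(list(sites = gm$sites[c("chrom", "pos")], pops = pops,
                 n_chrom = n_chrom, alt = alt),
            class = "allele_counts")
}

#' Shared and private SNP counts across populations
#'
#' A SNP is "present" in a population when at least one alternate allele is
#' observed there. Sites carrying no alternate allele anywhere (monomorphic
#' reference) are not counted. The returned subsets partition the
#' segregating sites, so the counts sum to the number of sites present
#' anywhere.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a population map covering every sample.
#' @return data.frame with columns `populations` (comma-joined subset
#'   label), `n_pops`, and `n_snps`, one row per non-empty subset observed,
#'   sorted by subset label. The row whose subset includes every population
#'   is the all-populations intersection.
#' @export
count_shared_private <- function(gm, popmap) {
  ac <- population_allele_counts(gm, popmap)
  if (length(ac$pops) < 2L) stop("need at least two populations")
  present <- ac$alt >= 1L
  seg <- rowSums(present) > 0L
  lab <- apply(present[seg, , drop = FALSE], 1L, function(z)
    paste(sort(ac$pops[z]), collapse = ","))
  tab <- table(lab)
  out <- data.frame(populations = names(tab),
                    n_pops = lengths(strsplit(names(tab), ",", fixed = TRUE)),
                    n_snps = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$populations), , drop = FALSE]
}
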