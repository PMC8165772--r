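#' Parameters of the coalescent data generator
#'
#' Defaults emulate a wild-vs-domestic resequencing design: a neutral
#' per-bp scaled mutation rate 4*Ne*mu = 5e-4 (Ne = 78125 diploids with the
#' avian-style mutation rate mu = 1.6e-9 per bp per generation, one
#' generation per year), 20 wild and 30 domestic diploid individuals, and a
#' clean two-deme split 0.2*Ne generations ago (pairwise-expectation
#' FST about 0.09). Each 40-kb locus is an independent non-recombining
#' genealogy, one per window of the downstream scan.
#'
#' @param Ne diploid effective size per deme.
#' @param mu per-bp per-generation mutation rate.
#' @param samples_per_pop named integer vector of diploid sample counts,
#'   one entry per population (one entry implies a single-deme model).
#' @param model demographic model: `list(type = "single_deme")`,
#'   `list(type = "split", T = <generations>)` (isolated demes merging into
#'   one ancestral deme of size `Ne` at time `T` looking backward), or
#'   `list(type = "island", m = <migration rate per lineage per
#'   generation>)`.
#' @param chrom_length total simulated sequence length in bp.
#' @param locus_size length of one independent locus (default 40000).
#' @param seed optional integer seed making the dataset reproducible.
#' @return A `coalescent_params` list.
#' @export
coalescent_params <- function(Ne = 78125, mu = 1.6e-9,
                              samples_per_pop = c(wild = 20L, domestic = 30L),
                              model = list(type = "split", T = 0.2 * 78125),
                              chrom_length = 4e6, locus_size = 40000L,
                              seed = NULL) {
  stopifnot(Ne > 0, mu > 0, all(samples_per_pop >= 1),
            model$type %in% c("single_deme", "split", "island"))
  if (is.null(names(samples_per_pop)))
    names(samples_per_pop) <- paste0("pop", seq_along(samples_per_pop))
  if (model$type == "split") stopifnot(model$T >= 0)
  if (model$type == "island") stopifnot(model$m >= 0)
  if (model$type != "single_deme" && length(samples_per_pop) != 2L)
    stop("two-deme models need exactly two populations")
  structure(list(Ne = Ne, mu = mu,
                 samples_per_pop = as.integer(samples_per_pop) |>
                   stats::setNames(names(samples_per_pop)),
                 model = model, chrom_length = as.numeric(chrom_length),
                 locus_size = as.integer(locus_size), seed = seed),
            class = "coalescent_params")
}

#' Planted-sweep specification
#'
#' Sweeps are emulated by a star genealogy: all sampled lineages of the
#' swept deme are forced to coalesce simultaneously at time `tau`, which
#' gives the hallmark signature of a recent sweep - expected per-bp
#' diversity about `2 * mu * tau` in the swept deme, strongly negative
#' Tajima's D, and elevated FST - with a closed-form ground truth.
#'
#' @param intervals data.frame with `start`, `end` (1-based inclusive bp);
#'   every locus overlapping an interval by at least 1 bp is simulated as
#'   swept, so intervals are best aligned to the locus grid.
#' @param tau forced coalescence time in generations.
#' @param deme population label of the swept deme (default `"domestic"`).
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(intervals, tau, deme = "domestic") {
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)),
            tau >= 0, all(intervals$end >= intervals$start))
  structure(list(intervals = intervals, tau = tau, deme = deme),
            class = "sweep_spec")
}

#' Simulate one structured-coalescent genealogy
#'
#' Kingman coalescent within demes (pairwise rate `k(k-1)/2 / (2*Ne)` per
#' generation), with either a clean split (isolated demes merging at `T`
#' looking backward) or symmetric island migration (per-lineage rate `m`).
#' Optionally, one deme's lineages are withheld from coalescence until
#' `sweep_tau` and then star-coalesced. Uses the current RNG state.
#'
#' @param k_by_deme integer vector: sampled chromosomes per deme.
#' @param Ne diploid effective size per deme.
#' @param model as in [coalescent_params()].
#' @param sweep_tau star-coalescence time, or `NULL` for neutral.
#' @param sweep_deme index of the swept deme in `k_by_deme`.
#' @return A `coalescent_tree`: list with `members` (per branch, the tip
#'   chromosomes below it), `len` (branch lengths in generations; the root
#'   branch is excluded), `tmrca`, and `n` (total chromosomes).
#' @export
simulate_genealogy <- function(k_by_deme, Ne, model = list(type = "single_deme"),
                               sweep_tau = NULL, sweep_deme = 2L) {
  total <- sum(k_by_deme)
  stopifnot(total >= 2L)
  members <- as.list(seq_len(total))
  birth <- numeric(total)
  deme <- rep(seq_along(k_by_deme), k_by_deme)
  active <- rep(TRUE, total)
  out_members <- vector("list", 2L * total)
  out_len <- numeric(2L * total)
  nb <- 0L
  close_branch <- function(i, t) {
    nb <<- nb + 1L
    out_members[[nb]] <<- members[[i]]
    out_len[nb] <<- t - birth[i]
  }
  new_lineage <- function(mem, t, d) {
    members[[length(members) + 1L]] <<- mem
    birth[length(birth) + 1L] <<- t
    deme[length(deme) + 1L] <<- d
    active[length(active) + 1L] <<- TRUE
  }
  t <- 0
  merged <- model$type != "split"
  sweep_pending <- !is.null(sweep_tau) && k_by_deme[sweep_deme] >= 2L
  repeat {
    act <- which(active)
    if (length(act) <= 1L) break
    kd <- tabulate(deme[act], nbins = length(k_by_deme))
    coal_rate <- kd * (kd - 1) / 2 / (2 * Ne)
    if (sweep_pending) coal_rate[sweep_deme] <- 0
    mig_rate <- if (model$type == "island") model$m * length(act) else 0
    tot <- sum(coal_rate) + mig_rate
    barrier <- Inf; barrier_kind <- ""
    if (sweep_pending && sweep_tau < barrier) {
      barrier <- sweep_tau; barrier_kind <- "star"
    }
    if (!merged && model$T < barrier) {
      barrier <- model$T; barrier_kind <- "merge"
    }
    dt <- if (tot > 0) stats::rexp(1, tot) else Inf
    if (t + dt > barrier) {
      t <- barrier
      if (barrier_kind == "star") {
        sw <- act[deme[act] == sweep_deme]
        if (length(sw) >= 2L) {
          for (i in sw) close_branch(i, t)
          active[sw] <- FALSE
          new_lineage(sort(unlist(members[sw])), t, sweep_deme)
        }
        sweep_pending <- FALSE
      } else {
        deme[active] <- 1L
        merged <- TRUE
      }
      next
    }
    t <- t + dt
    u <- stats::runif(1) * tot
    if (u < mig_rate) {
      i <- act[sample.int(length(act), 1L)]
      deme[i] <- if (deme[i] == 1L) 2L else 1L
    } else {
      u <- u - mig_rate
      d <- 1L
      while (u >= coal_rate[d]) { u <- u - coal_rate[d]; d <- d + 1L }
      cand <- act[deme[act] == d]
      ij <- cand[sample.int(length(cand), 2L)]
      close_branch(ij[1], t); close_branch(ij[2], t)
      active[ij] <- FALSE
      new_lineage(sort(c(members[[ij[1]]], members[[ij[2]]])), t, d)
    }
  }
  structure(list(members = out_members[seq_len(nb)], len = out_len[seq_len(nb)],
                 tmrca = t, n = total),
            class = "coalescent_tree")
}

#' Drop infinite-sites mutations on a genealogy
#'
#' The mutation count is Poisson with mean (total branch length) * mu *
#' locus_length; each mutation falls on a branch with probability
#' proportional to its length and claims a distinct position, producing one
#' biallelic column carried by the chromosomes below that branch.
#'
#' @param tree a `coalescent_tree` from [simulate_genealogy()].
#' @param mu per-bp per-generation mutation rate.
#' @param locus_length locus length in bp.
#' @return list with `pos` (sorted 1-based positions within the locus) and
#'   `haplotypes` (0/1 matrix, sites x chromosomes). Errors when the locus
#'   runs out of positions (theta too large for the locus).
#' @export
mutate_genealogy <- function(tree, mu, locus_length) {
  stopifnot(inherits(tree, "coalescent_tree"))
  total_len <- sum(tree$len)
  n_mut <- stats::rpois(1L, total_len * mu * locus_length)
  if (n_mut == 0L)
    return(list(pos = integer(0),
                haplotypes = matrix(0L, 0L, tree$n)))
  if (n_mut > locus_length)
    stop("locus saturated: ", n_mut, " mutations for ", locus_length,
         " positions; reduce theta or enlarge the locus")
  br <- sample.int(length(tree$len), n_mut, replace = TRUE, prob = tree$len)
  pos <- sort(sample.int(locus_length, n_mut))
  H <- matrix(0L, n_mut, tree$n)
  for (q in seq_len(n_mut)) H[q, tree$members[[br[q]]]] <- 1L
  list(pos = pos, haplotypes = H)
}

#' Simulate a complete synthetic SNP dataset
#'
#' One independent genealogy per locus tiling the chromosome; loci
#' overlapping a planted sweep interval use the star-genealogy sweep of
#' [sweep_spec()] in the designated deme. Chromosomes are paired into
#' diploid individuals within each deme. The result carries everything the
#' pipeline consumes: a genotype matrix (equivalently a VCF), a population
#' map, a BED12 gene track with one 20-kb gene every 50 kb (9-kb CDS), a
#' per-locus truth table, and optionally files on disk including a
#' reference FASTA consistent with the drawn REF alleles.
#'
#' Site QUAL is a passing constant (60) and aggregate depth is drawn around
#' 6.5x per sample within the passing range; `contaminate` injects a known
#' fraction of filter-failing records (low QUAL, or depth below 2 or above
#' 1000) to exercise the site filters.
#'
#' @param params a [coalescent_params()].
#' @param sweep a [sweep_spec()], or `NULL` for a fully neutral dataset.
#' @param dir output directory for files, or `NULL` to keep the dataset in
#'   memory only.
#' @param contaminate fraction of sites given filter-failing QUAL/DP
#'   (default 0).
#' @return A `simulated_dataset` list: `gm` (the [genotype_matrix()]),
#'   `popmap`, `truth` (per-locus data.frame with `chrom`, `start`, `end`,
#'   `swept`, and `theta_<pop>` expected per-bp diversities), `genes`
#'   (BED12-style data.frame), and `paths` (named file paths when `dir`
#'   was given).
#' @export
simulate_dataset <- function(params, sweep = NULL, dir = NULL,
                             contaminate = 0) {
  stopifnot(inherits(params, "coalescent_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  pops <- names(params$samples_per_pop)
  k_by_deme <- 2L * params$samples_per_pop
  L <- params$locus_size
  n_loci <- as.integer(ceiling(params$chrom_length / L))
  chrom_len <- n_loci * L
  starts <- (seq_len(n_loci) - 1L) * L + 1L
  ends <- starts + L - 1L

  swept <- rep(FALSE, n_loci)
  sweep_deme <- NA_integer_
  if (!is.null(sweep)) {
    stopifnot(inherits(sweep, "sweep_spec"))
    if (any(sweep$intervals$start < 1) || any(sweep$intervals$end > chrom_len))
      stop("sweep interval outside the simulated chromosome")
    sweep_deme <- match(sweep$deme, pops)
    if (is.na(sweep_deme)) stop("unknown swept deme: ", sweep$deme)
    for (r in seq_len(nrow(sweep$intervals)))
      swept <- swept | (starts <= sweep$intervals$end[r] &
                          ends >= sweep$intervals$start[r])
  }

  pos_list <- vector("list", n_loci)
  dos_list <- vector("list", n_loci)
  odd <- seq.int(1L, sum(k_by_deme), by = 2L)
  for (w in seq_len(n_loci)) {
    tree <- simulate_genealogy(
      k_by_deme, params$Ne, params$model,
      sweep_tau = if (swept[w]) sweep$tau else NULL,
      sweep_deme = if (swept[w]) sweep_deme else 2L)
    mut <- mutate_genealogy(tree, params$mu, L)
    pos_list[[w]] <- starts[w] - 1L + mut$pos
    dos_list[[w]] <- mut$haplotypes[, odd, drop = FALSE] +
      mut$haplotypes[, odd + 1L, drop = FALSE]
  }
  pos <- unlist(pos_list)
  geno <- do.call(rbind, dos_list)
  storage.mode(geno) <- "integer"
  sample_names <- unlist(lapply(pops, function(p)
    sprintf("%s_%02d", p, seq_len(params$samples_per_pop[[p]]))))
  colnames(geno) <- sample_names

  n_sites <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  shift <- sample.int(3L, n_sites, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  dp <- pmin(pmax(stats::rpois(n_sites, 6.5 * length(sample_names)), 2L), 1000L)
  qual <- rep(60, n_sites)
  if (contaminate > 0 && n_sites > 0L) {
    bad <- which(stats::runif(n_sites) < contaminate)
    kind <- sample.int(3L, length(bad), replace = TRUE)
    qual[bad[kind == 1L]] <- 10
    dp[bad[kind == 2L]] <- 1L
    dp[bad[kind == 3L]] <- 1500L
  }
  sites <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                      qual = qual, dp = as.integer(dp), n_alt = 1L,
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, geno, chrom_lengths = c(chr1 = chrom_len))

  popmap <- read_popmap(data.frame(
    sample = sample_names,
    population = rep(pops, params$samples_per_pop)))

  theta_neutral <- 4 * params$Ne * params$mu
  truth <- data.frame(chrom = "chr1", start = starts, end = ends,
                      swept = swept, stringsAsFactors = FALSE)
  for (p in pops) {
    th <- rep(theta_neutral, n_loci)
    if (!is.null(sweep) && p == sweep$deme)
      th[swept] <- 2 * params$mu * sweep$tau
    truth[[paste0("theta_", p)]] <- th
  }

  genes <- tile_genes(chrom_len)

  out <- list(gm = gm, popmap = popmap, truth = truth, genes = genes,
              paths = NULL)
  class(out) <- "simulated_dataset"
  if (!is.null(dir)) out <- write_dataset(out, dir)
  out
}

# one 20-kb gene every 50 kb, CDS = central 9 kb, BED12 columns
tile_genes <- function(chrom_len) {
  g0 <- seq.int(0L, max(0L, chrom_len - 50000L), by = 50000L)
  g0 <- g0[g0 + 20000L <= chrom_len]
  data.frame(
    chrom = "chr1", chromStart = g0, chromEnd = g0 + 20000L,
    name = sprintf("gene%04d", seq_along(g0)), score = 0L, strand = "+",
    thickStart = g0 + 5000L, thickEnd = g0 + 14000L, itemRgb = "0",
    blockCount = 1L, blockSizes = "20000,", blockStarts = "0,",
    stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Emits `sim.vcf`, `popmap.tsv`, `truth.tsv`, `genes.bed` (BED12) and
#' `reference.fa` (random sequence patched to match the drawn REF alleles)
#' into `dir`.
#'
#' @param ds a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return the dataset with `paths` filled in.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "sim.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             truth = file.path(dir, "truth.tsv"),
             genes = file.path(dir, "genes.bed"),
             fasta = file.path(dir, "reference.fa"))
  write_vcf(ds$gm, paths[["vcf"]])
  utils::write.table(ds$popmap, paths[["popmap"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$genes, paths[["genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  chrom_len <- ds$gm$chrom_lengths[["chr1"]]
  seq <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  seq[ds$gm$sites$pos] <- ds$gm$sites$ref
  lines <- vapply(split(seq, ceiling(seq_along(seq) / 70)),
                  paste, character(1), collapse = "")
  writeLines(c(">chr1", unname(lines)), paths[["fasta"]])
  ds$paths <- paths
  ds
}
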