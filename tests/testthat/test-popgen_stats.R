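counts_of <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- rep("P", length(gm$samples))
  population_allele_counts(
    gm, read_popmap(data.frame(sample = gm$samples, population = pops)))
}

test_that("window tiling covers chromosomes under the trailing-window rule", {
  w <- make_windows(c(chr1 = 100000L), window_spec(40000, 20000))
  expect_equal(w$start, c(1L, 20001L, 40001L, 60001L))
  expect_equal(w$end, c(40000L, 60000L, 80000L, 100000L))

  expect_equal(nrow(make_windows(c(c1 = 40000L), window_spec(40000, 20000))), 1L)

  w3 <- make_windows(c(c1 = 50000L), window_spec(40000, 20000))
  expect_equal(w3$start, c(1L, 20001L))
  expect_equal(w3$end, c(40000L, 50000L))
})

test_that("window diversity matches hand-computed values", {
  # no variation
  gm0 <- toy_gm(matrix(0L, 2, 4), pos = c(10L, 20L))
  d0 <- window_diversity(counts_of(gm0), list(chrom = "chr1", start = 1L, end = 1000L), "P")
  expect_equal(d0$n_snps, 0L)
  expect_equal(d0$theta_pi, 0)
  expect_equal(d0$theta_w, 0)
  expect_true(is.na(d0$tajimas_d))

  # n = 2 chromosomes (1 diploid) differing at 3 sites in 1 kb:
  # the heterozygote contributes 2*1*1/(2*1) = 1 per site
  gm2 <- toy_gm(matrix(1L, 3, 1), pos = c(100L, 200L, 300L))
  d2 <- suppressWarnings(
    window_diversity(counts_of(gm2), list(chrom = "chr1", start = 1L, end = 1000L), "P"))
  expect_equal(d2$theta_pi, 3 / 1000)

  # n = 4, S = 5, L = 1: a1 = 1 + 1/2 + 1/3 = 11/6, thetaW = 5/(11/6)
  gm4 <- toy_gm(matrix(c(0L, 1L), 5, 2), pos = 1:5)
  d4 <- window_diversity(counts_of(gm4), list(chrom = "chr1", start = 1L, end = 5L), "P")
  expect_equal(d4$theta_w, 5 / ((11 / 6) * 5), tolerance = 1e-12)
  expect_equal(d4$n_snps, 5L)

  # a single genotyped diploid gives n = 2 chromosomes: D undefined, warned
  gm_small <- toy_gm(matrix(1L, 2, 1), pos = c(5L, 6L))
  expect_warning(
    ds <- window_diversity(counts_of(gm_small),
                           list(chrom = "chr1", start = 1L, end = 100L), "P"),
    "below 4")
  expect_true(is.na(ds$tajimas_d))
})

test_that("diversity statistics are invariant to sample order and allele relabel", {
  gm <- random_gm(n_sites = 120, n_samples = 10, miss_rate = 0.08, seed = 41)
  w <- list(chrom = "chr1", start = 1L, end = 1000000L)
  base <- window_diversity(counts_of(gm), w, "P")

  perm <- sample(ncol(gm$geno))
  gm_perm <- gm; gm_perm$geno <- gm$geno[, perm]; gm_perm$samples <- gm$samples[perm]
  expect_equal(window_diversity(counts_of(gm_perm), w, "P"), base)

  gm_swap <- gm; gm_swap$geno <- 2L - gm$geno
  swapped <- window_diversity(counts_of(gm_swap), w, "P")
  expect_equal(swapped$theta_pi, base$theta_pi)
  expect_equal(swapped$theta_w, base$theta_w)
})

test_that("S and the pi sum are additive over disjoint site sets", {
  gm <- random_gm(n_sites = 100, n_samples = 8, miss_rate = 0.05, seed = 43,
                  n_chrom_seq = 1)
  cut <- stats::median(gm$sites$pos)
  w_all <- list(chrom = "chr1", start = 1L, end = 1000000L)
  w_lo <- list(chrom = "chr1", start = 1L, end = as.integer(cut))
  w_hi <- list(chrom = "chr1", start = as.integer(cut) + 1L, end = 1000000L)
  ac <- counts_of(gm)
  all <- window_diversity(ac, w_all, "P")
  lo <- window_diversity(ac, w_lo, "P")
  hi <- window_diversity(ac, w_hi, "P")
  expect_equal(all$n_snps, lo$n_snps + hi$n_snps)
  L_all <- 1000000; L_lo <- cut; L_hi <- 1000000 - cut
  expect_equal(all$theta_pi * L_all,
               lo$theta_pi * L_lo + hi$theta_pi * L_hi, tolerance = 1e-9)
})

test_that("FST behaves on fixed differences and identical populations", {
  # fixed difference at the only site: both estimators give 1
  g <- cbind(matrix(2L, 1, 4), matrix(0L, 1, 4))
  colnames(g) <- sprintf("s%d", 1:8)
  gm <- toy_gm(g)
  ac <- counts_of(gm, rep(c("A", "B"), each = 4))
  w <- list(chrom = "chr1", start = 1L, end = 1000L)
  expect_equal(window_fst(ac, w, "A", "B", "weir_cockerham"), 1)
  expect_equal(window_fst(ac, w, "A", "B", "hudson"), 1)

  # identical dosage vectors in both populations: Hudson <= 0
  gi <- cbind(matrix(c(0L, 1L, 2L, 1L), 4, 4), matrix(c(0L, 1L, 2L, 1L), 4, 4))
  colnames(gi) <- sprintf("s%d", 1:8)
  gmi <- toy_gm(gi)
  aci <- counts_of(gmi, rep(c("A", "B"), each = 4))
  expect_lte(window_fst(aci, w, "A", "B", "hudson"), 0)

  # windows with no polymorphic site are missing, unknown estimator errors
  mono <- toy_gm(matrix(0L, 2, 8), pos = c(10L, 20L))
  acm <- counts_of(mono, rep(c("A", "B"), each = 4))
  expect_true(is.na(window_fst(acm, w, "A", "B")))
  expect_error(window_fst(ac, w, "A", "B", "nei"))
})

test_that("Weir-Cockerham windowed FST equals the scalar reference implementation", {
  for (seed in c(3, 17, 23)) {
    gm <- random_gm(n_sites = 150, n_samples = 12, miss_rate = 0.1, seed = seed,
                    n_chrom_seq = 1)
    pops <- rep(c("A", "B"), c(5, 7))
    ac <- counts_of(gm, pops)
    w <- list(chrom = "chr1", start = 1L, end = 1000000L)
    got <- window_fst(ac, w, "A", "B", "weir_cockerham")
    want <- wc_fst_reference(ac$alt[, "A"], ac$n_chrom[, "A"],
                             ac$alt[, "B"], ac$n_chrom[, "B"])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("statistics agree with the coalescent-simulation oracle fixture", {
  gm <- read_vcf(fixture_path("twopop_synthetic.vcf"))
  pm <- read_popmap(fixture_path("twopop_synthetic.popmap.tsv"))
  w <- data.frame(chrom = "1", start = 1L, end = 50000L)
  st <- windowed_stats(gm, pm, spec = w, pair = c("wild", "domestic"),
                       estimator = "hudson")
  expect_equal(st$n_snps, tskit_oracle$n_sites)
  expect_equal(st$theta_pi_wild, tskit_oracle$theta_pi_wild, tolerance = 1e-6)
  expect_equal(st$theta_pi_domestic, tskit_oracle$theta_pi_domestic, tolerance = 1e-6)
  expect_equal(st$theta_w_wild, tskit_oracle$theta_w_wild, tolerance = 1e-6)
  expect_equal(st$theta_w_domestic, tskit_oracle$theta_w_domestic, tolerance = 1e-6)
  expect_equal(st$tajimas_d_wild, tskit_oracle$tajimas_d_wild, tolerance = 1e-6)
  expect_equal(st$tajimas_d_domestic, tskit_oracle$tajimas_d_domestic,
               tolerance = 1e-6)
  expect_equal(st$fst, tskit_oracle$hudson_fst, tolerance = 1e-6)
  expect_equal(st$log2_ratio, tskit_oracle$log2_pi_ratio, tolerance = 1e-6)
})

test_that("log2 ratio handles doubling, equality, zeros and window mismatch", {
  a <- data.frame(chrom = "c", start = 1L, end = 10L, theta_pi = c(2, 1, 1))
  b <- data.frame(chrom = "c", start = 1L, end = 10L, theta_pi = c(1, 1, 0))
  r <- log2_pi_ratio(a, b)
  expect_equal(r[1], 1)
  expect_equal(r[2], 0)
  expect_true(is.na(r[3]))
  b2 <- b; b2$start <- 2L
  expect_error(log2_pi_ratio(a, b2), "do not match")
})

test_that("the windowed driver equals the single-window operations", {
  gm <- random_gm(n_sites = 300, n_samples = 10, miss_rate = 0.05, seed = 57,
                  n_chrom_seq = 2)
  pm <- two_pop_map(gm$samples)
  spec <- window_spec(200000, 100000)
  st <- suppressWarnings(
    windowed_stats(gm, pm, spec = spec, pair = c("A", "B")))
  ac <- population_allele_counts(gm, pm)
  for (i in sample(nrow(st), 5)) {
    w <- list(chrom = st$chrom[i], start = st$start[i], end = st$end[i])
    dv <- suppressWarnings(window_diversity(ac, w, "A"))
    expect_equal(st$theta_pi_A[i], dv$theta_pi)
    expect_equal(st$theta_w_A[i], dv$theta_w)
    expect_equal(st$tajimas_d_A[i], dv$tajimas_d)
    expect_equal(st$fst[i], window_fst(ac, w, "A", "B"))
  }
})
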