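# Shared fixture builders and independent reference implementations.
# Reference implementations here are deliberately written as plain scalar
# loops so they share no code path with the package internals.

toy_gm <- function(dosages, chrom = "chr1", pos = NULL, qual = NULL,
                   dp = NULL, alt = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("s%02d", seq_len(ncol(dosages)))
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep("A", n),
                      alt = if (is.null(alt)) rep("T", n) else alt,
                      stringsAsFactors = FALSE)
  if (!is.null(qual)) sites$qual <- qual
  if (!is.null(dp)) sites$dp <- dp
  sites$n_alt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  storage.mode(dosages) <- "integer"
  genotype_matrix(sites, dosages)
}

random_gm <- function(n_sites = 60, n_samples = 8, miss_rate = 0,
                      n_chrom_seq = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
              n_sites, n_samples)
  if (miss_rate > 0)
    g[runif(length(g)) < miss_rate] <- NA
  colnames(g) <- sprintf("s%02d", seq_len(n_samples))
  chrom <- sort(rep_len(sprintf("chr%d", seq_len(n_chrom_seq)), n_sites))
  pos <- unlist(lapply(split(seq_len(n_sites), chrom), function(i)
    sort(sample.int(1e6, length(i)))))
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                      n_alt = 1L, stringsAsFactors = FALSE)
  storage.mode(g) <- "integer"
  genotype_matrix(sites, g)
}

two_pop_map <- function(samples) {
  half <- length(samples) %/% 2
  read_popmap(data.frame(sample = samples,
                         population = rep(c("A", "B"),
                                          c(half, length(samples) - half))))
}

# Weir & Cockerham (1984) variance components, allele-count form, written
# as a direct scalar transcription: a and (a + b) summed over sites.
wc_fst_reference <- function(a1, n1, a2, n2) {
  num <- den <- 0
  for (s in seq_along(a1)) {
    if (n1[s] < 2 || n2[s] < 2) next
    tot <- a1[s] + a2[s]
    if (tot == 0 || tot == n1[s] + n2[s]) next
    p1 <- a1[s] / n1[s]; p2 <- a2[s] / n2[s]
    r <- 2
    nbar <- (n1[s] + n2[s]) / r
    nc <- (n1[s] + n2[s] - (n1[s]^2 + n2[s]^2) / (n1[s] + n2[s])) / (r - 1)
    pbar <- (n1[s] * p1 + n2[s] * p2) / (n1[s] + n2[s])
    ssq <- (n1[s] * (p1 - pbar)^2 + n2[s] * (p2 - pbar)^2) / ((r - 1) * nbar)
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - ssq * (r - 1) / r)
    a <- nbar / nc * (ssq - b / nbar)
    num <- num + a
    den <- den + a + b
  }
  num / den
}

# interval-union merge by position sweeping, one bp at a time
brute_merge <- function(windows) {
  out <- NULL
  for (ch in sort(unique(windows$chrom))) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    covered <- sort(unique(unlist(Map(seq.int, w$start, w$end))))
    gaps <- which(diff(covered) > 1)
    starts <- covered[c(1, gaps + 1)]
    ends <- covered[c(gaps, length(covered))]
    out <- rbind(out, data.frame(chrom = ch, start = starts, end = ends))
  }
  out
}

# full-CDS translation oracle: substitute the base in the genome, extract
# the entire CDS, translate with Biostrings, and compare proteins
coding_effect_oracle <- function(pos, alt, gene, reference) {
  seq0 <- reference[[gene$chrom]]
  seq1 <- paste0(substr(seq0, 1, pos - 1), alt,
                 substr(seq0, pos + 1, nchar(seq0)))
  cds_of <- function(s) {
    parts <- vapply(seq_len(nrow(gene$cds)), function(i)
      substr(s, gene$cds[i, 1], gene$cds[i, 2]), character(1))
    x <- Biostrings::DNAString(paste(parts, collapse = ""))
    if (gene$strand == "-") x <- Biostrings::reverseComplement(x)
    as.character(Biostrings::translate(x, no.init.codon = TRUE))
  }
  if (cds_of(seq0) == cds_of(seq1)) "synonymous" else "nonsynonymous"
}

# frozen expected values computed with msprime/tskit on the shipped
# two-population fixture (scratch generation script; see package sources)
tskit_oracle <- list(
  theta_pi_wild = 0.001220736842105265,
  theta_pi_domestic = 0.0005627368421052632,
  theta_w_wild = 0.0011613028007012923,
  theta_w_domestic = 0.0006483001071876146,
  tajimas_d_wild = 0.21258253100914784,
  tajimas_d_domestic = -0.5437210512419784,
  n_sites = 298L,
  hudson_fst = 0.2596622315439894,
  log2_pi_ratio = 1.117219903617379
)

fixture_path <- function(name) {
  system.file("extdata", name, package = "sweepscan", mustWork = TRUE)
}
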