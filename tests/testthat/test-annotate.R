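# A hand-built toy locus used throughout:
#   gene "g+" on +: exon1 1001-1300 (CDS 1001-1300), intron 1301-2000,
#   exon2 2001-2300 (CDS 2001-2300); 600-bp CDS
toy_gene_plus <- function() {
  gene_model("g+", "chrT", "+",
             exons = rbind(c(1001L, 1300L), c(2001L, 2300L)),
             cds = rbind(c(1001L, 1300L), c(2001L, 2300L)))
}

random_reference <- function(len = 5000L, seed = 5, chrom = "chrT") {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), chrom)
}

test_that("location categories follow the documented precedence", {
  g <- toy_gene_plus()
  genes <- list(g)
  cls <- function(pos) classify_location("chrT", pos, genes)$category
  expect_equal(cls(1150L), "exonic")
  expect_equal(cls(1302L), "splicing")   # 2 bp into the intron
  expect_equal(cls(1500L), "intronic")
  expect_equal(cls(500L), "upstream")    # 501 bp before the TSS, flank 1000
  expect_equal(cls(2500L), "downstream")
  expect_equal(cls(50000L), "intergenic")
  # unknown chromosome falls back to intergenic with a warning
  expect_warning(out <- classify_location("chrZ", 100L, genes), "absent")
  expect_equal(out$category, "intergenic")
})

test_that("UTR sites are exon-minus-CDS and never coding", {
  g <- gene_model("utr", "chrT", "+",
                  exons = rbind(c(1001L, 1300L)),
                  cds = rbind(c(1101L, 1250L)))
  expect_equal(classify_location("chrT", 1050L, list(g))$category, "UTR")
  expect_equal(classify_location("chrT", 1150L, list(g))$category, "exonic")
})

test_that("strand-aware flanks: upstream of a minus-strand gene is to its right", {
  g <- gene_model("gm", "chrT", "-", exons = rbind(c(1001L, 1300L)))
  expect_equal(classify_location("chrT", 1500L, list(g))$category, "upstream")
  expect_equal(classify_location("chrT", 800L, list(g))$category, "downstream")
})

test_that("simple codon changes are called through the genetic code", {
  ref <- stats::setNames(paste0(strrep("N", 1000), "GGATTT", strrep("N", 100)),
                         "chrT")
  # CDS 1001-1006 = GGA TTT; Gly Phe
  g <- gene_model("mini", "chrT", "+", exons = rbind(c(1001L, 1006L)),
                  cds = rbind(c(1001L, 1006L)))
  expect_equal(classify_coding_effect("chrT", 1003L, "A", "G", g, ref),
               "synonymous")     # GGA -> GGG, both Gly
  expect_equal(classify_coding_effect("chrT", 1001L, "G", "A", g, ref),
               "nonsynonymous")  # GGA -> AGA, Gly -> Arg
  expect_error(classify_coding_effect("chrT", 1001L, "C", "A", g, ref),
               "reference mismatch")
  expect_error(classify_coding_effect("chrT", 1500L, "N", "A", g, ref),
               "not inside the CDS")
})

test_that("every single-base CDS substitution matches full-CDS translation, both strands", {
  ref <- random_reference()
  for (strand in c("+", "-")) {
    # 30-bp CDS split over two exons to exercise the coordinate map
    g <- gene_model(paste0("ex", strand), "chrT", strand,
                    exons = rbind(c(2001L, 2012L), c(2101L, 2118L)),
                    cds = rbind(c(2001L, 2012L), c(2101L, 2118L)))
    cds_pos <- c(2001:2012, 2101:2118)
    for (pos in cds_pos) {
      base <- substr(ref[["chrT"]], pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), base)) {
        expect_equal(
          classify_coding_effect("chrT", pos, base, alt, g, ref),
          coding_effect_oracle(pos, alt, g, ref),
          info = sprintf("strand %s pos %d %s>%s", strand, pos, base, alt))
      }
    }
  }
})

test_that("mirrored genes on opposite strands give identical effect calls", {
  set.seed(9)
  n <- 3000L
  fwd <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev_seq <- rev(unname(comp[fwd]))
  refs <- list("+" = stats::setNames(paste(fwd, collapse = ""), "chrT"),
               "-" = stats::setNames(paste(rev_seq, collapse = ""), "chrT"))
  lo <- 1001L; hi <- 1030L
  g_plus <- gene_model("p", "chrT", "+", rbind(c(lo, hi)), rbind(c(lo, hi)))
  lo2 <- n - hi + 1L; hi2 <- n - lo + 1L
  g_minus <- gene_model("m", "chrT", "-", rbind(c(lo2, hi2)), rbind(c(lo2, hi2)))
  for (pos in lo:hi) {
    base <- fwd[pos]
    mpos <- n - pos + 1L
    for (alt in setdiff(c("A", "C", "G", "T"), base)) {
      expect_equal(
        classify_coding_effect("chrT", pos, base, alt, g_plus, refs[["+"]]),
        classify_coding_effect("chrT", mpos, comp[[base]], comp[[alt]],
                               g_minus, refs[["-"]]),
        info = sprintf("pos %d %s>%s", pos, base, alt))
    }
  }
})

test_that("annotation summary counts partition the input and form the ratio", {
  ann <- data.frame(
    chrom = "c", pos = 1:6,
    category = c("exonic", "exonic", "exonic", "intronic", "intergenic", "UTR"),
    effect = c("synonymous", "synonymous", "nonsynonymous",
               "noncoding", "noncoding", "noncoding"),
    gene_id = NA_character_)
  sm <- annotation_summary(ann)
  expect_equal(sum(sm$category_counts), nrow(ann))
  expect_equal(sm$nonsyn_syn_ratio, 1 / 2)
  # degenerate: no synonymous site -> ratio is NA, counts intact
  sm0 <- annotation_summary(ann[ann$effect != "synonymous", ])
  expect_true(is.na(sm0$nonsyn_syn_ratio))
  expect_equal(sum(sm0$category_counts), 4L)
  # the ratio reproduces the x/y division shape exactly
  many <- data.frame(chrom = "c", pos = seq_len(54),
                     category = "exonic",
                     effect = rep(c("nonsynonymous", "synonymous"), c(12, 42)),
                     gene_id = NA_character_)
  expect_equal(annotation_summary(many)$nonsyn_syn_ratio, 12 / 42,
               tolerance = 1e-12)
})

test_that("gene models round-trip through GFF3 and BED12 readers", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\tsrc\tgene\t1001\t2300\t.\t+\t.\tID=geneA",
    "chrT\tsrc\tmRNA\t1001\t2300\t.\t+\t.\tID=txA;Parent=geneA",
    "chrT\tsrc\texon\t1001\t1300\t.\t+\t.\tParent=txA",
    "chrT\tsrc\texon\t2001\t2300\t.\t+\t.\tParent=txA",
    "chrT\tsrc\tCDS\t1001\t1300\t.\t+\t0\tParent=txA",
    "chrT\tsrc\tCDS\t2001\t2300\t.\t+\t0\tParent=txA"), gff)
  gg <- read_gene_models(gff)
  expect_length(gg, 1L)
  expect_equal(gg[[1]]$tx_start, 1001L)
  expect_equal(gg[[1]]$tx_end, 2300L)
  expect_equal(nrow(gg[[1]]$cds), 2L)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chrT", 1000, 2300, "txA", 0, "+", 1000, 2300, "0",
                     2, "300,300,", "0,1000,"), collapse = "\t"), bed)
  gb <- read_gene_models(bed)
  expect_equal(gb[[1]]$exons, rbind(c(1001L, 1300L), c(2001L, 2300L)))
  expect_equal(gb[[1]]$cds, rbind(c(1001L, 1300L), c(2001L, 2300L)))
  expect_equal(gb[[1]]$strand, "+")
})
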