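#' Construct a gene model
#'
#' One transcript per gene: ordered exon intervals, the CDS intervals they
#' contain, and the transcript bounds. Intervals are 1-based inclusive
#' genomic coordinates, stored in ascending genomic order regardless of
#' strand; total CDS length must be divisible by 3 when a CDS is present.
#'
#' @param gene_id identifier.
#' @param chrom sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of exon intervals.
#' @param cds two-column matrix of CDS intervals, or `NULL` for a
#'   noncoding transcript.
#' @return A `gene_model` list with fields `gene_id`, `chrom`, `strand`,
#'   `exons`, `cds`, `tx_start`, `tx_end`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1])) stop("malformed exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exon intervals in gene ", gene_id)
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2)
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    len <- sum(cds[, 2] - cds[, 1] + 1L)
    if (len %% 3L != 0L)
      stop("CDS length of gene ", gene_id, " (", len, ") not divisible by 3")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds,
                 tx_start = min(exons[, 1]), tx_end = max(exons[, 2])),
            class = "gene_model")
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 files are parsed with `rtracklayer`; each `mRNA`/`transcript`
#' feature (or `gene` feature when no transcripts are present) becomes one
#' gene model with its child `exon` and `CDS` features. BED12 files map each
#' line to one gene model: blocks become exons and the thick interval,
#' intersected with the blocks, becomes the CDS (no thick interval means a
#' noncoding transcript).
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED12 (`.bed`) file.
#' @return list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
    read_gene_models_bed12(path)
  else
    read_gene_models_gff3(path)
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  tx_idx <- which(type %in% c("mRNA", "transcript"))
  parent_of <- function(i) {
    p <- gr$Parent[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }
  if (length(tx_idx)) {
    ids <- as.character(gr$ID[tx_idx])
  } else {
    tx_idx <- which(type == "gene")
    ids <- as.character(gr$ID[tx_idx])
  }
  child_parent <- vapply(seq_along(gr), parent_of, character(1))
  lapply(seq_along(tx_idx), function(k) {
    i <- tx_idx[k]
    kids <- which(child_parent == ids[k])
    ex <- kids[type[kids] == "exon"]
    cd <- kids[type[kids] == "CDS"]
    exons <- if (length(ex))
      cbind(BiocGenerics::start(gr)[ex], BiocGenerics::end(gr)[ex])
    else
      cbind(BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i])
    cds <- if (length(cd))
      cbind(BiocGenerics::start(gr)[cd], BiocGenerics::end(gr)[cd])
    else NULL
    gene_model(ids[k], as.character(GenomeInfoDb::seqnames(gr)[i]),
               as.character(BiocGenerics::strand(gr)[i]), exons, cds)
  })
}

read_gene_models_bed12 <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 12L) stop("expected BED12 (12 columns) in ", path)
  lapply(seq_len(nrow(bed)), function(i) {
    chrom_start <- bed[i, 2] # 0-based
    sizes <- as.integer(strsplit(sub(",$", "", bed[i, 11]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", bed[i, 12]), ",")[[1]])
    exons <- cbind(chrom_start + offs + 1L, chrom_start + offs + sizes)
    thick_lo <- bed[i, 7] + 1L; thick_hi <- bed[i, 8]
    cds <- NULL
    if (thick_hi >= thick_lo) {
      lo <- pmax(exons[, 1], thick_lo); hi <- pmin(exons[, 2], thick_hi)
      keep <- hi >= lo
      if (any(keep)) cds <- cbind(lo[keep], hi[keep])
    }
    strand <- if (bed[i, 6] %in% c("+", "-")) bed[i, 6] else "+"
    gene_model(as.character(bed[i, 4]), as.character(bed[i, 1]), strand,
               exons, cds)
  })
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences, one per record.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

in_interval <- function(pos, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(FALSE)
  any(pos >= iv[, 1] & pos <= iv[, 2])
}

# severity order used when several genes/transcripts cover a site
.category_levels <- c("exonic", "splicing", "UTR", "intronic",
                      "upstream", "downstream", "intergenic")

#' Classify a SNP's genomic location
#'
#' Categories follow the usual variant-annotation vocabulary with
#' precedence exonic > splicing > UTR > intronic > upstream/downstream >
#' intergenic. "Exonic" means inside a CDS interval; exon sequence outside
#' the CDS is UTR; "splicing" is an intronic position within 2 bp of an
#' exon/intron junction; upstream/downstream are within `flank` bp of the
#' transcript start/end, respecting strand. When several genes cover the
#' site, the most severe category (and its gene) wins.
#'
#' @param chrom,pos site coordinate (1-based).
#' @param genes list of [gene_model()] objects.
#' @param flank up/downstream window in bp (default 1000).
#' @return list with `category` and `gene_id` (NA for intergenic).
#' @export
classify_location <- function(chrom, pos, genes, flank = 1000L) {
  best <- "intergenic"; best_gene <- NA_character_
  chroms <- vapply(genes, `[[`, "", "chrom")
  if (length(genes) && !chrom %in% chroms)
    warning("chromosome ", chrom, " absent from the gene annotation")
  for (g in genes[chroms == chrom]) {
    cat <- classify_location_one(pos, g, flank)
    if (match(cat, .category_levels) < match(best, .category_levels)) {
      best <- cat; best_gene <- g$gene_id
    }
  }
  list(category = best, gene_id = best_gene)
}

classify_location_one <- function(pos, g, flank) {
  if (pos >= g$tx_start && pos <= g$tx_end) {
    if (in_interval(pos, g$cds)) return("exonic")
    if (in_interval(pos, g$exons)) return("UTR")
    # intronic; splicing when within 2 bp of an exon boundary
    d <- min(abs(pos - as.vector(g$exons)))
    if (d <= 2L) return("splicing")
    return("intronic")
  }
  tss <- if (g$strand == "+") g$tx_start else g$tx_end
  tes <- if (g$strand == "+") g$tx_end else g$tx_start
  upstream <- (g$strand == "+" && pos < g$tx_start && g$tx_start - pos <= flank) ||
    (g$strand == "-" && pos > g$tx_end && pos - g$tx_end <= flank)
  if (upstream) return("upstream")
  downstream <- (g$strand == "+" && pos > g$tx_end && pos - g$tx_end <= flank) ||
    (g$strand == "-" && pos < g$tx_start && g$tx_start - pos <= flank)
  if (downstream) return("downstream")
  "intergenic"
}

# genomic positions of the CDS in translation (5'->3' mRNA) order
cds_positions <- function(g) {
  pos <- unlist(lapply(seq_len(nrow(g$cds)), function(i)
    seq.int(g$cds[i, 1], g$cds[i, 2])))
  if (g$strand == "-") rev(pos) else pos
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Call a coding SNP synonymous or nonsynonymous
#'
#' Rebuilds the codon containing the site from the reference sequence
#' (strand-aware, reverse-complementing minus-strand genes), substitutes the
#' alternate base, and compares amino acids under the standard genetic code.
#' Any amino-acid change, including stop gain or loss, is nonsynonymous.
#'
#' @param chrom,pos site coordinate.
#' @param ref_allele,alt_allele single reference/alternate bases (as given
#'   in the VCF, i.e. on the + strand).
#' @param gene a [gene_model()] whose CDS contains the site.
#' @param reference named character vector of chromosome sequences (see
#'   [read_reference()]).
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_coding_effect <- function(chrom, pos, ref_allele, alt_allele, gene,
                                   reference) {
  if (is.null(gene$cds) || !in_interval(pos, gene$cds))
    stop("site ", chrom, ":", pos, " is not inside the CDS of ", gene$gene_id)
  seq <- reference[[chrom]]
  if (is.null(seq)) stop("chromosome ", chrom, " absent from reference")
  genome_base <- substr(seq, pos, pos)
  if (genome_base != toupper(ref_allele))
    stop("reference mismatch at ", chrom, ":", pos, " (reference has ",
         genome_base, ", site claims ", ref_allele, ")")
  cpos <- cds_positions(gene)
  idx <- match(pos, cpos)
  codon_i <- (idx - 1L) %/% 3L
  cidx <- codon_i * 3L + 1:3
  bases <- vapply(cpos[cidx], function(p) substr(seq, p, p), character(1))
  if (gene$strand == "-") bases <- unname(.complement[bases])
  codon_ref <- paste(bases, collapse = "")
  sub_base <- toupper(alt_allele)
  if (gene$strand == "-") sub_base <- unname(.complement[sub_base])
  bases[match(idx, cidx)] <- sub_base
  codon_alt <- paste(bases, collapse = "")
  aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  if (is.null(aa_ref) || is.null(aa_alt))
    stop("codon with non-ACGT base at ", chrom, ":", pos)
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

#' Annotate every SNP of a genotype matrix
#'
#' Drives [classify_location()] over all sites and, for exonic sites of
#' biallelic SNPs, [classify_coding_effect()]. Sites outside a CDS get
#' effect `"noncoding"`.
#'
#' @param gm a [genotype_matrix()].
#' @param genes list of [gene_model()] objects.
#' @param reference named character vector of sequences; may be `NULL`, in
#'   which case exonic sites keep effect `NA`.
#' @param flank up/downstream window in bp (default 1000).
#' @return data.frame with columns `chrom`, `pos`, `category`, `effect`,
#'   `gene_id`.
#' @export
annotate_sites <- function(gm, genes, reference = NULL, flank = 1000L) {
  s <- gm$sites
  n <- nrow(s)
  category <- character(n); effect <- rep("noncoding", n)
  gene_id <- rep(NA_character_, n)
  gene_chroms <- vapply(genes, `[[`, "", "chrom")
  missing_chroms <- setdiff(unique(s$chrom), gene_chroms)
  if (length(missing_chroms))
    warning("chromosome(s) absent from the gene annotation: ",
            paste(missing_chroms, collapse = ", "))
  for (i in seq_len(n)) {
    loc <- suppressWarnings(
      classify_location(s$chrom[i], s$pos[i], genes, flank))
    category[i] <- loc$category
    gene_id[i] <- loc$gene_id
    if (loc$category == "exonic") {
      if (is.null(reference) || nchar(s$alt[i]) != 1L) {
        effect[i] <- NA_character_
      } else {
        g <- genes[[match(loc$gene_id, vapply(genes, `[[`, "", "gene_id"))]]
        effect[i] <- classify_coding_effect(s$chrom[i], s$pos[i], s$ref[i],
                                            s$alt[i], g, reference)
      }
    }
  }
  data.frame(chrom = s$chrom, pos = s$pos, category = category,
             effect = effect, gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Summarize site annotations
#'
#' @param annotations data.frame from [annotate_sites()].
#' @return list with `category_counts` (named integer vector over the
#'   category vocabulary), `n_synonymous`, `n_nonsynonymous`, and
#'   `nonsyn_syn_ratio` (`NA` when no synonymous site exists).
#' @export
annotation_summary <- function(annotations) {
  counts <- table(factor(annotations$category, levels = .category_levels))
  n_syn <- sum(annotations$effect == "synonymous", na.rm = TRUE)
  n_non <- sum(annotations$effect == "nonsynonymous", na.rm = TRUE)
  list(category_counts = stats::setNames(as.integer(counts), names(counts)),
       n_synonymous = n_syn, n_nonsynonymous = n_non,
       nonsyn_syn_ratio = if (n_syn == 0L) NA_real_ else n_non / n_syn)
}
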