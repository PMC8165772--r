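#' Individual-level p-distance matrix
#'
#' The allele-sharing p-distance between two diploid individuals:
#' `sum(|g_i - g_j|) / (2 * m)` over the `m` sites where both are
#' genotyped, which lies in `[0, 1]` (0 for identical dosage rows, 1 for
#' opposite homozygotes everywhere). Sites with a missing genotype in
#' either individual are excluded pairwise.
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = sample
#'   ids. A pair with no jointly genotyped site is an error naming the pair.
#' @export
p_distance_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$samples) < 3L) stop("need at least 3 samples")
  G <- gm$geno
  V <- !is.na(G); storage.mode(V) <- "double"
  X <- G; X[is.na(X)] <- 0L; storage.mode(X) <- "double"
  njoint <- crossprod(V)
  if (any(njoint[upper.tri(njoint)] == 0)) {
    bad <- which(njoint == 0 & upper.tri(njoint), arr.ind = TRUE)[1, ]
    stop("samples ", gm$samples[bad[1]], " and ", gm$samples[bad[2]],
         " share no genotyped site")
  }
  Sxy <- crossprod(X)
  A <- crossprod(X * X, V)           # A[i,j] = sum over j-valid sites of x_i^2
  d2 <- A + t(A) - 2 * Sxy           # sum (g_i - g_j)^2 over joint sites
  O <- crossprod((G == 0L & V) * 1, (G == 2L & V) * 1)
  opp <- O + t(O)                    # opposite-homozygote site counts
  dabs <- d2 - 2 * opp               # |d| = d^2 - 2*I(d^2 = 4)
  D <- dabs / (2 * njoint)
  diag(D) <- 0
  dimnames(D) <- list(gm$samples, gm$samples)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion. Ties in Q are
#' broken deterministically by the lexicographically smallest pair of
#' representative labels (each cluster is represented by its smallest tip
#' label), so the output never depends on input order. Negative branch
#' length estimates are clamped to zero with the deficit transferred to the
#' sibling edge. On an additive (tree-metric) input the path lengths of the
#' output reproduce the input exactly.
#'
#' @param d symmetric distance matrix with labelled rows/columns, or a
#'   `dist` object.
#' @return an unrooted `ape` `"phylo"` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix is not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n0 <- nrow(d)
  if (n0 < 3L) stop("need at least 3 taxa")
  # active clusters: newick fragment + representative (smallest tip) label
  frag <- vapply(labels, function(l) l, character(1))
  rep_lab <- labels
  D <- unname(d)
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], li, frag[j], lj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  # resolve the final three clusters on a central node
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (k in 1:3) {
    l <- c(la, lb, lc)
    if (l[k] < 0) {
      others <- setdiff(1:3, k)
      l[others] <- l[others] + l[k] / 2
      l[k] <- 0
      la <- l[1]; lb <- l[2]; lc <- l[3]
    }
  }
  ord <- order(rep_lab)
  fr <- frag[ord]; ln <- c(la, lb, lc)[ord]
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 fr[1], ln[1], fr[2], ln[2], fr[3], ln[3])
  ape::read.tree(text = nwk)
}

# leaf bipartitions of the internal edges, canonicalized as the sorted
# label set on the side not containing the reference (first) label
tree_bipartitions <- function(tree) {
  ref <- sort(tree$tip.label)[1]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  splits <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) next
    tips <- ape::extract.clade(tree, child)$tip.label
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    splits <- c(splits, paste(sort(side), collapse = "\r"))
  }
  unique(splits)
}

#' Bootstrap support for a p-distance NJ tree
#'
#' Resamples SNP columns with replacement, recomputes the p-distance matrix
#' and NJ tree for each replicate, and scores every internal edge of the
#' full-data tree by the percentage of replicates containing the same leaf
#' bipartition (branch lengths ignored). Seeded and reproducible.
#'
#' @param gm a [genotype_matrix()] with at least 4 samples.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed optional integer seed for the resampling.
#' @return the full-data `"phylo"` tree with `node.label` holding integer
#'   percentage supports (root label empty).
#' @export
bootstrap_support <- function(gm, B = 1000L, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$samples) < 4L) stop("need at least 4 samples")
  B <- as.integer(B)
  if (B < 1L) stop("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  main <- nj_tree(p_distance_matrix(gm))
  splits <- tree_bipartitions(main)
  hits <- stats::setNames(integer(length(splits)), splits)
  n_sites <- nrow(gm$sites)
  for (b in seq_len(B)) {
    idx <- sample.int(n_sites, n_sites, replace = TRUE)
    bt <- nj_tree(p_distance_matrix(subset_sites(gm, idx)))
    bs <- tree_bipartitions(bt)
    found <- splits %in% bs
    hits[found] <- hits[found] + 1L
  }
  support <- round(100 * hits / B)
  # map supports onto node labels of the main tree
  n_tip <- length(main$tip.label)
  ref <- sort(main$tip.label)[1]
  lab <- rep("", main$Nnode)
  for (e in seq_len(nrow(main$edge))) {
    child <- main$edge[e, 2]
    if (child <= n_tip) next
    tips <- ape::extract.clade(main, child)$tip.label
    side <- if (ref %in% tips) setdiff(main$tip.label, tips) else tips
    key <- paste(sort(side), collapse = "\r")
    if (key %in% splits) lab[child - n_tip] <- as.character(support[[key]])
  }
  main$node.label <- lab
  main
}

#' Write a tree as Newick
#'
#' @param tree a `"phylo"` object (node labels, e.g. bootstrap supports,
#'   are written on internal nodes).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
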