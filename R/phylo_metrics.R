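#' Cophenetic (patristic) distances between tree tips
#'
#' Sum of branch lengths on the path between each pair of tips.
#'
#' @param tree an [ape::phylo] tree with at least two tips.
#' @return symmetric numeric matrix with zero diagonal, labelled by tip.
#' @export
cophenetic_dist <- function(tree) {
  .assert(inherits(tree, "phylo"), "tree must be a phylo object")
  .assert(length(tree$tip.label) >= 2, "tree needs at least 2 tips")
  stats::cophenetic(tree)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`, in `[0, 1]` for non-negative input.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(all(x >= 0) && all(y >= 0), "abundances must be non-negative")
  tot <- sum(x) + sum(y)
  .assert(tot > 0, "both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For communities X and Y with relative abundances `fx`, `fy` and
#' tip-to-tip phylogenetic distances `d`, computes
#' \deqn{\beta MNTD = \frac{1}{2}\Big[\sum_{i \in X} f_{x i}\,
#'   \min_{j \in Y} d(i,j) + \sum_{j \in Y} f_{y j}
#'   \min_{i \in X} d(j,i)\Big]}
#' where the nearest taxon is searched among taxa present (abundance > 0)
#' in the opposite community; a shared taxon matches itself at distance 0.
#'
#' @param fx,fy named numeric vectors of (relative) abundances; names must
#'   appear among the row labels of `d`. They are normalized to sum to 1
#'   over their positive entries.
#' @param d symmetric cophenetic distance matrix (see [cophenetic_dist]).
#' @return non-negative phylogenetic turnover; 0 for identical communities.
#' @export
beta_mntd <- function(fx, fy, d) {
  prep <- function(f) {
    .assert(!is.null(names(f)), "abundance vectors must be named by taxon")
    f <- f[f > 0]
    .assert(length(f) > 0, "community has no taxa with positive abundance")
    .assert(all(names(f) %in% rownames(d)),
            "taxa missing from the distance matrix")
    f / sum(f)
  }
  fx <- prep(fx)
  fy <- prep(fy)
  ix <- match(names(fx), rownames(d))
  iy <- match(names(fy), rownames(d))
  cpp_bmntd(d, ix - 1L, iy - 1L, unname(fx), unname(fy))
}

# edge-by-tip branch incidence for weighted UniFrac: sparse matrix E with
# E[e, t] = 1 if tip t descends from edge e, plus edge lengths
branch_tip_matrix <- function(tree) {
  nt <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  tips_below <- vector("list", nt + tree$Nnode)
  for (t in seq_len(nt)) tips_below[[t]] <- t
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]
    chi <- edge[e, 2]
    tips_below[[par]] <- c(tips_below[[par]], tips_below[[chi]])
  }
  idx_i <- rep.int(seq_len(nrow(edge)),
                   vapply(edge[, 2], function(n) length(tips_below[[n]]), 1L))
  idx_j <- unlist(tips_below[edge[, 2]])
  mat <- Matrix::sparseMatrix(i = idx_i, j = idx_j, x = 1,
                              dims = c(nrow(edge), nt))
  colnames(mat) <- tree$tip.label
  list(incidence = mat, lengths = tree$edge.length)
}

#' Weighted UniFrac dissimilarity between two samples
#'
#' With `A_b`, `B_b` the proportions of each sample's total abundance
#' descending from branch `b` (length `l_b`), the raw statistic is
#' `sum(l_b |A_b - B_b|)`; the normalized form (default) divides by
#' `sum(l_b (A_b + B_b))` and lies in `[0, 1]`. Taxa absent from the tree
#' are dropped with a warning (error when `strict = TRUE`) and abundances
#' are renormalized.
#'
#' @param x,y named non-negative abundance vectors (counts or proportions).
#' @param tree an [ape::phylo] tree containing the taxa as tips.
#' @param normalized return the normalized statistic (default TRUE).
#' @param strict error (rather than warn) on taxa missing from the tree.
#' @return dissimilarity (in `[0, 1]` when normalized).
#' @export
weighted_unifrac <- function(x, y, tree, normalized = TRUE, strict = FALSE) {
  .assert(!is.null(names(x)) && !is.null(names(y)),
          "abundance vectors must be named by taxon")
  taxa <- union(names(x), names(y))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    msg <- sprintf("%d taxa absent from the tree were dropped", length(missing))
    if (strict) stop(msg, call. = FALSE) else warning(msg)
    x <- x[names(x) %in% tree$tip.label]
    y <- y[names(y) %in% tree$tip.label]
  }
  .assert(sum(x) > 0 && sum(y) > 0, "each sample needs positive total abundance")
  bt <- branch_tip_matrix(tree)
  px <- py <- numeric(length(tree$tip.label))
  names(px) <- names(py) <- tree$tip.label
  px[names(x)] <- x / sum(x)
  py[names(y)] <- y / sum(y)
  a <- as.numeric(bt$incidence %*% px)
  b <- as.numeric(bt$incidence %*% py)
  raw <- sum(bt$lengths * abs(a - b))
  if (!normalized) return(raw)
  denom <- sum(bt$lengths * (a + b))
  if (denom == 0) return(0)
  raw / denom
}

#' Serialize a distance matrix as square TSV
#'
#' @param d symmetric labelled matrix.
#' @param path output file.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(as.matrix(d), path, sep = "\t", quote = FALSE,
                     col.names = NA)
}
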