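#' Ensemble association scores for one OTU pair
#'
#' Four measures over the samples: Pearson and Spearman correlation of the
#' raw count vectors, and Bray-Curtis plus symmetrized Kullback-Leibler
#' dissimilarity of the two OTUs' per-sample relative-abundance profiles
#' (each vector normalized to sum to 1 across samples). KL profiles get a
#' pseudocount of `1e-6` after normalization (then renormalized) so the
#' divergence is finite on disjoint supports.
#'
#' @param x,y non-negative abundance vectors over the same samples
#'   (length >= 5, not constant).
#' @param pseudocount added to KL profiles (default 1e-6).
#' @return named numeric vector: `pearson`, `spearman`, `bray_curtis`,
#'   `kullback_leibler`.
#' @export
association_scores <- function(x, y, pseudocount = 1e-6) {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(length(x) >= 5, "need at least 5 samples")
  .assert(all(x >= 0) && all(y >= 0), "abundances must be non-negative")
  .assert(stats::sd(x) > 0 && stats::sd(y) > 0, "constant vector")
  px <- x / sum(x)
  py <- y / sum(y)
  qx <- px + pseudocount
  qx <- qx / sum(qx)
  qy <- py + pseudocount
  qy <- qy / sum(qy)
  c(pearson = stats::cor(x, y),
    spearman = stats::cor(x, y, method = "spearman"),
    bray_curtis = sum(abs(px - py)) / 2,
    kullback_leibler = sum((qx - qy) * (log(qx) - log(qy))))
}

# vectorized null scores for one pair under B permutations of y
# perm_idx: B x n matrix of sample indices
.null_scores <- function(x, y, perm_idx, pseudocount = 1e-6) {
  n <- length(x)
  B <- nrow(perm_idx)
  yp <- matrix(y[perm_idx], B, n)
  xc <- x - mean(x)
  pear <- as.numeric(yp %*% xc) / ((n - 1) * stats::sd(x) * stats::sd(y))
  rx <- rank(x)
  ry <- rank(y)
  ryp <- matrix(ry[perm_idx], B, n)
  rxc <- rx - mean(rx)
  spear <- as.numeric(ryp %*% rxc) /
    ((n - 1) * stats::sd(rx) * stats::sd(ry))
  px <- x / sum(x)
  py <- y / sum(y)
  pyp <- matrix(py[perm_idx], B, n)
  bc <- rowSums(abs(sweep(pyp, 2, px))) / 2
  qx <- px + pseudocount
  qx <- qx / sum(qx)
  qy <- py + pseudocount
  qy <- qy / sum(qy)
  qyp <- matrix(qy[perm_idx], B, n)
  lqx <- log(qx)
  lqyp <- log(qyp)
  kl <- sum(qx * lqx) + rowSums(qyp * lqyp) -
    as.numeric(lqyp %*% qx) - as.numeric(qyp %*% lqx)
  cbind(pearson = pear, spearman = spear, bray_curtis = bc,
        kullback_leibler = kl)
}

# empirical p-value of each null draw within its own null distribution,
# on the same tail convention used for the observed statistic; the
# -2 log p transforms feed the Brown covariance estimate
.null_p_transform <- function(null_scores) {
  B <- nrow(null_scores)
  t_mat <- matrix(0, B, 4, dimnames = list(NULL, colnames(null_scores)))
  for (m in c("pearson", "spearman")) {
    a <- abs(null_scores[, m])
    p <- (B + 1 - rank(a, ties.method = "average")) / B
    t_mat[, m] <- -2 * log(pmax(p, 1 / (B + 1)))
  }
  for (m in c("bray_curtis", "kullback_leibler")) {
    p <- rank(null_scores[, m], ties.method = "average") / B
    t_mat[, m] <- -2 * log(pmax(p, 1 / (B + 1)))
  }
  t_mat
}

#' Permutation p-values for OTU-pair association measures
#'
#' The null permutes one OTU's abundance vector across samples (one shared
#' set of `B` permutations for all measures, so between-measure dependence
#' is preserved). Correlations use two-sided p-values
#' `(#{|null| >= |obs|} + 1) / (B + 1)`; dissimilarities use the left tail
#' (low dissimilarity = association). The correlation matrix of the null
#' `-2 log p` transforms is returned per pair for Brown's method.
#'
#' @param table a [community_table].
#' @param pairs 2-column matrix/data.frame of taxon ids (default: all
#'   pairs).
#' @param B number of permutations (>= 100, default 1000).
#' @param seed integer seed.
#' @return list with one element per pair: `taxa`, `obs` (4 scores), `p`
#'   (4 p-values) and `rho` (4 x 4 correlation of null transforms).
#' @export
permutation_pvalues <- function(table, pairs = NULL, B = 1000, seed = NULL) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  .assert(B >= 100, "B must be >= 100")
  counts <- table$counts
  n <- ncol(counts)
  .assert(n >= 5, "need at least 5 samples")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(rownames(counts), 2))
  }
  pairs <- as.matrix(pairs)
  perm_idx <- .with_seed(seed, {
    t(replicate(B, sample.int(n)))
  })
  lapply(seq_len(nrow(pairs)), function(k) {
    x <- counts[pairs[k, 1], ]
    y <- counts[pairs[k, 2], ]
    obs <- association_scores(x, y)
    nulls <- .null_scores(x, y, perm_idx)
    p <- c(
      pearson = (sum(abs(nulls[, "pearson"]) >= abs(obs[["pearson"]])) + 1) / (B + 1),
      spearman = (sum(abs(nulls[, "spearman"]) >= abs(obs[["spearman"]])) + 1) / (B + 1),
      bray_curtis = (sum(nulls[, "bray_curtis"] <= obs[["bray_curtis"]]) + 1) / (B + 1),
      kullback_leibler = (sum(nulls[, "kullback_leibler"] <= obs[["kullback_leibler"]]) + 1) / (B + 1))
    t_mat <- .null_p_transform(nulls)
    rho <- suppressWarnings(stats::cor(t_mat))
    rho[!is.finite(rho)] <- 0
    diag(rho) <- 1
    list(taxa = pairs[k, ], obs = obs, p = p, rho = rho)
  })
}

#' Combine dependent p-values with Brown's method
#'
#' Fisher's statistic `X = -2 sum(log p)` has mean `2k` under the null; to
#' account for dependence its variance is inflated using the
#' Kost-McDermott polynomial approximation of the covariance between
#' `-2 log p_i` terms, `cov = 3.263 rho + 0.710 rho^2 + 0.027 rho^3`. The
#' merged p-value is the upper tail of a scaled chi-square: with
#' `c = Var / (2 E)` and `f = 2 E^2 / Var`, `p = P(chi^2_f > X / c)`. With
#' `rho = 0` this reduces exactly to Fisher's method; with all `rho = 1`
#' and identical inputs it returns the common p-value.
#'
#' @param p_values numeric vector of k >= 2 p-values in (0, 1].
#' @param rho k x k correlation matrix of the `-2 log p` transforms.
#' @return merged p-value.
#' @export
brown_merge <- function(p_values, rho) {
  k <- length(p_values)
  .assert(k >= 2, "need at least 2 p-values")
  .assert(all(p_values > 0 & p_values <= 1), "p-values must lie in (0, 1]")
  rho <- as.matrix(rho)
  .assert(all(dim(rho) == k), "rho must be %d x %d", k, k)
  .assert(max(abs(rho - t(rho))) < 1e-8, "rho must be symmetric")
  .assert(max(abs(diag(rho) - 1)) < 1e-8, "rho must have unit diagonal")
  x <- -2 * sum(log(p_values))
  e <- 2 * k
  r <- rho[upper.tri(rho)]
  cov_sum <- sum(3.263 * r + 0.710 * r^2 + 0.027 * r^3)
  v <- 4 * k + 2 * cov_sum
  c_scale <- v / (2 * e)
  f <- 2 * e^2 / v
  stats::pchisq(x / c_scale, df = f, lower.tail = FALSE)
}

#' Build an ensemble co-occurrence network
#'
#' Scores every OTU pair of a (prevalence-filtered) table with the four
#' association measures, merges the four permutation p-values with
#' [brown_merge], applies Benjamini-Hochberg correction across all
#' candidate pairs, and retains edges with `|pearson| > r_cut` AND
#' `|spearman| > r_cut` AND BH-adjusted merged p < `p_cut`. Edge sign is
#' the sign of the Pearson coefficient (Spearman breaks exact-zero ties).
#' Constant-vector taxa are excluded with a warning.
#'
#' @param table a [community_table], already prevalence-filtered and
#'   subset to the group's samples.
#' @param r_cut correlation threshold (default 0.6).
#' @param p_cut threshold on the BH-adjusted merged p-value (default
#'   0.01).
#' @param B permutations per pair (default 1000).
#' @param seed integer seed.
#' @param taxonomy optional named phylum labels for the nodes (default:
#'   the table's taxonomy).
#' @return object of class `cooccurrence_network`: list with `graph`
#'   (igraph, all taxa as vertices, retained edges with `weight` =
#'   Pearson r and `sign`), `edges` (per candidate pair: scores,
#'   p-values, brown_p, bh_q, retained, sign) and `params`.
#' @export
build_network <- function(table, r_cut = 0.6, p_cut = 0.01, B = 1000,
                          seed = NULL, taxonomy = NULL) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  .assert(ncol(table$counts) >= 5, "need at least 5 samples")
  taxonomy <- taxonomy %||% table$taxonomy
  counts <- table$counts
  keep <- apply(counts, 1, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning(sprintf("%d constant taxa excluded from the network", sum(!keep)))
    counts <- counts[keep, , drop = FALSE]
  }
  .assert(nrow(counts) >= 2, "fewer than 2 variable taxa")
  sub <- community_table(counts, taxonomy = taxonomy[rownames(counts)])
  res <- permutation_pvalues(sub, B = B, seed = seed)
  edges <- do.call(rbind, lapply(res, function(r) {
    data.frame(otu_a = r$taxa[1], otu_b = r$taxa[2],
               pearson = r$obs[["pearson"]], spearman = r$obs[["spearman"]],
               bray_curtis = r$obs[["bray_curtis"]],
               kullback_leibler = r$obs[["kullback_leibler"]],
               p_pearson = r$p[["pearson"]], p_spearman = r$p[["spearman"]],
               p_bray_curtis = r$p[["bray_curtis"]],
               p_kullback_leibler = r$p[["kullback_leibler"]],
               brown_p = brown_merge(r$p, r$rho),
               stringsAsFactors = FALSE)
  }))
  edges$bh_q <- stats::p.adjust(edges$brown_p, method = "BH")
  edges$retained <- abs(edges$pearson) > r_cut &
    abs(edges$spearman) > r_cut & edges$bh_q < p_cut
  edges$sign <- ifelse(edges$pearson > 0, "+",
                ifelse(edges$pearson < 0, "-",
                ifelse(edges$spearman >= 0, "+", "-")))
  if (!any(edges$retained)) message("no edges retained: empty network")
  g <- igraph::graph_from_data_frame(
    edges[edges$retained, c("otu_a", "otu_b", "pearson", "sign")],
    directed = FALSE,
    vertices = data.frame(name = rownames(counts),
                          phylum = if (is.null(taxonomy)) NA_character_
                                   else unname(taxonomy[rownames(counts)]),
                          stringsAsFactors = FALSE))
  igraph::E(g)$weight <- igraph::E(g)$pearson
  structure(list(graph = g, edges = edges,
                 params = list(r_cut = r_cut, p_cut = p_cut, B = B,
                               seed = seed, n_samples = ncol(counts))),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges retained of %d candidate pairs\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              nrow(x$edges)))
  invisible(x)
}

#' Topological properties of a co-occurrence network
#'
#' Density `2E / (n (n - 1))`, average degree `2E / n`, mean local
#' clustering coefficient (nodes with degree < 2 contribute 0), average
#' path length and diameter on the largest connected component, greedy
#' modularity, and PNC, the percentage of negative edges. An empty network
#' yields `NA` metrics rather than an error.
#'
#' @param net a `cooccurrence_network` (or bare igraph with a `sign` edge
#'   attribute).
#' @return named list of metrics.
#' @export
network_topology <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (e == 0) {
    return(list(n_nodes = n, n_edges = 0, density = if (n > 1) 0 else NA_real_,
                average_degree = 0, clustering = NA_real_,
                average_path_length = NA_real_, diameter = NA_real_,
                modularity = NA_real_, pnc = NA_real_))
  }
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))
  comm <- igraph::cluster_fast_greedy(
    g, weights = abs(igraph::E(g)$weight))
  signs <- igraph::E(g)$sign
  list(n_nodes = n, n_edges = e,
       density = 2 * e / (n * (n - 1)),
       average_degree = 2 * e / n,
       clustering = mean(local_cc),
       average_path_length = igraph::mean_distance(giant, weights = NA),
       diameter = igraph::diameter(giant, weights = NA),
       modularity = igraph::modularity(comm),
       pnc = 100 * sum(signs == "-") / e)
}

#' Observed-over-random (O/R) intra- and inter-phylum association
#'
#' For each unordered phylum pair, `O%` is the percentage of network edges
#' joining nodes of those phyla; `R%` is the percentage expected when
#' edges are thrown uniformly at random over node pairs (exact,
#' without-replacement counting): for a single phylum A with `n_A` of `n`
#' nodes, `R = 100 n_A (n_A - 1) / (n (n - 1))`; for distinct A, B,
#' `R = 100 * 2 n_A n_B / (n (n - 1))`. The with-replacement product of
#' phylum frequencies is also reported (`r_wr`). O/R > 1 suggests
#' deterministic association, O/R < 1 stochastic.
#'
#' @param net a `cooccurrence_network`.
#' @param labels optional named phylum labels (default: the graph's
#'   `phylum` vertex attribute).
#' @return data.frame per phylum pair: phylum_a, phylum_b, n_a, n_b, eo,
#'   o_pct, r_pct, r_wr, ratio. `o_pct` and `r_pct` each sum to 100.
#' @export
or_ratio <- function(net, labels = NULL) {
  .assert(inherits(net, "cooccurrence_network"),
          "net must be a cooccurrence_network")
  g <- net$graph
  .assert(igraph::ecount(g) >= 1, "network has no edges")
  if (is.null(labels)) {
    labels <- stats::setNames(igraph::V(g)$phylum, igraph::V(g)$name)
  }
  .assert(!anyNA(labels[igraph::V(g)$name]), "every node needs a phylum label")
  labels <- labels[igraph::V(g)$name]
  phyla <- sort(unique(labels))
  n_per <- table(labels)[phyla]
  n <- length(labels)
  ends <- igraph::as_edgelist(g)
  edge_lab <- cbind(labels[ends[, 1]], labels[ends[, 2]])
  edge_key <- paste(pmin(edge_lab[, 1], edge_lab[, 2]),
                    pmax(edge_lab[, 1], edge_lab[, 2]), sep = "\r")
  e_total <- nrow(ends)
  combos <- expand.grid(a = seq_along(phyla), b = seq_along(phyla))
  combos <- combos[combos$a <= combos$b, ]
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    pa <- phyla[combos$a[i]]
    pb <- phyla[combos$b[i]]
    na <- as.numeric(n_per[[pa]])
    nb <- as.numeric(n_per[[pb]])
    eo <- sum(edge_key == paste(pa, pb, sep = "\r"))
    if (pa == pb) {
      r <- 100 * na * (na - 1) / (n * (n - 1))
      r_wr <- 100 * (na / n)^2
    } else {
      r <- 100 * 2 * na * nb / (n * (n - 1))
      r_wr <- 100 * 2 * (na / n) * (nb / n)
    }
    data.frame(phylum_a = pa, phylum_b = pb, n_a = na, n_b = nb, eo = eo,
               o_pct = 100 * eo / e_total, r_pct = r, r_wr = r_wr,
               ratio = if (r > 0) (100 * eo / e_total) / r else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export a co-occurrence network to GraphML
#'
#' @param net a `cooccurrence_network`.
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  .assert(inherits(net, "cooccurrence_network"),
          "net must be a cooccurrence_network")
  igraph::write_graph(net$graph, path, format = "graphml")
}
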