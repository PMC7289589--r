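#' @title Null models for community assembly inference
#' @description
#' The workhorse of the package: z-scores of phylogenetic turnover
#' (betaNTI) against a taxa-shuffle null, the Raup-Crick metric on
#' Bray-Curtis (RC-bray) against a probabilistic assembly null, the
#' five-way classification of ecological processes, and abundance-based
#' beta-null deviations.
#' @name assembly_null
NULL

# pool context shared by the null models: taxa with positive total counts
# across the pool samples (optionally intersected with the tree tips),
# their cophenetic distances, metacommunity relative abundances and
# occupancy frequencies
.pool_context <- function(table, tree = NULL, pool_samples = NULL) {
  pool_samples <- pool_samples %||% sample_ids(table)
  counts <- table$counts[, pool_samples, drop = FALSE]
  taxa <- rownames(counts)[rowSums(counts) > 0]
  d <- NULL
  if (!is.null(tree)) {
    missing <- setdiff(taxa, tree$tip.label)
    if (length(missing)) {
      warning(sprintf(
        "%d taxa absent from the tree dropped from phylogenetic nulls",
        length(missing)))
      taxa <- intersect(taxa, tree$tip.label)
    }
    .assert(length(taxa) >= 2, "fewer than 2 pool taxa on the tree")
    d <- cophenetic_dist(ape::keep.tip(tree, taxa))
    d <- d[taxa, taxa]
  }
  sub <- counts[taxa, , drop = FALSE]
  list(taxa = taxa, d = d,
       meta_p = rowSums(sub) / sum(sub),
       occupancy = rowMeans(sub > 0))
}

.bnti_engine <- function(counts, ctx, a, b, reps, seed) {
  xa <- counts[ctx$taxa, a]
  xb <- counts[ctx$taxa, b]
  ix <- which(xa > 0)
  iy <- which(xb > 0)
  .assert(length(ix) > 0 && length(iy) > 0,
          "community with zero taxa after reconciliation with the tree")
  wx <- xa[ix] / sum(xa[ix])
  wy <- xb[iy] / sum(xb[iy])
  obs <- cpp_bmntd(ctx$d, ix - 1L, iy - 1L, unname(wx), unname(wy))
  p <- length(ctx$taxa)
  null <- .with_seed(seed, {
    perms <- matrix(0L, nrow = reps, ncol = p)
    for (r in seq_len(reps)) perms[r, ] <- sample.int(p) - 1L
    cpp_bmntd_null(ctx$d, ix - 1L, iy - 1L, unname(wx), unname(wy), perms)
  })
  sd_null <- stats::sd(null)
  if (sd_null == 0) stop("degenerate null: zero variance in betaMNTD draws",
                         call. = FALSE)
  list(beta_mntd_obs = obs,
       null = list(reps = reps, values = null,
                   mean = mean(null), sd = sd_null),
       bnti = (obs - mean(null)) / sd_null)
}

.rc_engine <- function(counts, ctx, a, b, reps, seed) {
  xa <- counts[ctx$taxa, a]
  xb <- counts[ctx$taxa, b]
  .assert(sum(xa) > 0 && sum(xb) > 0, "empty community")
  obs <- bray_curtis(xa, xb)
  null <- .with_seed(seed, {
    cpp_rc_null(unname(ctx$meta_p), unname(ctx$occupancy),
                sum(xa > 0), sum(xa), sum(xb > 0), sum(xb), reps)
  })
  eps <- 1e-12
  below <- sum(null < obs - eps)
  ties <- sum(abs(null - obs) <= eps)
  rc <- 2 * ((below + 0.5 * ties) / reps - 0.5)
  list(bc_obs = obs,
       null = list(reps = reps, values = null,
                   mean = mean(null), sd = stats::sd(null)),
       rc_bray = rc)
}

#' betaNTI for one pair of communities
#'
#' Computes the observed abundance-weighted betaMNTD between two samples,
#' a null distribution obtained by shuffling taxon labels across all tips
#' of the metacommunity species pool (the picante "taxa.labels"
#' convention), and the standardized score
#' `betaNTI = (obs - mean(null)) / sd(null)`. Values above +2 indicate
#' variable selection, below -2 homogeneous selection.
#'
#' @param table a [community_table].
#' @param tree an [ape::phylo] tree covering the taxa.
#' @param x,y sample ids.
#' @param reps null replicates (>= 100; default 999).
#' @param seed integer seed (NULL = current RNG state).
#' @param pool_samples sample ids defining the species pool (default: all
#'   samples in `table`; pass the group's samples for a per-group pool).
#' @return list with `beta_mntd_obs`, `null` (reps, values, mean, sd) and
#'   `bnti`.
#' @export
bnti_pair <- function(table, tree, x, y, reps = 999, seed = NULL,
                      pool_samples = NULL) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  .assert(all(c(x, y) %in% sample_ids(table)), "sample not found in table")
  .assert(reps >= 100, "reps must be >= 100 for inferential use")
  ctx <- .pool_context(table, tree, pool_samples)
  .bnti_engine(table$counts, ctx, x, y, reps, seed)
}

#' RC-bray for one pair of communities
#'
#' Null draws assemble both communities probabilistically while preserving
#' each community's observed richness and total individual count: taxa are
#' included with probability proportional to their metacommunity occupancy
#' frequency, each included taxon receives one individual, and the
#' remaining individuals are assigned with probability proportional to
#' metacommunity relative abundance (the Stegen-style null). The observed
#' Bray-Curtis value is ranked within the null (ties weighted 0.5) and
#' rescaled to `[-1, 1]`: values > 0.95 indicate dispersal limitation,
#' values < -0.95 homogenizing dispersal (given |betaNTI| <= 2).
#'
#' @inheritParams bnti_pair
#' @return list with `bc_obs`, `null` (reps, values, mean, sd) and
#'   `rc_bray`.
#' @export
rc_bray_pair <- function(table, x, y, reps = 999, seed = NULL,
                         pool_samples = NULL) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  .assert(all(c(x, y) %in% sample_ids(table)), "sample not found in table")
  .assert(reps >= 100, "reps must be >= 100 for inferential use")
  ctx <- .pool_context(table, tree = NULL, pool_samples = pool_samples)
  .assert(length(ctx$taxa) >= 2, "metacommunity with a single taxon")
  .rc_engine(table$counts, ctx, x, y, reps, seed)
}

#' Classify ecological assembly processes from betaNTI and RC-bray
#'
#' Deterministic processes: betaNTI > `bnti_cut` is variable selection,
#' betaNTI < -`bnti_cut` is homogeneous selection. Within |betaNTI| <=
#' `bnti_cut`, RC-bray > `rc_cut` is dispersal limitation, RC-bray <
#' -`rc_cut` is homogenizing dispersal, and |RC-bray| <= `rc_cut` is
#' undominated. Every finite (betaNTI, RC-bray) pair receives exactly one
#' category.
#'
#' @param bnti numeric vector of betaNTI scores.
#' @param rc_bray numeric vector in `[-1, 1]`, recycled against `bnti`.
#' @param bnti_cut selection threshold (default 2).
#' @param rc_cut dispersal threshold (default 0.95).
#' @return factor with levels `variable_selection`, `homogeneous_selection`,
#'   `homogenizing_dispersal`, `dispersal_limitation`, `undominated`.
#' @export
classify_processes <- function(bnti, rc_bray, bnti_cut = 2, rc_cut = 0.95) {
  .assert(all(is.finite(bnti)) && all(is.finite(rc_bray)),
          "betaNTI and RC-bray must be finite")
  n <- max(length(bnti), length(rc_bray))
  bnti <- rep_len(bnti, n)
  rc_bray <- rep_len(rc_bray, n)
  .assert(all(rc_bray >= -1 - 1e-9 & rc_bray <= 1 + 1e-9),
          "rc_bray must lie in [-1, 1]")
  out <- ifelse(bnti > bnti_cut, "variable_selection",
         ifelse(bnti < -bnti_cut, "homogeneous_selection",
         ifelse(rc_bray > rc_cut, "dispersal_limitation",
         ifelse(rc_bray < -rc_cut, "homogenizing_dispersal",
                "undominated"))))
  factor(out, levels = process_levels())
}

#' @rdname classify_processes
#' @export
process_levels <- function() {
  c("variable_selection", "homogeneous_selection", "homogenizing_dispersal",
    "dispersal_limitation", "undominated")
}

#' Assembly-process profile over sample groups
#'
#' Scores every within-group pair of samples with betaNTI and RC-bray and
#' tallies the fraction of pairs assigned to each of the five ecological
#' processes. Per-pair random streams are derived from `seed` and the
#' sample ids, so results do not depend on the order in which pairs are
#' evaluated.
#'
#' @inheritParams bnti_pair
#' @param groups grouping of samples: a factor/character vector either
#'   named by sample id or aligned with `sample_ids(table)`.
#' @param pool `"metacommunity"` (one species pool across all samples,
#'   default) or `"group"` (pool restricted to each group's samples).
#' @param bnti_cut,rc_cut classification thresholds (see
#'   [classify_processes]).
#' @return object of class `assembly_profile`: list with `pairs` (one row
#'   per pair: sample_a, sample_b, group, beta_mntd, bnti, bc_obs,
#'   rc_bray, process), `fractions` (per group x process, summing to 1 per
#'   group) and `params`.
#' @export
assembly_profile <- function(table, tree, groups, reps = 999, seed = 1,
                             pool = c("metacommunity", "group"),
                             bnti_cut = 2, rc_cut = 0.95) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  pool <- match.arg(pool)
  ids <- sample_ids(table)
  if (is.null(names(groups))) {
    .assert(length(groups) == length(ids),
            "groups must be named by sample id or aligned with the table")
    groups <- stats::setNames(as.character(groups), ids)
  } else {
    .assert(all(ids %in% names(groups)), "groups missing some samples")
    groups <- stats::setNames(as.character(groups[ids]), ids)
  }
  group_names <- unique(groups)
  ctx_all <- if (pool == "metacommunity") .pool_context(table, tree) else NULL
  rows <- list()
  for (g in group_names) {
    members <- ids[groups == g]
    if (length(members) < 2) {
      warning(sprintf("group '%s' has a single sample; skipped", g))
      next
    }
    ctx <- ctx_all %||% .pool_context(table, tree, pool_samples = members)
    prs <- utils::combn(members, 2)
    for (k in seq_len(ncol(prs))) {
      # canonical pair orientation so per-pair seeds (and hence results)
      # do not depend on sample ordering
      a <- min(prs[, k])
      b <- max(prs[, k])
      bn <- .bnti_engine(table$counts, ctx, a, b, reps,
                         .derive_seed(seed, c("bnti", a, b)))
      rc <- .rc_engine(table$counts, ctx, a, b, reps,
                       .derive_seed(seed, c("rc", a, b)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_a = a, sample_b = b, group = g,
        beta_mntd = bn$beta_mntd_obs, bnti = bn$bnti,
        bc_obs = rc$bc_obs, rc_bray = rc$rc_bray,
        stringsAsFactors = FALSE)
    }
  }
  .assert(length(rows) > 0, "no group with >= 2 samples")
  pairs <- do.call(rbind, rows)
  pairs$process <- classify_processes(pairs$bnti, pairs$rc_bray,
                                      bnti_cut, rc_cut)
  tab <- table(pairs$group, pairs$process)
  fractions <- as.data.frame.matrix(sweep(tab, 1, rowSums(tab), "/"))
  fractions <- cbind(group = rownames(fractions), fractions,
                     stringsAsFactors = FALSE)
  rownames(fractions) <- NULL
  structure(list(pairs = pairs, fractions = fractions,
                 params = list(reps = reps, seed = seed, pool = pool,
                               bnti_cut = bnti_cut, rc_cut = rc_cut)),
            class = "assembly_profile")
}

#' @export
print.assembly_profile <- function(x, ...) {
  cat(sprintf("assembly_profile: %d pairs in %d group(s), %d null reps (pool: %s)\n",
              nrow(x$pairs), length(unique(x$pairs$group)),
              x$params$reps, x$params$pool))
  print(x$fractions, digits = 3)
  invisible(x)
}

#' Assembly-process profile for one phylum
#'
#' Subsets the community table to the taxa of one phylum (relative
#' abundances are renormalized within the subset), prunes the tree to the
#' matching tips and runs [assembly_profile] on the subset. Phyla with few
#' taxa give unstable null standard deviations, hence the `min_taxa`
#' floor.
#'
#' @inheritParams assembly_profile
#' @param phylum phylum/class label to keep.
#' @param taxonomy named character vector of labels per taxon (default:
#'   the table's own taxonomy).
#' @param min_taxa minimum metacommunity taxa for the phylum (default 20).
#' @return an `assembly_profile` for the phylum subset.
#' @export
per_phylum_assembly <- function(table, tree, phylum, groups, reps = 999,
                                seed = 1, taxonomy = NULL, min_taxa = 20,
                                pool = c("metacommunity", "group"),
                                bnti_cut = 2, rc_cut = 0.95) {
  taxonomy <- taxonomy %||% table$taxonomy
  .assert(!is.null(taxonomy), "no taxonomy available")
  keep <- names(taxonomy)[!is.na(taxonomy) & taxonomy == phylum]
  keep <- intersect(keep, taxon_ids(table))
  if (length(keep) < min_taxa) {
    stop(sprintf(
      "phylum '%s' has %d taxa, fewer than min_taxa = %d; lower min_taxa only if you accept unstable nulls",
      phylum, length(keep), min_taxa), call. = FALSE)
  }
  sub <- subset_table(table, taxa = keep)
  nonzero <- colSums(sub$counts) > 0
  if (!all(nonzero)) {
    warning(sprintf("%d sample(s) with no '%s' reads dropped",
                    sum(!nonzero), phylum))
    sub <- subset_table(sub, samples = which(nonzero))
  }
  subtree <- ape::keep.tip(tree, intersect(keep, tree$tip.label))
  assembly_profile(sub, subtree, groups = groups[sample_ids(sub)],
                   reps = reps, seed = seed, pool = match.arg(pool),
                   bnti_cut = bnti_cut, rc_cut = rc_cut)
}

# pairwise normalized weighted UniFrac from a tips x samples matrix of
# relative abundances, given a precomputed branch incidence
.pairwise_wunifrac <- function(p_mat, bt) {
  b <- as.matrix(bt$incidence %*% p_mat)
  l <- bt$lengths
  n <- ncol(p_mat)
  d <- matrix(0, n, n, dimnames = list(colnames(p_mat), colnames(p_mat)))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      den <- sum(l * (b[, i] + b[, j]))
      d[i, j] <- d[j, i] <-
        if (den > 0) sum(l * abs(b[, i] - b[, j])) / den else 0
    }
  }
  d
}

.pairwise_bray <- function(counts) {
  as.matrix(vegan::vegdist(t(counts), method = "bray"))
}

#' Abundance-based beta-null deviations
#'
#' For every pair of samples, the observed beta-diversity (Bray-Curtis or
#' normalized weighted UniFrac) is compared with the mean beta-diversity
#' of randomly assembled communities: in each of `reps` null draws every
#' sample is rebuilt by drawing its observed number of individuals from
#' the metacommunity relative-abundance distribution (richness free to
#' vary). The deviation `observed - mean(null)` is near 0 under stochastic
#' assembly and approaches +/-1 under strong determinism.
#'
#' @inheritParams bnti_pair
#' @param metric `"bray_curtis"` or `"weighted_unifrac"` (the latter
#'   requires `tree`).
#' @return data.frame with one row per pair: sample_a, sample_b, metric,
#'   observed, null_mean, deviation.
#' @export
beta_null_deviation <- function(table, metric = c("bray_curtis",
                                                  "weighted_unifrac"),
                                tree = NULL, reps = 999, seed = NULL) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  metric <- match.arg(metric)
  counts <- table$counts
  .assert(ncol(counts) >= 2, "need at least 2 samples")
  if (metric == "weighted_unifrac") {
    .assert(!is.null(tree), "weighted_unifrac requires a tree")
    missing <- setdiff(rownames(counts)[rowSums(counts) > 0], tree$tip.label)
    if (length(missing)) {
      warning(sprintf("%d taxa absent from the tree dropped", length(missing)))
    }
    counts <- counts[intersect(rownames(counts), tree$tip.label), , drop = FALSE]
    bt <- branch_tip_matrix(ape::keep.tip(tree, rownames(counts)))
    counts <- counts[colnames(bt$incidence), , drop = FALSE]
  }
  totals <- colSums(counts)
  .assert(all(totals > 0), "samples with zero reads after tree reconciliation")
  meta_p <- rowSums(counts) / sum(counts)
  .assert(sum(meta_p > 0) >= 2, "metacommunity with a single taxon")
  obs <- if (metric == "bray_curtis") {
    .pairwise_bray(counts)
  } else {
    .pairwise_wunifrac(sweep(counts, 2, totals, "/"), bt)
  }
  null_sum <- .with_seed(seed, {
    acc <- matrix(0, ncol(counts), ncol(counts))
    for (r in seq_len(reps)) {
      null_counts <- vapply(totals, function(n)
        as.numeric(stats::rmultinom(1, n, meta_p)), numeric(nrow(counts)))
      acc <- acc + if (metric == "bray_curtis") {
        .pairwise_bray(null_counts)
      } else {
        .pairwise_wunifrac(sweep(null_counts, 2, totals, "/"), bt)
      }
    }
    acc
  })
  null_mean <- null_sum / reps
  prs <- utils::combn(colnames(counts), 2)
  idx <- cbind(match(prs[1, ], colnames(counts)),
               match(prs[2, ], colnames(counts)))
  data.frame(sample_a = prs[1, ], sample_b = prs[2, ], metric = metric,
             observed = obs[idx], null_mean = null_mean[idx],
             deviation = obs[idx] - null_mean[idx],
             stringsAsFactors = FALSE)
}
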