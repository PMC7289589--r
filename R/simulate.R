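#' Simulation configuration for synthetic metacommunities
#'
#' Bundles the generator's parameters. The defaults describe a desk-scale
#' soil-profile survey: five depth layers of 12 samples (4 treatments x 3
#' replicates) drawn from a 300-taxon regional pool at 2000 reads per
#' sample, with environmental heterogeneity decreasing with depth and one
#' assembly regime per layer spanning the five ecological processes.
#'
#' @param n_taxa regional pool size (default 400).
#' @param n_layers number of depth layers (default 5).
#' @param samples_per_layer samples per layer (default 12).
#' @param reads_per_sample sequencing depth per sample (default 2000).
#' @param regimes character vector, one per layer, each one of
#'   `selection_variable`, `selection_homogeneous`,
#'   `homogenizing_dispersal`, `dispersal_limitation`, `neutral`.
#' @param sigma_sel width of the Gaussian niche filter on the latent
#'   environmental axis (default 0.5; smaller = stronger selection).
#' @param sigma_bm Brownian-motion rate of niche-optimum evolution along
#'   the tree (default 1; larger = stronger phylogenetic signal).
#' @param sel_drift_sigma lognormal drift sd applied to the sampling
#'   weights of the variable-selection regime (default 0 = purely
#'   deterministic filtering).
#' @param hs_inclusion,hs_drift,hs_tau homogeneous-selection regime:
#'   consistent filtering favours one mid-sized clade (6-15% of the pool,
#'   chosen deterministically from the tree); outside taxa are suppressed
#'   as `exp(-d/hs_tau)` in the patristic distance `d` to the clade, and
#'   within the clade establishment is a founder lottery (inclusion
#'   probability `hs_inclusion`, lognormal abundance sd `hs_drift`), so
#'   replicate samples turn over taxonomically among close relatives.
#' @param m_true migration rate of the neutral regime's drift-migration
#'   equilibrium (default 0.1).
#' @param dirichlet_alpha concentration of the dispersal-limitation
#'   regime's per-sample pools (default 200).
#' @param drift_sigma lognormal drift sd multiplying dispersal-limited
#'   pools (default 3); this is the dominant source of between-sample
#'   turnover in that regime, decorrelating which taxa dominate each
#'   isolated community.
#' @param lognormal_sigma sd of the log-normal regional abundance
#'   distribution (default 1.5).
#' @param env_heterogeneity per-layer spread of the environmental axis,
#'   decreasing with depth by default.
#' @param lambda birth rate of the Yule tree (default 1).
#' @param seed master seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 400,
                              n_layers = 5,
                              samples_per_layer = 12,
                              reads_per_sample = 2000,
                              regimes = c("selection_variable",
                                          "selection_homogeneous",
                                          "homogenizing_dispersal",
                                          "dispersal_limitation",
                                          "neutral"),
                              sigma_sel = 0.5,
                              sigma_bm = 1,
                              sel_drift_sigma = 0,
                              hs_inclusion = 0.4,
                              hs_drift = 0.5,
                              hs_tau = 0.3,
                              m_true = 0.1,
                              dirichlet_alpha = 200,
                              drift_sigma = 3,
                              lognormal_sigma = 1.5,
                              env_heterogeneity = NULL,
                              lambda = 1,
                              seed = 1) {
  valid <- c("selection_variable", "selection_homogeneous",
             "homogenizing_dispersal", "dispersal_limitation", "neutral")
  regimes <- rep_len(regimes, n_layers)
  .assert(all(regimes %in% valid), "invalid regime; must be one of: %s",
          paste(valid, collapse = ", "))
  .assert(n_taxa >= 4 && samples_per_layer >= 2 && reads_per_sample >= 1,
          "sizes must be positive")
  .assert(sigma_bm >= 0 && m_true > 0 && m_true <= 1 &&
            dirichlet_alpha > 0 && lognormal_sigma > 0,
          "parameters must be positive")
  env_heterogeneity <- env_heterogeneity %||%
    (2 * 0.75^(seq_len(n_layers) - 1))
  .assert(length(env_heterogeneity) == n_layers && all(env_heterogeneity > 0),
          "env_heterogeneity must be positive, one value per layer")
  structure(list(n_taxa = n_taxa, n_layers = n_layers,
                 samples_per_layer = samples_per_layer,
                 reads_per_sample = reads_per_sample, regimes = regimes,
                 sigma_sel = sigma_sel, sigma_bm = sigma_bm,
                 sel_drift_sigma = sel_drift_sigma,
                 hs_inclusion = hs_inclusion, hs_drift = hs_drift,
                 hs_tau = hs_tau,
                 m_true = m_true, dirichlet_alpha = dirichlet_alpha,
                 drift_sigma = drift_sigma,
                 lognormal_sigma = lognormal_sigma,
                 env_heterogeneity = env_heterogeneity, lambda = lambda,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Starting from two lineages, waiting times between speciations are
#' exponential with rate `lambda * k` (k = current number of lineages) and
#' a uniformly chosen lineage splits, until `n_taxa` tips exist; a final
#' exponential epoch gives the tips positive terminal branches. The
#' result is ultrametric with expected root-to-tip depth
#' `(H(n) - 1) / lambda` (harmonic number H).
#'
#' @param n_taxa number of tips (>= 4).
#' @param lambda birth rate (default 1).
#' @param seed integer seed.
#' @return an ultrametric [ape::phylo] tree with tips `otu001`, ...
#' @export
simulate_tree <- function(n_taxa, lambda = 1, seed = NULL) {
  .assert(n_taxa >= 4, "n_taxa must be >= 4")
  .with_seed(seed, {
    node_parent <- c(0L, 0L)   # temp id 0 = root, splitting at time 0
    node_start <- c(0, 0)
    node_end <- c(NA_real_, NA_real_)
    act <- c(1L, 2L)
    nxt <- 3L
    k <- 2L
    t_now <- 0
    while (k < n_taxa) {
      t_now <- t_now + stats::rexp(1, lambda * k)
      i <- sample.int(k, 1)
      id <- act[i]
      node_end[id] <- t_now
      kids <- c(nxt, nxt + 1L)
      nxt <- nxt + 2L
      node_parent[kids] <- id
      node_start[kids] <- t_now
      node_end[kids] <- NA_real_
      act[i] <- kids[1]
      act <- c(act, kids[2])
      k <- k + 1L
    }
    t_now <- t_now + stats::rexp(1, lambda * k)
    node_end[act] <- t_now
    n_tmp <- nxt - 1L
    internals <- setdiff(seq_len(n_tmp), act)
    phylo_id <- integer(n_tmp + 1L)
    phylo_id[1L] <- n_taxa + 1L                     # root
    phylo_id[act + 1L] <- seq_len(n_taxa)           # tips
    phylo_id[internals + 1L] <- n_taxa + 1L + seq_along(internals)
    edge <- cbind(phylo_id[node_parent + 1L], phylo_id[seq_len(n_tmp) + 1L])
    storage.mode(edge) <- "integer"
    tree <- structure(list(
      edge = edge,
      edge.length = node_end - node_start,
      tip.label = sprintf("otu%03d", seq_len(n_taxa)),
      Nnode = n_taxa - 1L), class = "phylo")
    # round-trip through Newick to canonicalize edge ordering
    ape::read.tree(text = ape::write.tree(tree))
  })
}

#' Evolve niche optima along a tree by Brownian motion
#'
#' Each taxon's optimum on the latent environmental axis evolves from a
#' root value of 0; closely related taxa therefore carry similar optima,
#' which is the phylogenetic signal that lets the betaNTI null model
#' detect selection. Under `model = "BM"` the rate is constant and the
#' variance of tip values is `sigma_bm^2 * depth`. Under `model = "EB"`
#' (early burst) the instantaneous rate decays as `exp(-eb_rate * t / T)`
#' with time `t` since the root, concentrating trait divergence on the
#' deep branches so that niches are conserved within clades — the pattern
#' expected when habitat preference is a deeply conserved trait. The EB
#' rates are rescaled so the mean tip variance still equals
#' `sigma_bm^2 * mean depth`, keeping the two models comparable.
#'
#' @param tree an ultrametric [ape::phylo] tree.
#' @param sigma_bm overall trait rate (per unit branch length).
#' @param seed integer seed.
#' @param model `"BM"` (default) or `"EB"`.
#' @param eb_rate decay exponent of the early-burst rate over the tree
#'   height (default 4).
#' @return named numeric vector of tip optima.
#' @export
evolve_niche <- function(tree, sigma_bm, seed = NULL,
                         model = c("BM", "EB"), eb_rate = 4) {
  .assert(inherits(tree, "phylo"), "tree must be a phylo object")
  .assert(sigma_bm >= 0, "sigma_bm must be >= 0")
  model <- match.arg(model)
  if (sigma_bm == 0) {
    return(stats::setNames(numeric(length(tree$tip.label)), tree$tip.label))
  }
  sigma <- sigma_bm
  # rTraitCont simulates on the postorder tree, so per-edge rates must be
  # computed in that edge order
  tree <- stats::reorder(tree, "postorder")
  if (model == "EB") {
    depth <- ape::node.depth.edgelength(tree)
    total <- max(depth[seq_along(tree$tip.label)])
    t_mid <- (depth[tree$edge[, 1]] + depth[tree$edge[, 2]]) / 2
    mult <- exp(-eb_rate * t_mid / total)
    # per-tip trait variance with unit base rate, then rescale to match BM;
    # accumulate root-to-tip (reverse postorder = parents first)
    var_node <- numeric(max(tree$edge))
    for (e in rev(seq_len(nrow(tree$edge)))) {
      var_node[tree$edge[e, 2]] <- var_node[tree$edge[e, 1]] +
        mult[e] * tree$edge.length[e]
    }
    mean_var <- mean(var_node[seq_along(tree$tip.label)])
    mean_depth <- mean(depth[seq_along(tree$tip.label)])
    scale <- sigma_bm^2 * mean_depth / mean_var
    sigma <- sqrt(scale * mult)
  }
  .with_seed(seed, {
    ape::rTraitCont(tree, model = "BM", sigma = sigma, root.value = 0)
  })
}

#' Simulate regional (metacommunity) relative abundances
#'
#' Log-normal species-abundance distribution, the canonical shape for
#' microbial surveys: abundances proportional to
#' `LogNormal(0, lognormal_sigma)`, normalized to sum to 1.
#'
#' @param n_taxa pool size.
#' @param lognormal_sigma log-scale sd (larger = less even).
#' @param seed integer seed.
#' @return named relative-abundance vector summing to 1.
#' @export
simulate_metacommunity <- function(n_taxa, lognormal_sigma = 1.5, seed = NULL) {
  .assert(lognormal_sigma > 0, "lognormal_sigma must be > 0")
  .with_seed(seed, {
    x <- stats::rlnorm(n_taxa, 0, lognormal_sigma)
    stats::setNames(x / sum(x), sprintf("otu%03d", seq_len(n_taxa)))
  })
}

#' Simulate neutral (drift-migration equilibrium) communities
#'
#' Each sample's local pool is drawn from the stationary law of
#' Wright-Fisher drift with migration from the regional pool:
#' `Dirichlet(N m * meta)`, whose marginals are the
#' `Beta(N m p, N m (1 - p))` distributions assumed by the Sloan model.
#' Counts are multinomial at `reads` per sample.
#'
#' @param meta regional relative abundances (named).
#' @param n_samples number of samples.
#' @param reads reads per sample (also the community size N).
#' @param m migration rate in (0, 1].
#' @param seed integer seed.
#' @return a [community_table].
#' @export
simulate_neutral_community <- function(meta, n_samples, reads, m,
                                       seed = NULL) {
  .assert(m > 0 && m <= 1, "m must lie in (0, 1]")
  .with_seed(seed, {
    counts <- vapply(seq_len(n_samples), function(s) {
      pool <- stats::rgamma(length(meta), shape = reads * m * meta)
      if (sum(pool) == 0) pool <- meta
      as.integer(stats::rmultinom(1, reads, pool / sum(pool)))
    }, integer(length(meta)))
    rownames(counts) <- names(meta)
    colnames(counts) <- sprintf("S%03d", seq_len(n_samples))
    community_table(counts)
  })
}

# clade-coherent phylum labels: cut the cophenetic dendrogram into k
# groups and name them after dominant soil phyla/classes, largest first
.assign_phyla <- function(tree, k = 8) {
  labels <- c("Chloroflexi", "Acidobacteria", "Actinobacteria",
              "Alphaproteobacteria", "Firmicutes", "Deltaproteobacteria",
              "Betaproteobacteria", "Gammaproteobacteria")
  k <- min(k, length(labels), length(tree$tip.label) %/% 2)
  cl <- stats::cutree(stats::hclust(stats::as.dist(cophenetic_dist(tree)),
                                    method = "average"), k = k)
  sizes <- sort(table(cl), decreasing = TRUE)
  map <- stats::setNames(labels[seq_len(k)], names(sizes))
  stats::setNames(unname(map[as.character(cl)]), names(cl))
}

#' Assemble a synthetic metacommunity with known assembly regimes
#'
#' Generates samples layer by layer according to the configured regime:
#' \describe{
#'   \item{selection_variable}{environment varies across samples within
#'     the layer; sampling weights are
#'     `meta * exp(-(e_s - optimum)^2 / (2 sigma_sel^2))`.}
#'   \item{selection_homogeneous}{consistent filtering on a deeply
#'     conserved trait: one mid-sized clade is favoured in every sample
#'     (outside taxa suppressed by patristic distance), with a founder
#'     lottery among its members (see [simulation_config]), so samples
#'     turn over taxonomically among close relatives — the signature of
#'     homogeneous selection.}
#'   \item{homogenizing_dispersal}{all samples multinomial from the shared
#'     regional pool (an infinitely wide filter).}
#'   \item{dispersal_limitation}{each sample's pool is an independent
#'     `Dirichlet(alpha * meta)` perturbation with small `alpha`, times
#'     sample-specific lognormal drift.}
#'   \item{neutral}{drift-migration equilibrium pools,
#'     `Dirichlet(N m * meta)` (see [simulate_neutral_community]).}
#' }
#' Counts are multinomial at `reads_per_sample`; every column sums to
#' exactly that depth. The sample table carries the latent axis `e` plus
#' correlated soil-like variables whose within-layer noise scales with
#' the layer's `env_heterogeneity`.
#'
#' @param config a [simulation_config].
#' @param tree,optima,meta optionally precomputed truth inputs; by default
#'   they are generated from `config$seed`.
#' @return list with `table` (a [community_table] with phylum taxonomy),
#'   `samples` (data.frame: sample_id, layer, treatment, e, pH, TP, SOC,
#'   TN, TK, SMC, NO3N, NH4N) and `truth` (class `simulation_truth`).
#' @export
assemble_samples <- function(config, tree = NULL, optima = NULL, meta = NULL) {
  .assert(inherits(config, "simulation_config"),
          "config must be a simulation_config")
  tree <- tree %||% simulate_tree(config$n_taxa, config$lambda,
                                  seed = .derive_seed(config$seed, "tree"))
  optima <- optima %||% evolve_niche(tree, config$sigma_bm,
                                     seed = .derive_seed(config$seed, "niche"))
  meta <- meta %||% simulate_metacommunity(
    config$n_taxa, config$lognormal_sigma,
    seed = .derive_seed(config$seed, "meta"))
  taxa <- tree$tip.label
  meta <- meta[taxa]
  optima <- optima[taxa]
  ns <- config$samples_per_layer
  reads <- config$reads_per_sample
  hs_filter <- NULL
  hs_clade <- NULL
  if ("selection_homogeneous" %in% config$regimes) {
    # favoured clade: the largest whose size is 6-15% of the pool
    parts <- ape::prop.part(tree)
    sizes <- lengths(parts)
    cand <- which(sizes >= 0.06 * config$n_taxa &
                    sizes <= 0.15 * config$n_taxa)
    .assert(length(cand) > 0,
            "no clade in the 6-15%% size range; increase n_taxa")
    chosen <- cand[which.max(sizes[cand])]
    hs_clade <- tree$tip.label[parts[[chosen]]]
    d_tree <- cophenetic_dist(tree)[taxa, taxa]
    hs_filter <- exp(-apply(d_tree[, hs_clade, drop = FALSE], 1, min) /
                       config$hs_tau)
  }
  counts_all <- NULL
  sample_rows <- list()
  env_truth <- numeric(0)
  for (l in seq_len(config$n_layers)) {
    regime <- config$regimes[l]
    het <- config$env_heterogeneity[l]
    ids <- sprintf("L%d_%s_r%d", l, rep(c("M0", "M1", "M2", "M3"),
                                        length.out = ns),
                   stats::ave(seq_len(ns),
                              rep(c("M0", "M1", "M2", "M3"),
                                  length.out = ns), FUN = seq_along))
    layer <- .with_seed(.derive_seed(config$seed, c("layer", l)), {
      e <- switch(regime,
        selection_variable = het * seq(-1.5, 1.5, length.out = ns),
        selection_homogeneous = rep(1, ns),
        rep(0, ns) + stats::rnorm(ns, 0, 0.1 * het))
      counts <- vapply(seq_len(ns), function(s) {
        pool <- switch(regime,
          selection_variable = {
            .assert(config$sigma_sel > 0,
                    "sigma_sel must be > 0 for selection regimes")
            w <- meta * exp(-(e[s] - optima)^2 / (2 * config$sigma_sel^2))
            if (config$sel_drift_sigma > 0) {
              w <- w * stats::rlnorm(length(w), 0, config$sel_drift_sigma)
            }
            .assert(sum(w) > 0, "niche filter eliminated every taxon")
            w
          },
          selection_homogeneous = {
            w <- hs_filter *
              stats::rbinom(length(hs_filter), 1, config$hs_inclusion) *
              stats::rlnorm(length(hs_filter), 0, config$hs_drift)
            if (sum(w) == 0) w <- hs_filter
            w
          },
          homogenizing_dispersal = meta,
          dispersal_limitation = {
            g <- stats::rgamma(length(meta),
                               shape = config$dirichlet_alpha * meta)
            g <- g * stats::rlnorm(length(meta), 0, config$drift_sigma)
            if (sum(g) == 0) g <- meta
            g
          },
          neutral = {
            g <- stats::rgamma(length(meta),
                               shape = reads * config$m_true * meta)
            if (sum(g) == 0) g <- meta
            g
          })
        as.integer(stats::rmultinom(1, reads, pool / sum(pool)))
      }, integer(length(meta)))
      env_noise <- function(scale) stats::rnorm(ns, 0, scale * het)
      samples <- data.frame(
        sample_id = ids,
        layer = sprintf("L%d", l),
        treatment = rep(c("M0", "M1", "M2", "M3"), length.out = ns),
        e = e,
        pH = 6 - 0.15 * l + 0.4 * e + env_noise(0.15),
        TP = 0.8 - 0.08 * l + 0.1 * e + env_noise(0.05),
        SOC = 12 - 1.5 * l + 0.8 * e + env_noise(0.4),
        TN = 1.4 - 0.15 * l + 0.1 * e + env_noise(0.05),
        TK = 14 + 0.5 * sin(l) + 0.2 * e + env_noise(0.2),
        SMC = 18 + 2 * sin(l / 2) + 0.5 * e + env_noise(0.5),
        NO3N = 20 - 2 * l + 1.2 * e + env_noise(0.8),
        NH4N = 8 + sin(l) + 0.5 * e + env_noise(0.4),
        stringsAsFactors = FALSE)
      list(counts = counts, samples = samples)
    })
    colnames(layer$counts) <- ids
    counts_all <- cbind(counts_all, layer$counts)
    sample_rows[[l]] <- layer$samples
    env_truth <- c(env_truth, stats::setNames(layer$samples$e, ids))
  }
  rownames(counts_all) <- taxa
  samples <- do.call(rbind, sample_rows)
  table <- community_table(counts_all, taxonomy = .assign_phyla(tree))
  truth <- structure(list(
    tree = tree, optima = optima, meta = meta, env = env_truth,
    hs_clade = hs_clade,
    regimes = stats::setNames(config$regimes,
                              sprintf("L%d", seq_len(config$n_layers))),
    m_true = config$m_true, config = config), class = "simulation_truth")
  list(table = table, samples = samples, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth: regimes per layer\n")
  print(x$regimes)
  invisible(x)
}

# EcoPlate guild sizes (31 substrate wells)
.ecoplate_guilds <- function() {
  rep(c("carbohydrates", "carboxylic_acids", "amino_acids", "polymers",
        "phenolic_acids", "amines"),
      times = c(10, 7, 6, 4, 2, 2))
}

#' Simulate a Biolog EcoPlate
#'
#' Generates OD590 readings every 24 h for 7 days: each guild develops
#' colour along a saturating curve scaled so the whole-plate AWCD at 96 h
#' equals `awcd_target` exactly when `noise_sd = 0`.
#'
#' @param awcd_target whole-plate AWCD at 96 h.
#' @param noise_sd Gaussian OD noise (default 0).
#' @param seed integer seed.
#' @return a [biolog_plate].
#' @export
simulate_plate <- function(awcd_target, noise_sd = 0, seed = NULL) {
  .assert(awcd_target > 0, "awcd_target must be > 0")
  guilds <- .ecoplate_guilds()
  rel <- c(carbohydrates = 1.2, carboxylic_acids = 1.0, amino_acids = 0.9,
           polymers = 0.7, phenolic_acids = 0.5, amines = 0.6)
  level <- rel[guilds] * awcd_target / mean(rel[guilds])
  hours <- seq(24, 168, by = 24)
  ramp <- (1 - exp(-hours / 40)) / (1 - exp(-96 / 40))
  blank_od <- 0.06
  .with_seed(seed, {
    od <- outer(level, ramp) + blank_od +
      matrix(stats::rnorm(length(level) * length(hours), 0, noise_sd),
             length(level), length(hours))
    od <- rbind(od, blank_od +
                  stats::rnorm(length(hours), 0, noise_sd))
    od <- pmax(od, 0)
    wells <- c(sprintf("C%02d", seq_along(guilds)), "blank")
    dimnames(od) <- list(wells, hours)
    biolog_plate(od, guild = stats::setNames(guilds, wells[seq_along(guilds)]))
  })
}

#' Simulate a cumulative SOC mineralization series
#'
#' First-order kinetics `C_t = C_0 (1 - exp(-k t))` sampled at the
#' standard incubation days (1, 3, 5, 7, 14, 21, 28, 42, 56, 70, 85, 100)
#' with multiplicative Gaussian noise.
#'
#' @param C0 potentially mineralizable carbon (mg per kg).
#' @param k rate constant (per day).
#' @param noise_sd relative noise sd (e.g. 0.05 for 5%).
#' @param seed integer seed.
#' @param days sampling days.
#' @return a [mineralization_series].
#' @export
simulate_co2 <- function(C0, k, noise_sd = 0, seed = NULL,
                         days = c(1, 3, 5, 7, 14, 21, 28, 42, 56, 70, 85, 100)) {
  .assert(C0 > 0 && k > 0, "C0 and k must be positive")
  .with_seed(seed, {
    ct <- C0 * (1 - exp(-k * days))
    ct <- pmax(ct * (1 + stats::rnorm(length(days), 0, noise_sd)), 0)
    suppressWarnings(mineralization_series(days, ct))
  })
}
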