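test_that("process classification covers the plane with exactly one category", {
  expect_equal(as.character(classify_processes(3.1, 0)), "variable_selection")
  expect_equal(as.character(classify_processes(-2.7, 0)), "homogeneous_selection")
  expect_equal(as.character(classify_processes(0.4, -0.97)), "homogenizing_dispersal")
  expect_equal(as.character(classify_processes(0.4, 0.97)), "dispersal_limitation")
  expect_equal(as.character(classify_processes(0.4, 0.1)), "undominated")
  # boundaries belong to the stochastic/undominated side
  expect_equal(as.character(classify_processes(2, 0)), "undominated")
  expect_equal(as.character(classify_processes(-2, 0)), "undominated")
  expect_equal(as.character(classify_processes(0, 0.95)), "undominated")
  # totality over a grid
  grid <- expand.grid(b = seq(-4, 4, by = 0.5), r = seq(-1, 1, by = 0.25))
  out <- classify_processes(grid$b, grid$r)
  expect_false(anyNA(out))
  expect_identical(levels(out), process_levels())
  expect_error(classify_processes(NA, 0), "finite")
  expect_error(classify_processes(0, 2), "\\[-1, 1\\]")
})

test_that("betaNTI and RC-bray pair engines are reproducible and order-independent", {
  tr <- simulate_tree(60, seed = 31)
  meta <- simulate_metacommunity(60, 1.5, seed = 32)
  tab <- exchangeable_table(tr, meta, 6, 800, seed = 33)
  b1 <- bnti_pair(tab, tr, "s01", "s02", reps = 150, seed = 9)
  b2 <- bnti_pair(tab, tr, "s01", "s02", reps = 150, seed = 9)
  expect_identical(b1$bnti, b2$bnti)
  expect_identical(b1$null$values, b2$null$values)
  r1 <- rc_bray_pair(tab, "s01", "s02", reps = 150, seed = 9)
  r2 <- rc_bray_pair(tab, "s01", "s02", reps = 150, seed = 9)
  expect_identical(r1$rc_bray, r2$rc_bray)
  expect_true(r1$rc_bray >= -1 && r1$rc_bray <= 1)

  # per-pair seeds derived from sample ids: group results do not depend on
  # the order in which samples (hence pairs) are listed
  groups <- stats::setNames(rep("g", 6), sample_ids(tab))
  p1 <- assembly_profile(tab, tr, groups, reps = 150, seed = 5)
  perm <- c(4, 2, 6, 1, 3, 5)
  tab2 <- ecoassembly:::subset_table(tab, samples = perm)
  p2 <- assembly_profile(tab2, tr, groups[sample_ids(tab2)], reps = 150, seed = 5)
  key <- function(df) {
    k <- paste(pmin(df$sample_a, df$sample_b), pmax(df$sample_a, df$sample_b))
    df[order(k), c("bnti", "rc_bray")]
  }
  expect_equal(key(p1$pairs), key(p2$pairs), ignore_attr = TRUE)
})

test_that("identical communities yield a degenerate betaMNTD null", {
  tr <- simulate_tree(20, seed = 41)
  set.seed(42)
  x <- as.integer(rmultinom(1, 300, rep(1 / 20, 20)))
  counts <- cbind(a = x, b = x)
  rownames(counts) <- tr$tip.label
  tab <- community_table(counts)
  expect_error(bnti_pair(tab, tr, "a", "b", reps = 120, seed = 1),
               "degenerate null")
})

test_that("assembly profiles partition pairs and handle small groups", {
  tr <- simulate_tree(40, seed = 51)
  meta <- simulate_metacommunity(40, 1, seed = 52)
  tab <- exchangeable_table(tr, meta, 5, 500, seed = 53)
  groups <- stats::setNames(c("g1", "g1", "g2", "g2", "solo"), sample_ids(tab))
  expect_warning(prof <- assembly_profile(tab, tr, groups, reps = 120, seed = 3),
                 "single sample")
  expect_identical(nrow(prof$pairs), 2L)  # one pair per 2-sample group
  frac <- as.matrix(prof$fractions[, -1])
  expect_equal(unname(rowSums(frac)), rep(1, nrow(frac)))
  expect_true(all(apply(frac, 1, max) == 1))  # single pair = one category at 100%
})

test_that("per-phylum analysis on the full taxon set reproduces the whole-community result", {
  tr <- simulate_tree(30, seed = 61)
  meta <- simulate_metacommunity(30, 1, seed = 62)
  tab <- exchangeable_table(tr, meta, 4, 400, seed = 63)
  tab$taxonomy <- stats::setNames(rep("OnlyPhylum", 30), taxon_ids(tab))
  groups <- stats::setNames(rep("g", 4), sample_ids(tab))
  whole <- assembly_profile(tab, tr, groups, reps = 120, seed = 7)
  sub <- per_phylum_assembly(tab, tr, "OnlyPhylum", groups, reps = 120,
                             seed = 7, min_taxa = 20)
  expect_equal(whole$pairs$bnti, sub$pairs$bnti)
  expect_equal(whole$pairs$rc_bray, sub$pairs$rc_bray)
  expect_error(per_phylum_assembly(tab, tr, "Missing", groups, reps = 120,
                                   seed = 7), "min_taxa")
})

test_that("a phylum under selection is classified as more deterministic than one that is not", {
  # two clades; only clade A members track the environment
  cfg <- simulation_config(n_taxa = 120, n_layers = 1,
                           samples_per_layer = 8, reads_per_sample = 1500,
                           regimes = "selection_variable", seed = 71)
  sim <- assemble_samples(cfg)
  groups <- stats::setNames(sim$samples$layer, sim$samples$sample_id)
  phyla <- table(sim$table$taxonomy)
  big <- names(phyla)[phyla >= 20]
  skip_if(length(big) < 1, "no phylum large enough in this draw")
  prof <- per_phylum_assembly(sim$table, sim$truth$tree, big[1], groups,
                              reps = 150, seed = 72)
  expect_s3_class(prof, "assembly_profile")
  expect_true(all(abs(prof$pairs$rc_bray) <= 1))
})

test_that("beta-null deviations are bounded and near zero for stochastic assembly", {
  tr <- simulate_tree(80, seed = 81)
  meta <- simulate_metacommunity(80, 1.2, seed = 82)
  tab <- exchangeable_table(tr, meta, 6, 1000, seed = 83)
  dev_bc <- beta_null_deviation(tab, "bray_curtis", reps = 150, seed = 84)
  expect_true(all(abs(dev_bc$deviation) <= 1))
  expect_lt(abs(mean(dev_bc$deviation)), 0.1)
  dev_wu <- beta_null_deviation(tab, "weighted_unifrac", tree = tr,
                                reps = 150, seed = 85)
  expect_true(all(abs(dev_wu$deviation) <= 1))
  expect_lt(abs(mean(dev_wu$deviation)), 0.1)
  expect_error(beta_null_deviation(tab, "weighted_unifrac"), "tree")
  # reproducibility
  dev_bc2 <- beta_null_deviation(tab, "bray_curtis", reps = 150, seed = 84)
  expect_identical(dev_bc$deviation, dev_bc2$deviation)
})

test_that("selection inflates |beta-null deviation| relative to shared-pool assembly", {
  cfg <- simulation_config(n_taxa = 150, n_layers = 2,
                           samples_per_layer = 8, reads_per_sample = 1500,
                           regimes = c("selection_variable",
                                       "homogenizing_dispersal"),
                           seed = 91)
  sim <- assemble_samples(cfg)
  ids_sel <- sim$samples$sample_id[sim$samples$layer == "L1"]
  ids_hd <- sim$samples$sample_id[sim$samples$layer == "L2"]
  d_sel <- beta_null_deviation(
    ecoassembly:::subset_table(sim$table, samples = ids_sel),
    "bray_curtis", reps = 150, seed = 92)
  d_hd <- beta_null_deviation(
    ecoassembly:::subset_table(sim$table, samples = ids_hd),
    "bray_curtis", reps = 150, seed = 93)
  expect_gt(mean(abs(d_sel$deviation)), mean(abs(d_hd$deviation)))
})
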