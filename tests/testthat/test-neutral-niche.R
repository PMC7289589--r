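test_that("Sloan occurrence predictions match quadrature and obey limits", {
  # direct numerical integration of the Beta density as oracle
  for (par in list(c(0.01, 1000, 0.1), c(0.005, 2000, 0.3),
                   c(0.2, 500, 0.05))) {
    p <- par[1]; N <- par[2]; m <- par[3]; d <- 1 / N
    oracle <- stats::integrate(function(x)
      stats::dbeta(x, N * m * p, N * m * (1 - p)), d, 1,
      rel.tol = 1e-10)$value
    expect_equal(sloan_predict(p, N, m), oracle, tolerance = 1e-8)
  }
  # increasing in p at fixed N, m (strictly until it saturates at 1)
  ps <- seq(0.0005, 0.02, length.out = 30)
  expect_true(all(diff(sloan_predict(ps, 1000, 0.1)) > 0))
  ps2 <- seq(0.001, 0.2, length.out = 30)
  expect_true(all(diff(sloan_predict(ps2, 1000, 0.1)) >= 0))
  # Nm -> infinity: step function at the detection limit
  expect_gt(sloan_predict(0.01, 1e7, 1, d = 0.001), 0.999)
  expect_lt(sloan_predict(0.0001, 1e7, 1, d = 0.001), 0.001)
  expect_error(sloan_predict(0, 1000, 0.1), "strictly in")
  expect_error(sloan_predict(0.5, 1000, 1.5), "m must lie")
})

test_that("Sloan predictions agree with a Beta-simulation oracle within MC error", {
  set.seed(11)
  p <- 0.02; N <- 1000; m <- 0.2; d <- 1 / N
  draws <- stats::rbeta(40000, N * m * p, N * m * (1 - p))
  frac <- mean(draws > d)
  se <- sqrt(frac * (1 - frac) / 40000)
  expect_lt(abs(sloan_predict(p, N, m) - frac), 3 * se)
})

test_that("migration-rate fitting recovers contracts and invariances", {
  meta <- simulate_metacommunity(80, 1, seed = 21)
  tab <- simulate_neutral_community(meta, 30, 1000, 0.1, seed = 22)
  fit <- fit_sloan(tab)
  expect_true(fit$m > 0 && fit$m <= 1)
  expect_lte(fit$r_squared, 1)
  expect_true(all(c("otu_id", "p", "freq_obs", "freq_pred", "ci_lower",
                    "ci_upper", "within_ci") %in% names(fit$taxa)))
  expect_true(all(fit$taxa$ci_lower <= fit$taxa$ci_upper))
  # taxon order is irrelevant
  perm <- sample(nrow(tab$counts))
  tab_perm <- community_table(tab$counts[perm, ])
  expect_equal(fit_sloan(tab_perm)$m, fit$m, tolerance = 1e-8)
  # duplicating every taxon (fresh ids) leaves the estimate unchanged:
  # the fit weights taxa, not reads
  dup <- tab$counts
  rownames(dup) <- paste0(rownames(dup), "_copy")
  tab_dup <- community_table(rbind(tab$counts, dup))
  expect_equal(fit_sloan(tab_dup)$m, fit$m, tolerance = 5e-3)
})

test_that("saturated occupancy is rejected as unidentifiable", {
  m <- matrix(5L, 4, 8, dimnames = list(paste0("t", 1:4), paste0("s", 1:8)))
  m[1, 1] <- 6L
  suppressWarnings(expect_error(fit_sloan(community_table(m)), "saturated"))
})

test_that("Levins' niche breadth matches closed forms and invariants", {
  # P = (0.5, 0.25, 0.25) -> B = 1/0.375
  m <- matrix(c(20L, 10L, 10L,
                0L, 5L, 0L,
                7L, 7L, 7L), nrow = 3, byrow = TRUE,
              dimnames = list(c("spread", "single", "even"), c("c1", "c2", "c3")))
  nb <- levins_breadth(community_table(m))
  expect_equal(nb$B[["spread"]], 1 / 0.375, tolerance = 1e-9)
  expect_equal(nb$B[["single"]], 1)        # confined to one community
  expect_equal(nb$B[["even"]], 3)          # even over all three
  expect_true(all(nb$B >= 1 & nb$B <= 3))
  # B_com of c1 averages the breadths of taxa present in c1
  expect_equal(nb$B_com[["c1"]],
               mean(c(nb$B[["spread"]], nb$B[["even"]])))
  # rescaling one taxon's counts leaves its breadth unchanged
  m2 <- m
  m2["spread", ] <- m2["spread", ] * 13L
  expect_equal(levins_breadth(community_table(m2))$B[["spread"]],
               nb$B[["spread"]])
  # absent taxa are excluded, not NaN
  nb_sub <- levins_breadth(community_table(m), samples = c("c1", "c3"))
  expect_false("single" %in% names(nb_sub$B))
  expect_false(anyNA(unlist(nb_sub)))
})

test_that("the within-community convention is exposed behind a flag", {
  m <- matrix(c(10L, 30L, 5L, 5L), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  nb <- levins_breadth(community_table(m), convention = "within_community")
  p <- c(10 / 15, 30 / 35)
  expect_equal(nb$B[["a"]], 1 / sum(p^2))
})

test_that("higher dispersal yields higher fitted migration rates", {
  cfg <- simulation_config(n_taxa = 150, n_layers = 2, samples_per_layer = 10,
                           reads_per_sample = 1500,
                           regimes = c("homogenizing_dispersal",
                                       "dispersal_limitation"),
                           seed = 31)
  sim <- assemble_samples(cfg)
  ids_hd <- sim$samples$sample_id[sim$samples$layer == "L1"]
  ids_dl <- sim$samples$sample_id[sim$samples$layer == "L2"]
  m_hd <- suppressWarnings(fit_sloan(
    ecoassembly:::subset_table(sim$table, samples = ids_hd))$m)
  m_dl <- suppressWarnings(fit_sloan(
    ecoassembly:::subset_table(sim$table, samples = ids_dl))$m)
  expect_gt(m_hd, m_dl)
})
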