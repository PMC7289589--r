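test_that("community tables round-trip through TSV with taxonomy parsing", {
  f <- write_tmp(c(
    "# comment line",
    "otu\ts1\ts2\ttaxonomy",
    "t1\t5\t2\tk__Bacteria; p__Chloroflexi; c__Anaerolineae",
    "t2\t0\t1\tk__Bacteria; p__Proteobacteria; c__Alphaproteobacteria",
    "t3\t3\t4\tsome free text"))
  tab <- read_community(f)
  expect_identical(dim(tab$counts), c(3L, 2L))
  expect_identical(tab$counts["t1", "s1"], 5L)
  expect_identical(unname(tab$taxonomy),
                   c("Chloroflexi", "Alphaproteobacteria", "some free text"))

  # plain numeric table (identity round-trip)
  f2 <- write_tmp(c("otu\ts1\ts2", "a\t1\t2", "b\t3\t4", "c\t0\t7"))
  tab2 <- read_community(f2)
  expect_identical(unname(tab2$counts), matrix(c(1L, 3L, 0L, 2L, 4L, 7L), 3))

  # biom-style export with '#OTU ID' header
  f3 <- write_tmp(c("# Constructed from biom file",
                    "#OTU ID\ts1\ts2", "x\t1\t2", "y\t3\t4"))
  expect_identical(dim(read_community(f3, format = "biom-tsv")$counts),
                   c(2L, 2L))
})

test_that("malformed community tables are rejected with informative errors", {
  f <- write_tmp(c("otu\ts1\ts1", "a\t1\t2", "b\t3\t4"))
  expect_error(read_community(f), "duplicated sample")
  f2 <- write_tmp(c("otu\ts1\ts2", "a\t1\t-2", "b\t3\t4"))
  expect_error(read_community(f2), "taxon 'a', sample 's2'")
  f3 <- write_tmp(c("otu\ts1\ts2", "a\t1\tNA_ish", "b\t3\t4"))
  expect_error(read_community(f3), "non-numeric")
  expect_error(community_table(matrix(c(0.5, 1), 2, 1,
                                      dimnames = list(c("a", "b"), "s1"))),
               "whole numbers")
})

test_that("Newick trees are parsed, validated, and repaired per policy", {
  f <- write_tmp("((A:1,B:1):1,C:2);", ext = ".nwk")
  tr <- read_tree(f)
  expect_s3_class(tr, "phylo")
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(depths[match("A", tr$tip.label)], 2)

  expect_error(read_tree(write_tmp("((A:1,B:1:1,C:2);", ext = ".nwk")),
               "unbalanced")
  expect_error(read_tree(write_tmp("(A:-1,B:1);", ext = ".nwk")),
               "negative branch")
  expect_warning(tr2 <- read_tree(write_tmp("(A,B);", ext = ".nwk")),
                 "branch lengths")
  expect_true(all(tr2$edge.length == 0))
})

test_that("rarefaction hits the target depth exactly and reproducibly", {
  set.seed(1)
  m <- matrix(rpois(40, 60) + 1L, nrow = 8,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:5)))
  tab <- community_table(m)
  r <- rarefy(tab, depth = 100, seed = 7)
  expect_true(all(colSums(r$counts) == 100))
  expect_identical(r$counts, rarefy(tab, depth = 100, seed = 7)$counts)
  # exhaustive draw: depth equal to a sample's total returns it unchanged
  tot <- sum(m[, 1])
  single <- community_table(m[, 1, drop = FALSE])
  expect_identical(rarefy(single, depth = tot, seed = 1)$counts[, 1], m[, 1])
  expect_error(rarefy(tab, depth = 10000), "exceeds total reads.*s1")
  expect_identical(eval(formals(rarefy)$depth), 20515)
})

test_that("rarefaction is unbiased: expected counts track original proportions", {
  x <- c(a = 50L, b = 30L, c = 20L)
  tab <- community_table(matrix(x, 3, 1, dimnames = list(names(x), "s")))
  draws <- vapply(1:300, function(i) rarefy(tab, 20, seed = i)$counts[, 1],
                  integer(3))
  # hypergeometric mean 20 * p; se of the mean over 300 draws
  p <- x / sum(x)
  expect_true(all(abs(rowMeans(draws) - 20 * p) <
                    3 * apply(draws, 1, sd) / sqrt(300)))
})

test_that("prevalence filter applies a strict threshold and is idempotent", {
  m <- matrix(0L, 3, 12, dimnames = list(c("in9", "in10", "everywhere"),
                                         paste0("s", 1:12)))
  m["in9", 1:9] <- 1L
  m["in10", 1:10] <- 1L
  m["everywhere", ] <- 2L
  tab <- community_table(m)
  kept <- prevalence_filter(tab, min_fraction = 0.75)
  expect_identical(taxon_ids(kept), c("in10", "everywhere"))
  expect_identical(prevalence_filter(kept, min_fraction = 0.75)$counts,
                   kept$counts)
  expect_identical(taxon_ids(prevalence_filter(tab, min_fraction = 0)),
                   taxon_ids(tab))
  expect_error(prevalence_filter(tab, group_samples = character(0)), "empty")
})

test_that("alpha diversity matches closed forms and is invariant as expected", {
  expect_equal(alpha_diversity(c(10, 0, 0))$shannon, 0)
  expect_equal(alpha_diversity(rep(10, 4))$shannon, log(4))
  # shannon: taxon order and common rescaling are irrelevant
  x <- c(4, 1, 7, 2)
  expect_equal(alpha_diversity(x)$shannon, alpha_diversity(rev(x))$shannon)
  expect_equal(alpha_diversity(x)$shannon, alpha_diversity(10 * x)$shannon)
  # chao1: bias-corrected hand value, F1 = 0 limit, classic form
  expect_equal(alpha_diversity(c(1, 1, 2, 3))$chao1, 4 + 2 * 1 / (2 * 2))
  expect_equal(alpha_diversity(c(3, 4, 5))$chao1, 3)
  expect_equal(alpha_diversity(c(1, 1, 2, 3),
                               chao1_bias_corrected = FALSE)$chao1, 6)
  expect_error(alpha_diversity(c(0, 0)), "all-zero")
})

test_that("environmental variation summaries match direct covariance algebra", {
  df <- data.frame(
    sample_id = paste0("s", 1:6),
    layer = rep(c("top", "deep"), each = 3),
    pH = c(5.1, 6.2, 4.4, 5.0, 5.0, 5.1),
    TP = c(0.9, 0.4, 0.7, 0.5, 0.5, 0.5))
  ev <- env_variation(df)
  z <- scale(as.matrix(df[, c("pH", "TP")]))
  for (g in c("top", "deep")) {
    expect_equal(ev$dispersion$dispersion[ev$dispersion$group == g],
                 sum(diag(cov(z[df$layer == g, ]))))
  }
  expect_equal(ev$cv$cv[ev$cv$group == "top" & ev$cv$variable == "pH"],
               sd(df$pH[1:3]) / mean(df$pH[1:3]))
  # identical samples within a layer: zero dispersion and distances
  df2 <- df
  df2[4:6, c("pH", "TP")] <- list(rep(5, 3), rep(0.5, 3))
  ev2 <- env_variation(df2)
  expect_equal(ev2$dispersion$dispersion[ev2$dispersion$group == "deep"], 0)
  expect_true(all(ev2$sample_distances$sq_distance[4:6] == 0))
  # constant variable across the dataset is dropped with a warning
  df3 <- cbind(df, flat = 1)
  expect_warning(ev3 <- env_variation(df3), "constant")
  expect_false("flat" %in% ev3$cv$variable)
})
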