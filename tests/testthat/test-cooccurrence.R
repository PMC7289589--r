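test_that("association scores match direct evaluation", {
  x <- c(2, 4, 6, 8, 10)
  expect_equal(unname(association_scores(x, 2 * x)),
               c(1, 1, 0, 0), tolerance = 1e-9)
  # disjoint support: Bray-Curtis of the profiles is 1
  a <- c(5, 9, 0, 0, 0)
  b <- c(0, 0, 3, 1, 7)
  expect_equal(association_scores(a, b)[["bray_curtis"]], 1)
  # 5-sample toy against hand formulas
  y <- c(3, 1, 7, 2, 9)
  s <- association_scores(x, y)
  expect_equal(s[["pearson"]], cor(x, y))
  expect_equal(s[["spearman"]], cor(x, y, method = "spearman"))
  px <- x / sum(x); py <- y / sum(y)
  expect_equal(s[["bray_curtis"]], sum(abs(px - py)) / 2)
  qx <- (px + 1e-6) / sum(px + 1e-6)
  qy <- (py + 1e-6) / sum(py + 1e-6)
  expect_equal(s[["kullback_leibler"]],
               sum(qx * log(qx / qy)) + sum(qy * log(qy / qx)),
               tolerance = 1e-9)
  expect_error(association_scores(rep(2, 5), y), "constant")
  expect_error(association_scores(1:4, 1:4), "at least 5")
})

test_that("permutation p-values hit the pseudocount floor and reproduce under seed", {
  set.seed(1)
  base <- rlnorm(12, 2, 1)
  counts <- rbind(o1 = round(base * 40),
                  o2 = round(base * 25 + runif(12)),
                  o3 = round(rlnorm(12, 3, 1)))
  storage.mode(counts) <- "integer"
  colnames(counts) <- paste0("s", 1:12)
  tab <- community_table(counts)
  res <- permutation_pvalues(tab, pairs = rbind(c("o1", "o2")), B = 200,
                             seed = 4)
  expect_equal(res[[1]]$p[["pearson"]], 1 / 201)
  expect_equal(res[[1]]$p[["spearman"]], 1 / 201)
  res2 <- permutation_pvalues(tab, pairs = rbind(c("o1", "o2")), B = 200,
                              seed = 4)
  expect_identical(res[[1]]$p, res2[[1]]$p)
  expect_identical(res[[1]]$rho, res2[[1]]$rho)
  # rho is a proper correlation matrix of the four null transforms
  expect_equal(diag(res[[1]]$rho), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(res[[1]]$rho) <= 1 + 1e-12))
})

test_that("permutation p-values are roughly uniform for independent pairs", {
  set.seed(2)
  counts <- matrix(rpois(40 * 14, 8), nrow = 40,
                   dimnames = list(paste0("o", 1:40), paste0("s", 1:14)))
  tab <- community_table(counts)
  pairs <- cbind(paste0("o", 1:20), paste0("o", 21:40))
  res <- permutation_pvalues(tab, pairs = pairs, B = 200, seed = 6)
  pvals <- vapply(res, function(r) r$p[["pearson"]], numeric(1))
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  expect_lt(mean(pvals < 0.2), 0.45)
})

test_that("Brown's method reduces to Fisher, respects rho = 1, and is monotone", {
  p <- c(0.02, 0.01, 0.03, 0.05)
  fisher <- pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  expect_equal(brown_merge(p, diag(4)), fisher, tolerance = 1e-12)
  # perfectly dependent identical tests collapse to the common p-value
  ones <- matrix(1, 3, 3)
  expect_equal(brown_merge(rep(0.04, 3), ones), 0.04, tolerance = 1e-9)
  # monotone in each input
  r <- matrix(0.5, 4, 4); diag(r) <- 1
  expect_gt(brown_merge(c(0.2, 0.01, 0.03, 0.05), r),
            brown_merge(c(0.02, 0.01, 0.03, 0.05), r))
  expect_error(brown_merge(c(0, 0.1), diag(2)), "\\(0, 1\\]")
  expect_error(brown_merge(c(0.1, 0.1), matrix(c(1, 0.2, 0.4, 1), 2)),
               "symmetric")
})

test_that("network edges obey the correlation and BH thresholds", {
  set.seed(3)
  n <- 16
  z1 <- rnorm(n); z2 <- rnorm(n)
  mk <- function(z, w) as.integer(pmax(round(exp(2 + 1.2 * z + w * rnorm(n))), 0))
  counts <- rbind(a1 = mk(z1, 0.3), a2 = mk(z1, 0.3), a3 = mk(z1, 0.3),
                  b1 = mk(z2, 0.3), b2 = mk(z2, 0.3),
                  noise = as.integer(rpois(n, 20)))
  colnames(counts) <- paste0("s", 1:n)
  tab <- community_table(counts,
                         taxonomy = setNames(c("A", "A", "A", "B", "B", "C"),
                                             rownames(counts)))
  net <- build_network(tab, B = 300, seed = 5)
  kept <- net$edges[net$edges$retained, ]
  expect_true(all(abs(kept$pearson) > 0.6))
  expect_true(all(abs(kept$spearman) > 0.6))
  expect_true(all(kept$bh_q < 0.01))
  # BH wiring equals the textbook step-up computed by hand
  p <- net$edges$brown_p
  k <- length(p)
  ord <- order(p)
  manual <- numeric(k)
  manual[ord] <- rev(cummin(rev(p[ord] * k / seq_len(k))))
  expect_equal(net$edges$bh_q, pmin(manual, 1), tolerance = 1e-12)
  # invariance to OTU ordering
  tab_perm <- ecoassembly:::subset_table(tab, taxa = c(6, 4, 2, 1, 3, 5))
  net2 <- build_network(tab_perm, B = 300, seed = 5)
  edge_key <- function(x) {
    e <- x$edges[x$edges$retained, c("otu_a", "otu_b")]
    sort(paste(pmin(e$otu_a, e$otu_b), pmax(e$otu_a, e$otu_b)))
  }
  expect_identical(edge_key(net), edge_key(net2))
})

test_that("topology metrics match closed forms on K5 and P4", {
  k5 <- igraph::make_full_graph(5)
  igraph::E(k5)$sign <- "+"
  igraph::E(k5)$weight <- 1
  t5 <- network_topology(k5)
  expect_equal(t5$density, 1)
  expect_equal(t5$average_degree, 4)
  expect_equal(t5$clustering, 1)
  expect_equal(t5$diameter, 1)
  expect_equal(t5$average_path_length, 1)
  expect_equal(t5$pnc, 0)

  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  igraph::E(p4)$sign <- c("+", "-", "+")
  igraph::E(p4)$weight <- 1
  t4 <- network_topology(p4)
  expect_equal(t4$average_path_length, 10 / 6)
  expect_equal(t4$diameter, 3)
  expect_equal(t4$pnc, 100 / 3)
  # degree-1 nodes contribute 0 to mean clustering
  expect_equal(t4$clustering, 0)

  empty <- igraph::make_empty_graph(3, directed = FALSE)
  te <- network_topology(empty)
  expect_equal(te$n_edges, 0)
  expect_true(is.na(te$average_path_length))
})

test_that("O/R ratios partition exactly and respect the single-phylum identity", {
  g <- igraph::make_graph(~ a - b, a - c, b - c, c - d, d - e)
  igraph::V(g)$phylum <- c("P1", "P1", "P1", "P2", "P2")
  igraph::V(g)$name <- c("a", "b", "c", "d", "e")
  igraph::E(g)$sign <- "+"
  igraph::E(g)$weight <- 1
  net <- structure(list(graph = g, edges = NULL, params = list()),
                   class = "cooccurrence_network")
  orr <- or_ratio(net)
  expect_equal(sum(orr$o_pct), 100, tolerance = 1e-9)
  expect_equal(sum(orr$r_pct), 100, tolerance = 1e-9)
  # hand checks: n = 5 nodes, 10 possible pairs
  r11 <- orr[orr$phylum_a == "P1" & orr$phylum_b == "P1", ]
  expect_equal(r11$r_pct, 100 * 3 * 2 / (5 * 4))
  expect_equal(r11$eo, 3)
  r12 <- orr[orr$phylum_a == "P1" & orr$phylum_b == "P2", ]
  expect_equal(r12$r_pct, 100 * 2 * 3 * 2 / (5 * 4))
  # all nodes one phylum: O = R = 100, ratio 1
  g1 <- igraph::make_graph(~ a - b, b - c)
  igraph::V(g1)$phylum <- "only"
  igraph::V(g1)$name <- c("a", "b", "c")
  igraph::E(g1)$sign <- "+"
  net1 <- structure(list(graph = g1, edges = NULL, params = list()),
                    class = "cooccurrence_network")
  orr1 <- or_ratio(net1)
  expect_equal(orr1$o_pct, 100)
  expect_equal(orr1$r_pct, 100)
  expect_equal(orr1$ratio, 1)
})

test_that("networks export to GraphML", {
  g <- igraph::make_graph(~ a - b)
  igraph::V(g)$phylum <- "P"
  igraph::E(g)$sign <- "+"
  net <- structure(list(graph = g, edges = NULL, params = list()),
                   class = "cooccurrence_network")
  f <- tempfile(fileext = ".graphml")
  write_graphml(net, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
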