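# shared fixtures and independent oracles

toy_counts <- function() {
  m <- matrix(c(5L, 0L, 3L,
                2L, 1L, 4L), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  m
}

tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# exhaustive nearest-neighbour betaMNTD, independent of the C++ path
brute_bmntd <- function(fx, fy, d) {
  fx <- fx[fx > 0]
  fy <- fy[fy > 0]
  fx <- fx / sum(fx)
  fy <- fy / sum(fy)
  s <- 0
  for (i in names(fx)) {
    s <- s + fx[[i]] * min(vapply(names(fy), function(j) d[i, j], numeric(1)))
  }
  for (j in names(fy)) {
    s <- s + fy[[j]] * min(vapply(names(fx), function(i) d[j, i], numeric(1)))
  }
  s / 2
}

# per-branch enumeration of weighted UniFrac via clade extraction,
# independent of the package's postorder incidence matrix
brute_wunifrac <- function(x, y, tree, normalized = TRUE) {
  nt <- length(tree$tip.label)
  px <- py <- stats::setNames(rep(0, nt), tree$tip.label)
  px[names(x)] <- x / sum(x)
  py[names(y)] <- y / sum(y)
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= nt) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    a <- sum(px[tips])
    b <- sum(py[tips])
    num <- num + tree$edge.length[e] * abs(a - b)
    den <- den + tree$edge.length[e] * (a + b)
  }
  if (normalized) num / den else num
}

# metacommunity-multinomial community table with no phylogenetic signal
exchangeable_table <- function(tree, meta, n_samples, reads, seed) {
  set.seed(seed)
  counts <- sapply(seq_len(n_samples), function(i)
    as.integer(stats::rmultinom(1, reads, meta[tree$tip.label])))
  dimnames(counts) <- list(tree$tip.label, sprintf("s%02d", seq_len(n_samples)))
  community_table(counts)
}
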