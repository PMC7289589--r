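#' Read a community table from TSV
#'
#' Reads a taxa-by-samples count table. The first column holds taxon ids,
#' the header row holds sample ids, and an optional trailing `taxonomy`
#' column holds Greengenes-style lineage strings
#' (`k__Bacteria; p__Chloroflexi; ...`), from which a phylum-level label is
#' parsed. Proteobacterial classes (e.g. Alphaproteobacteria) are promoted
#' to the phylum slot, matching common phylum/class reporting. Lines
#' starting with `#` are treated as comments, except a `#OTU ID` header in
#' `biom-tsv` exports.
#'
#' @param path path to a tab-separated file.
#' @param format `"tsv"` (plain, header is first non-comment line) or
#'   `"biom-tsv"` (classic BIOM text export whose header line starts with
#'   `#OTU ID`).
#' @return a [community_table].
#' @export
read_community <- function(path, format = c("tsv", "biom-tsv")) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "biom-tsv") {
    hdr <- grep("^#OTU", lines)
    .assert(length(hdr) >= 1, "biom-tsv file lacks a '#OTU ID' header line")
    lines <- c(sub("^#", "", lines[hdr[1]]),
               lines[-seq_len(hdr[1])])
  }
  lines <- lines[!startsWith(lines, "#")]
  .assert(length(lines) >= 2, "no data rows in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  sample_names <- header[-1]
  if (anyDuplicated(sample_names)) {
    stop(sprintf("duplicated sample id(s) in header: %s",
                 paste(unique(sample_names[duplicated(sample_names)]),
                       collapse = ", ")), call. = FALSE)
  }
  body <- fields[-1]
  .assert(all(lengths(body) == length(header)),
          "ragged rows: expected %d fields per line", length(header))
  taxa <- vapply(body, `[[`, character(1), 1L)
  cells <- do.call(rbind, lapply(body, function(f) f[-1]))
  taxonomy <- NULL
  tax_col <- which(tolower(sample_names) %in% c("taxonomy", "taxon", "lineage"))
  if (length(tax_col)) {
    taxonomy <- parse_taxonomy(cells[, tax_col[1]])
    names(taxonomy) <- taxa
    cells <- cells[, -tax_col, drop = FALSE]
    sample_names <- sample_names[-tax_col]
  }
  m <- suppressWarnings(matrix(as.numeric(cells), nrow = length(taxa),
                               dimnames = list(taxa, sample_names)))
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative or non-numeric count at taxon '%s', sample '%s'",
                 taxa[bad[1, 1]], sample_names[bad[1, 2]]), call. = FALSE)
  }
  community_table(m, taxonomy = taxonomy)
}

#' Parse Greengenes-style taxonomy strings to phylum/class labels
#'
#' @param x character vector of `k__; p__; c__; ...` lineage strings.
#' @return character vector of labels: the class for Proteobacteria, the
#'   phylum otherwise, falling back to the raw string when no prefixed
#'   field is found.
#' @export
parse_taxonomy <- function(x) {
  vapply(x, function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    get_rank <- function(prefix) {
      hit <- grep(paste0("^", prefix, "__"), parts, value = TRUE)
      if (!length(hit)) return("")
      sub(paste0("^", prefix, "__"), "", hit[1])
    }
    phylum <- get_rank("p")
    class <- get_rank("c")
    if (identical(phylum, "Proteobacteria") && nzchar(class)) return(class)
    if (nzchar(phylum)) return(phylum)
    if (nzchar(s)) s else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read a sample metadata table from TSV
#'
#' Expects a `sample_id` column plus categorical (`layer`, `treatment`) and
#' numeric environmental columns. `#` lines are comments.
#'
#' @param path path to a tab-separated file.
#' @return a data.frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  .assert("sample_id" %in% names(df), "sample table needs a 'sample_id' column")
  .assert(anyDuplicated(df$sample_id) == 0, "duplicate sample_id values")
  df
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Wraps [ape::read.tree] with validation: tip labels must be unique,
#' missing branch lengths are set to zero (with a warning) and negative
#' branch lengths are an error. A cheap parenthesis-balance scan runs
#' before parsing so that malformed files fail with a character offset.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf(
        "unbalanced ')' at character %d of %s", i, path), call. = FALSE)
    }
  }
  if (depth != 0L) stop(sprintf(
    "unbalanced '(' (%d unclosed) in %s", depth, path), call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop(sprintf(
                     "failed to parse Newick in %s: %s", path,
                     conditionMessage(e)), call. = FALSE))
  .assert(inherits(tree, "phylo"), "failed to parse Newick in %s", path)
  .assert(anyDuplicated(tree$tip.label) == 0, "duplicate tip labels")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning(sprintf("%d missing branch length(s) set to 0",
                    sum(is.na(tree$edge.length))))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  .assert(all(tree$edge.length >= 0), "negative branch lengths are not allowed")
  tree
}

#' Rarefy a community table to even depth
#'
#' Subsamples every sample (column) without replacement down to `depth`
#' reads, the standard normalization before null-model work. The default
#' depth matches rarefaction to the shallowest sample in a typical 16S
#' survey of this design (20,515 reads).
#'
#' @param table a [community_table].
#' @param depth target reads per sample; must not exceed any column sum.
#' @param seed integer seed for reproducible subsampling (NULL = use the
#'   current RNG state).
#' @return a [community_table] whose column sums all equal `depth`.
#' @export
rarefy <- function(table, depth = 20515, seed = NULL) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  .assert(length(depth) == 1 && depth >= 1, "depth must be a positive integer")
  depth <- as.integer(depth)
  totals <- colSums(table$counts)
  shallow <- totals < depth
  if (any(shallow)) {
    stop(sprintf("depth %d exceeds total reads in sample(s): %s", depth,
                 paste(colnames(table$counts)[shallow], collapse = ", ")),
         call. = FALSE)
  }
  out <- .with_seed(seed, {
    apply(table$counts, 2, function(x) {
      if (sum(x) == depth) return(as.integer(x))
      picked <- sample(rep.int(seq_along(x), x), depth)
      tabulate(picked, nbins = length(x))
    })
  })
  rownames(out) <- rownames(table$counts)
  community_table(out, taxonomy = table$taxonomy)
}

#' Filter taxa by prevalence within a sample group
#'
#' Keeps taxa detected (count > 0) in strictly more than
#' `min_fraction` of the group's samples; with the default 0.75 and 12
#' samples a taxon must occur in 10 or more of them. This is the standard
#' pre-filter before co-occurrence network construction.
#'
#' @param table a [community_table].
#' @param group_samples sample ids defining the group (default: all).
#' @param min_fraction prevalence threshold in (0, 1]; occurrence must be
#'   strictly greater than `min_fraction * length(group_samples)`.
#' @return a [community_table] restricted to the retained taxa (all
#'   samples are kept; subset columns separately if needed).
#' @export
prevalence_filter <- function(table, group_samples = NULL, min_fraction = 0.75) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  group_samples <- group_samples %||% sample_ids(table)
  .assert(length(group_samples) > 0, "empty sample group")
  .assert(all(group_samples %in% sample_ids(table)),
          "group_samples not all present in table")
  .assert(min_fraction >= 0 && min_fraction <= 1,
          "min_fraction must be in [0, 1]")
  occ <- rowSums(table$counts[, group_samples, drop = FALSE] > 0)
  keep <- occ > min_fraction * length(group_samples)
  subset_table(table, taxa = which(keep))
}

#' Alpha diversity of one sample
#'
#' Shannon entropy (natural log) and the Chao1 richness estimator. Chao1
#' defaults to the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, which is defined even when no
#' doubletons are observed; the classic `S_obs + F1^2 / (2 F2)` form is
#' available via `chao1_bias_corrected = FALSE`.
#'
#' @param counts non-negative count vector for one sample; must have a
#'   positive total.
#' @param chao1_bias_corrected use the bias-corrected Chao1 (default TRUE).
#' @return named list with `shannon` (nats) and `chao1`.
#' @export
alpha_diversity <- function(counts, chao1_bias_corrected = TRUE) {
  .assert(is.numeric(counts) && all(counts >= 0), "counts must be non-negative")
  .assert(sum(counts) > 0, "all-zero count vector")
  p <- counts[counts > 0] / sum(counts)
  shannon <- -sum(p * log(p))
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  chao1 <- if (chao1_bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f1 > 0) {
    if (f2 == 0) stop("classic Chao1 undefined with singletons but no doubletons",
                      call. = FALSE)
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs
  }
  list(shannon = shannon, chao1 = chao1)
}

#' Per-group environmental variation summaries
#'
#' Summarizes the overall spread of environmental variables within sample
#' groups (e.g. depth layers). Variables are z-scored on the full dataset;
#' per group the function reports the trace of the within-group
#' variance-covariance matrix of the z-scored variables, each sample's
#' squared distance to its group centroid (suitable for a box plot), and
#' the raw-scale coefficient of variation per variable.
#'
#' @param samples data.frame with `sample_id`, a grouping column and
#'   numeric environmental columns.
#' @param env_vars names of the environmental columns (default: all
#'   numeric columns other than the grouping column).
#' @param group_col name of the grouping column (default "layer").
#' @return list with `dispersion` (data.frame: group, n, dispersion),
#'   `sample_distances` (data.frame: sample_id, group, sq_distance) and
#'   `cv` (data.frame: group, variable, cv).
#' @export
env_variation <- function(samples, env_vars = NULL, group_col = "layer") {
  .assert(is.data.frame(samples), "samples must be a data.frame")
  .assert(group_col %in% names(samples), "missing grouping column '%s'", group_col)
  if (is.null(env_vars)) {
    num <- vapply(samples, is.numeric, logical(1))
    env_vars <- setdiff(names(samples)[num], group_col)
  }
  .assert(length(env_vars) >= 1, "no environmental variables found")
  env <- as.matrix(samples[, env_vars, drop = FALSE])
  .assert(all(is.finite(env)), "environmental values must be finite")
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant variable(s): %s",
                    paste(env_vars[sds == 0], collapse = ", ")))
    env <- env[, sds > 0, drop = FALSE]
    env_vars <- env_vars[sds > 0]
  }
  z <- scale(env)
  groups <- as.character(samples[[group_col]])
  tab <- table(groups)
  .assert(all(tab >= 2), "every group needs at least 2 samples")
  disp <- data.frame(group = names(tab), n = as.integer(tab),
                     dispersion = NA_real_, stringsAsFactors = FALSE)
  dists <- data.frame(sample_id = samples$sample_id, group = groups,
                      sq_distance = NA_real_, stringsAsFactors = FALSE)
  cvs <- expand.grid(group = names(tab), variable = env_vars,
                     stringsAsFactors = FALSE)
  cvs$cv <- NA_real_
  for (g in names(tab)) {
    idx <- groups == g
    zg <- z[idx, , drop = FALSE]
    disp$dispersion[disp$group == g] <- sum(diag(stats::cov(zg)))
    centroid <- colMeans(zg)
    dists$sq_distance[idx] <- rowSums(sweep(zg, 2, centroid)^2)
    for (v in env_vars) {
      raw <- env[idx, v]
      cvs$cv[cvs$group == g & cvs$variable == v] <-
        stats::sd(raw) / mean(raw)
    }
  }
  list(dispersion = disp, sample_distances = dists, cv = cvs)
}
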