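#' Run the full community-assembly analysis
#'
#' Orchestrates every stage over a sample grouping (typically depth
#' layers): environmental variation, alpha diversity, the
#' betaNTI / RC-bray assembly profile, beta-null deviations (Bray-Curtis
#' and, when a tree is supplied, weighted UniFrac), the Sloan neutral fit
#' and Levins' niche breadth per group, and a prevalence-filtered
#' co-occurrence network per group with topology and O/R statistics.
#' Stage failures are caught and recorded so independent stages still
#' run. Each stage draws its randomness from a sub-seed derived from
#' `seed` and the stage name, so adding or removing a stage never
#' perturbs another stage's results.
#'
#' @param table a [community_table] (rarefied counts).
#' @param samples data.frame with `sample_id` and the grouping column.
#' @param tree optional [ape::phylo]; required for the phylogenetic
#'   stages.
#' @param group_col grouping column in `samples` (default "layer").
#' @param reps null-model replicates (default 999).
#' @param B network permutations (default 1000).
#' @param prevalence network prevalence threshold (default 0.75).
#' @param r_cut,p_cut,bnti_cut,rc_cut decision thresholds.
#' @param pool species-pool convention for the nulls (see
#'   [assembly_profile]).
#' @param seed master seed.
#' @param stages character subset of
#'   `c("env", "alpha", "assembly", "betanull", "neutral", "breadth",
#'   "network")` to run (default all feasible).
#' @param out_dir optional directory; when given, stage outputs are
#'   written as TSV plus a JSON run manifest recording every parameter
#'   and seed.
#' @return list of stage results (`errors` collects failed stages) with
#'   a `manifest` element.
#' @export
run_assembly_pipeline <- function(table, samples, tree = NULL,
                                  group_col = "layer", reps = 999, B = 1000,
                                  prevalence = 0.75, r_cut = 0.6,
                                  p_cut = 0.01, bnti_cut = 2, rc_cut = 0.95,
                                  pool = c("metacommunity", "group"),
                                  seed = 1, stages = NULL,
                                  out_dir = NULL) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  .assert(group_col %in% names(samples), "samples lacks column '%s'", group_col)
  .assert(all(sample_ids(table) %in% samples$sample_id),
          "samples table does not cover all samples")
  pool <- match.arg(pool)
  all_stages <- c("env", "alpha", "assembly", "betanull", "neutral",
                  "breadth", "network")
  stages <- stages %||% all_stages
  .assert(all(stages %in% all_stages), "unknown stage requested")
  if (is.null(tree) && any(c("assembly", "betanull") %in% stages)) {
    stop("a phylogenetic tree is required for the assembly/betanull stages",
         call. = FALSE)
  }
  groups <- stats::setNames(
    as.character(samples[[group_col]][match(sample_ids(table),
                                            samples$sample_id)]),
    sample_ids(table))
  group_names <- unique(groups)
  res <- list(errors = list())
  run_stage <- function(name, expr) {
    if (!name %in% stages) return(invisible(NULL))
    out <- tryCatch(expr, error = function(e) {
      warning(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      res$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    res[[name]] <<- out
    invisible(NULL)
  }
  run_stage("env", env_variation(samples, group_col = group_col))
  run_stage("alpha", {
    data.frame(sample_id = sample_ids(table),
               group = unname(groups),
               t(vapply(sample_ids(table), function(s) {
                 a <- alpha_diversity(table$counts[, s])
                 c(shannon = a$shannon, chao1 = a$chao1)
               }, numeric(2))),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  run_stage("assembly",
            assembly_profile(table, tree, groups, reps = reps,
                             seed = .derive_seed(seed, "assembly"),
                             pool = pool, bnti_cut = bnti_cut,
                             rc_cut = rc_cut))
  run_stage("betanull", {
    out <- lapply(group_names, function(g) {
      sub <- subset_table(table, samples = names(groups)[groups == g])
      bc <- beta_null_deviation(sub, "bray_curtis", reps = reps,
                                seed = .derive_seed(seed, c("betanull", g)))
      wu <- beta_null_deviation(sub, "weighted_unifrac", tree = tree,
                                reps = reps,
                                seed = .derive_seed(seed, c("betanull-wu", g)))
      cbind(group = g, rbind(bc, wu))
    })
    do.call(rbind, out)
  })
  run_stage("neutral", {
    fits <- lapply(group_names, function(g) {
      sub <- subset_table(table, samples = names(groups)[groups == g])
      fit_sloan(sub)
    })
    names(fits) <- group_names
    fits
  })
  run_stage("breadth", {
    out <- lapply(group_names, function(g) {
      levins_breadth(table, samples = names(groups)[groups == g])
    })
    names(out) <- group_names
    out
  })
  run_stage("network", {
    nets <- lapply(group_names, function(g) {
      members <- names(groups)[groups == g]
      filtered <- prevalence_filter(table, group_samples = members,
                                    min_fraction = prevalence)
      filtered <- subset_table(filtered, samples = members)
      net <- tryCatch(
        build_network(filtered, r_cut = r_cut, p_cut = p_cut, B = B,
                      seed = .derive_seed(seed, c("network", g))),
        error = function(e) {
          warning(sprintf("network for group '%s' skipped: %s", g,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(net)) return(NULL)
      topo <- network_topology(net)
      orr <- if (igraph::ecount(net$graph) >= 1 &&
                 !is.null(net$graph) && !anyNA(igraph::V(net$graph)$phylum)) {
        or_ratio(net)
      } else NULL
      list(network = net, topology = topo, or_ratio = orr)
    })
    names(nets) <- group_names
    nets
  })
  res$manifest <- list(
    package = "ecoassembly",
    version = as.character(utils::packageVersion("ecoassembly")),
    n_taxa = nrow(table$counts), n_samples = ncol(table$counts),
    group_col = group_col, groups = unname(group_names),
    reps = reps, B = B, prevalence = prevalence, r_cut = r_cut,
    p_cut = p_cut, bnti_cut = bnti_cut, rc_cut = rc_cut, pool = pool,
    seed = seed, stages = stages,
    stage_seeds = stats::setNames(
      lapply(c("assembly", "betanull", "network"),
             function(s) .derive_seed(seed, s)),
      c("assembly", "betanull", "network")))
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$assembly)) {
    .write_tsv(res$assembly$pairs, file.path(out_dir, "assembly_pairs.tsv"))
    .write_tsv(res$assembly$fractions,
               file.path(out_dir, "assembly_fractions.tsv"))
  }
  if (!is.null(res$betanull)) {
    .write_tsv(res$betanull, file.path(out_dir, "beta_null_deviations.tsv"))
  }
  if (!is.null(res$alpha)) {
    .write_tsv(res$alpha, file.path(out_dir, "alpha_diversity.tsv"))
  }
  if (!is.null(res$env)) {
    .write_tsv(res$env$dispersion, file.path(out_dir, "env_dispersion.tsv"))
    .write_tsv(res$env$cv, file.path(out_dir, "env_cv.tsv"))
  }
  if (!is.null(res$neutral)) {
    .write_tsv(do.call(rbind, lapply(names(res$neutral), function(g) {
      f <- res$neutral[[g]]
      data.frame(group = g, m = f$m, N = f$N, r_squared = f$r_squared,
                 frac_within_ci = f$frac_within_ci)
    })), file.path(out_dir, "neutral_fits.tsv"))
  }
  if (!is.null(res$breadth)) {
    .write_tsv(do.call(rbind, lapply(names(res$breadth), function(g) {
      data.frame(group = g, sample_id = names(res$breadth[[g]]$B_com),
                 b_com = unname(res$breadth[[g]]$B_com))
    })), file.path(out_dir, "niche_breadth.tsv"))
  }
  if (!is.null(res$network)) {
    done <- names(res$network)[!vapply(res$network, is.null, logical(1))]
    if (length(done)) {
      topo <- do.call(rbind, lapply(done, function(g) {
        cbind(group = g, as.data.frame(res$network[[g]]$topology))
      }))
      .write_tsv(topo, file.path(out_dir, "network_topology.tsv"))
    }
    for (g in done) {
      .write_tsv(res$network[[g]]$network$edges,
                 file.path(out_dir, sprintf("network_edges_%s.tsv", g)))
      if (!is.null(res$network[[g]]$or_ratio)) {
        .write_tsv(res$network[[g]]$or_ratio,
                   file.path(out_dir, sprintf("or_ratio_%s.tsv", g)))
      }
    }
  }
  manifest_path <- file.path(out_dir, "run_manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(res$manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    writeLines(utils::capture.output(utils::str(res$manifest)), manifest_path)
  }
  invisible(res)
}
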