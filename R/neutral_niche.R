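#' Sloan neutral-model occurrence frequency
#'
#' Under the Sloan et al. neutral community model, a taxon with mean
#' metacommunity relative abundance `p` in local communities of `N`
#' individuals experiencing migration rate `m` has local relative
#' abundance distributed Beta(N m p, N m (1 - p)); its expected occurrence
#' frequency is the probability of exceeding the detection limit `d`
#' (default one read, `1/N`):
#' `freq = 1 - pbeta(d, N m p, N m (1 - p))`.
#'
#' @param p mean relative abundance(s), strictly inside (0, 1).
#' @param N community size (reads per sample).
#' @param m migration rate in (0, 1].
#' @param d detection limit (default `1/N`).
#' @return expected occurrence frequency in `[0, 1]`.
#' @export
sloan_predict <- function(p, N, m, d = 1 / N) {
  .assert(all(p > 0 & p < 1), "p must lie strictly in (0, 1)")
  .assert(N >= 1, "N must be >= 1")
  .assert(m > 0 && m <= 1, "m must lie in (0, 1]")
  1 - stats::pbeta(d, N * m * p, N * m * (1 - p))
}

# 95% Wilson score interval for a proportion estimated from n trials
.wilson_interval <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  cbind(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration rate `m` by nonlinear least squares of observed
#' occurrence frequencies (fraction of samples where each taxon is
#' detected) against [sloan_predict] at each taxon's mean relative
#' abundance. The table should be rarefied to a common depth, which is
#' taken as `N`. Fitting uses Levenberg-Marquardt least squares on
#' untransformed frequencies with multiple starting values, constrained to
#' `m` in (0, 1]. 95% Wilson score intervals around the predicted
#' frequencies (at `n` = number of samples) give the reported fraction of
#' taxa consistent with neutrality.
#'
#' @param table a [community_table], ideally rarefied (see [rarefy]).
#' @param N community size; default the median column sum (a warning is
#'   issued when column sums are unequal).
#' @return object of class `sloan_fit`: list with `m`, `N`, `r_squared`,
#'   `frac_within_ci`, `n_taxa_fit` and a per-taxon data.frame `taxa`
#'   (otu_id, p, freq_obs, freq_pred, ci_lower, ci_upper, within_ci).
#' @export
fit_sloan <- function(table, N = NULL) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  counts <- table$counts
  n_samples <- ncol(counts)
  .assert(n_samples >= 5, "need at least 5 samples")
  totals <- colSums(counts)
  if (is.null(N)) {
    N <- round(stats::median(totals))
    if (stats::sd(totals) > 0) {
      warning("column sums are unequal; using the median as N (rarefy first?)")
    }
  }
  rel <- sweep(counts, 2, totals, "/")
  p <- rowMeans(rel)
  freq <- rowMeans(counts > 0)
  keep <- p > 0 & p < 1
  p <- p[keep]
  freq <- freq[keep]
  if (all(freq >= 1)) {
    stop("saturated occupancy: every taxon occurs in every sample, m unidentifiable",
         call. = FALSE)
  }
  if (sum(freq > 0 & freq < 1) < 20) {
    warning("fewer than 20 taxa with intermediate occupancy; m estimate may be unstable")
  }
  d <- 1 / N
  sse <- function(m) sum((freq - sloan_predict(p, N, m, d))^2)
  fits <- lapply(c(0.01, 0.1, 0.5), function(start) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        freq ~ 1 - stats::pbeta(d, N * m * p, N * m * (1 - p)),
        start = list(m = start), lower = 1e-6, upper = 1,
        control = minpack.lm::nls.lm.control(maxiter = 200))
      stats::coef(fit)[["m"]]
    }, error = function(e) NA_real_)
  })
  cand <- unlist(fits)
  cand <- cand[is.finite(cand)]
  if (!length(cand)) { # fall back to bounded scalar minimization
    cand <- stats::optimize(sse, c(1e-6, 1))$minimum
  }
  m_hat <- cand[which.min(vapply(cand, sse, numeric(1)))]
  pred <- sloan_predict(p, N, m_hat, d)
  sse_val <- sum((freq - pred)^2)
  sst <- sum((freq - mean(freq))^2)
  r2 <- 1 - sse_val / sst
  ci <- .wilson_interval(pred, n_samples)
  within <- freq >= ci[, "lower"] & freq <= ci[, "upper"]
  taxa <- data.frame(otu_id = names(p), p = p, freq_obs = freq,
                     freq_pred = pred, ci_lower = ci[, "lower"],
                     ci_upper = ci[, "upper"], within_ci = within,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(m = unname(m_hat), N = N, r_squared = r2,
                 frac_within_ci = mean(within), n_taxa_fit = length(p),
                 n_samples = n_samples, taxa = taxa),
            class = "sloan_fit")
}

#' @export
print.sloan_fit <- function(x, ...) {
  cat(sprintf(
    "Sloan neutral model fit: m = %.4f, N = %d, R^2 = %.3f\n%d taxa, %.1f%% within the 95%% Wilson interval\n",
    x$m, as.integer(x$N), x$r_squared, x$n_taxa_fit,
    100 * x$frac_within_ci))
  invisible(x)
}

#' Levins' habitat niche breadth
#'
#' For each taxon `j`, `P_ij` is the fraction of taxon j's individuals
#' found in community `i` (so `sum_i P_ij = 1`), and Levins' breadth is
#' `B_j = 1 / sum_i P_ij^2`, ranging from 1 (confined to one community) to
#' the number of communities (spread evenly). The community-level breadth
#' `B_com` of sample `i` is the unweighted mean of `B_j` over the taxa
#' occurring in `i`. An alternative convention normalizing within each
#' community (`P_ij` = taxon j's relative abundance in community i) is
#' available via `convention = "within_community"`.
#'
#' @param table a [community_table].
#' @param samples optional sample ids defining the communities evaluated
#'   (default: all samples).
#' @param convention `"taxon_total"` (default, Levins' original) or
#'   `"within_community"`.
#' @return list with `B` (named per-taxon breadth; taxa absent from the
#'   group are excluded) and `B_com` (named per-community mean breadth).
#' @export
levins_breadth <- function(table, samples = NULL,
                           convention = c("taxon_total", "within_community")) {
  .assert(inherits(table, "community_table"), "table must be a community_table")
  convention <- match.arg(convention)
  samples <- samples %||% sample_ids(table)
  counts <- table$counts[, samples, drop = FALSE]
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  .assert(nrow(counts) > 0, "no taxa present in the sample group")
  p <- if (convention == "taxon_total") {
    sweep(counts, 1, rowSums(counts), "/")
  } else {
    sweep(counts, 2, colSums(counts), "/")
  }
  b <- 1 / rowSums(p^2)
  b_com <- vapply(seq_len(ncol(counts)), function(i) {
    present <- counts[, i] > 0
    if (!any(present)) return(NA_real_)
    mean(b[present])
  }, numeric(1))
  names(b_com) <- colnames(counts)
  list(B = b, B_com = b_com)
}
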