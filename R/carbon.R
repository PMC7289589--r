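#' Biolog EcoPlate OD container
#'
#' Holds blank-inclusive OD590 readings for the 31 carbon-source wells of
#' an EcoPlate plus the water blank, across incubation timepoints, with a
#' substrate-guild label per well (carbohydrates, carboxylic acids, amino
#' acids, polymers, phenolic acids, amines).
#'
#' @param od numeric matrix, wells x timepoints; rownames are well ids,
#'   colnames are hours (coercible to numeric, strictly increasing).
#' @param guild named character vector assigning each substrate well to a
#'   guild; wells not named here (exactly one) form the blank.
#' @param blank id of the blank well (default `"blank"`).
#' @return object of class `biolog_plate`.
#' @export
biolog_plate <- function(od, guild, blank = "blank") {
  od <- as.matrix(od)
  .assert(!is.null(rownames(od)), "od needs well ids as rownames")
  .assert(blank %in% rownames(od), "blank well '%s' missing", blank)
  substrates <- setdiff(rownames(od), blank)
  .assert(length(substrates) == 31,
          "expected 31 substrate wells, got %d", length(substrates))
  .assert(all(substrates %in% names(guild)), "every substrate well needs a guild")
  hours <- suppressWarnings(as.numeric(colnames(od)))
  .assert(!anyNA(hours), "column names must be numeric hours")
  .assert(all(diff(hours) > 0), "timepoints must be strictly increasing")
  structure(list(od = od, guild = guild[substrates], blank = blank,
                 hours = hours),
            class = "biolog_plate")
}

#' Average well colour development (AWCD)
#'
#' Blank-corrects each substrate well at the requested timepoint
#' (`OD_well - OD_blank`, negatives clamped to 0, standard Biolog
#' practice), then averages over all 31 wells and within each substrate
#' guild. Readings at 96 h, where colour development plateaus, are the
#' conventional summary.
#'
#' @param plate a [biolog_plate].
#' @param at_hours timepoint to evaluate (default 96).
#' @return list with `awcd_total`, `awcd_per_guild` (named) and
#'   `at_hours`.
#' @export
awcd <- function(plate, at_hours = 96) {
  .assert(inherits(plate, "biolog_plate"), "plate must be a biolog_plate")
  col <- which(plate$hours == at_hours)
  if (!length(col)) {
    stop(sprintf("timepoint %s h not measured; available: %s", at_hours,
                 paste(plate$hours, collapse = ", ")), call. = FALSE)
  }
  substrates <- names(plate$guild)
  corrected <- plate$od[substrates, col] - plate$od[plate$blank, col]
  corrected <- pmax(corrected, 0)
  list(awcd_total = mean(corrected),
       awcd_per_guild = tapply(corrected, plate$guild, mean),
       at_hours = at_hours)
}

#' Cumulative SOC mineralization series
#'
#' @param t incubation days, strictly increasing.
#' @param Ct cumulative CO2-C (mg per kg soil), non-negative; a warning
#'   (not an error) is raised if not non-decreasing, since titration noise
#'   can produce small reversals.
#' @return object of class `mineralization_series` (data.frame t, Ct).
#' @export
mineralization_series <- function(t, Ct) {
  .assert(length(t) == length(Ct), "t and Ct must have equal length")
  .assert(all(diff(t) > 0), "t must be strictly increasing")
  .assert(all(Ct >= 0), "Ct must be non-negative")
  if (any(diff(Ct) < 0)) {
    warning("cumulative CO2-C is not non-decreasing; check the series")
  }
  structure(data.frame(t = t, Ct = Ct),
            class = c("mineralization_series", "data.frame"))
}

#' Fit first-order SOC mineralization kinetics
#'
#' Fits `C_t = C_0 (1 - exp(-k t))` by Levenberg-Marquardt nonlinear least
#' squares, where `C_0` (mg per kg) is the potentially mineralizable
#' carbon pool and `k` (per day) the mineralization rate constant.
#' Initialization is deterministic: `C_0 = 1.1 max(Ct)` and `k` from a
#' through-origin log-linear regression of `-log(1 - Ct / C_0)` on `t`, so
#' repeated fits are identical.
#'
#' @param series a [mineralization_series] (or data.frame with `t`, `Ct`),
#'   at least 4 timepoints.
#' @return list with `C0`, `k`, `residual_norm` and `fitted`.
#' @export
fit_mineralization <- function(series) {
  .assert(is.data.frame(series) && all(c("t", "Ct") %in% names(series)),
          "series needs columns t and Ct")
  t <- series$t
  Ct <- series$Ct
  .assert(length(t) >= 4, "need at least 4 timepoints")
  .assert(all(Ct >= 0), "Ct must be non-negative")
  c0_init <- 1.1 * max(Ct)
  frac <- pmax(1 - Ct / c0_init, 1e-6)
  k_init <- max(-stats::coef(stats::lm(log(frac) ~ t - 1))[[1]], 1e-4)
  fit <- tryCatch(
    minpack.lm::nlsLM(Ct ~ C0 * (1 - exp(-k * t)),
                      start = list(C0 = c0_init, k = k_init),
                      lower = c(1e-8, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop(sprintf(
      "mineralization fit failed to converge (start C0 = %.3g, k = %.3g): %s",
      c0_init, k_init, conditionMessage(e)), call. = FALSE))
  est <- stats::coef(fit)
  list(C0 = est[["C0"]], k = est[["k"]],
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       fitted = stats::fitted(fit))
}
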