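#' Fit a spike-in calibration curve
#'
#' Ordinary least squares of the replicate-averaged `log10(LFQ)` signal on
#' `log10(known concentration)` over the detected standard proteins. The
#' replicate average is taken in log space; standard proteins with no
#' nonzero replicate are excluded. The fitted line maps instrument signal
#' to molar concentration over the standard's dynamic range.
#'
#' @param standard a [spikein_standard()].
#' @param measurements LFQ matrix, standard proteins x replicates (zeros
#'   and `NA` treated as not detected).
#' @return object of class `calibration_model`: `slope`, `intercept`
#'   (log10 space), `r_squared`, `valid_range` (molar), `n_points`.
#' @export
fit_calibration <- function(standard, measurements) {
  stopifnot(inherits(standard, "spikein_standard"))
  measurements <- as.matrix(measurements)
  if (nrow(measurements) != length(standard$protein_ids))
    stop("measurements must have one row per standard protein")
  log_lfq <- apply(measurements, 1L, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(log10(v)) else NA_real_
  })
  detected <- !is.na(log_lfq)
  if (sum(detected) < 3L)
    stop("need at least 3 detected standard proteins to fit a calibration")
  log_conc <- log10(standard$known_concentration[detected])
  y <- log_lfq[detected]
  fit <- stats::lm(y ~ log_conc)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = r2,
    valid_range = range(standard$known_concentration[detected]),
    n_points = sum(detected)
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "calibration: log10(LFQ) = %.4f + %.4f * log10(conc), r2 = %.4f (%d points, range %g-%g)\n",
    x$intercept, x$slope, x$r_squared, x$n_points,
    x$valid_range[1L], x$valid_range[2L]))
  invisible(x)
}

#' Estimate molar concentrations from LFQ signal
#'
#' Inverts the calibration line: `conc = 10^((log10(LFQ) - intercept) /
#' slope)`. Zero or missing signal is a non-detect (`NA` concentration);
#' estimates outside the standard's concentration range are flagged as
#' extrapolated.
#'
#' @param model a [fit_calibration()] result.
#' @param lfq numeric vector or matrix of LFQ signal.
#' @return data.frame with `lfq`, `concentration` and `extrapolated`.
#' @export
estimate_concentration <- function(model, lfq) {
  stopifnot(inherits(model, "calibration_model"))
  v <- as.numeric(lfq)
  conc <- rep(NA_real_, length(v))
  det <- !is.na(v) & v > 0
  conc[det] <- 10^((log10(v[det]) - model$intercept) / model$slope)
  extrap <- !is.na(conc) &
    (conc < model$valid_range[1L] | conc > model$valid_range[2L])
  data.frame(lfq = v, concentration = conc, extrapolated = extrap)
}

#' Per-group concentration mean and SD
#'
#' Summarizes estimated concentrations per group, excluding non-detects.
#'
#' @param concentration numeric vector (non-detects as `NA`).
#' @param groups factor with levels case/control.
#' @return one-row data.frame with mean and SD per group and detect counts.
#' @export
concentration_summary <- function(concentration, groups) {
  groups <- as.factor(groups)
  one <- function(g) {
    v <- concentration[groups == g]
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
      n = length(v))
  }
  a <- one(levels(groups)[1L]); b <- one(levels(groups)[2L])
  data.frame(conc_mean_case = a["mean"], conc_sd_case = a["sd"],
             n_detect_case = a["n"],
             conc_mean_control = b["mean"], conc_sd_control = b["sd"],
             n_detect_control = b["n"], row.names = NULL)
}
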