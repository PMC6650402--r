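#' Extract decay-corrected per-ROI uptake series from a PSL stack
#'
#' For each frame and each ROI label: the ROI mean of [psl_to_dose()] over
#' pixels, divided by the frame duration (nGy/pixel/min), multiplied by the
#' frame's [decay_correction_factor()]. The ROI statistic is the mean over
#' pixels (per-pixel normalization makes the value independent of ROI
#' size for homogeneous tissue); no background subtraction is applied.
#'
#' Integer PSL images may contain values below the plate's representable
#' floor (e.g. zeros); these are clamped to `floor_psl` before conversion
#' so that they do not encode spurious small doses.
#'
#' @param stack An [image_stack()].
#' @param roi_mask Integer label matrix, same shape as the frames; 0 =
#'   outside any ROI.
#' @param calib A [plate_calibration()].
#' @param nuclide A [nuclide()].
#' @param reference_min Decay-correction reference time (default 0, the
#'   start of incubation).
#' @param floor_psl Minimum PSL before conversion (default 1).
#' @param labels ROI labels to extract; defaults to all positive labels in
#'   the mask. Requesting a label with no pixels is an error naming it.
#' @return A data frame of class `uptake_series` with columns `roi`,
#'   `frame`, `start_min`, `mid_min`, `duration_min`, `uptake`
#'   (decay-corrected nGy/pixel/min), and `n_pixels`.
#' @export
extract_uptake_series <- function(stack, roi_mask,
                                  calib = plate_calibration(),
                                  nuclide = bioradr::nuclide(),
                                  reference_min = 0, floor_psl = 1,
                                  labels = NULL) {
  if (!inherits(stack, "image_stack"))
    stop_input("'stack' must be an image_stack")
  calib <- as_plate_calibration(calib)
  nuclide <- as_nuclide(nuclide)
  if (!is.matrix(roi_mask) ||
      !identical(dim(roi_mask), dim(stack$frames[[1]])))
    stop_input("'roi_mask' shape (%s) does not match frames (%s)",
               paste(dim(roi_mask), collapse = "x"),
               paste(dim(stack$frames[[1]]), collapse = "x"))
  if (is.null(labels)) labels <- sort(unique(roi_mask[roi_mask > 0]))
  if (length(labels) == 0L) stop_input("mask contains no ROI labels")
  roi_idx <- lapply(labels, function(l) which(roi_mask == l))
  empty <- vapply(roi_idx, length, integer(1)) == 0L
  if (any(empty))
    stop_input("ROI label(s) %s have no pixels",
               paste(labels[empty], collapse = ", "))

  sched <- stack$schedule
  dcf <- decay_correction_factor(sched$start_min, sched$duration_min,
                                 nuclide, reference_min)
  out <- vector("list", nrow(sched))
  for (f in seq_len(nrow(sched))) {
    frame <- stack$frames[[f]]
    means <- vapply(roi_idx, function(ii) {
      mean(psl_to_dose(pmax(as.numeric(frame[ii]), floor_psl), calib))
    }, numeric(1))
    out[[f]] <- data.frame(
      roi = labels, frame = f,
      start_min = sched$start_min[f], mid_min = sched$mid_min[f],
      duration_min = sched$duration_min[f],
      uptake = means / sched$duration_min[f] * dcf[f],
      n_pixels = vapply(roi_idx, length, integer(1)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$roi, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("uptake_series", "data.frame")
  res
}

#' Fit an irreversible uptake rate to a decay-corrected series
#'
#' Ordinary least squares of decay-corrected uptake (nGy/pixel/min) on
#' frame midpoint time. With irreversible trapping and decay-corrected
#' frame values the series is linear in time, and the slope — reported in
#' delta-nGy/pixel/min per minute of incubation — is the tissue's uptake
#' rate, the viability/metabolism readout. The frame midpoint is used as
#' the regression abscissa (decay correction makes the corrected value the
#' window-average trapped amount); `time_col` can be switched to
#' `"start_min"` for sensitivity checks.
#'
#' @param series A single-ROI `uptake_series` (or any data frame with the
#'   time and uptake columns), or a numeric vector of times when `uptake`
#'   is given.
#' @param uptake Numeric uptake values if `series` is a numeric time
#'   vector.
#' @param time_col,uptake_col Column names when `series` is a data frame.
#' @return An object of class `uptake_fit`: coefficients (intercept,
#'   slope), slope standard error, r-squared, n_frames, fitted values and
#'   residuals. Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals`, `fitted`.
#' @export
#' @examples
#' t <- seq(22.5, 382.5, by = 60)
#' fit <- fit_uptake_rate(t, 0.002 * t + 0.1)
#' coef(fit)["slope"]  # 0.002
fit_uptake_rate <- function(series, uptake = NULL, time_col = "mid_min",
                            uptake_col = "uptake") {
  if (is.data.frame(series)) {
    if (!is.null(series$roi) && length(unique(series$roi)) > 1)
      stop_input("'series' contains %d ROIs; use fit_uptake_rates()",
                 length(unique(series$roi)))
    x <- series[[time_col]]
    y <- series[[uptake_col]]
    if (is.null(x) || is.null(y))
      stop_input("'series' lacks columns '%s'/'%s'", time_col, uptake_col)
  } else {
    x <- series
    y <- uptake
  }
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop_input("times and uptake must be numeric vectors of equal length")
  if (length(x) < 2) stop_input("need at least 2 frames to fit a rate")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_input("times and uptake must be finite")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop_input("frame times have zero variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  resid <- y - fitted
  n <- length(x)
  ssr <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  se <- if (n > 2) sqrt(ssr / (n - 2) / sxx) else NA_real_
  r2 <- if (sst <= 0) 0 else 1 - ssr / sst
  structure(list(coefficients = c(intercept = intercept, slope = slope),
                 slope_se = se,
                 r_squared = max(0, min(1, r2)),
                 n_frames = n,
                 time = x, uptake = y,
                 fitted.values = fitted, residuals = resid),
            class = "uptake_fit")
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat("Uptake rate fit (", x$n_frames, "frames )\n")
  cat(sprintf("  rate: %.6g delta-nGy/pixel/min per min (SE %.3g)\n",
              x$coefficients["slope"], x$slope_se))
  cat(sprintf("  intercept: %.6g nGy/pixel/min, r^2 = %.4f\n",
              x$coefficients["intercept"], x$r_squared))
  invisible(x)
}

#' @export
summary.uptake_fit <- function(object, ...) {
  structure(list(coefficients = object$coefficients,
                 slope_se = object$slope_se,
                 r_squared = object$r_squared,
                 n_frames = object$n_frames,
                 residual_sd = stats::sd(object$residuals)),
            class = "summary.uptake_fit")
}

#' @export
print.summary.uptake_fit <- function(x, ...) {
  cat("Uptake rate fit summary\n")
  cat(sprintf("  slope     %.6g +/- %.3g (SE), n = %d frames\n",
              x$coefficients["slope"], x$slope_se, x$n_frames))
  cat(sprintf("  intercept %.6g\n", x$coefficients["intercept"]))
  cat(sprintf("  r^2 = %.4f, residual sd = %.3g\n",
              x$r_squared, x$residual_sd))
  invisible(x)
}

#' @export
coef.uptake_fit <- function(object, ...) object$coefficients

#' @export
predict.uptake_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time
  else if (is.numeric(newdata)) newdata
  else newdata$mid_min %||% stop_input("'newdata' lacks times")
  object$coefficients["intercept"] + object$coefficients["slope"] * t
}

#' @export
residuals.uptake_fit <- function(object, ...) object$residuals

#' @export
fitted.uptake_fit <- function(object, ...) object$fitted.values

#' @export
plot.uptake_fit <- function(x, xlab = "incubation time (min)",
                            ylab = "uptake (nGy/pixel/min)", ...) {
  graphics::plot(x$time, x$uptake, xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$coefficients["intercept"], x$coefficients["slope"])
  invisible(x)
}

#' Fit uptake rates for every ROI in an uptake series table
#'
#' @param series An `uptake_series` data frame (see
#'   [extract_uptake_series()]).
#' @inheritParams fit_uptake_rate
#' @return A data frame with one row per ROI: `roi`, `slope`
#'   (delta-nGy/pixel/min per min), `intercept`, `slope_se`, `r_squared`,
#'   `n_frames`.
#' @export
fit_uptake_rates <- function(series, time_col = "mid_min",
                             uptake_col = "uptake") {
  if (!is.data.frame(series) || is.null(series$roi))
    stop_input("'series' must be a data frame with a 'roi' column")
  rois <- unique(series$roi)
  do.call(rbind, lapply(rois, function(r) {
    f <- fit_uptake_rate(series[series$roi == r, , drop = FALSE],
                         time_col = time_col, uptake_col = uptake_col)
    data.frame(roi = r, slope = unname(coef(f)["slope"]),
               intercept = unname(coef(f)["intercept"]),
               slope_se = f$slope_se, r_squared = f$r_squared,
               n_frames = f$n_frames)
  }))
}

#' Express per-condition uptake rates as percent of control
#'
#' Group means relative to the control group mean, with the SEM propagated
#' by the delta method for a ratio of independent means.
#'
#' @param rates Data frame with one row per ROI containing a condition
#'   label column and a value column (typically the output of
#'   [fit_uptake_rates()] merged with a design table).
#' @param control Label of the control condition.
#' @param condition_col,value_col Column names.
#' @return A data frame with one row per condition: `condition`, `n`,
#'   `mean`, `sem`, `percent` (100 x group mean / control mean) and
#'   `percent_sem`.
#' @export
relative_to_control <- function(rates, control = "control",
                                condition_col = "condition",
                                value_col = "slope") {
  if (!is.data.frame(rates) || is.null(rates[[condition_col]]) ||
      is.null(rates[[value_col]]))
    stop_input("'rates' must contain columns '%s' and '%s'",
               condition_col, value_col)
  conds <- unique(rates[[condition_col]])
  if (!control %in% conds)
    stop_input("control group '%s' not present", control)
  grp <- split(rates[[value_col]], rates[[condition_col]])
  stat <- function(v) {
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }
  s <- vapply(grp, stat, numeric(3))
  m0 <- s["mean", control]
  s0 <- s["sem", control]
  if (!is.finite(m0) || m0 == 0)
    stop_input("control group mean is zero; percentages undefined")
  out <- data.frame(
    condition = conds,
    n = s["n", conds],
    mean = s["mean", conds],
    sem = s["sem", conds],
    percent = 100 * s["mean", conds] / m0,
    percent_sem = 100 * sqrt((s["sem", conds] / m0)^2 +
                               (s["mean", conds] * s0 / m0^2)^2),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tissue thickness map from background attenuation
#'
#' Tissue lying between the radioactive medium and the plate attenuates
#' the ambient signal; comparing a no-tissue (background) image with a
#' no-uptake tissue image (at time zero) therefore yields a per-pixel
#' transmission measurement, analogous to the attenuation correction from
#' transmission data in PET. Thickness is
#' `t = ln(D_background / D_tissue) / mu` after PSL-to-dose conversion.
#'
#' @param background_psl PSL matrix of the no-tissue exposure.
#' @param tissue_psl PSL matrix of the no-uptake (time-zero) tissue
#'   exposure, same shape.
#' @param calib A [plate_calibration()].
#' @param mu_per_um Linear attenuation coefficient per micrometre (> 0).
#' @param floor_psl Minimum PSL before conversion (default 1).
#' @return Matrix of thickness in micrometres. Pixels where the tissue
#'   dose meets or exceeds the background report 0; pixels with
#'   non-positive background dose are undefined and returned as `NA`.
#' @export
attenuation_thickness_map <- function(background_psl, tissue_psl,
                                      calib = plate_calibration(),
                                      mu_per_um, floor_psl = 1) {
  calib <- as_plate_calibration(calib)
  check_scalar(mu_per_um, "mu_per_um")
  if (mu_per_um <= 0) stop_input("'mu_per_um' must be > 0")
  if (!is.matrix(background_psl) || !is.matrix(tissue_psl) ||
      !identical(dim(background_psl), dim(tissue_psl)))
    stop_input("background and tissue images must be matrices of the same shape")
  db <- psl_to_dose(pmax(as.numeric(background_psl), floor_psl), calib)
  dt <- psl_to_dose(pmax(as.numeric(tissue_psl), floor_psl), calib)
  th <- log(db / dt) / mu_per_um
  th[dt >= db] <- 0
  th[!is.finite(db) | db <= 0] <- NA_real_
  matrix(th, nrow(background_psl), ncol(background_psl))
}
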