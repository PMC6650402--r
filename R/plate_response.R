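#' Radioluminography plate calibration
#'
#' The storage-phosphor (radioluminography) plate records photostimulated
#' luminescence (PSL) that is *logarithmic* in absorbed dose: PSL saturates
#' at high radioactivity while the underlying dose keeps growing linearly.
#' The manufacturer calibration converts a PSL reading into an 80 kV
#' X-ray-equivalent dose in nGy:
#'
#' \deqn{\mathrm{nGy} = s \times 10^{\,(PSL - o)/d \; - \; \log_{10} r}}
#'
#' with dose scale \eqn{s}, PSL offset \eqn{o}, PSL per decade \eqn{d} and
#' sensitivity ratio \eqn{r}. The defaults are the manufacturer constants
#' for the plate family used in dynamic FDG bioradiography
#' (8770 nGy, 1535 PSL, 1024 PSL/decade, ratio 1.25). `log 1.25` is base-10:
#' the formula is written in decades via the `/1024` term.
#'
#' @param dose_scale Dose scale \eqn{s} in nGy. Default 8770.
#' @param psl_offset PSL offset \eqn{o}. Default 1535.
#' @param psl_per_decade PSL per decade of dose \eqn{d}. Default 1024.
#' @param sensitivity_ratio Dimensionless sensitivity ratio \eqn{r \ge 1}.
#'   Default 1.25.
#' @return An object of class `plate_calibration`.
#' @seealso [psl_to_dose()], [dose_to_psl()]
#' @export
#' @examples
#' calib <- plate_calibration()
#' psl_to_dose(1535, calib)  # 8770 / 1.25
plate_calibration <- function(dose_scale = 8770, psl_offset = 1535,
                              psl_per_decade = 1024, sensitivity_ratio = 1.25) {
  for (nm in c("dose_scale", "psl_offset", "psl_per_decade", "sensitivity_ratio")) {
    v <- check_scalar(get(nm), nm)
    if (v <= 0) stop_input("'%s' must be strictly positive", nm)
  }
  if (sensitivity_ratio < 1)
    stop_input("'sensitivity_ratio' must be >= 1")
  structure(list(dose_scale = as.numeric(dose_scale),
                 psl_offset = as.numeric(psl_offset),
                 psl_per_decade = as.numeric(psl_per_decade),
                 sensitivity_ratio = as.numeric(sensitivity_ratio)),
            class = "plate_calibration")
}

#' @export
print.plate_calibration <- function(x, ...) {
  cat("Plate calibration: nGy =", x$dose_scale,
      "x 10^((PSL -", x$psl_offset, ") /", x$psl_per_decade,
      "- log10(", x$sensitivity_ratio, "))\n")
  invisible(x)
}

as_plate_calibration <- function(x) {
  if (inherits(x, "plate_calibration")) return(x)
  if (is.list(x)) return(do.call(plate_calibration, x))
  stop_input("cannot interpret object of class '%s' as a plate calibration",
             class(x)[1])
}

#' Convert PSL readings to 80 kV X-ray-equivalent dose
#'
#' Applies the plate's logarithmic response formula (see
#' [plate_calibration()]). The conversion is strictly increasing and convex
#' in PSL, which is what linearizes the saturating PSL-vs-activity curves.
#'
#' Image pixels arriving as 16-bit integers may contain zeros below the
#' plate's representable floor; the image-ingestion path
#' ([extract_uptake_series()]) clamps those to a configurable minimum PSL
#' before calling this function. The scalar conversion itself is exact and
#' unclamped so that `psl_to_dose(dose_to_psl(d)) == d` for all `d > 0`.
#'
#' @param psl Numeric vector of PSL values (finite).
#' @param calib A [plate_calibration()].
#' @return Dose in nGy, same shape as `psl`; always strictly positive.
#' @export
psl_to_dose <- function(psl, calib = plate_calibration()) {
  calib <- as_plate_calibration(calib)
  if (!is.numeric(psl) || length(psl) == 0L)
    stop_input("'psl' must be numeric")
  if (any(!is.finite(psl)))
    stop_input("'psl' contains non-finite values")
  psl <- as.numeric(psl)
  calib$dose_scale *
    10^((psl - calib$psl_offset) / calib$psl_per_decade -
          log10(calib$sensitivity_ratio))
}

#' Convert dose to PSL (inverse plate response)
#'
#' Exact algebraic inverse of [psl_to_dose()]. Used by the phantom
#' simulator to render plate readouts; it also explains why raw PSL
#' saturates: a tenfold dose increase adds only `psl_per_decade` PSL.
#'
#' @param dose Dose in nGy; must be strictly positive.
#' @inheritParams psl_to_dose
#' @return PSL values, same shape as `dose`.
#' @export
dose_to_psl <- function(dose, calib = plate_calibration()) {
  calib <- as_plate_calibration(calib)
  if (!is.numeric(dose) || length(dose) == 0L)
    stop_input("'dose' must be numeric")
  if (any(!is.finite(dose)) || any(dose <= 0))
    stop_input("'dose' must be finite and strictly positive")
  calib$psl_offset + calib$psl_per_decade *
    (log10(dose / calib$dose_scale) + log10(calib$sensitivity_ratio))
}

#' Normalize an ROI total to a per-pixel-per-minute rate
#'
#' @param total Summed quantity over an ROI (PSL or nGy).
#' @param n_pixels Number of pixels in the ROI (>= 1).
#' @param exposure_min Exposure duration in minutes (> 0).
#' @return `total / (n_pixels * exposure_min)`.
#' @export
normalize_rate <- function(total, n_pixels, exposure_min) {
  if (!is.numeric(total) || any(!is.finite(total)))
    stop_input("'total' must be finite numeric")
  check_scalar(n_pixels, "n_pixels")
  check_scalar(exposure_min, "exposure_min")
  if (n_pixels < 1) stop_input("'n_pixels' must be >= 1")
  if (exposure_min <= 0) stop_input("'exposure_min' must be > 0")
  total / (n_pixels * exposure_min)
}
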