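#' Phantom specification for the multiwell imaging simulator
#'
#' Describes a plate of disc-shaped tissue wells (the 12-mm holes of the
#' imaging chamber), the ambient background, the noise model and the
#' rendering parameters used by [simulate_stack()].
#'
#' The background is the ambient dose rate from the radioactive medium
#' surrounding the tissues; it decays with the nuclide, so after decay
#' correction it contributes a constant offset to every frame.
#' `background_dose_rate` is its value at time zero.
#'
#' @param wells List of well entries, each a list with elements `center`
#'   (c(row, col) in pixels), `radius_px`, `condition` (a
#'   [well_condition()]), and optionally `label` and `viability` (ground
#'   truth viability fraction; defaults to the condition's viable cell
#'   density). [well_grid()] builds this list for factorial designs. May
#'   be empty (background-only plate).
#' @param image_shape c(rows, cols) in pixels; by default just large
#'   enough to hold the wells plus a 4-px margin.
#' @param pixel_size_um Pixel edge length in micrometres (default 350).
#' @param background_dose_rate Ambient dose rate at time zero in
#'   nGy/pixel/min (default 120).
#' @param noise_scale Latent photons per nGy for the Poisson noise model
#'   (default 0.5); `Inf` disables noise (expected-value rendering).
#' @param mu_per_um Linear attenuation coefficient of tissue per
#'   micrometre (default 0.002); tissue of thickness t attenuates the
#'   ambient background reaching the plate by exp(-mu t).
#' @param base_rate_per_MBq Passed to [trapping_rate()] (default 37.5).
#' @param seed Integer seed used by [simulate_stack()] unless overridden.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(wells, image_shape = NULL, pixel_size_um = 350,
                         background_dose_rate = 120, noise_scale = 0.5,
                         mu_per_um = 0.002, base_rate_per_MBq = 37.5,
                         seed = NULL) {
  if (!is.list(wells)) stop_input("'wells' must be a list")
  wells <- lapply(seq_along(wells), function(i) {
    w <- wells[[i]]
    if (is.null(w$center) || length(w$center) != 2L)
      stop_input("well %d lacks a center = c(row, col)", i)
    w$radius_px <- w$radius_px %||% 17
    if (!inherits(w$condition, "well_condition"))
      stop_input("well %d lacks a well_condition", i)
    w$label <- w$label %||% sprintf("well%d", i)
    w$viability <- w$viability %||% w$condition$viable_cell_density
    w
  })
  if (is.null(image_shape)) {
    if (length(wells) == 0L) {
      image_shape <- c(64, 64)
    } else {
      mx <- vapply(wells, function(w) w$center + w$radius_px, numeric(2))
      image_shape <- ceiling(c(max(mx[1, ]), max(mx[2, ])) + 4)
    }
  }
  image_shape <- as.integer(image_shape)
  for (w in wells) {
    if (any(w$center - w$radius_px < 1) ||
        w$center[1] + w$radius_px > image_shape[1] ||
        w$center[2] + w$radius_px > image_shape[2])
      stop_input("well '%s' does not fit inside the %d x %d image",
                 w$label, image_shape[1], image_shape[2])
  }
  if (length(wells) > 1) {
    for (i in seq_len(length(wells) - 1)) for (j in (i + 1):length(wells)) {
      d <- sqrt(sum((wells[[i]]$center - wells[[j]]$center)^2))
      if (d < wells[[i]]$radius_px + wells[[j]]$radius_px)
        stop_input("wells '%s' and '%s' overlap",
                   wells[[i]]$label, wells[[j]]$label)
    }
  }
  for (nm in c("pixel_size_um", "background_dose_rate", "mu_per_um",
               "base_rate_per_MBq")) {
    v <- check_scalar(get(nm), nm)
    if (v < 0) stop_input("'%s' must be non-negative", nm)
  }
  check_scalar(noise_scale, "noise_scale", allow_inf = TRUE)
  if (noise_scale <= 0) stop_input("'noise_scale' must be > 0")
  structure(list(wells = wells, image_shape = image_shape,
                 pixel_size_um = as.numeric(pixel_size_um),
                 background_dose_rate = as.numeric(background_dose_rate),
                 noise_scale = as.numeric(noise_scale),
                 mu_per_um = as.numeric(mu_per_um),
                 base_rate_per_MBq = as.numeric(base_rate_per_MBq),
                 seed = seed),
            class = "phantom_spec")
}

#' Arrange well conditions on a rectangular grid
#'
#' Lays out one well per condition entry, row-major with `n_cols` wells per
#' row (replicates across columns, conditions down rows), mimicking a
#' multiwell plate.
#'
#' @param conditions Flat list of [well_condition()] objects, one per well.
#' @param n_cols Wells per row.
#' @param labels Optional character vector of per-well condition labels.
#' @param viability Optional numeric vector of ground-truth viability
#'   fractions per well.
#' @param radius_px Well radius in pixels (default 17, a 12-mm disc at
#'   350 um/px).
#' @param pitch_px Center-to-center spacing in pixels (default 55).
#' @return A list of well entries for [phantom_spec()].
#' @export
well_grid <- function(conditions, n_cols = 4, labels = NULL,
                      viability = NULL, radius_px = 17, pitch_px = 55) {
  n <- length(conditions)
  if (n == 0L) stop_input("'conditions' must be non-empty")
  if (!is.null(labels) && length(labels) != n)
    stop_input("'labels' must have one entry per condition")
  if (!is.null(viability) && length(viability) != n)
    stop_input("'viability' must have one entry per condition")
  lapply(seq_len(n), function(i) {
    r <- (i - 1) %/% n_cols
    c_ <- (i - 1) %% n_cols
    list(center = c((r + 0.5) * pitch_px, (c_ + 0.5) * pitch_px),
         radius_px = radius_px,
         condition = conditions[[i]],
         label = if (is.null(labels)) sprintf("well%d", i) else labels[i],
         viability = if (is.null(viability)) NULL else viability[i])
  })
}

# time integrals over an exposure window [s, s + d] of the physical decay
# e^{-lambda tau} (background) and tau e^{-lambda tau} (linearly trapped
# activity), in "minutes equivalent at time zero"
decay_window_integrals <- function(start, duration, lam) {
  e0 <- exp(-lam * start)
  e1 <- exp(-lam * (start + duration))
  bg <- (e0 - e1) / lam
  sig <- (start / lam + 1 / lam^2) * e0 -
    ((start + duration) / lam + 1 / lam^2) * e1
  list(background = bg, signal = sig)
}

#' Simulate a multi-frame plate readout of a phantom
#'
#' Physical model per pixel and frame `[t, t + d]`:
#' the decay-corrected trapped amount in a tissue grows linearly,
#' `T(tau) = r tau` with `r` the well's [trapping_rate()], so the physical
#' activity is `r tau exp(-lambda tau)` and the frame integrates it; the
#' ambient background `b exp(-lambda tau)` is attenuated by
#' `exp(-mu * thickness)` under the tissue and reaches the plate unshielded
#' elsewhere. Poisson noise is applied to `dose * noise_scale` and rescaled,
#' then the dose is rendered to PSL through the plate's logarithmic
#' response ([dose_to_psl()]) and quantized to 16-bit integers (doses below
#' the plate floor render as PSL 0).
#'
#' @param phantom A [phantom_spec()].
#' @param schedule An [exposure_schedule()].
#' @param calib A [plate_calibration()].
#' @param nuclide A [nuclide()].
#' @param seed Integer seed for the Poisson noise; defaults to the
#'   phantom's seed. The same phantom, schedule and seed give bit-identical
#'   stacks.
#' @return A list with elements `stack` (an [image_stack()] of integer PSL
#'   matrices), `mask` (integer ROI label matrix, wells numbered in order),
#'   and `truth` (data frame of per-well ground truth: condition
#'   parameters, realized trapping rate, viability, thickness).
#' @export
simulate_stack <- function(phantom, schedule = exposure_schedule(),
                           calib = plate_calibration(),
                           nuclide = bioradr::nuclide(),
                           seed = phantom$seed) {
  if (!inherits(phantom, "phantom_spec"))
    stop_input("'phantom' must be a phantom_spec")
  schedule <- as_exposure_schedule(schedule)
  calib <- as_plate_calibration(calib)
  nuclide <- as_nuclide(nuclide)
  lam <- lambda_per_min(nuclide)
  sh <- phantom$image_shape
  n_frames <- nrow(schedule)

  rowg <- matrix(seq_len(sh[1]), sh[1], sh[2])
  colg <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
  mask <- matrix(0L, sh[1], sh[2])
  wells <- phantom$wells
  idx <- vector("list", length(wells))
  rates <- numeric(length(wells))
  atten <- numeric(length(wells))
  for (i in seq_along(wells)) {
    w <- wells[[i]]
    idx[[i]] <- which((rowg - w$center[1])^2 + (colg - w$center[2])^2 <=
                        w$radius_px^2)
    mask[idx[[i]]] <- i
    rates[i] <- trapping_rate(w$condition, phantom$base_rate_per_MBq)
    atten[i] <- exp(-phantom$mu_per_um * w$condition$tissue_thickness_um)
  }

  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      ints <- decay_window_integrals(schedule$start_min[f],
                                     schedule$duration_min[f], lam)
      dose <- matrix(phantom$background_dose_rate * ints$background,
                     sh[1], sh[2])
      for (i in seq_along(wells)) {
        dose[idx[[i]]] <- phantom$background_dose_rate * ints$background *
          atten[i] + rates[i] * ints$signal
      }
      if (is.finite(phantom$noise_scale)) {
        dose[] <- stats::rpois(length(dose), dose * phantom$noise_scale) /
          phantom$noise_scale
      }
      psl <- matrix(0, sh[1], sh[2])
      pos <- dose > 0
      psl[pos] <- dose_to_psl(dose[pos], calib)
      m <- matrix(as.integer(pmin(pmax(round(psl), 0), 65535)),
                  sh[1], sh[2])
      m
    })
  })

  truth <- do.call(rbind, lapply(seq_along(wells), function(i) {
    w <- wells[[i]]
    data.frame(roi = i, label = w$label,
               fdg_activity_MBq = w$condition$fdg_activity_MBq,
               glucose_mM = w$condition$glucose_mM,
               viable_cell_density = w$condition$viable_cell_density,
               metabolic_modifier = w$condition$metabolic_modifier,
               tissue_thickness_um = w$condition$tissue_thickness_um,
               viability = w$viability,
               true_rate = rates[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(roi = integer(), label = character(),
                        true_rate = numeric())

  list(stack = image_stack(frames, schedule, phantom$pixel_size_um),
       mask = mask, truth = truth)
}

#' Preset experimental scenarios
#'
#' Builds a phantom plus design table for the study designs the
#' bioradiography experiments used: an activity titration
#' (`fig2_activity`), a glucose competition series (`fig3_glucose`),
#' proliferation days (`fig4_growth`), chemical insults (`fig5_insult`)
#' and hypothermia/hypoxia (`fig6_hypo`).
#'
#' Replicate tissues are biologically variable: each well's viable cell
#' density is drawn lognormally around its nominal value with coefficient
#' of variation `rep_cv` (mean-preserving). The realized density, and
#' hence the realized trapping rate, is recorded in the design table and
#' in the simulator's ground truth; the nominal ground-truth viability
#' fraction is kept separately (1 for the hypothermia/hypoxia arms, whose
#' metabolic change leaves viability intact).
#'
#' @param name One of `"fig2_activity"`, `"fig3_glucose"`, `"fig4_growth"`,
#'   `"fig5_insult"`, `"fig6_hypo"`.
#' @param seed Integer seed (mandatory); drives both the replicate
#'   variability and, via the phantom, the imaging noise.
#' @param n_rep Replicates per condition; defaults to the design's tissue
#'   count (4, or 5 for the growth series).
#' @param rep_cv Well-to-well biological coefficient of variation of
#'   viable cell density (default 0.14).
#' @param ... Passed on to [phantom_spec()] (noise, background, geometry).
#' @return A list with `phantom` (a [phantom_spec()]) and `design` (data
#'   frame: roi, condition label, replicate, nominal and realized
#'   parameters, viability, true trapping rate).
#' @export
scenario <- function(name, seed, n_rep = NULL, rep_cv = 0.14, ...) {
  name <- match.arg(name, c("fig2_activity", "fig3_glucose", "fig4_growth",
                            "fig5_insult", "fig6_hypo"))
  if (missing(seed) || is.null(seed)) stop_input("'seed' is required")
  spec <- switch(name,
    fig2_activity = list(
      labels = c("0.0115625 MBq", "0.023125 MBq", "0.04625 MBq",
                 "0.0925 MBq", "0.185 MBq", "0.37 MBq"),
      activity = c(0.0115625, 0.023125, 0.04625, 0.0925, 0.185, 0.37),
      glucose = 5, density = 1, modifier = 1, viability = 1, n_rep = 4),
    fig3_glucose = list(
      labels = c("control", "1 mM", "2 mM", "5 mM", "10 mM", "20 mM"),
      activity = 0.04625, glucose = c(0, 1, 2, 5, 10, 20),
      density = 1, modifier = 1, viability = 1, n_rep = 4),
    fig4_growth = list(
      labels = c("day 3", "day 6", "day 14"),
      activity = 0.04625, glucose = 5, density = c(0.45, 1, 1.25),
      modifier = 1, viability = 1, n_rep = 5),
    fig5_insult = list(
      labels = c("control", "H2SO4", "HCl", "octanoic acid", "KOH"),
      activity = 0.04625, glucose = 5,
      density = c(1, 0.21, 0.24, 0.12, 0.14), modifier = 1,
      viability = c(1, 0.21, 0.24, 0.12, 0.14), n_rep = 4),
    fig6_hypo = list(
      labels = c("control", "hypothermia", "hypoxia"),
      activity = 0.04625, glucose = 5, density = 1,
      modifier = c(1, 0.34, 2.35), viability = 1, n_rep = 4))
  n_cond <- length(spec$labels)
  n_rep <- n_rep %||% spec$n_rep
  rec <- function(x) rep(rep_len(x, n_cond), each = n_rep)
  lab <- rec(spec$labels)
  act <- rec(spec$activity)
  glu <- rec(spec$glucose)
  dens_nom <- rec(spec$density)
  mod <- rec(spec$modifier)
  viab <- rec(spec$viability)
  n <- n_cond * n_rep
  sdlog <- sqrt(log(1 + rep_cv^2))
  dens <- with_seed(seed,
    dens_nom * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  conds <- lapply(seq_len(n), function(i)
    well_condition(fdg_activity_MBq = act[i], glucose_mM = glu[i],
                   viable_cell_density = dens[i],
                   metabolic_modifier = mod[i]))
  phantom <- phantom_spec(
    well_grid(conds, n_cols = n_rep, labels = lab, viability = viab),
    seed = seed + 1L, ...)
  design <- data.frame(
    roi = seq_len(n), condition = lab,
    replicate = rep(seq_len(n_rep), times = n_cond),
    fdg_activity_MBq = act, glucose_mM = glu,
    nominal_density = dens_nom, viable_cell_density = dens,
    metabolic_modifier = mod, viability = viab,
    true_rate = vapply(conds, trapping_rate, numeric(1),
                       base_rate_per_MBq = phantom$base_rate_per_MBq),
    stringsAsFactors = FALSE)
  list(phantom = phantom, design = design)
}

#' Emulated destructive assay readout
#'
#' Stands in for the wet-lab viability/DNA comparator readouts (MTT
#' formazan absorbance, diphenylamine DNA assay): the ground-truth value
#' times mean-preserving lognormal assay noise. The assays' chemistry is
#' not modeled. The default CV matches the low single-digit precision
#' reported for plate-reader viability assays.
#'
#' @param truth Numeric vector of ground-truth values (viability fractions
#'   or relative cell densities).
#' @param cv Assay coefficient of variation (default 0.04).
#' @param seed Optional integer seed.
#' @return Noisy readouts, same length as `truth`.
#' @export
assay_readout <- function(truth, cv = 0.04, seed = NULL) {
  if (!is.numeric(truth) || any(!is.finite(truth)) || any(truth < 0))
    stop_input("'truth' must be non-negative numeric")
  check_scalar(cv, "cv")
  if (cv < 0) stop_input("'cv' must be >= 0")
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed,
    truth * stats::rlnorm(length(truth), meanlog = -sdlog^2 / 2,
                          sdlog = sdlog))
}
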