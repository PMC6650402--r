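#' Radionuclide specification
#'
#' @param name Nuclide label.
#' @param half_life_min Physical half-life in minutes. The default, 109.77,
#'   is the fluorine-18 half-life; it is configurable because published
#'   decay constants differ in the third decimal.
#' @return An object of class `nuclide`.
#' @export
nuclide <- function(name = "F-18", half_life_min = 109.77) {
  check_scalar(half_life_min, "half_life_min")
  if (half_life_min <= 0) stop_input("'half_life_min' must be > 0")
  structure(list(name = as.character(name)[1],
                 half_life_min = as.numeric(half_life_min)),
            class = "nuclide")
}

#' @export
print.nuclide <- function(x, ...) {
  cat(x$name, ": half-life", x$half_life_min, "min\n")
  invisible(x)
}

as_nuclide <- function(x) {
  if (inherits(x, "nuclide")) return(x)
  if (is.list(x)) return(do.call(nuclide, x))
  stop_input("cannot interpret object of class '%s' as a nuclide", class(x)[1])
}

lambda_per_min <- function(nuc) log(2) / nuc$half_life_min

#' Decay-correction factor for a finite exposure window
#'
#' Converts the dose integrated over the exposure window
#' `[start, start + duration]` into the value that would have been recorded
#' had the activity stayed at its level at the reference time:
#'
#' \deqn{f = \frac{\lambda \Delta}{e^{-\lambda (t_0 - t_{ref})}\,
#'           (1 - e^{-\lambda \Delta})}}
#'
#' with \eqn{\lambda = \ln 2 / T_{1/2}}, window start \eqn{t_0} and
#' duration \eqn{\Delta}. The factor tends to 1 as \eqn{\Delta \to 0} and
#' \eqn{t_0 \to t_{ref}}, is >= 1 whenever the window starts at or after the
#' reference, and doubles for every half-life the window start is delayed.
#'
#' The default reference time is 0, the start of incubation, so corrected
#' frame values plot directly against incubation time.
#'
#' @param frame_start_min Window start(s) in minutes.
#' @param frame_duration_min Window duration(s) in minutes (> 0).
#' @param nuclide A [nuclide()].
#' @param reference_min Reference time in minutes (default 0).
#' @return Multiplicative correction factor(s).
#' @export
#' @examples
#' # one half-life long window starting at the reference: 2*log(2)
#' decay_correction_factor(0, 109.77)
decay_correction_factor <- function(frame_start_min, frame_duration_min,
                                    nuclide = bioradr::nuclide(),
                                    reference_min = 0) {
  nuclide <- as_nuclide(nuclide)
  if (!is.numeric(frame_start_min) || any(!is.finite(frame_start_min)))
    stop_input("'frame_start_min' must be finite numeric")
  if (!is.numeric(frame_duration_min) || any(!is.finite(frame_duration_min)) ||
      any(frame_duration_min <= 0))
    stop_input("'frame_duration_min' must be > 0")
  check_scalar(reference_min, "reference_min")
  lam <- lambda_per_min(nuclide)
  d <- frame_duration_min
  (lam * d) /
    (exp(-lam * (frame_start_min - reference_min)) * (1 - exp(-lam * d)))
}

#' Number of atoms corresponding to an activity
#'
#' \eqn{N = A \, T_{1/2} / \ln 2} with the half-life in seconds. At the
#' 0.04625 MBq used as the standard medium activity this gives about
#' 4.4e8 fluorine-18 atoms. (Published alongside "0.0425 MBq", which is
#' mutually inconsistent with the printed atom count at the ~9% level; the
#' atom count corresponds to 0.04625 MBq and both readings are left as
#' found.)
#'
#' @param activity_Bq Activity in becquerel (>= 0).
#' @param nuclide A [nuclide()].
#' @return Expected number of atoms.
#' @export
atoms_from_activity <- function(activity_Bq, nuclide = bioradr::nuclide()) {
  nuclide <- as_nuclide(nuclide)
  if (!is.numeric(activity_Bq) || any(!is.finite(activity_Bq)) ||
      any(activity_Bq < 0))
    stop_input("'activity_Bq' must be >= 0")
  activity_Bq * (nuclide$half_life_min * 60) / log(2)
}

#' Time until a single atom is expected to remain
#'
#' Deterministic "last nuclide" time: the t at which the expected number of
#' survivors \eqn{N 2^{-t/T_{1/2}}} equals one, i.e.
#' \eqn{t = T_{1/2} \log_2 N}, reported in hours. This expected-value
#' definition (rather than a stochastic first-passage time) reproduces the
#' back-of-envelope waste-decay argument: 4.4e8 fluorine-18 atoms reach
#' their last nuclide at 52.5 h.
#'
#' @param n_atoms Initial atom count (>= 1).
#' @param nuclide A [nuclide()].
#' @return Time in hours.
#' @export
time_to_last_atom <- function(n_atoms, nuclide = bioradr::nuclide()) {
  nuclide <- as_nuclide(nuclide)
  if (!is.numeric(n_atoms) || any(!is.finite(n_atoms)) || any(n_atoms < 1))
    stop_input("'n_atoms' must be >= 1")
  nuclide$half_life_min * log2(n_atoms) / 60
}

#' Fraction of activity remaining after an elapsed time
#'
#' @param elapsed_min Elapsed time in minutes (>= 0).
#' @param nuclide A [nuclide()].
#' @return \eqn{2^{-t/T_{1/2}}} in (0, 1].
#' @export
fraction_remaining <- function(elapsed_min, nuclide = bioradr::nuclide()) {
  nuclide <- as_nuclide(nuclide)
  if (!is.numeric(elapsed_min) || any(!is.finite(elapsed_min)) ||
      any(elapsed_min < 0))
    stop_input("'elapsed_min' must be >= 0")
  2^(-elapsed_min / nuclide$half_life_min)
}

#' Cumulated activity (time-integrated activity)
#'
#' \eqn{\tilde A = A_0 / \lambda_{eff}} with
#' \eqn{\lambda_{eff} = \lambda_{phys} + \lambda_{bio}}. An infinite
#' biological half-life means pure physical decay, in which case the
#' cumulated activity equals the initial atom count.
#'
#' @param initial_activity_Bq Initial activity in Bq (> 0).
#' @param nuclide A [nuclide()].
#' @param biological_halflife_min Biological half-life in minutes;
#'   `Inf` (default) for pure physical decay.
#' @return Cumulated activity in Bq s.
#' @export
cumulated_activity <- function(initial_activity_Bq,
                               nuclide = bioradr::nuclide(),
                               biological_halflife_min = Inf) {
  nuclide <- as_nuclide(nuclide)
  check_scalar(initial_activity_Bq, "initial_activity_Bq")
  if (initial_activity_Bq <= 0)
    stop_input("'initial_activity_Bq' must be > 0")
  check_scalar(biological_halflife_min, "biological_halflife_min",
               allow_inf = TRUE)
  if (biological_halflife_min <= 0)
    stop_input("'biological_halflife_min' must be > 0")
  lam_phys <- log(2) / (nuclide$half_life_min * 60)
  lam_bio <- if (is.finite(biological_halflife_min))
    log(2) / (biological_halflife_min * 60) else 0
  initial_activity_Bq / (lam_phys + lam_bio)
}

#' Absorbed dose from cumulated activity (simplified MIRD)
#'
#' \eqn{D = \tilde A \, E / m}, converted to mGy. `energy_per_decay_J` is a
#' configuration product (mean emitted energy times absorbed fraction), not
#' computed from particle transport.
#'
#' @param cumulated_Bq_s Cumulated activity in Bq s (> 0).
#' @param energy_per_decay_J Energy absorbed per decay in joules (> 0).
#' @param target_mass_kg Target mass in kg (> 0).
#' @return Absorbed dose in mGy.
#' @export
absorbed_dose <- function(cumulated_Bq_s, energy_per_decay_J, target_mass_kg) {
  for (nm in c("cumulated_Bq_s", "energy_per_decay_J", "target_mass_kg")) {
    v <- check_scalar(get(nm), nm)
    if (v <= 0) stop_input("'%s' must be > 0", nm)
  }
  1e3 * cumulated_Bq_s * energy_per_decay_J / target_mass_kg
}

#' Effective dose from absorbed dose
#'
#' Absorbed dose times the radiation weighting factor w_R and the tissue
#' weighting factor w_T, in mSv. With the 6 mGy absorbed-dose estimate,
#' w_R = 1 and w_T = 0.01 this is 0.06 mSv, well below the 1 mSv/year
#' public dose limit.
#'
#' @param absorbed_mGy Absorbed dose in mGy (>= 0).
#' @param w_R Radiation weighting factor (>= 0); 1 for photons/positrons.
#' @param w_T Tissue weighting factor (>= 0); 0.01 for skin.
#' @return Effective dose in mSv.
#' @export
effective_dose <- function(absorbed_mGy, w_R = 1, w_T = 0.01) {
  for (nm in c("absorbed_mGy", "w_R", "w_T")) {
    v <- check_scalar(get(nm), nm)
    if (v < 0) stop_input("'%s' must be >= 0", nm)
  }
  absorbed_mGy * w_R * w_T
}

#' Full dose estimate for an exposure configuration
#'
#' Chains [cumulated_activity()], [absorbed_dose()] and [effective_dose()]
#' into a single record.
#'
#' @param activity_Bq Initial activity in Bq.
#' @param energy_per_decay_J Energy absorbed per decay in joules.
#' @param target_mass_kg Target mass in kg.
#' @param w_R,w_T Radiation and tissue weighting factors.
#' @param nuclide A [nuclide()].
#' @param biological_halflife_min Biological half-life in minutes (`Inf`
#'   for pure physical decay).
#' @return An object of class `dose_estimate` with fields
#'   `cumulated_Bq_s`, `absorbed_dose_mGy`, `radiation_weighting`,
#'   `tissue_weighting`, `effective_dose_mSv`.
#' @export
dose_estimate <- function(activity_Bq, energy_per_decay_J, target_mass_kg,
                          w_R = 1, w_T = 0.01, nuclide = bioradr::nuclide(),
                          biological_halflife_min = Inf) {
  cum <- cumulated_activity(activity_Bq, nuclide, biological_halflife_min)
  abs_mGy <- absorbed_dose(cum, energy_per_decay_J, target_mass_kg)
  structure(list(cumulated_Bq_s = cum,
                 absorbed_dose_mGy = abs_mGy,
                 radiation_weighting = w_R,
                 tissue_weighting = w_T,
                 effective_dose_mSv = effective_dose(abs_mGy, w_R, w_T)),
            class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat("Dose estimate\n")
  cat("  cumulated activity:", format(x$cumulated_Bq_s), "Bq s\n")
  cat("  absorbed dose:     ", format(x$absorbed_dose_mGy), "mGy\n")
  cat("  effective dose:    ", format(x$effective_dose_mSv),
      sprintf("mSv (w_R = %g, w_T = %g)\n", x$radiation_weighting,
              x$tissue_weighting))
  invisible(x)
}
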