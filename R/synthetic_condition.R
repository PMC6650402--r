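#' Experimental condition of a single phantom well
#'
#' Captures the axes that the bioradiography experiments vary: medium
#' tracer activity, medium glucose (competing with FDG for transport and
#' phosphorylation), viable cell density (proliferation days, chemical
#' insults), a metabolic modifier (hypothermia < 1, hypoxia > 1 through
#' enhanced glycolysis), and tissue thickness (attenuates the ambient
#' background reaching the plate).
#'
#' @param fdg_activity_MBq Medium FDG activity in MBq per 0.5 mL well
#'   (default 0.04625, the standard medium activity).
#' @param glucose_mM Medium glucose concentration in mM (default 5, the
#'   standard physiological medium).
#' @param viable_cell_density Relative viable cell density; 1 = healthy
#'   day-6 control tissue.
#' @param metabolic_modifier Dimensionless multiplier on the trapping rate
#'   (1 = control; hypothermia < 1; hypoxia > 1).
#' @param tissue_thickness_um Tissue thickness in micrometres (default 100,
#'   typical for the reconstructed epidermal model).
#' @param km_glucose_mM Apparent competitive constant for medium glucose in
#'   mM. The default is the grid least-squares fit of the competitive
#'   inhibition model to the published relative uptake-rate series
#'   (see [fit_km_glucose()]).
#' @return An object of class `well_condition`.
#' @export
well_condition <- function(fdg_activity_MBq = 0.04625, glucose_mM = 5,
                           viable_cell_density = 1, metabolic_modifier = 1,
                           tissue_thickness_um = 100,
                           km_glucose_mM = km_glucose_default) {
  for (nm in c("fdg_activity_MBq", "glucose_mM", "viable_cell_density",
               "metabolic_modifier", "tissue_thickness_um", "km_glucose_mM")) {
    v <- check_scalar(get(nm), nm)
    if (v < 0) stop_input("'%s' must be non-negative", nm)
  }
  if (km_glucose_mM <= 0) stop_input("'km_glucose_mM' must be > 0")
  structure(list(fdg_activity_MBq = as.numeric(fdg_activity_MBq),
                 glucose_mM = as.numeric(glucose_mM),
                 viable_cell_density = as.numeric(viable_cell_density),
                 metabolic_modifier = as.numeric(metabolic_modifier),
                 tissue_thickness_um = as.numeric(tissue_thickness_um),
                 km_glucose_mM = as.numeric(km_glucose_mM)),
            class = "well_condition")
}

#' Fit the apparent glucose Km to a relative uptake-rate series
#'
#' Grid least-squares fit of the single-site competitive inhibition model
#' \eqn{p(g) = 1/(1 + g/K_m)} to percent-of-control uptake rates measured
#' at a series of glucose concentrations. The default data are the
#' published relative rates 89, 73, 44, 39 and 23% at 1, 2, 5, 10 and
#' 20 mM; the fit lands near 5.4 mM and reproduces the five percentages
#' within 8 points.
#'
#' @param percent Percent-of-control uptake rates.
#' @param glucose_mM Glucose concentrations in mM (same length).
#' @param km_grid Candidate Km values searched (default 0.5 to 20 mM in
#'   0.001 mM steps).
#' @return Fitted Km in mM, with attributes `sse` and `predicted`
#'   (model percentages at `glucose_mM`).
#' @export
fit_km_glucose <- function(percent = c(89, 73, 44, 39, 23),
                           glucose_mM = c(1, 2, 5, 10, 20),
                           km_grid = seq(0.5, 20, by = 0.001)) {
  if (length(percent) != length(glucose_mM))
    stop_input("'percent' and 'glucose_mM' must have equal length")
  p <- percent / 100
  sse <- vapply(km_grid,
                function(K) sum((1 / (1 + glucose_mM / K) - p)^2),
                numeric(1))
  km <- km_grid[which.min(sse)]
  structure(km, sse = min(sse),
            predicted = 100 / (1 + glucose_mM / km))
}

# frozen output of fit_km_glucose() at its defaults; asserted by a test
km_glucose_default <- 5.352

#' True FDG trapping rate for a well condition
#'
#' The simulator's ground-truth uptake rate, in decay-corrected
#' nGy/pixel/min per minute of incubation:
#'
#' \deqn{r = b \cdot A \cdot \rho \cdot m \cdot \frac{1}{1 + g/K_m}}
#'
#' linear in medium activity \eqn{A} (the activity-titration experiments),
#' linear in viable cell density \eqn{\rho} (proliferation and insult
#' experiments), scaled by the metabolic modifier \eqn{m}, and suppressed
#' by medium glucose \eqn{g} through single-site competitive inhibition.
#'
#' @param cond A [well_condition()].
#' @param base_rate_per_MBq Trapping rate per MBq of medium activity at
#'   zero glucose for healthy control tissue, in (nGy/pixel/min)/min/MBq.
#'   The default 37.5 puts the standard control condition (0.04625 MBq,
#'   5 mM glucose) at about 0.9 nGy/pixel/min per min, which renders the
#'   phantom frames into the plate's working PSL range.
#' @return Trapping rate (nGy/pixel/min per min).
#' @export
trapping_rate <- function(cond, base_rate_per_MBq = 37.5) {
  if (!inherits(cond, "well_condition"))
    stop_input("'cond' must be a well_condition")
  check_scalar(base_rate_per_MBq, "base_rate_per_MBq")
  base_rate_per_MBq * cond$fdg_activity_MBq * cond$viable_cell_density *
    cond$metabolic_modifier / (1 + cond$glucose_mM / cond$km_glucose_mM)
}
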