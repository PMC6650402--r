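#' Read a PSL image stack from disk
#'
#' Accepts a multi-page 16-bit grayscale TIFF, or a directory of
#' whitespace-delimited numeric matrices (one file per frame, read in
#' sorted name order). Values are loaded losslessly as integers.
#'
#' @param path Path to a `.tif`/`.tiff` file or a directory.
#' @param schedule An [exposure_schedule()]; the page count must match.
#' @param pixel_size_um Pixel size metadata (default 350).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, schedule, pixel_size_um = 350) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  schedule <- as_exposure_schedule(schedule)
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    if (length(files) == 0L) stop_input("directory %s is empty", path)
    frames <- lapply(files, function(f)
      as.matrix(utils::read.table(f, header = FALSE)))
    frames <- lapply(frames, function(m) {
      dimnames(m) <- NULL
      matrix(as.numeric(m), nrow(m), ncol(m))
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]
      matrix(as.numeric(p), nrow(p), ncol(p))
    })
  }
  if (length(frames) != nrow(schedule))
    stop_input("stack at %s has %d frames but the schedule has %d",
               path, length(frames), nrow(schedule))
  image_stack(frames, schedule, pixel_size_um)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param stack An [image_stack()] (or plain list of matrices) of PSL
#'   values in 0..65535.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  if (!is.list(frames)) frames <- list(frames)
  vals <- lapply(frames, function(m) {
    if (any(m < 0 | m > 65535)) stop_input("PSL values out of 16-bit range")
    m / 65535
  })
  tiff::writeTIFF(vals, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read and validate an experiment configuration
#'
#' Configurations are YAML with sections for the plate calibration, the
#' nuclide, the exposure schedule, the simulated scenario, and dosimetry
#' constants. Defaults are the published acquisition values (calibration
#' 8770/1535/1024/1.25; 45-min frames every 60 min; 0.04625 MBq; 5 mM
#' glucose; 109.77-min half-life). Unknown or ill-typed fields raise an
#' error naming the field.
#'
#' @param path Path to a YAML file, or a list already in memory.
#' @return Validated config list with defaults filled in.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop_input("config file not found: %s", path)
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

config_defaults <- function() {
  list(
    seed = NULL,
    scenario = "fig3_glucose",
    calibration = list(dose_scale = 8770, psl_offset = 1535,
                       psl_per_decade = 1024, sensitivity_ratio = 1.25),
    nuclide = list(name = "F-18", half_life_min = 109.77),
    schedule = list(start_min = seq(0, 360, by = 60), duration_min = 45),
    phantom = list(background_dose_rate = 120, noise_scale = 0.5,
                   mu_per_um = 0.002, base_rate_per_MBq = 37.5,
                   pixel_size_um = 350),
    stats = list(control = "control", alternative = "two.sided",
                 n_perm = 10000, max_exact = 20000),
    # reproduces the published tentative 6 mGy absorbed-dose estimate for
    # a 12-mm disc of 100-um tissue at the standard medium activity
    dosimetry = list(activity_MBq = 0.04625, energy_per_decay_J = 1.54e-16,
                     target_mass_kg = 1.13e-5, w_R = 1, w_T = 0.01,
                     biological_halflife_min = Inf))
}

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop_input("config must be a YAML mapping")
  def <- config_defaults()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop_input("unknown config field(s): %s", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(def, cfg)
  num_field <- function(section, name, kind = c("positive", "nonneg", "any"),
                        allow_inf = FALSE) {
    kind <- match.arg(kind)
    v <- merged[[section]][[name]]
    ok <- is.numeric(v) && length(v) >= 1 && !any(is.na(v)) &&
      (allow_inf || all(is.finite(v)))
    if (!ok || (kind == "positive" && any(v <= 0)) ||
        (kind == "nonneg" && any(v < 0)))
      stop_input("config field '%s.%s' must be %s numeric", section, name,
                 switch(kind, positive = "positive",
                        nonneg = "non-negative", any = "finite"))
    v
  }
  for (nm in c("dose_scale", "psl_offset", "psl_per_decade",
               "sensitivity_ratio"))
    num_field("calibration", nm)
  num_field("nuclide", "half_life_min")
  num_field("schedule", "start_min", kind = "any")
  num_field("schedule", "duration_min")
  for (nm in c("background_dose_rate", "mu_per_um", "base_rate_per_MBq"))
    num_field("phantom", nm, kind = "nonneg")
  num_field("phantom", "pixel_size_um")
  num_field("phantom", "noise_scale", allow_inf = TRUE)
  for (nm in c("activity_MBq", "energy_per_decay_J", "target_mass_kg"))
    num_field("dosimetry", nm)
  for (nm in c("w_R", "w_T"))
    num_field("dosimetry", nm, kind = "nonneg")
  num_field("dosimetry", "biological_halflife_min", allow_inf = TRUE)
  if (!is.character(merged$scenario) ||
      !merged$scenario %in% c("fig2_activity", "fig3_glucose", "fig4_growth",
                              "fig5_insult", "fig6_hypo"))
    stop_input("config field 'scenario' must name a known scenario")
  if (!is.null(merged$seed)) {
    if (!is.numeric(merged$seed) || length(merged$seed) != 1)
      stop_input("config field 'seed' must be a single integer")
    merged$seed <- as.integer(merged$seed)
  }
  merged
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

write_table <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_md5=%s seed=%s", hash,
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full bioradiography pipeline on a simulated scenario
#'
#' simulate -> quantify -> stats -> dose, writing tidy CSV tables (and a
#' JSON dose record) to `out_dir`. Every table carries the config MD5 hash
#' and seed as a leading `#` comment line (read them back with
#' `read.csv(..., comment.char = "#")`); identical config and seed give
#' byte-identical outputs. Units: uptake in nGy/pixel/min, rates in
#' delta-nGy/pixel/min per min, percentages in %, doses in mGy/mSv.
#'
#' @param config Path to a YAML config or a config list
#'   (see [read_experiment_config()]).
#' @param out_dir Output directory, created if needed.
#' @param seed Overrides the config seed.
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the design, uptake series, rates,
#'   percent-of-control table, Steel test and dose estimate.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  cfg <- read_experiment_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) stop_input("a seed is required (config or argument)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(cfg)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  calib <- do.call(plate_calibration, cfg$calibration)
  nuc <- do.call(nuclide, cfg$nuclide)
  sched <- exposure_schedule(cfg$schedule$start_min,
                             cfg$schedule$duration_min)

  say("simulate", "scenario %s, seed %d", cfg$scenario, cfg$seed)
  sim <- stage("simulate", {
    sc <- do.call(scenario, c(list(name = cfg$scenario, seed = cfg$seed),
                              cfg$phantom))
    out <- simulate_stack(sc$phantom, sched, calib, nuc)
    out$design <- sc$design
    out
  })
  write_image_stack(sim$stack, file.path(out_dir, "stack.tif"))
  write_image_stack(list(sim$mask), file.path(out_dir, "roi_mask.tif"))
  write_table(sim$design, file.path(out_dir, "design.csv"), hash, cfg$seed)
  write_table(sim$truth, file.path(out_dir, "ground_truth.csv"), hash,
              cfg$seed)

  say("quantify", "%d ROIs x %d frames", nrow(sim$truth), nrow(sched))
  series <- stage("quantify",
                  extract_uptake_series(sim$stack, sim$mask, calib, nuc))
  rates <- stage("quantify", fit_uptake_rates(series))
  rates$condition <- sim$design$condition[match(rates$roi, sim$design$roi)]
  names(series)[names(series) == "uptake"] <- "uptake_nGy_per_px_per_min"
  names(rates)[names(rates) == "slope"] <- "rate_dnGy_per_px_per_min"
  write_table(series, file.path(out_dir, "uptake_series.csv"), hash,
              cfg$seed)
  write_table(rates, file.path(out_dir, "uptake_rates.csv"), hash, cfg$seed)

  control <- cfg$stats$control
  has_control <- control %in% rates$condition
  pct <- NULL
  steel <- NULL
  if (has_control) {
    say("stats", "percent of control '%s' + Steel test", control)
    pct <- stage("stats",
                 relative_to_control(rates, control,
                                     value_col = "rate_dnGy_per_px_per_min"))
    names(pct)[names(pct) == "percent"] <- "percent_of_control"
    write_table(pct, file.path(out_dir, "percent_of_control.csv"), hash,
                cfg$seed)
    grp <- split(rates$rate_dnGy_per_px_per_min, rates$condition)
    steel <- stage("stats",
                   steel_test(grp[[control]], grp[names(grp) != control],
                              alternative = cfg$stats$alternative,
                              max_exact = cfg$stats$max_exact,
                              n_perm = cfg$stats$n_perm,
                              seed = cfg$seed + 2L))
    write_table(steel$table, file.path(out_dir, "steel_test.csv"), hash,
                cfg$seed)
  } else {
    say("stats", "no '%s' group; skipping group comparison", control)
  }

  say("dose", "activity %g MBq", cfg$dosimetry$activity_MBq)
  dose <- stage("dose", with(cfg$dosimetry,
    dose_estimate(activity_MBq * 1e6, energy_per_decay_J, target_mass_kg,
                  w_R, w_T, nuc, biological_halflife_min)))
  jsonlite::write_json(
    c(list(config_md5 = hash, seed = cfg$seed), unclass(dose)),
    file.path(out_dir, "dose_estimate.json"),
    auto_unbox = TRUE, digits = NA)

  invisible(list(design = sim$design, truth = sim$truth, series = series,
                 rates = rates, percent_of_control = pct, steel = steel,
                 dose = dose, config_md5 = hash))
}
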