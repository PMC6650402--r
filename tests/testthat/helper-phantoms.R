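# fixture builders used across test files

# single-well phantom at the standard control condition
control_phantom <- function(seed, noise_scale = 0.5, cond = well_condition()) {
  phantom_spec(well_grid(list(cond), n_cols = 1),
               noise_scale = noise_scale, seed = seed)
}

# simulate a phantom and return fitted rates joined to the ground truth
recover_rates <- function(phantom, schedule = exposure_schedule()) {
  sim <- simulate_stack(phantom, schedule)
  rates <- fit_uptake_rates(extract_uptake_series(sim$stack, sim$mask))
  merge(rates, sim$truth, by = "roi")
}

# brute-force oracle for the Steel max-statistic permutation p-value:
# enumerates every way to relabel the pooled values into groups of the
# given sizes, computing standardized midrank Mann-Whitney statistics
# directly from their definition
steel_oracle <- function(control, treatments, alternative = "greater") {
  pooled <- c(control, unlist(treatments, use.names = FALSE))
  sizes <- c(length(control), lengths(treatments))
  dir <- switch(alternative, two.sided = abs, greater = identity,
                less = function(s) -s)
  stat <- function(cv, tv) {
    r <- rank(c(cv, tv))
    U <- sum(r[seq_along(tv) + length(cv)]) -
      length(tv) * (length(tv) + 1) / 2
    tie <- table(c(cv, tv))
    m <- length(cv) + length(tv)
    v <- length(cv) * length(tv) / 12 *
      ((m + 1) - sum(tie^3 - tie) / (m * (m - 1)))
    if (v <= 0) 0 else (U - length(cv) * length(tv) / 2) / sqrt(v)
  }
  splits <- function(idx, sz) {
    if (length(sz) == 1) return(list(list(idx)))
    out <- list()
    for (f in utils::combn(idx, sz[1], simplify = FALSE))
      for (r in splits(setdiff(idx, f), sz[-1]))
        out[[length(out) + 1]] <- c(list(f), r)
    out
  }
  all_splits <- splits(seq_along(pooled), sizes)
  maxima <- vapply(all_splits, function(s) {
    max(vapply(seq_along(treatments), function(i)
      dir(stat(pooled[s[[1]]], pooled[s[[i + 1]]])), numeric(1)))
  }, numeric(1))
  obs <- vapply(seq_along(treatments), function(i)
    dir(stat(control, treatments[[i]])), numeric(1))
  vapply(obs, function(o) mean(maxima >= o - 1e-9), numeric(1))
}
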