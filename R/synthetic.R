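#' Counting-noise model for simulated tracer measurements
#'
#' Emulates liquid-scintillation counting: a measurement worth 100% of the
#' added tracer corresponds to `expected_counts` expected decays, individual
#' measurements are Poisson draws rescaled back to percent. The lognormal
#' kind models multiplicative (e.g. pipetting) error with unit mean; `none`
#' returns the latent values.
#'
#' @param kind `"none"`, `"poisson"` or `"lognormal"`.
#' @param expected_counts Expected counts at 100% signal (> 0), default 1e4.
#' @param sigma Lognormal sigma (log scale), required for
#'   `kind = "lognormal"`.
#' @param seed Integer seed; mandatory for stochastic kinds.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "poisson", "lognormal"),
                        expected_counts = 1e4, sigma = NULL, seed = NULL) {
  kind <- match.arg(kind)
  .check_num(expected_counts, "expected_counts", positive = TRUE, len = 1)
  if (kind == "lognormal") .check_num(sigma, "sigma", positive = TRUE, len = 1)
  if (kind != "none" && is.null(seed))
    .stopf("a seed is mandatory for stochastic noise kinds")
  if (!is.null(seed)) .check_num(seed, "seed", len = 1)
  structure(list(kind = kind, expected_counts = expected_counts,
                 sigma = sigma, seed = seed),
            class = "noise_model")
}

## apply a noise model to percent-of-added values; assumes the RNG state has
## already been seeded by the caller
.apply_noise <- function(values_pct, noise) {
  switch(noise$kind,
    none = values_pct,
    poisson = {
      lam <- values_pct * noise$expected_counts / 100
      stats::rpois(length(lam), lam) / noise$expected_counts * 100
    },
    lognormal = values_pct *
      stats::rlnorm(length(values_pct), -noise$sigma^2 / 2, noise$sigma))
}

#' Generate a synthetic pulse-chase tracer time course
#'
#' Runs the compartment model ([simulate_kinetics()]), applies every
#' measurement protocol in the design at the design's sampling times for
#' each technical replicate, converts to percent of the tracer added on
#' that isotope channel, and applies counting noise. Deterministic given
#' the noise model's seed.
#'
#' @param params A [kinetic_parameters()] object.
#' @param design An [experiment_design()] object (must contain at least one
#'   addition).
#' @param noise A [noise_model()]; default noiseless.
#' @return A data frame of class `tracer_timecourse` with columns
#'   `time_min`, `channel`, `protocol`, `replicate`, `value_pct_of_added`
#'   and `counts_bq` (expected scintillation counts; `NA` for noiseless
#'   data), plus attributes `params`, `design`, `added_per_cell`.
#' @examples
#' tc <- generate_pulse_chase(fig3_parameters(), fig3_design())
#' head(tc)
#' @export
generate_pulse_chase <- function(params, design, noise = noise_model("none")) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  if (nrow(design$additions) == 0)
    .stopf("design must contain at least one tracer addition")
  if (!is.null(noise$seed)) set.seed(noise$seed)
  traj <- simulate_kinetics(params, design,
                            grid = sort(unique(design$sampling_times)))
  added <- attr(traj, "added_per_cell")
  rows <- list()
  for (prot in design$protocols) {
    meas <- apply_measurement(traj, prot, params = params)
    pct <- 100 * meas$value_molecules_per_cell /
      added[as.character(meas$channel)]
    pct[!is.finite(pct)] <- 0  # channel never added
    for (r in seq_len(design$replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        time_min = meas$time_min, channel = meas$channel, protocol = prot,
        replicate = r, value_pct_of_added = .apply_noise(pct, noise))
    }
  }
  out <- do.call(rbind, rows)
  out$counts_bq <- if (noise$kind == "poisson")
    out$value_pct_of_added * noise$expected_counts / 100 else NA_real_
  out <- out[order(out$protocol, out$channel, out$replicate, out$time_min), ]
  rownames(out) <- NULL
  structure(out, class = c("tracer_timecourse", "data.frame"),
            params = params, design = design, added_per_cell = added)
}

#' Generate a synthetic isotope-dilution bioassay series
#'
#' For each added carrier concentration `C_a` and incubation time `t`, the
#' latent taken-up fraction is `1 - exp(-t * v / (C_amb + C_a))`; noise is
#' applied multiplicatively and results clipped to `[0, 1 - 1e-6]` (clipped
#' values are flagged in the `clipped` column — clipping, not resampling,
#' keeps the generator deterministic but introduces a small bias at
#' near-complete uptake).
#'
#' @param ambient Ambient concentration `C_amb` in mol/l (> 0).
#' @param velocity Uptake velocity `v` in mol/l/min (> 0).
#' @param added_concs Added carrier concentrations in mol/l (>= 0, non-empty).
#' @param times Incubation times in minutes (> 0).
#' @param noise A [noise_model()]; default noiseless. (Poisson noise is
#'   applied on the percent scale of the fraction.)
#' @return A [bioassay_series()] data frame with an extra `clipped` column.
#' @examples
#' generate_bioassay(5e-9, 1e-10, added_concs = c(0, 5e-9, 1e-8), times = 60)
#' @export
generate_bioassay <- function(ambient, velocity, added_concs, times,
                              noise = noise_model("none")) {
  .check_num(ambient, "ambient", positive = TRUE, len = 1)
  .check_num(velocity, "velocity", positive = TRUE, len = 1)
  if (length(added_concs) == 0) .stopf("added_concs must be non-empty")
  .check_num(added_concs, "added_concs", nonneg = TRUE)
  .check_num(times, "times", positive = TRUE)
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  grid <- expand.grid(time_min = times, added_conc = added_concs)
  f <- 1 - exp(-grid$time_min * velocity / (ambient + grid$added_conc))
  fn <- .apply_noise(100 * f, noise) / 100
  clipped <- fn >= 1 | fn < 0
  fn <- pmin(pmax(fn, 0), 1 - 1e-6)
  out <- bioassay_series(grid$added_conc, grid$time_min, fn)
  out$clipped <- clipped
  out
}

#' Generate a paired control/treated inhibitor experiment
#'
#' Simulates total cell-associated label (seawater-wash protocol) for an
#' uninhibited control and for each requested inhibitor treatment, under
#' identical parameters, design and noise. The onset delay of an inhibitor
#' is recoverable from the pair as `plateau / control rate` (see
#' [estimate_inhibition_delay()]).
#'
#' @param params A [kinetic_parameters()] object.
#' @param inhibitors A data frame with columns `time_min`, `kind` and
#'   optionally `factor` (one treatment per row), or a character vector of
#'   kinds added at time 0.
#' @param design An [experiment_design()]; default: a single 1e-8 mol/l
#'   33P addition at 0 min sampled densely over 30 min with the seawater-wash
#'   protocol.
#' @param noise A [noise_model()]; default noiseless.
#' @return A named list of `tracer_timecourse` objects: `control` plus one
#'   entry per treatment (named by inhibitor kind).
#' @examples
#' ex <- generate_inhibitor_experiment(fig3_parameters(), "CCCP")
#' names(ex)
#' @export
generate_inhibitor_experiment <- function(params, inhibitors,
                                          design = NULL,
                                          noise = noise_model("none")) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (is.character(inhibitors))
    inhibitors <- data.frame(time_min = 0, kind = inhibitors,
                             factor = NA_real_)
  stopifnot(is.data.frame(inhibitors))
  if (is.null(inhibitors$factor)) inhibitors$factor <- NA_real_
  if (is.null(design)) {
    design <- experiment_design(
      cell_density = 2.5e10,
      additions = data.frame(time_min = 0, channel = "P33",
                             conc_mol_l = 1e-8),
      sampling_times = c(seq(0.5, 5, by = 0.5), seq(6, 30, by = 2)),
      protocols = "ASW", replicates = 1)
  }
  out <- list(control = generate_pulse_chase(params, design, noise))
  for (i in seq_len(nrow(inhibitors))) {
    dtreat <- design
    dtreat$inhibitor_events <- inhibitors[i, c("time_min", "kind", "factor")]
    out[[inhibitors$kind[i]]] <- generate_pulse_chase(params, dtreat, noise)
  }
  out
}

#' Inhibition onset delay from a control/treated pair
#'
#' The operational definition used for inhibitor experiments: the label
#' accumulated by treated cells before the inhibitor takes effect, divided
#' by the accumulation rate of the uninhibited control. The control rate is
#' the early-time slope (regression through the origin over
#' `t <= rate_window`); the treated plateau is the mean of the last
#' `plateau_points` observations.
#'
#' @param control,treated `tracer_timecourse` objects (seawater-wash
#'   protocol) from [generate_inhibitor_experiment()].
#' @param channel Isotope channel to use, default `"P33"`.
#' @param rate_window Control observations at `t <= rate_window` minutes
#'   enter the rate fit; default 2.
#' @param plateau_points Number of trailing treated observations averaged
#'   for the plateau; default 3.
#' @return Estimated delay in minutes.
#' @examples
#' ex <- generate_inhibitor_experiment(fig3_parameters(), "CCCP")
#' estimate_inhibition_delay(ex$control, ex$CCCP)  # ~4 min
#' @export
estimate_inhibition_delay <- function(control, treated, channel = "P33",
                                      rate_window = 2, plateau_points = 3) {
  pick <- function(tc) {
    d <- tc[tc$protocol == "ASW" & tc$channel == channel, ]
    stats::aggregate(value_pct_of_added ~ time_min, d, mean)
  }
  ctl <- pick(control); trt <- pick(treated)
  early <- ctl[ctl$time_min <= rate_window & ctl$time_min > 0, ]
  if (nrow(early) < 1)
    .stopf("no control observations within the rate window")
  rate <- unname(stats::coef(
    stats::lm(value_pct_of_added ~ 0 + time_min, early))[1])
  if (rate <= 0) .stopf("control accumulation rate is not positive")
  plateau <- mean(utils::tail(trt$value_pct_of_added[order(trt$time_min)],
                              plateau_points))
  plateau / rate
}
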