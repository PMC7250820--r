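#' Turnover time from a single tracer-uptake fraction
#'
#' In an isotope-dilution bioassay the fraction of added tracer taken up by
#' time `t` follows `f(t) = 1 - exp(-t/T)`, so a single observation inverts
#' to `T = -t / log(1 - f)`. For small `f` this reduces to `T ~ t/f`.
#'
#' @param fraction Fraction of tracer taken up, strictly in (0, 1).
#' @param t Incubation time in minutes (> 0).
#' @return Turnover time `T` in minutes.
#' @examples
#' turnover_time(0.5, 60)        # 60 / log(2)
#' turnover_time(1 - exp(-1), 60)  # 60
#' @export
turnover_time <- function(fraction, t) {
  .check_num(fraction, "fraction")
  .check_num(t, "t", positive = TRUE)
  if (any(fraction <= 0) || any(fraction >= 1))
    .stopf("'fraction' must be strictly between 0 and 1")
  -t / log(1 - fraction)
}

#' Concentration-series bioassay data
#'
#' Validated container for isotope-dilution bioassay observations: for each
#' added carrier concentration `C_a`, the fraction of tracer taken up at one
#' or more incubation times.
#'
#' @param added_conc Added carrier concentrations, mol/l (>= 0), one per row.
#' @param time_min Incubation times in minutes (> 0).
#' @param fraction_taken_up Tracer fractions in `[0, 1)`.
#' @return A data frame of class `bioassay_series`.
#' @export
bioassay_series <- function(added_conc, time_min, fraction_taken_up) {
  .check_num(added_conc, "added_conc", nonneg = TRUE)
  .check_num(time_min, "time_min", positive = TRUE)
  .check_num(fraction_taken_up, "fraction_taken_up", nonneg = TRUE)
  n <- length(added_conc)
  if (length(time_min) != n || length(fraction_taken_up) != n)
    .stopf("added_conc, time_min and fraction_taken_up must have equal length")
  if (any(fraction_taken_up >= 1))
    .stopf("fractions must be < 1")
  structure(
    data.frame(added_conc = added_conc, time_min = time_min,
               fraction_taken_up = fraction_taken_up),
    class = c("bioassay_series", "data.frame"))
}

#' Isotope-dilution concentration-series estimate of ambient concentration
#'
#' The classical bioassay: at each added carrier concentration `C_a` the
#' tracer turnover time is `T = (C_amb + C_a) / v`, where `C_amb` is the
#' ambient (bioavailable) concentration and `v` the community uptake
#' velocity. Per concentration, `T` is estimated by a through-origin
#' log-linear regression of `log(1 - f)` on time (all time points are used;
#' with a single time point this reduces to [turnover_time()]). The
#' estimated turnover times are then regressed on `C_a` by ordinary least
#' squares; the line's intercept/slope ratio estimates `C_amb` and the
#' inverse slope estimates `v`.
#'
#' Fractions at or below `detection_floor` are censored (excluded from the
#' per-concentration regression) as being below the counting detection
#' limit.
#'
#' @param series A [bioassay_series()] (or data frame with the same columns).
#' @param weighted If `TRUE`, weight the `T` vs `C_a` regression by the
#'   inverse squared standard error of each turnover estimate (only
#'   available when concentrations have >= 3 time points). Default `FALSE`
#'   (ordinary least squares).
#' @param detection_floor Censoring floor on uptake fractions, default 1e-9.
#' @return An object of class `bioassay_fit`: a list with `ambient_conc`
#'   (mol/l), `uptake_velocity` (mol/l/min), their standard errors
#'   (delta method), the per-concentration turnover table, and the
#'   underlying `lm` fit.
#' @examples
#' s <- generate_bioassay(ambient = 5e-9, velocity = 1e-10,
#'                        added_concs = c(0, 2e-9, 5e-9, 1e-8),
#'                        times = c(30, 60, 90))
#' isotope_dilution_fit(s)
#' @export
isotope_dilution_fit <- function(series, weighted = FALSE,
                                 detection_floor = 1e-9) {
  stopifnot(is.data.frame(series))
  req <- c("added_conc", "time_min", "fraction_taken_up")
  if (!all(req %in% names(series)))
    .stopf("series must have columns %s", paste(req, collapse = ", "))
  keep <- series$fraction_taken_up > detection_floor
  series <- series[keep, , drop = FALSE]
  concs <- sort(unique(series$added_conc))
  if (length(concs) < 2)
    .stopf("at least 2 distinct added concentrations are required")
  per <- lapply(concs, function(ca) {
    d <- series[series$added_conc == ca, , drop = FALSE]
    z <- log(1 - d$fraction_taken_up)
    fit <- stats::lm(z ~ 0 + d$time_min)
    slope <- unname(stats::coef(fit)[1])
    if (slope >= 0)
      .stopf("degenerate design: non-negative log-depletion slope at C_a = %g",
             ca)
    se <- if (nrow(d) >= 3)
      suppressWarnings(summary(fit))$coefficients[1, 2] else NA_real_
    data.frame(added_conc = ca, turnover_min = -1 / slope,
               turnover_se = se / slope^2, n_times = nrow(d))
  })
  per <- do.call(rbind, per)
  w <- if (weighted) {
    if (any(!is.finite(per$turnover_se)))
      .stopf("weighted fit needs >= 3 time points per concentration")
    1 / per$turnover_se^2
  } else NULL
  line <- stats::lm(turnover_min ~ added_conc, data = per, weights = w)
  cf <- stats::coef(line)
  spread <- cf[2] * diff(range(per$added_conc))
  if (!is.finite(cf[2]) || cf[2] <= 0 ||
      spread < 1e-6 * mean(per$turnover_min))
    .stopf("degenerate design: turnover does not increase with added concentration")
  vc <- suppressWarnings(stats::vcov(line))
  ambient <- unname(cf[1] / cf[2])
  velocity <- unname(1 / cf[2])
  ## delta method: C_amb = b0/b1, v = 1/b1
  g <- c(1 / cf[2], -cf[1] / cf[2]^2)
  ambient_se <- sqrt(drop(t(g) %*% vc %*% g))
  velocity_se <- sqrt(vc[2, 2]) / cf[2]^2
  structure(
    list(ambient_conc = ambient, uptake_velocity = velocity,
         ambient_se = unname(ambient_se), velocity_se = unname(velocity_se),
         turnover = per, line = line, weighted = weighted),
    class = "bioassay_fit")
}

#' @export
print.bioassay_fit <- function(x, ...) {
  cat("Isotope-dilution concentration-series bioassay fit\n")
  cat(sprintf("  ambient conc:   %.4g +/- %.2g mol/l\n",
              x$ambient_conc, x$ambient_se))
  cat(sprintf("  uptake velocity: %.4g +/- %.2g mol/l/min\n",
              x$uptake_velocity, x$velocity_se))
  cat(sprintf("  %d concentrations, %s least squares\n",
              nrow(x$turnover), if (x$weighted) "weighted" else "ordinary"))
  invisible(x)
}

#' Clearance rate from a tracer-depletion time course
#'
#' Log-linear fit of the remaining tracer fraction `F(t)`:
#' `log F = -CL * rho * t`, through the origin (F(0) = 1). The fitted
#' clearance is independent of the initial tracer concentration — cells
#' clear the same volume of water per minute across many orders of magnitude
#' of ambient Pi.
#'
#' Fractions at or below `detection_floor` (default the ratio of a
#' 1e-15 mol/l instrument floor to a 1e-9 mol/l start, i.e. 1e-6) are
#' censored. A gross non-monotone increase (beyond 3 standard deviations of
#' the residual noise) is flagged with a warning but does not stop the fit.
#'
#' @param fraction_remaining Remaining tracer fractions in (0, 1].
#' @param time_min Times in minutes (>= 0), same length.
#' @param cell_density Cells per litre (> 0).
#' @param detection_floor Censoring floor for fractions, default 1e-6.
#' @return An object of class `clearance_fit`: list with `clearance_cl`
#'   (l/cell/min), `se`, `r_squared`, `n_used`, `flagged_nonmonotone`.
#' @examples
#' tt <- c(10, 30, 60, 120)
#' clearance_from_depletion(exp(-4.45e-3 * tt), tt, cell_density = 2.5e10)
#' @export
clearance_from_depletion <- function(fraction_remaining, time_min,
                                     cell_density, detection_floor = 1e-6) {
  .check_num(fraction_remaining, "fraction_remaining", positive = TRUE)
  .check_num(time_min, "time_min", nonneg = TRUE)
  .check_num(cell_density, "cell_density", positive = TRUE, len = 1)
  if (any(fraction_remaining > 1))
    .stopf("fractions must be in (0, 1]")
  if (length(fraction_remaining) != length(time_min))
    .stopf("fraction_remaining and time_min must have equal length")
  keep <- fraction_remaining > detection_floor
  f <- fraction_remaining[keep]; tt <- time_min[keep]
  if (length(unique(tt)) < 2)
    .stopf("at least 2 time points above the detection floor are required")
  if (length(unique(f)) == 1)
    .stopf("degenerate data: all remaining fractions are identical")
  z <- log(f)
  fit <- stats::lm(z ~ 0 + tt)
  slope <- unname(stats::coef(fit)[1])
  if (slope >= 0)
    .stopf("degenerate data: tracer fraction does not decay")
  ## robust noise scale so a single gross spike cannot mask itself
  sigma <- stats::mad(stats::residuals(fit))
  incr <- diff(z[order(tt)])
  flagged <- any(incr > 3 * max(sigma, .Machine$double.eps))
  if (flagged)
    warning("non-monotone tracer increase beyond 3 sigma of fit noise",
            call. = FALSE)
  se <- suppressWarnings(summary(fit))$coefficients[1, 2]
  structure(
    list(clearance_cl = -slope / cell_density,
         se = se / cell_density,
         r_squared = suppressWarnings(summary(fit))$r.squared,
         n_used = length(f), flagged_nonmonotone = flagged),
    class = "clearance_fit")
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat(sprintf("Tracer-depletion clearance fit: CL = %.4g +/- %.2g l/cell/min (n = %d, R2 = %.4f)%s\n",
              x$clearance_cl, x$se, x$n_used, x$r_squared,
              if (x$flagged_nonmonotone) " [non-monotone flag]" else ""))
  invisible(x)
}

#' Micro-beam X-ray fluorescence calibration against sorted cells
#'
#' Least-squares line of measured phosphorus mass against the number of
#' flow-sorted calibrant cells. The intercept absorbs the blank-filter
#' background; a through-origin variant is also reported. The calibrated
#' method's working window (sensitivity floor and upper linear range, in
#' cells) is carried along so that quantifications outside it are flagged.
#'
#' @param cells_sorted Numbers of cells in each calibration spot (> 0).
#' @param p_signal_g Measured phosphorus masses in grams (>= 0).
#' @param linear_range Two-element numeric: the validated `[min, max]` cell
#'   window, default `c(2e4, 7.5e5)`.
#' @return Object of class `sxrf_calibration`: list with `slope_g_per_cell`,
#'   `intercept_g`, their standard errors, `slope_through_origin`,
#'   `linear_range`, and the `lm` fit.
#' @export
sxrf_calibration <- function(cells_sorted, p_signal_g,
                             linear_range = c(2e4, 7.5e5)) {
  .check_num(cells_sorted, "cells_sorted", positive = TRUE)
  .check_num(p_signal_g, "p_signal_g", nonneg = TRUE)
  .check_num(linear_range, "linear_range", positive = TRUE, len = 2)
  if (length(cells_sorted) < 2 || length(unique(cells_sorted)) < 2)
    .stopf("at least 2 calibration points with distinct cell numbers are required")
  if (length(cells_sorted) != length(p_signal_g))
    .stopf("cells_sorted and p_signal_g must have equal length")
  fit <- stats::lm(p_signal_g ~ cells_sorted)
  cf <- suppressWarnings(summary(fit))$coefficients
  if (cf["cells_sorted", "Estimate"] <= 0)
    .stopf("calibration slope must be positive")
  fit0 <- stats::lm(p_signal_g ~ 0 + cells_sorted)
  structure(
    list(slope_g_per_cell = unname(cf["cells_sorted", "Estimate"]),
         slope_se = unname(cf["cells_sorted", "Std. Error"]),
         intercept_g = unname(cf["(Intercept)", "Estimate"]),
         intercept_se = unname(cf["(Intercept)", "Std. Error"]),
         slope_through_origin = unname(stats::coef(fit0)[1]),
         linear_range = linear_range, fit = fit),
    class = "sxrf_calibration")
}

#' @export
print.sxrf_calibration <- function(x, ...) {
  const <- physical_constants()
  cat("micro-SXRF calibration\n")
  cat(sprintf("  slope: %.4g g/cell (%.4g P atoms/cell); intercept %.3g g\n",
              x$slope_g_per_cell,
              x$slope_g_per_cell / const$phosphorus_molar_mass * const$avogadro,
              x$intercept_g))
  cat(sprintf("  linear range: %.3g - %.3g cells\n",
              x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Phosphorus quota of a cell preparation from its X-ray fluorescence signal
#'
#' Converts a background-corrected phosphorus mass into atoms per cell:
#' `atoms/cell = (p_signal - intercept) * N_A / (M_P * cells)`. Preparations
#' outside the calibrated cell window are flagged `out_of_range`; a
#' non-positive net signal returns a below-detection result (0 atoms,
#' flagged), not an error.
#'
#' @param cal An [sxrf_calibration()] object.
#' @param p_signal_g Measured phosphorus mass in grams.
#' @param cells Number of cells in the preparation (> 0).
#' @return A data frame with `p_atoms_per_cell`, `out_of_range`,
#'   `below_detection`.
#' @export
sxrf_quantify <- function(cal, p_signal_g, cells) {
  stopifnot(inherits(cal, "sxrf_calibration"))
  .check_num(p_signal_g, "p_signal_g", nonneg = TRUE)
  .check_num(cells, "cells", positive = TRUE)
  net <- p_signal_g - cal$intercept_g
  below <- net <= 0
  atoms <- ifelse(below, 0, net * .N_A / (.M_P * cells))
  data.frame(
    p_atoms_per_cell = atoms,
    out_of_range = cells < cal$linear_range[1] | cells > cal$linear_range[2],
    below_detection = below)
}

#' Cellular phosphorus expressed as genome equivalents
#'
#' `p_atoms / (p_per_bp * genome_bp)`. With the convention of 2 phosphorus
#' atoms per base pair (one per strand nucleotide), a 1.9e7-atom quota
#' against a 2.4 Mb genome is ~4 genome equivalents. The convention is a
#' parameter because published genome-equivalent figures are not always
#' reconcilable under a single value.
#'
#' @param p_atoms Phosphorus atoms per cell (>= 0).
#' @param genome_bp Genome size in base pairs (> 0).
#' @param p_per_bp Phosphorus atoms per base pair, default 2.
#' @return Genome equivalents (dimensionless).
#' @examples
#' genome_p_equivalents(1.9e7, 2.4e6)  # ~4
#' @export
genome_p_equivalents <- function(p_atoms, genome_bp, p_per_bp = 2) {
  .check_num(p_atoms, "p_atoms", nonneg = TRUE)
  .check_num(genome_bp, "genome_bp", positive = TRUE)
  .check_num(p_per_bp, "p_per_bp", positive = TRUE)
  p_atoms / (p_per_bp * genome_bp)
}
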