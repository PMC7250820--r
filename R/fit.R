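## objective machinery -------------------------------------------------------

.fit_default_params <- c("clearance_cl", "import_vmax", "assim_rate",
                         "pfa_retained_fraction")

## latent percent-of-added predictions for the observed (time, channel,
## protocol) combinations under candidate parameters
.predict_pct <- function(params, design, key_times, key) {
  pdesign <- design
  pdesign$sampling_times <- key_times
  pdesign$replicates <- 1L
  pred <- generate_pulse_chase(params, pdesign, noise_model("none"))
  stats::setNames(pred$value_pct_of_added,
                  paste(pred$time_min, pred$channel, pred$protocol))[key]
}

.pk_objective <- function(theta, fixed, fit_params, design, obs, key_times,
                          key, weighting) {
  vals <- as.list(exp(theta))
  names(vals) <- fit_params
  params <- do.call(kinetic_parameters, utils::modifyList(fixed, vals))
  pred <- .predict_pct(params, design, key_times, key)
  if (any(!is.finite(pred))) return(1e10)
  if (weighting == "sqrt") sum((sqrt(obs) - sqrt(pred))^2)
  else sum((obs - pred)^2)
}

#' Fit the pulse-chase compartment model to tracer time courses
#'
#' Weighted least squares of the compartment model of
#' [simulate_kinetics()]/[apply_measurement()] against observed
#' percent-of-added tracer values across all (time, channel, protocol,
#' replicate) records. The default loss operates on the square-root scale,
#' which stabilises the variance of Poisson-like scintillation counts;
#' `weighting = "none"` gives unweighted least squares.
#'
#' Optimisation is multi-start L-BFGS-B on the log-parameter scale: the
#' first start is `init`, the remaining `n_starts - 1` are drawn
#' log-uniformly between the bounds under `seed`. Ties are broken by lowest
#' objective, then lowest clearance. The import half-saturation `import_km`
#' is deliberately not fitted: pulse-chase data at two concentrations cannot
#' separate it from `import_vmax`.
#'
#' @param timecourse A `tracer_timecourse` (or data frame with columns
#'   `time_min`, `channel`, `protocol`, `replicate`, `value_pct_of_added`).
#' @param design The [experiment_design()] the data were collected under.
#' @param init A [kinetic_parameters()] object: starting values for the
#'   fitted parameters and fixed values for the rest. Default
#'   [fig3_parameters()].
#' @param fit_params Character vector of parameters to estimate, a subset of
#'   `clearance_cl`, `import_vmax`, `assim_rate`, `pfa_retained_fraction`.
#' @param lower,upper Named numeric bounds for the fitted parameters
#'   (natural scale). Defaults: `init / 30` and `init * 30`, with
#'   `pfa_retained_fraction` capped at 1.
#' @param n_starts Number of optimiser starts (>= 1), default 8.
#' @param seed Integer seed controlling the random starts, default 1.
#' @param weighting `"sqrt"` (default) or `"none"`.
#' @return An object of class `pkfit` with `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()`, `residuals()`, `simulate()` and
#'   `plot()` methods. Standard errors are Gauss-Newton (delta-method on
#'   the log scale).
#' @seealso [bootstrap_ci()] for resampling intervals.
#' @examples
#' \donttest{
#' tc <- generate_pulse_chase(fig3_parameters(), fig3_design(),
#'                            noise_model("poisson", 1e4, seed = 1))
#' fit <- fit_kinetics(tc, fig3_design(), n_starts = 2, seed = 1)
#' coef(fit)
#' }
#' @export
fit_kinetics <- function(timecourse, design, init = fig3_parameters(),
                         fit_params = .fit_default_params,
                         lower = NULL, upper = NULL,
                         n_starts = 8, seed = 1,
                         weighting = c("sqrt", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(timecourse), inherits(design, "experiment_design"),
            inherits(init, "kinetic_parameters"))
  req <- c("time_min", "channel", "protocol", "replicate",
           "value_pct_of_added")
  if (!all(req %in% names(timecourse)))
    .stopf("timecourse must have columns %s", paste(req, collapse = ", "))
  if (!all(timecourse$protocol %in% design$protocols))
    .stopf("timecourse protocols must be a subset of the design's protocols")
  fit_params <- match.arg(fit_params, .fit_default_params, several.ok = TRUE)
  obs <- timecourse$value_pct_of_added
  if (all(obs == 0)) .stopf("degenerate data: all observations are zero")
  .check_num(n_starts, "n_starts", positive = TRUE, len = 1)
  .check_num(seed, "seed", len = 1)

  fixed <- unclass(init)
  init_vals <- unlist(fixed[fit_params])
  if (is.null(lower)) {
    lower <- init_vals / 30
  }
  if (is.null(upper)) {
    upper <- init_vals * 30
    if ("pfa_retained_fraction" %in% fit_params)
      upper["pfa_retained_fraction"] <-
        min(upper["pfa_retained_fraction"], 1)
  }
  lower <- lower[fit_params]; upper <- upper[fit_params]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(upper < lower))
    .stopf("bounds must be finite, positive and ordered")
  if (any(init_vals < lower) || any(init_vals > upper))
    .stopf("bounds must enclose the initial values")

  key <- paste(timecourse$time_min, timecourse$channel, timecourse$protocol)
  key_times <- sort(unique(timecourse$time_min))

  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- matrix(log(init_vals), nrow = 1)
  if (n_starts > 1) {
    extra <- vapply(seq_len(n_starts - 1), function(i)
      stats::runif(length(fit_params), log(lower), log(upper)),
      numeric(length(fit_params)))
    starts <- rbind(starts, t(matrix(extra, nrow = length(fit_params))))
  }
  colnames(starts) <- fit_params

  runs <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      stats::optim(starts[i, ], .pk_objective, method = "L-BFGS-B",
                   lower = log(lower), upper = log(upper),
                   control = list(maxit = 200),
                   fixed = fixed, fit_params = fit_params, design = design,
                   obs = obs, key_times = key_times, key = key,
                   weighting = weighting),
      error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0)
    .stopf("optimiser failed to converge from every start")
  vals <- vapply(runs, `[[`, numeric(1), "value")
  cl_of <- vapply(runs, function(r)
    if ("clearance_cl" %in% fit_params) exp(r$par[["clearance_cl"]])
    else fixed$clearance_cl, numeric(1))
  best <- runs[[order(vals, cl_of)[1]]]
  est <- exp(best$par)
  ## L-BFGS-B flags an abnormal line search when started at (or reaching) a
  ## perfect fit; an essentially zero objective is a normal termination here
  converged <- best$convergence == 0 || best$value <= 1e-10

  ## Gauss-Newton standard errors via finite-difference Jacobian of the
  ## (possibly sqrt-scale) residual vector w.r.t. log-parameters
  resid_vec <- function(theta) {
    vals <- as.list(exp(theta)); names(vals) <- fit_params
    p <- do.call(kinetic_parameters, utils::modifyList(fixed, vals))
    pred <- .predict_pct(p, design, key_times, key)
    if (weighting == "sqrt") sqrt(obs) - sqrt(pred) else obs - pred
  }
  r0 <- resid_vec(best$par)
  h <- 1e-4
  J <- vapply(seq_along(best$par), function(j) {
    th <- best$par; th[j] <- th[j] + h
    (resid_vec(th) - r0) / h
  }, numeric(length(r0)))
  dof <- max(length(r0) - length(best$par), 1)
  sigma2 <- sum(r0^2) / dof
  se <- tryCatch({
    covm <- sigma2 * solve(crossprod(J))
    sqrt(diag(covm)) * est  # delta method log -> natural
  }, error = function(e) rep(NA_real_, length(est)))
  names(se) <- fit_params

  params_hat <- do.call(kinetic_parameters,
                        utils::modifyList(fixed, as.list(est)))
  structure(
    list(coefficients = est, se = se,
         estimates = params_hat,
         rss = best$value, weighting = weighting,
         convergence = converged,
         n_observations = length(obs),
         fit_params = fit_params, lower = lower, upper = upper,
         init = init, n_starts = n_starts, seed = seed,
         data = timecourse, design = design),
    class = "pkfit")
}

#' @export
coef.pkfit <- function(object, ...) object$coefficients

#' @export
print.pkfit <- function(x, ...) {
  cat("Pulse-chase compartment model fit (periplasmic buffer)\n")
  cat(sprintf("  %d observations, %s-scale least squares, RSS = %.5g, %s\n",
              x$n_observations, x$weighting, x$rss,
              if (x$convergence) "converged" else "NOT converged"))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.pkfit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, std_error = object$se,
                    lower_bound = object$lower, upper_bound = object$upper)
  out <- list(coefficients = tab, rss = object$rss,
              n_observations = object$n_observations,
              convergence = object$convergence,
              weighting = object$weighting, seed = object$seed,
              n_starts = object$n_starts)
  class(out) <- "summary.pkfit"
  out
}

#' @export
print.summary.pkfit <- function(x, ...) {
  cat("Pulse-chase compartment model fit\n\n")
  print(signif(as.matrix(x$coefficients), 4))
  cat(sprintf("\nRSS %.5g on %d observations (%s weighting); %d starts, seed %s; %s\n",
              x$rss, x$n_observations, x$weighting, x$n_starts,
              format(x$seed), if (x$convergence) "converged" else "not converged"))
  invisible(x)
}

#' Model predictions on the percent-of-added scale
#'
#' @param object A `pkfit`.
#' @param times Optional times (min); default: the fitted data's times.
#' @param protocols Optional protocols; default: those in the fitted data.
#' @param ... Unused.
#' @return Data frame `time_min`, `channel`, `protocol`, `value_pct_of_added`.
#' @export
predict.pkfit <- function(object, times = NULL, protocols = NULL, ...) {
  if (is.null(times)) times <- sort(unique(object$data$time_min))
  if (is.null(protocols)) protocols <- unique(object$data$protocol)
  d <- object$design
  d$sampling_times <- sort(unique(times))
  d$protocols <- protocols
  d$replicates <- 1L
  pred <- generate_pulse_chase(object$estimates, d, noise_model("none"))
  pred[, c("time_min", "channel", "protocol", "value_pct_of_added")]
}

#' @export
fitted.pkfit <- function(object, ...) {
  key <- paste(object$data$time_min, object$data$channel,
               object$data$protocol)
  key_times <- sort(unique(object$data$time_min))
  .predict_pct(object$estimates, object$design, key_times, key)
}

#' @export
residuals.pkfit <- function(object, ...) {
  object$data$value_pct_of_added - fitted(object)
}

#' Simulate new noisy datasets from a fitted model
#'
#' Parametric simulation: regenerates the fitted design under the estimated
#' parameters with Poisson counting noise.
#'
#' @param object A `pkfit`.
#' @param nsim Number of datasets, default 1.
#' @param seed Integer seed, default 1.
#' @param expected_counts Counts at 100% signal for the noise model.
#' @param ... Unused.
#' @return A list of `tracer_timecourse` data frames.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = 1,
                           expected_counts = 1e4, ...) {
  lapply(seq_len(nsim), function(i)
    generate_pulse_chase(object$estimates, object$design,
                         noise_model("poisson", expected_counts,
                                     seed = seed + i - 1)))
}

#' Plot observed and fitted pulse-chase time courses
#'
#' One panel per measurement protocol; points are observations, lines the
#' fitted model, colour-coded by isotope channel.
#'
#' @param x A `pkfit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pkfit <- function(x, ...) {
  prots <- unique(x$data$protocol)
  old <- graphics::par(mfrow = c(1, length(prots)))
  on.exit(graphics::par(old))
  cols <- c(P33 = "black", P32 = "red3")
  tgrid <- seq(min(x$data$time_min), max(x$data$time_min), length.out = 80)
  pred <- predict(x, times = tgrid)
  for (p in prots) {
    d <- x$data[x$data$protocol == p, ]
    graphics::plot(d$time_min, d$value_pct_of_added,
                   col = cols[as.character(d$channel)], pch = 16,
                   xlab = "time (min)", ylab = "% of added tracer",
                   main = p, ...)
    for (ch in unique(d$channel)) {
      pr <- pred[pred$protocol == p & pred$channel == ch, ]
      graphics::lines(pr$time_min, pr$value_pct_of_added,
                      col = cols[ch])
    }
  }
  invisible(x)
}

#' Case-resampling bootstrap intervals for a fitted pulse-chase model
#'
#' Resamples (time, channel, protocol, replicate) records with replacement,
#' refits from the point estimates, and returns percentile intervals.
#' Requires technical replication (at least 2 replicates) so that resampling
#' has within-condition variation to draw on.
#'
#' @param fit A converged `pkfit`.
#' @param n_boot Number of bootstrap datasets (>= 100), default 200.
#' @param seed Integer seed, default 1.
#' @param level Interval level, default 0.95.
#' @return Object of class `pkfit_boot`: list with `intervals` (data frame
#'   of per-parameter percentile bounds), the bootstrap `draws` matrix,
#'   `n_boot` and `seed`.
#' @export
bootstrap_ci <- function(fit, n_boot = 200, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "pkfit"))
  if (!fit$convergence) .stopf("bootstrap requires a converged fit")
  .check_num(n_boot, "n_boot", positive = TRUE, len = 1)
  if (n_boot < 100) .stopf("n_boot must be >= 100")
  if (length(unique(fit$data$replicate)) < 2)
    .stopf("bootstrap requires at least 2 replicates")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- nrow(fit$data)
  draws <- matrix(NA_real_, n_boot, length(fit$coefficients),
                  dimnames = list(NULL, fit$fit_params))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bfit <- tryCatch(
      fit_kinetics(fit$data[idx, ], fit$design, init = fit$estimates,
                   fit_params = fit$fit_params,
                   lower = fit$lower, upper = fit$upper,
                   n_starts = 1, seed = seed, weighting = fit$weighting),
      error = function(e) NULL)
    if (!is.null(bfit)) draws[b, ] <- bfit$coefficients
  }
  ok <- stats::complete.cases(draws)
  a <- (1 - level) / 2
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a))
  intervals <- data.frame(parameter = fit$fit_params,
                          estimate = unname(fit$coefficients),
                          lower = qs[1, ], upper = qs[2, ],
                          row.names = NULL)
  structure(list(intervals = intervals, draws = draws[ok, , drop = FALSE],
                 n_boot = n_boot, n_ok = sum(ok), seed = seed,
                 level = level),
            class = "pkfit_boot")
}

#' @export
print.pkfit_boot <- function(x, ...) {
  cat(sprintf("Bootstrap percentile intervals (%d/%d refits, %.0f%%, seed %s)\n",
              x$n_ok, x$n_boot, 100 * x$level, format(x$seed)))
  print(x$intervals)
  invisible(x)
}
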