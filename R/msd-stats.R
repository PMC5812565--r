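# Ensemble-averaged MSD, log-log profiles, anomalous-exponent fits and the
# apparent / instantaneous / effective diffusion coefficients.

#' Ensemble-averaged mean squared displacement
#'
#' For each trajectory record the per-time MSD is the average over tracers of
#' the squared displacement from the measurement origin,
#' \eqn{\langle r^2\rangle(t) = \frac1N \sum_i (x_i(t)-x_i(0))^2 +
#' (y_i(t)-y_i(0))^2}; profiles from replicate simulations are then averaged
#' with equal weight per ensemble.
#'
#' @param trajectories a `cd_trajectory` or a list of them sharing one
#'   recording grid.
#' @return an object of class `msd_profile`: a data frame with columns
#'   `time_ms` and `msd_um2`, with attributes `n_tracers` (per ensemble) and
#'   `n_ensembles`.
#' @export
#' @examples
#' cfg <- lattice_config(n_side = 50)
#' f <- build_obstacle_field(cfg)
#' p <- place_tracers(cfg, f, n_tracers = 50, exclusion = FALSE, seed = 1)
#' m <- ensemble_msd(simulate_lattice(cfg, f, p, sim_schedule(10), seed = 1))
#' head(m)
ensemble_msd <- function(trajectories) {
  if (inherits(trajectories, "cd_trajectory"))
    trajectories <- list(trajectories)
  if (length(trajectories) == 0) stopf("no trajectories supplied")
  times <- trajectories[[1]]$times_ms
  per_ens <- vapply(trajectories, function(tr) {
    stopifnot(inherits(tr, "cd_trajectory"))
    if (length(tr$times_ms) != length(times) ||
        any(abs(tr$times_ms - times) > 1e-9))
      stopf("trajectory recording grids differ; cannot average")
    if (ncol(tr$x) == 0) return(rep(NA_real_, length(times)))
    rowMeans(tr$x^2 + tr$y^2)
  }, numeric(length(times)))
  per_ens <- matrix(per_ens, nrow = length(times))
  msd <- rowMeans(per_ens)
  out <- data.frame(time_ms = times, msd_um2 = msd)
  attr(out, "n_tracers") <- ncol(trajectories[[1]]$x)
  attr(out, "n_ensembles") <- length(trajectories)
  attr(out, "per_ensemble") <- per_ens
  class(out) <- c("msd_profile", "data.frame")
  out
}

#' Log-log profile of an MSD curve
#'
#' The transform \eqn{\log(\langle r^2\rangle/t)} versus \eqn{\log t}
#' (natural logarithms). Under the power law
#' \eqn{\langle r^2\rangle = 4 D t^\alpha} this is a straight line of slope
#' \eqn{\alpha - 1} and intercept \eqn{\log 4D}, so normal diffusion is a
#' flat profile and subdiffusion a declining one.
#'
#' @param profile an [ensemble_msd()] result, or a data frame with `time_ms`
#'   and `msd_um2` columns.
#' @return data frame with columns `log_t` and `log_msd_t`; zero or negative
#'   MSD entries are dropped with a warning.
#' @export
loglog_profile <- function(profile) {
  t <- profile$time_ms
  m <- profile$msd_um2
  if (is.null(t) || is.null(m)) stopf("profile needs time_ms and msd_um2")
  keep <- t > 0 & m > 0
  if (any(!keep)) warning("dropping ", sum(!keep),
                          " non-positive MSD/time entries")
  data.frame(log_t = log(t[keep]), log_msd_t = log(m[keep] / t[keep]))
}

# Least-squares slope/intercept on a subset of a log-log table.
ll_fit <- function(ll, idx = seq_len(nrow(ll))) {
  f <- lm(log_msd_t ~ log_t, data = ll[idx, , drop = FALSE])
  cf <- coef(f)
  ss_tot <- sum((ll$log_msd_t[idx] - mean(ll$log_msd_t[idx]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(f$residuals^2) / ss_tot else 1
  list(intercept = unname(cf[1]), slope = unname(cf[2]), r2 = r2, fit = f)
}

#' Characterize diffusion from an MSD profile
#'
#' Fits the power-law model \eqn{\langle r^2\rangle = 4 D t^\alpha} through
#' its log-log representation and classifies the regime the way obstructed
#' lattice studies read these plots:
#'
#' * **normal** -- the global slope magnitude is within `flatness_tol`:
#'   \eqn{\alpha = 1}, \eqn{D} from the mean level of the profile;
#' * **anomalous** -- the late-time window is steeply and linearly declining
#'   (slope below `tail_slope`): \eqn{\alpha} and \eqn{D} from the tail fit;
#' * **transition** -- otherwise: \eqn{\alpha} is fitted on the initial
#'   segment up to the detected crossover to flatness, and the crossover time
#'   and length (MSD at the crossover) are recorded.
#'
#' Crossover detection uses local slopes over sliding windows of
#' `window_frac` of the log-time span; the crossover is the first time after
#' which the local slope stays within `flatness_tol`. Fitted \eqn{\alpha} is
#' clipped to `[0, 1.05]`, and values within `flatness_tol` of 1 are
#' reported as exactly 1 with regime `normal`.
#'
#' @param profile an [ensemble_msd()] result (or data frame with `time_ms`,
#'   `msd_um2`), or a log-log table with columns `log_t`, `log_msd_t`.
#' @param flatness_tol slope magnitude counted as "flat" (default 0.05).
#' @param tail_frac fraction of the log-time span forming the late-time
#'   window (default 0.25).
#' @param tail_slope slope threshold below which the tail counts as strongly
#'   anomalous (default -0.5).
#' @param window_frac sliding-window width for local slopes, as a fraction of
#'   the log-time span (default 0.2).
#' @param t_obs observation horizon (ms) at which the effective diffusion
#'   coefficient is evaluated (default 2000 ms, the standard 2 s measurement).
#' @return an object of class `diffusion_fit` with components `alpha`,
#'   `alpha_raw` (1 + the global log-log slope, neither clipped nor collapsed
#'   to the normal regime; a diagnostic for small departures from normality),
#'   `D_fit` (\eqn{\mu m^2 ms^{-\alpha}}), `D_eff` (\eqn{\mu m^2 ms^{-1}};
#'   also `D_eff_nm2_us` in \eqn{nm^2 \mu s^{-1}}), `regime`,
#'   `crossover_time_ms`, `crossover_length_um2`, and the fit inputs.
#' @export
#' @examples
#' t <- seq(1, 1000, length.out = 50)
#' m <- 4 * 2e-4 * t          # exactly normal diffusion
#' fit_alpha(data.frame(time_ms = t, msd_um2 = m))
fit_alpha <- function(profile, flatness_tol = 0.05, tail_frac = 0.25,
                      tail_slope = -0.5, window_frac = 0.2, t_obs = 2000) {
  ll <- if (!is.null(profile$log_t)) profile else loglog_profile(profile)
  ll <- ll[order(ll$log_t), , drop = FALSE]
  n <- nrow(ll)
  span <- if (n) diff(range(ll$log_t)) else 0
  if (n < 10 || span < log(10))
    stopf("fit-domain error: need >= 10 points spanning >= 1 decade of time")

  glob <- ll_fit(ll)
  regime <- NULL
  crossover_time <- NA_real_
  crossover_length <- NA_real_

  if (abs(glob$slope) <= flatness_tol) {
    regime <- "normal"
    alpha <- 1
    D_fit <- exp(mean(ll$log_msd_t)) / 4
  } else {
    tail_idx <- which(ll$log_t >= max(ll$log_t) - tail_frac * span)
    if (length(tail_idx) < 3) tail_idx <- seq(max(1, n - 2), n)
    tf <- ll_fit(ll, tail_idx)
    if (tf$slope <= tail_slope && tf$r2 >= 0.8) {
      regime <- "anomalous"
      alpha <- 1 + tf$slope
      D_fit <- exp(tf$intercept) / 4
    } else {
      regime <- "transition"
      w <- max(3, ceiling(window_frac * n))
      local_slope <- rep(NA_real_, n)
      for (k in seq_len(n - w + 1)) {
        idx <- k:(k + w - 1)
        local_slope[k] <- ll_fit(ll, idx)$slope
      }
      ok <- which(!is.na(local_slope))
      flat_from <- NA_integer_
      for (k in ok) {
        if (all(abs(local_slope[ok[ok >= k]]) <= flatness_tol)) {
          flat_from <- k
          break
        }
      }
      if (!is.na(flat_from)) {
        crossover_time <- exp(ll$log_t[flat_from])
        crossover_length <- exp(ll$log_msd_t[flat_from] + ll$log_t[flat_from])
        init_idx <- seq_len(max(3, flat_from))
      } else {
        init_idx <- seq_len(n)
      }
      inf <- ll_fit(ll, init_idx)
      alpha <- 1 + inf$slope
      D_fit <- exp(inf$intercept) / 4
    }
  }

  alpha <- min(max(alpha, 0), 1.05)
  if (abs(alpha - 1) <= flatness_tol && regime != "transition") {
    alpha <- 1
    regime <- "normal"
  }
  D_eff <- if (regime == "normal") D_fit else D_fit * t_obs^(alpha - 1)

  structure(
    list(alpha = alpha, alpha_raw = 1 + glob$slope,
         D_fit = D_fit, D_eff = D_eff,
         D_eff_nm2_us = D_eff * 1e3, regime = regime,
         crossover_time_ms = crossover_time,
         crossover_length_um2 = crossover_length,
         t_obs = t_obs,
         settings = list(flatness_tol = flatness_tol, tail_frac = tail_frac,
                         tail_slope = tail_slope, window_frac = window_frac),
         global_slope = glob$slope, loglog = ll),
    class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Diffusion characterization (%s regime)\n", x$regime))
  cat(sprintf("  alpha  %.4g\n", x$alpha))
  cat(sprintf("  D_fit  %.4g um^2/ms^alpha\n", x$D_fit))
  cat(sprintf("  D_eff  %.4g um^2/ms  (%.4g nm^2/us at t = %g ms)\n",
              x$D_eff, x$D_eff_nm2_us, x$t_obs))
  if (!is.na(x$crossover_time_ms))
    cat(sprintf("  crossover at %.4g ms, MSD %.4g um^2\n",
                x$crossover_time_ms, x$crossover_length_um2))
  invisible(x)
}

#' @export
summary.diffusion_fit <- function(object, ...) {
  cat(sprintf(
    "Power-law MSD model <r^2> = 4 D t^alpha fitted on %d log-log points\n",
    nrow(object$loglog)))
  print(object)
  cat(sprintf("  global log-log slope %.4g (flatness tolerance %g)\n",
              object$global_slope, object$settings$flatness_tol))
  invisible(object)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(alpha = object$alpha, D = object$D_fit)
}

#' @export
predict.diffusion_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) exp(object$loglog$log_t) else newdata
  4 * object$D_fit * t^object$alpha
}

#' @export
plot.diffusion_fit <- function(x, ...) {
  ll <- x$loglog
  graphics::plot(ll$log_t, ll$log_msd_t, xlab = "log t (ms)",
                 ylab = "log(MSD/t)", ...)
  graphics::abline(log(4 * x$D_fit), x$alpha - 1, col = 2)
  invisible(x)
}

#' Apparent diffusion coefficient of anomalous diffusion
#'
#' \eqn{D_{app}(t) = D\,t^{\alpha-1}}: the constant coefficient whose normal
#' diffusion would reach the same MSD at time `t`, i.e.
#' \eqn{4 D_{app}(t)\,t = 4 D t^\alpha}. For subdiffusion
#' (\eqn{\alpha < 1}) it decays with time.
#'
#' @param D_fit power-law constant \eqn{D}, \eqn{\mu m^2 ms^{-\alpha}}.
#' @param alpha anomalous exponent.
#' @param t time, ms (> 0).
#' @return \eqn{\mu m^2 ms^{-1}}.
#' @export
#' @examples
#' apparent_diffusion(1, 0.5, 4)  # 0.5
apparent_diffusion <- function(D_fit, alpha, t) {
  if (any(t <= 0)) stopf("t must be positive")
  D_fit * t^(alpha - 1)
}

#' Instantaneous diffusion coefficient of anomalous diffusion
#'
#' \eqn{D_{inst}(t) = \alpha D\,t^{\alpha-1}}: one quarter of the slope of
#' the MSD at time `t`; equals \eqn{\alpha D_{app}(t)}.
#'
#' @inheritParams apparent_diffusion
#' @return \eqn{\mu m^2 ms^{-1}}.
#' @export
instantaneous_diffusion <- function(D_fit, alpha, t) {
  alpha * apparent_diffusion(D_fit, alpha, t)
}

#' Effective diffusion coefficient at the observation horizon
#'
#' For normal diffusion the fitted constant itself; otherwise the apparent
#' diffusion coefficient evaluated at the observation horizon (2 s by
#' convention for these measurements).
#'
#' @param fit a [fit_alpha()] result.
#' @param t_obs observation horizon, ms.
#' @return \eqn{\mu m^2 ms^{-1}} (multiply by 1e3 for \eqn{nm^2 \mu s^{-1}}).
#' @export
effective_diffusion <- function(fit, t_obs = 2000) {
  stopifnot(inherits(fit, "diffusion_fit"))
  if (fit$regime == "normal") fit$D_fit
  else apparent_diffusion(fit$D_fit, fit$alpha, t_obs)
}

#' Fit the power-law MSD model to a generic MSD table
#'
#' Fits \eqn{\langle r^2\rangle = 4 D t^\alpha} to arbitrary (t, MSD) pairs,
#' for example externally digitized single-particle-tracking curves. The
#' default fits a straight line in log-log space; `method = "nls"` performs
#' nonlinear least squares on the original scale (started from the log-log
#' estimates).
#'
#' @param t times (> 0), ms.
#' @param msd MSD values (> 0), \eqn{\mu m^2}.
#' @param method `"loglog"` (default) or `"nls"`.
#' @return an object of class `msd_powerlaw` with `alpha`, `D` and standard
#'   errors; `coef()` returns `c(alpha, D)`.
#' @export
#' @examples
#' t <- 1:50
#' coef(fit_msd_powerlaw(t, 4 * 0.2 * t^0.7))
fit_msd_powerlaw <- function(t, msd, method = c("loglog", "nls")) {
  method <- match.arg(method)
  if (length(t) != length(msd)) stopf("t and msd lengths differ")
  if (length(t) < 3) stopf("fit error: need at least 3 points")
  if (any(t <= 0) || any(msd <= 0))
    stopf("fit error: times and MSD values must be positive")
  lf <- lm(log(msd) ~ log(t))
  cf <- coef(lf)
  # standard errors by hand: vcov.lm warns on exactly generated data
  n <- length(t)
  s2 <- sum(lf$residuals^2) / (n - 2)
  xtxi <- chol2inv(qr.R(lf$qr))
  se <- sqrt(pmax(s2 * diag(xtxi), 0))
  alpha <- unname(cf[2])
  D <- exp(unname(cf[1])) / 4
  alpha_se <- se[2]
  D_se <- D * se[1]             # delta method on the intercept
  fitted_obj <- lf
  if (method == "nls") {
    # exactly power-law data makes the relative-offset criterion degenerate;
    # warnOnly + the log-log start keeps the fit robust either way
    nf <- suppressWarnings(
      nls(msd ~ 4 * D * t^alpha, start = list(D = D, alpha = alpha),
          control = stats::nls.control(maxiter = 200, warnOnly = TRUE)))
    cf <- coef(nf)
    se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(nf)))),
                   error = function(e) c(NA_real_, NA_real_))
    D <- unname(cf["D"]); alpha <- unname(cf["alpha"])
    D_se <- unname(se[1]); alpha_se <- unname(se[2])
    fitted_obj <- nf
  }
  structure(list(alpha = alpha, D = D, alpha_se = alpha_se, D_se = D_se,
                 method = method, n = length(t), fit = fitted_obj),
            class = "msd_powerlaw")
}

#' @export
coef.msd_powerlaw <- function(object, ...) c(alpha = object$alpha, D = object$D)

#' @export
print.msd_powerlaw <- function(x, ...) {
  cat(sprintf("MSD power law <r^2> = 4 D t^alpha (%s fit, n = %d)\n",
              x$method, x$n))
  cat(sprintf("  alpha %.4g (se %.3g)\n  D     %.4g (se %.3g) um^2/ms^alpha\n",
              x$alpha, x$alpha_se, x$D, x$D_se))
  invisible(x)
}
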