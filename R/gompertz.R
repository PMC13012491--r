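#' Gompertz heat model
#'
#' Cumulative-heat form of the modified (Zwietering-style) Gompertz growth
#' model, reparameterized so each parameter is directly interpretable:
#' \deqn{Q(t) = Q_{max} \exp\{-\exp[(\mu_{max} e / Q_{max})(\lambda - t) + 1]\}}
#' with `q_max` the asymptotic total heat (J), `mu_max` the maximal heat
#' production rate (J h^-1, equal to the peak of the flow curve), and `lag`
#' the adaptation phase \eqn{\lambda} (h). `gompertz_flow()` is the exact
#' time derivative, converted to mW (1 mW sustained for 1 h releases 3.6 J,
#' so 1 J h^-1 = 1/3.6 mW).
#'
#' @param t time, hours.
#' @param q_max asymptotic heat, J (> 0).
#' @param mu_max maximal heat-production rate, J h^-1 (> 0).
#' @param lag adaptation phase, h (>= 0).
#' @return `gompertz_heat`: cumulative heat (J); `gompertz_flow`: heat flow
#'   (mW) at `t`.
#' @export
#' @examples
#' t <- seq(0, 80, 0.5)
#' q <- gompertz_heat(t, q_max = 2, mu_max = 0.1, lag = 10)
#' max(q) # approaches 2 J
gompertz_heat <- function(t, q_max, mu_max, lag) {
  q_max * exp(-exp((mu_max * exp(1) / q_max) * (lag - t) + 1))
}

#' @rdname gompertz_heat
#' @export
gompertz_flow <- function(t, q_max, mu_max, lag) {
  k <- mu_max * exp(1) / q_max
  u <- k * (lag - t) + 1
  dq_dt <- q_max * exp(-exp(u)) * exp(u) * k # J h^-1
  dq_dt / 3.6
}

JOULES_PER_MW_HOUR <- 3.6

trapz_cum <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' Convert a thermogram to cumulative heat
#'
#' Trapezoidal integration of heat flow (mW) over time (h), converted to
#' joules (1 mW h = 3.6 J). Negative recorded flows are retained: transient
#' baseline dips are physically meaningful in paired comparisons.
#'
#' @param tg a [thermogram()].
#' @return An object of class `"heat_curve"`: list with `time` (h), `q`
#'   (cumulative heat, J, starting at 0), and the thermogram's identifiers.
#' @export
#' @examples
#' tg <- thermogram(c(0, 0.5, 1), c(1, 1, 1))
#' integrate_heat(tg)$q # 0, 1.8, 3.6 J
integrate_heat <- function(tg) {
  stopifnot(inherits(tg, "thermogram"))
  if (length(tg$time) < 2) stop("need at least 2 points to integrate")
  q <- trapz_cum(tg$time, tg$heat_flow) * JOULES_PER_MW_HOUR
  structure(
    list(time = tg$time, q = q, sample_id = tg$sample_id,
         treatment = tg$treatment),
    class = "heat_curve"
  )
}

#' @export
print.heat_curve <- function(x, ...) {
  cat(sprintf("heat_curve '%s' (%s): final heat %.4g J over %.1f h\n",
              x$sample_id, x$treatment, x$q[length(x$q)],
              max(x$time) - min(x$time)))
  invisible(x)
}

#' Fit the Gompertz model to a cumulative-heat curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the cumulative heat
#' curve with multi-start initialization: `q_max` starts at the final
#' observed heat, `mu_max` at the maximal finite-difference flow, and the
#' lag start ranges over 0 h, the time at 10% of final heat, and the
#' configured fallback peak hour. The best-RSS converged start wins; ties go
#' to the smallest fitted lag. Fitting targets cumulative heat rather than
#' raw flow because integration damps instrument noise; flow-domain
#' residuals are still reported by [summary.gompertz_fit()].
#'
#' Derived quantities are always recomputed from the fitted parameters:
#' time-to-peak `ttp = lag + q_max / (e * mu_max)` (the flow maximum of this
#' parameterization) and the mean log-phase rate
#' `mu = (Q(ttp) - Q(lag)) / (ttp - lag)`, i.e. the average heat-production
#' rate between the end of the adaptation phase and the activity peak.
#'
#' @param curve a `heat_curve` (or a [thermogram()], integrated on the fly).
#' @param config a [pipeline_config()].
#' @return An object of class `"gompertz_fit"` with elements `q_max`,
#'   `mu_max`, `lag`, `mu`, `ttp`, `rss`, `converged`, `n_starts_used`,
#'   plus the data and call. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`, `deviance`.
#' @export
#' @examples
#' t <- seq(0, 80, 0.5)
#' tg <- thermogram(t, gompertz_flow(t, 2, 0.1, 10))
#' fit <- fit_gompertz(integrate_heat(tg))
#' coef(fit)
fit_gompertz <- function(curve, config = pipeline_config()) {
  if (inherits(curve, "thermogram")) curve <- integrate_heat(curve)
  stopifnot(inherits(curve, "heat_curve"))
  t <- curve$time
  q <- curve$q
  if (length(t) < 5) stop("need at least 5 points to fit")
  q_end <- q[length(q)]
  if (!(q_end > 0)) {
    stop("non-positive final heat (", signif(q_end, 3),
         " J): curve reported unfit, not forced")
  }

  q_max0 <- q_end
  mu_max0 <- max(diff(q) / diff(t))
  if (!(mu_max0 > 0)) mu_max0 <- q_end / (max(t) - min(t))
  t10 <- t[which(q >= 0.1 * q_end)[1]]
  lag_starts <- unique(pmax(0, c(0, t10, config$fallback_peak_hour)))

  dat <- data.frame(t = t, q = q)
  best <- NULL
  n_used <- 0L
  for (lag0 in lag_starts) {
    n_used <- n_used + 1L
    fit <- tryCatch(
      minpack.lm::nlsLM(
        q ~ q_max * exp(-exp((mu_max * exp(1) / q_max) * (lag - t) + 1)),
        data = dat,
        start = list(q_max = q_max0, mu_max = mu_max0, lag = lag0),
        lower = c(q_max = 1e-12, mu_max = 1e-12, lag = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    cf <- stats::coef(fit)
    if (is.null(best) || rss < best$rss - 1e-15 ||
        (abs(rss - best$rss) <= 1e-15 && cf[["lag"]] < best$lag)) {
      best <- list(q_max = cf[["q_max"]], mu_max = cf[["mu_max"]],
                   lag = cf[["lag"]], rss = rss)
    }
  }

  if (is.null(best)) {
    out <- list(q_max = NA_real_, mu_max = NA_real_, lag = NA_real_,
                mu = NA_real_, ttp = NA_real_, rss = NA_real_,
                converged = FALSE, n_starts_used = n_used,
                diagnostics = sprintf(
                  "no start converged (starts tried: lag0 = %s)",
                  paste(signif(lag_starts, 3), collapse = ", ")),
                data = curve, call = match.call())
    class(out) <- "gompertz_fit"
    return(out)
  }

  ttp <- best$lag + best$q_max / (exp(1) * best$mu_max)
  q_at <- function(x) gompertz_heat(x, best$q_max, best$mu_max, best$lag)
  mu <- (q_at(ttp) - q_at(best$lag)) / (ttp - best$lag)
  out <- list(q_max = best$q_max, mu_max = best$mu_max, lag = best$lag,
              mu = mu, ttp = ttp, rss = best$rss, converged = TRUE,
              n_starts_used = n_used, diagnostics = NULL,
              data = curve, call = match.call())
  class(out) <- "gompertz_fit"
  out
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz heat-curve fit", if (!x$converged) " (NOT converged)", "\n",
      sep = "")
  if (x$converged) {
    cat(sprintf(
      "  Q_max  = %.4g J\n  mu_max = %.4g J/h\n  lag    = %.4g h\n  TTP    = %.4g h\n  mu     = %.4g J/h\n  RSS    = %.3g J^2 (%d starts)\n",
      x$q_max, x$mu_max, x$lag, x$ttp, x$mu, x$rss, x$n_starts_used
    ))
  } else {
    cat("  ", x$diagnostics, "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) {
  c(q_max = object$q_max, mu_max = object$mu_max, lag = object$lag)
}

#' @export
deviance.gompertz_fit <- function(object, ...) object$rss

#' Predict heat or flow from a Gompertz fit
#'
#' @param object a `gompertz_fit`.
#' @param newdata optional list/data frame with a `time` component (hours);
#'   defaults to the fitted time grid.
#' @param type `"heat"` (cumulative J) or `"flow"` (mW).
#' @param ... unused.
#' @export
predict.gompertz_fit <- function(object, newdata = NULL,
                                 type = c("heat", "flow"), ...) {
  type <- match.arg(type)
  if (!object$converged) stop("cannot predict from an unconverged fit")
  t <- if (is.null(newdata)) object$data$time else newdata$time
  if (type == "heat") {
    gompertz_heat(t, object$q_max, object$mu_max, object$lag)
  } else {
    gompertz_flow(t, object$q_max, object$mu_max, object$lag)
  }
}

#' @export
fitted.gompertz_fit <- function(object, ...) predict(object)

#' @export
residuals.gompertz_fit <- function(object, type = c("heat", "flow"), ...) {
  type <- match.arg(type)
  if (type == "heat") {
    object$data$q - predict(object, type = "heat")
  } else {
    t <- object$data$time
    obs_flow <- c(NA, diff(object$data$q) / diff(t)) / JOULES_PER_MW_HOUR
    obs_flow - predict(object, type = "flow")
  }
}

#' @export
summary.gompertz_fit <- function(object, ...) {
  res_q <- if (object$converged) residuals(object, "heat") else NA_real_
  res_f <- if (object$converged) residuals(object, "flow") else NA_real_
  out <- list(
    fit = object,
    heat_rmse = sqrt(mean(res_q^2)),
    flow_rmse = sqrt(mean(res_f^2, na.rm = TRUE)),
    n = length(object$data$time)
  )
  class(out) <- "summary.gompertz_fit"
  out
}

#' @export
print.summary.gompertz_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  n = %d points; heat RMSE %.3g J; flow RMSE %.3g mW\n",
              x$n, x$heat_rmse, x$flow_rmse))
  invisible(x)
}

#' @export
plot.gompertz_fit <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  t <- x$data$time
  graphics::plot(t, x$data$q, pch = 16, cex = 0.4, xlab = "time (h)",
                 ylab = "cumulative heat (J)", main = x$data$sample_id, ...)
  if (x$converged) {
    graphics::lines(t, predict(x, type = "heat"), col = 2, lwd = 2)
    graphics::abline(v = c(x$lag, x$ttp), lty = 3, col = "grey40")
  }
  obs_flow <- c(NA, diff(x$data$q) / diff(t)) / JOULES_PER_MW_HOUR
  graphics::plot(t, obs_flow, type = "l", col = "grey50", xlab = "time (h)",
                 ylab = "heat flow (mW)", main = "flow domain")
  if (x$converged) graphics::lines(t, predict(x, type = "flow"), col = 2)
  invisible(x)
}

#' Simulate heat curves from a fitted Gompertz model
#'
#' Draws `nsim` replicates of the fitted cumulative-heat curve with additive
#' Gaussian noise at the residual standard deviation (parametric bootstrap
#' style).
#'
#' @param object a converged `gompertz_fit`.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A matrix (time points x nsim) of simulated heat values.
#' @export
simulate.gompertz_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from an unconverged fit")
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, type = "heat")
  sd_hat <- sqrt(object$rss / max(1, length(mu) - 3))
  matrix(stats::rnorm(length(mu) * nsim, mean = mu, sd = sd_hat),
         ncol = nsim)
}

#' Detect the activity peak of a thermogram
#'
#' Smooths the flow with a centred moving average (window
#' `config$peak_smooth_window` hours) and takes the global maximum. The
#' maximum qualifies as a peak only if it is interior to the record and the
#' smoothed curve rises at least `config$peak_prominence` mW above its
#' minimum. When no peak qualifies, `found` is `FALSE` and `peak_time`
#' falls back to `config$fallback_peak_hour` (the sampling rule used when
#' no activity peak occurs by then).
#'
#' @param tg a [thermogram()].
#' @param config a [pipeline_config()].
#' @return List with `peak_time` (h), `peak_flow` (mW, smoothed), `found`.
#' @export
detect_peak <- function(tg, config = pipeline_config()) {
  stopifnot(inherits(tg, "thermogram"))
  n <- length(tg$time)
  dt <- if (n >= 2) stats::median(diff(tg$time)) else 1
  half <- max(0L, floor(config$peak_smooth_window / (2 * dt)))
  s <- vapply(seq_len(n), function(i) {
    mean(tg$heat_flow[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  i_max <- which.max(s)
  prominence <- max(s) - min(s)
  interior <- i_max > 1 && i_max < n
  if (interior && prominence >= config$peak_prominence) {
    list(peak_time = tg$time[i_max], peak_flow = s[i_max], found = TRUE)
  } else {
    list(peak_time = config$fallback_peak_hour,
         peak_flow = if (n) s[i_max] else NA_real_, found = FALSE)
  }
}

#' Paired spiked-vs-control delta of a thermogram pair
#'
#' Each control ampoule is the activity baseline for its spiked partner.
#' Cumulative heats are compared on the common time support (the finer
#' series' grid; the coarser series is linearly interpolated). A sample is
#' called activity-responsive when the spiked member released more total
#' heat than its control (`delta_auc > 0`). `cd_imm` is the spiked/control
#' final-heat ratio, a documented proxy for the Cd immobilization ratio.
#'
#' @param spiked,control [thermogram()]s sharing `sample_id`.
#' @param spiked_fit,control_fit optional [fit_gompertz()] results for the
#'   pair; when supplied, `delta_qmax` and `delta_mumax` are populated.
#' @return List of class `"paired_delta"`: `sample_id`, `delta_auc` (J),
#'   `delta_qmax` (J), `delta_mumax` (J h^-1), `cd_imm`, `cd_imm_defined`,
#'   `activity_responsive`.
#' @export
paired_delta <- function(spiked, control, spiked_fit = NULL,
                         control_fit = NULL) {
  stopifnot(inherits(spiked, "thermogram"), inherits(control, "thermogram"))
  if (!identical(spiked$sample_id, control$sample_id)) {
    stop("pair members have different sample ids: '", spiked$sample_id,
         "' vs '", control$sample_id, "'")
  }
  lo <- max(min(spiked$time), min(control$time))
  hi <- min(max(spiked$time), max(control$time))
  if (!(hi > lo)) stop("thermogram pair has no overlapping time support")
  # evaluate on the finer member's grid, restricted to the common support
  finer <- if (length(spiked$time) >= length(control$time)) spiked else control
  grid <- finer$time[finer$time >= lo & finer$time <= hi]
  fs <- stats::approx(spiked$time, spiked$heat_flow, grid)$y
  fc <- stats::approx(control$time, control$heat_flow, grid)$y
  auc_s <- sum(diff(grid) * (fs[-1] + fs[-length(fs)]) / 2) * JOULES_PER_MW_HOUR
  auc_c <- sum(diff(grid) * (fc[-1] + fc[-length(fc)]) / 2) * JOULES_PER_MW_HOUR
  delta_auc <- auc_s - auc_c
  delta_qmax <- delta_mumax <- NA_real_
  if (!is.null(spiked_fit) && !is.null(control_fit) &&
      isTRUE(spiked_fit$converged) && isTRUE(control_fit$converged)) {
    delta_qmax <- spiked_fit$q_max - control_fit$q_max
    delta_mumax <- spiked_fit$mu_max - control_fit$mu_max
  }
  cd_imm_defined <- auc_c != 0
  structure(
    list(sample_id = spiked$sample_id,
         delta_auc = delta_auc,
         delta_qmax = delta_qmax,
         delta_mumax = delta_mumax,
         cd_imm = if (cd_imm_defined) auc_s / auc_c else NA_real_,
         cd_imm_defined = cd_imm_defined,
         activity_responsive = delta_auc > 0),
    class = "paired_delta"
  )
}

#' @export
print.paired_delta <- function(x, ...) {
  cat(sprintf(
    "paired_delta '%s': dAUC = %.4g J, dQmax = %.4g J, dMumax = %.4g J/h, Cd_imm = %.3g -> %s\n",
    x$sample_id, x$delta_auc, x$delta_qmax, x$delta_mumax, x$cd_imm,
    if (x$activity_responsive) "activity-responsive" else "not responsive"
  ))
  invisible(x)
}
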