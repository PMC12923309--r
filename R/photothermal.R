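#' Temperature-time trace
#'
#' A heating/cooling time series from a photothermal experiment: sample
#' times (s), temperatures (deg C), a per-sample laser on/off marker, and
#' the ambient (surrounding) temperature.
#'
#' @param times Strictly increasing sample times in seconds (>= 2).
#' @param temperatures Temperatures in deg C, one per sample.
#' @param laser_on Integer/logical vector, 1 while the laser is on.
#' @param t_surr Ambient temperature in deg C (default: first sample).
#' @return An object of class `temperature_trace`.
#' @export
temperature_trace <- function(times, temperatures, laser_on,
                              t_surr = temperatures[1]) {
  if (length(times) < 2) stop("a trace needs at least 2 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(temperatures) != length(times) ||
      length(laser_on) != length(times))
    stop("times, temperatures and laser_on must have equal length")
  structure(list(times = as.numeric(times),
                 temperatures = as.numeric(temperatures),
                 laser_on = as.integer(laser_on),
                 t_surr = as.numeric(t_surr)),
            class = "temperature_trace")
}

#' Lumped thermal parameters of a photothermal cell
#'
#' The lumped (well-stirred) energy balance
#' `m Cp dT/dt = eta I (1 - 10^(-Abs)) + Q_dis - hS (T - T_surr)`
#' describes heating of a solution of mass `m` under laser power `I`:
#' `eta` is the photothermal conversion efficiency, `Abs` the decadic
#' absorbance at the laser wavelength, `Q_dis` the baseline dissipation of
#' the blank cell and `hS` the lumped heat-transfer coefficient times
#' surface area. The cooling time constant is `tau_c = m Cp / hS`.
#'
#' @param m_g Solution mass in grams.
#' @param cp_J_gC Specific heat in J/g/degC (default 4.18, water).
#' @param hS_mW_C Lumped transfer coefficient, mW/degC. Give either this
#'   or `tau_c_s`; the other is filled in from `hS = m Cp / tau_c`.
#' @param tau_c_s Cooling time constant in seconds.
#' @param q_dis_mW Baseline dissipation of the blank cell, mW (default 0).
#' @param I_mW Incident laser power in mW.
#' @param abs_lambda Decadic absorbance of the solution at the laser
#'   wavelength (dimensionless).
#' @param t_surr_C Surrounding temperature, deg C.
#' @return An object of class `lumped_thermal_params`.
#' @export
lumped_thermal_params <- function(m_g = 1, cp_J_gC = 4.18, hS_mW_C = NULL,
                                  tau_c_s = NULL, q_dis_mW = 0, I_mW = 2000,
                                  abs_lambda = 1.0, t_surr_C = 25) {
  if (m_g <= 0 || cp_J_gC <= 0 || I_mW <= 0)
    stop("m_g, cp_J_gC and I_mW must be positive")
  if (abs_lambda < 0) stop("abs_lambda must be nonnegative")
  if (is.null(hS_mW_C) && is.null(tau_c_s))
    stop("give one of hS_mW_C or tau_c_s")
  if (is.null(hS_mW_C)) hS_mW_C <- compute_hS(m_g, cp_J_gC, tau_c_s)
  if (hS_mW_C <= 0) stop("hS must be positive")
  tau_c_s <- 1000 * m_g * cp_J_gC / hS_mW_C
  structure(list(m_g = m_g, cp_J_gC = cp_J_gC, hS_mW_C = hS_mW_C,
                 tau_c_s = tau_c_s, q_dis_mW = q_dis_mW, I_mW = I_mW,
                 abs_lambda = abs_lambda, t_surr_C = t_surr_C),
            class = "lumped_thermal_params")
}

#' Lumped heat-transfer coefficient from the cooling time constant
#'
#' `hS = m Cp / tau_c`, reported in mW/degC.
#'
#' @param m_g Mass in grams.
#' @param cp_J_gC Specific heat in J/g/degC.
#' @param tau_c_s Cooling time constant in seconds.
#' @return hS in mW/degC.
#' @examples
#' compute_hS(1, 4.18, 209)  # 20 mW/degC
#' @export
compute_hS <- function(m_g, cp_J_gC, tau_c_s) {
  if (m_g <= 0 || cp_J_gC <= 0 || tau_c_s <= 0)
    stop("m_g, cp_J_gC and tau_c_s must be positive")
  1000 * m_g * cp_J_gC / tau_c_s
}

#' Forward-simulate a lumped heating/cooling trace
#'
#' Integrates the lumped energy balance with the laser source term
#' `eta I (1 - 10^(-Abs)) + Q_dis` active during the on-segment and absent
#' during the off-segment, using the exact exponential solution of the
#' linear ODE on each segment (no numerical integration error).
#'
#' @param params A [lumped_thermal_params()].
#' @param eta Photothermal conversion efficiency in `[0, 1]`.
#' @param on_s Laser-on duration in seconds.
#' @param off_s Laser-off (cooling) duration in seconds.
#' @param dt_s Sampling interval in seconds.
#' @param t0_C Initial temperature (default `params$t_surr_C`).
#' @return A [temperature_trace()].
#' @export
simulate_heating <- function(params, eta, on_s, off_s, dt_s = 1,
                             t0_C = params$t_surr_C) {
  stopifnot(inherits(params, "lumped_thermal_params"))
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  if (on_s <= 0 || off_s <= 0 || dt_s <= 0)
    stop("durations and dt must be positive")
  tau <- params$tau_c_s
  src_mW <- eta * params$I_mW * (1 - 10^(-params$abs_lambda)) + params$q_dis_mW
  t_ss <- params$t_surr_C + src_mW / params$hS_mW_C
  t_on <- seq(0, on_s, by = dt_s)
  T_on <- t_ss + (t0_C - t_ss) * exp(-t_on / tau)
  t_peak <- T_on[length(T_on)]
  t_off <- seq(dt_s, off_s, by = dt_s)
  T_off <- params$t_surr_C + (t_peak - params$t_surr_C) * exp(-t_off / tau)
  temperature_trace(c(t_on, on_s + t_off), c(T_on, T_off),
                    c(rep(1L, length(t_on)), rep(0L, length(t_off))),
                    t_surr = params$t_surr_C)
}

#' Extract the cooling segment of a trace
#'
#' @param trace A [temperature_trace()].
#' @return List with `times` (seconds since laser-off), `temperatures`,
#'   `t_off` (the laser-off instant) and `T_max` (temperature at laser-off).
#' @export
cooling_segment <- function(trace) {
  stopifnot(inherits(trace, "temperature_trace"))
  on <- trace$laser_on == 1
  if (!any(on) || !any(!on))
    stop("trace must contain both an on- and an off-segment")
  i_off <- max(which(on))
  if (i_off == length(trace$times))
    stop("trace has no cooling samples after laser-off")
  idx <- i_off:length(trace$times)    # t = 0 is the laser-off sample
  list(times = trace$times[idx] - trace$times[i_off],
       temperatures = trace$temperatures[idx],
       t_off = trace$times[i_off],
       T_max = trace$temperatures[i_off])
}

#' Dimensionless cooling transform
#'
#' Maps the cooling segment to `(t, ln theta)` with
#' `theta = (T - T_surr) / (T_max - T_surr)`; for single-exponential
#' cooling `ln theta = -t / tau_c`. Samples at or below the ambient
#' temperature are excluded (log undefined), as are samples within the
#' sensor-lag window right after laser-off.
#'
#' @param trace A [temperature_trace()].
#' @param lag_s Seconds after laser-off to exclude (default 2).
#' @param theta_min Exclude samples with `theta` below this floor, where
#'   measurement noise dominates the log (default 0.05).
#' @return Data frame with columns `t_s` and `ln_theta`.
#' @export
theta_transform <- function(trace, lag_s = 2, theta_min = 0.05) {
  seg <- cooling_segment(trace)
  dT <- seg$T_max - trace$t_surr
  if (dT <= 0) stop("degenerate trace: T_max must exceed T_surr")
  theta <- (seg$temperatures - trace$t_surr) / dT
  keep <- seg$times >= lag_s & theta > theta_min & theta <= 1
  if (!any(keep))
    stop("no usable cooling samples above the ambient temperature")
  data.frame(t_s = seg$times[keep], ln_theta = log(theta[keep]))
}

#' Fit the cooling time constant from the log-theta line
#'
#' Ordinary least squares of `ln theta` on time: the slope is `-1/tau_c`.
#'
#' @param theta A data frame from [theta_transform()].
#' @return List with `tau_c_s`, `r_squared`, `n_points` and `slope`.
#' @export
fit_tau_c <- function(theta) {
  if (nrow(theta) < 3) stop("need at least 3 usable cooling points")
  fit <- lm(ln_theta ~ t_s, data = theta)
  slope <- coef(fit)[["t_s"]]
  if (slope >= 0) stop("cooling fit gave a non-negative slope")
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless traces fit exactly
  list(tau_c_s = -1 / slope, r_squared = r2,
       n_points = nrow(theta), slope = slope)
}

#' Baseline dissipation from a blank-cell trace
#'
#' From a trace of the background solution alone: fits the blank's
#' cooling constant, then reads the steady-state balance
#' `Q_dis = hS_blank * (T_max_blank - T_surr)`.
#'
#' @param blank_trace A [temperature_trace()] of the blank cell.
#' @param m_g,cp_J_gC Mass and specific heat of the blank solution.
#' @param lag_s,theta_min Passed to [theta_transform()].
#' @return Q_dis in mW.
#' @export
estimate_q_dis <- function(blank_trace, m_g = 1, cp_J_gC = 4.18,
                           lag_s = 2, theta_min = 0.05) {
  fit <- fit_tau_c(theta_transform(blank_trace, lag_s, theta_min))
  hS <- compute_hS(m_g, cp_J_gC, fit$tau_c_s)
  dT <- max(blank_trace$temperatures[blank_trace$laser_on == 1]) -
    blank_trace$t_surr
  hS * dT
}

#' Photothermal conversion efficiency from lumped parameters
#'
#' `eta = [hS (T_max - T_surr) - Q_dis] / [I (1 - 10^(-Abs))]`:
#' the steady-state heat output attributable to the absorber, divided by
#' the optical power it absorbs (decadic attenuation, matching
#' spectrophotometric absorbance).
#'
#' @param hS_mW_C Lumped transfer coefficient, mW/degC.
#' @param t_max_C Maximum (plateau) temperature, deg C.
#' @param t_surr_C Surrounding temperature, deg C.
#' @param q_dis_mW Baseline dissipation of the blank, mW.
#' @param I_mW Incident laser power, mW.
#' @param abs_lambda Decadic absorbance at the laser wavelength (> 0).
#' @param diagnostics Optional list (e.g. the [fit_tau_c()] output) echoed
#'   into the result.
#' @return An object of class `pce_result`: `eta` (dimensionless; multiply
#'   by 100 for percent), inputs, `clamped` flag and diagnostics. Values
#'   outside `[0, 1]` are clamped with a warning - they signal
#'   inconsistent inputs.
#' @examples
#' compute_pce(hS_mW_C = 2, t_max_C = 45, t_surr_C = 25, q_dis_mW = 5,
#'             I_mW = 300, abs_lambda = 1)$eta  # 0.1296...
#' @export
compute_pce <- function(hS_mW_C, t_max_C, t_surr_C, q_dis_mW = 0, I_mW,
                        abs_lambda, diagnostics = NULL) {
  if (I_mW <= 0) stop("laser power I must be positive")
  if (abs_lambda <= 0) stop("no absorbed light: abs_lambda must be > 0")
  if (t_max_C <= t_surr_C) stop("T_max must exceed T_surr")
  eta <- (hS_mW_C * (t_max_C - t_surr_C) - q_dis_mW) /
    (I_mW * (1 - 10^(-abs_lambda)))
  clamped <- FALSE
  if (eta < 0 || eta > 1) {
    warning("estimated eta = ", signif(eta, 4),
            " outside [0, 1]; clamped (check inputs)")
    eta <- min(max(eta, 0), 1)
    clamped <- TRUE
  }
  structure(list(eta = eta, hS_mW_C = hS_mW_C, t_max_C = t_max_C,
                 t_surr_C = t_surr_C, q_dis_mW = q_dis_mW, I_mW = I_mW,
                 abs_lambda = abs_lambda, clamped = clamped,
                 diagnostics = diagnostics),
            class = "pce_result")
}

#' @export
print.pce_result <- function(x, ...) {
  cat(sprintf("photothermal conversion efficiency: %.1f%%\n", 100 * x$eta))
  if (!is.null(x$diagnostics))
    cat(sprintf("  tau_c = %.1f s (R^2 = %.4f, %d cooling points), hS = %.2f mW/degC\n",
                x$diagnostics$tau_c_s, x$diagnostics$r_squared,
                x$diagnostics$n_points, x$hS_mW_C))
  invisible(x)
}

#' Estimate the photothermal conversion efficiency from a trace
#'
#' The full estimation pipeline: extract the cooling segment, fit
#' `tau_c` from the `ln theta` line, convert to `hS = m Cp / tau_c`, read
#' the plateau temperature from the end of the heating segment, and apply
#' the efficiency formula. Assumes the heating segment reaches its
#' steady-state plateau.
#'
#' @param trace A [temperature_trace()].
#' @param m_g,cp_J_gC Solution mass (g) and specific heat (J/g/degC).
#' @param I_mW Incident laser power, mW.
#' @param abs_lambda Decadic absorbance at the laser wavelength.
#' @param q_dis_mW Baseline dissipation (mW), e.g. from
#'   [estimate_q_dis()]; defaults to 0.
#' @param t_max_n Number of trailing laser-on samples averaged for the
#'   plateau temperature (default 5; robust to sensor noise).
#' @param lag_s,theta_min Passed to [theta_transform()].
#' @return A `pce_result` (see [compute_pce()]) with fit diagnostics.
#' @export
estimate_pce <- function(trace, m_g = 1, cp_J_gC = 4.18, I_mW,
                         abs_lambda, q_dis_mW = 0, t_max_n = 5,
                         lag_s = 2, theta_min = 0.05) {
  fit <- fit_tau_c(theta_transform(trace, lag_s, theta_min))
  hS <- compute_hS(m_g, cp_J_gC, fit$tau_c_s)
  on_idx <- which(trace$laser_on == 1)
  tail_idx <- tail(on_idx, t_max_n)
  t_max <- mean(trace$temperatures[tail_idx])
  compute_pce(hS, t_max, trace$t_surr, q_dis_mW, I_mW, abs_lambda,
              diagnostics = fit)
}
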