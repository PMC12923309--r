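#' Cumulative equivalent minutes at 43 degC (CEM43)
#'
#' Thermal dose `CEM43 = sum_i dt_i * R^(43 - T_i)` in minutes, with
#' `R = 0.25` below 43 degC and `R = 0.5` above. At exactly 43 degC the
#' exponent is zero, so the choice of R is immaterial; 0.5 is used. Each
#' interval between consecutive samples contributes with its left-endpoint
#' temperature by default (`midpoint = TRUE` uses the interval midpoint;
#' the difference vanishes as dt -> 0).
#'
#' @param trace A [temperature_trace()] (times in seconds).
#' @param midpoint Use midpoint instead of left-endpoint temperatures.
#' @return An object of class `thermal_dose`: `cem43_min`, per-interval
#'   contributions (`t_s`, `dt_min`, `T_C`, `minutes`).
#' @examples
#' tr <- temperature_trace(seq(0, 600, 10), rep(44, 61), rep(1L, 61))
#' cem43(tr)$cem43_min  # 20
#' @export
cem43 <- function(trace, midpoint = FALSE) {
  stopifnot(inherits(trace, "temperature_trace"))
  dt_min <- diff(trace$times) / 60
  n <- length(trace$times)
  T_int <- if (midpoint)
    (trace$temperatures[-n] + trace$temperatures[-1]) / 2
  else trace$temperatures[-n]
  R <- ifelse(T_int < 43, 0.25, 0.5)
  contrib <- dt_min * R^(43 - T_int)
  structure(list(cem43_min = sum(contrib),
                 intervals = data.frame(t_s = trace$times[-n],
                                        dt_min = dt_min, T_C = T_int,
                                        minutes = contrib)),
            class = "thermal_dose")
}

#' @export
print.thermal_dose <- function(x, ...) {
  cat(sprintf("thermal dose: %.4g equivalent minutes at 43 degC (%d intervals)\n",
              x$cem43_min, nrow(x$intervals)))
  invisible(x)
}

#' Contrast-enhancement ratios
#'
#' `CE_t = signal_t / baseline`: the post-injection signal in the region
#' of interest relative to the pre-injection baseline, per timepoint.
#'
#' @param baseline Pre-injection signal (arbitrary units, > 0).
#' @param signals Named or unnamed numeric vector of post-injection
#'   signals, keyed by timepoint.
#' @return Numeric vector of CE ratios (same names as `signals`).
#' @examples
#' contrast_enhancement(1.0, c(`0h` = 2.3, `4h` = 2.6))
#' @export
contrast_enhancement <- function(baseline, signals) {
  if (!is.numeric(baseline) || length(baseline) != 1 || baseline <= 0)
    stop("baseline signal must be a single positive number")
  signals / baseline
}

#' Photoacoustic initial-pressure proxy
#'
#' The initial photoacoustic pressure is proportional to the absorbed
#' optical energy density: `p0 = Gamma * mu_a * Phi = Gamma * A`. This
#' proxy scales an absorbed-energy-density map elementwise by the
#' Grueneisen parameter; no acoustic propagation is modelled.
#'
#' @param absorbed Absorbed energy density map (any numeric array, J/mm^3)
#'   or a `fluence_map` (its `A` grid is used).
#' @param grueneisen Grueneisen parameter Gamma (>= 0, dimensionless).
#' @return Array of the same shape, proxy pressure units.
#' @export
pa_signal_proxy <- function(absorbed, grueneisen) {
  if (!is.numeric(grueneisen) || grueneisen < 0)
    stop("Grueneisen parameter must be nonnegative")
  if (inherits(absorbed, "fluence_map")) absorbed <- absorbed$A
  grueneisen * absorbed
}
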