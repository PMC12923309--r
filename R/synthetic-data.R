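#' Synthetic absorber spectra: IcG monomer and J-aggregate
#'
#' Gaussian-band models of the two spectral species. The monomer carries
#' its dominant band at 780 nm with a 710 nm shoulder; the J-aggregate
#' (LJA) carries a dominant band redshifted to 890 nm plus a minor
#' residual 780 nm band, calibrated so that the extinction ratios
#' `eps(852)/eps(808)` and `eps(890)/eps(808)` both exceed 3. Band
#' magnitudes are expressed relative to a monomer 780 nm peak of
#' 2e5 /M/cm; these are structural stand-ins, not measured values.
#'
#' @param kind `"monomer"` or `"j_aggregate"`.
#' @param bands Optional override: data frame with columns `center_nm`,
#'   `width_nm` (Gaussian sigma) and `peak` (per M per cm).
#' @param wavelengths nm grid (default 650..1000 in 1 nm steps).
#' @return An [absorber_spectrum()].
#' @examples
#' lja <- gen_absorbance_spectra("j_aggregate")
#' epsilon_at(lja, 890) / epsilon_at(lja, 808)  # > 3
#' @export
gen_absorbance_spectra <- function(kind = c("monomer", "j_aggregate"),
                                   bands = NULL,
                                   wavelengths = seq(650, 1000, by = 1)) {
  kind <- match.arg(kind)
  if (is.null(bands)) {
    bands <- switch(kind,
      monomer = data.frame(center_nm = c(780, 710),
                           width_nm = c(25, 20),
                           peak = c(2.0e5, 0.5e5)),
      j_aggregate = data.frame(center_nm = c(890, 780),
                               width_nm = c(30, 28),
                               peak = c(2.5e5, 0.35e5)))
  }
  if (any(bands$width_nm <= 0) || any(bands$peak < 0))
    stop("band widths must be positive and peaks nonnegative")
  eps <- rep(0, length(wavelengths))
  for (i in seq_len(nrow(bands)))
    eps <- eps + bands$peak[i] *
      exp(-(wavelengths - bands$center_nm[i])^2 / (2 * bands$width_nm[i]^2))
  name <- if (kind == "monomer") "icg_monomer" else "lja"
  absorber_spectrum(name, wavelengths, eps)
}

#' Generate a noisy heating/cooling trace with known ground truth
#'
#' Wraps [simulate_heating()] and adds i.i.d. Gaussian sensor noise, so
#' estimator-recovery studies can score against the generating
#' parameters. Pure given `(spec, seed)`: regeneration is bit-identical.
#'
#' @param params A [lumped_thermal_params()].
#' @param eta True photothermal conversion efficiency.
#' @param on_s,off_s,dt_s Segment durations and sampling interval (s).
#' @param noise_sd_C Gaussian noise standard deviation in deg C
#'   (default 0.1, a typical IR-camera noise scale).
#' @param seed Integer seed.
#' @return List with `trace` (a [temperature_trace()]) and `truth`
#'   (the generating `eta`, `tau_c_s`, `hS_mW_C`, `q_dis_mW`, `seed`).
#' @export
gen_temperature_trace <- function(params = lumped_thermal_params(tau_c_s = 180),
                                  eta = 0.15, on_s = 12 * params$tau_c_s,
                                  off_s = 3 * params$tau_c_s, dt_s = 1,
                                  noise_sd_C = 0.1, seed = 1) {
  if (noise_sd_C < 0) stop("noise_sd_C must be nonnegative")
  clean <- simulate_heating(params, eta, on_s, off_s, dt_s)
  temps <- clean$temperatures
  if (noise_sd_C > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    temps <- temps + rnorm(length(temps), sd = noise_sd_C)
  }
  trace <- temperature_trace(clean$times, temps, clean$laser_on,
                             t_surr = params$t_surr_C)
  list(trace = trace,
       truth = list(eta = eta, tau_c_s = params$tau_c_s,
                    hS_mW_C = params$hS_mW_C, q_dis_mW = params$q_dis_mW,
                    noise_sd_C = noise_sd_C, seed = seed))
}

#' Packaged synthetic optical-property table
#'
#' Returns the packaged literature-style near-infrared table (see
#' [default_tissue_table()]) restricted to the requested wavelengths,
#' optionally interpolating linearly between the tabulated 808/852/890 nm
#' records.
#'
#' @param wavelengths nm values; must be tabulated, or within the
#'   tabulated range with `interpolate = TRUE`.
#' @param interpolate Allow linear interpolation between tabulated
#'   wavelengths.
#' @return Data frame in the layout of [read_optical_table()].
#' @export
gen_optical_property_table <- function(wavelengths = c(808, 852, 890),
                                       interpolate = FALSE) {
  tab <- default_tissue_table()
  have <- sort(unique(tab$wavelength_nm))
  missing <- setdiff(wavelengths, have)
  if (length(missing) > 0 && !interpolate)
    stop("wavelength(s) ", paste(missing, collapse = ", "),
         " nm not tabulated; set interpolate = TRUE")
  if (any(wavelengths < min(have) | wavelengths > max(have)))
    stop("wavelengths outside the tabulated range ", min(have), "-",
         max(have), " nm")
  out <- list()
  for (lname in unique(tab$layer)) {
    sub <- tab[tab$layer == lname, ]
    sub <- sub[order(sub$wavelength_nm), ]
    out[[lname]] <- data.frame(
      layer = lname, wavelength_nm = wavelengths,
      mu_a = approx(sub$wavelength_nm, sub$mu_a, wavelengths)$y,
      mu_s = approx(sub$wavelength_nm, sub$mu_s, wavelengths)$y,
      g = approx(sub$wavelength_nm, sub$g, wavelengths)$y,
      n = approx(sub$wavelength_nm, sub$n, wavelengths)$y,
      thickness_mm = sub$thickness_mm[1])
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Synthetic photoacoustic signal-vs-depth series
#'
#' Emulates a phantom depth study: an agent-loaded target sits under an
#' increasing thickness of plain tissue-mimicking material, so the signal
#' at depth `z` is the photoacoustic proxy of the target's absorption
#' under the background-attenuated fluence,
#' `Gamma * mu_a_agent * Phi_background(z)`, with multiplicative
#' log-normal measurement noise. One background Monte Carlo run plus beam
#' convolution supplies the fluence; the noiseless expectation decreases
#' with depth, and at equal concentration the species with the higher
#' extinction at its own illumination wavelength signals stronger.
#'
#' @param spectrum An [absorber_spectrum()] for the target's agent.
#' @param wavelength Illumination wavelength in nm.
#' @param depths_mm Positive increasing target depths.
#' @param concentration_M Agent molar concentration in the target
#'   (default 20e-6, a 20 uM phantom).
#' @param background Background phantom properties
#'   (an [optical_properties()]; default a weakly absorbing gel).
#' @param grueneisen Grueneisen parameter (default 0.2, aqueous tissue).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.05; 0 for the noiseless expectation).
#' @param n_photons Photons for the background run (default 2e4).
#' @param seed Integer seed.
#' @return Data frame with columns `depth_mm`, `signal`, `signal_clean`.
#' @export
gen_pa_depth_series <- function(spectrum, wavelength, depths_mm = 1:10,
                                concentration_M = 20e-6,
                                background = optical_properties(0.005, 1.0, 0.9, 1.37),
                                grueneisen = 0.2, noise_cv = 0.05,
                                n_photons = 2e4, seed = 1) {
  if (any(depths_mm <= 0) || any(diff(depths_mm) <= 0))
    stop("depths must be positive and increasing")
  mua_agent <- molar_to_mua(spectrum, concentration_M, wavelength)
  props <- data.frame(wavelength_nm = wavelength, mu_a = background$mu_a,
                      mu_s = background$mu_s, g = background$g,
                      n = background$n)
  depth_span <- max(depths_mm) + 1
  st <- tissue_stack(list(tissue_layer("phantom", depth_span, props)),
                     n_above = 1.0, n_below = background$n)
  grid <- simulation_grid(dz = 0.05, dr = 0.05, nr = 200)
  ir <- run_simulation(st, wavelength, grid = grid,
                       config = mc_config(n_photons = n_photons, seed = seed))
  fm <- convolve_beam(ir, beam_profile(1, 4))
  prof <- depth_profile(fm)
  proxy <- pa_signal_proxy(mua_agent * prof$fluence_J_mm2, grueneisen)
  clean <- approx(prof$z_mm, proxy, xout = depths_mm)$y
  sig <- clean
  if (noise_cv > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    sig <- clean * exp(rnorm(length(clean), mean = -noise_cv^2 / 2,
                             sd = noise_cv))
  }
  data.frame(depth_mm = depths_mm, signal = sig, signal_clean = clean)
}
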