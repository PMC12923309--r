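#' Simulation grid for the Monte Carlo tallies
#'
#' @param dz Depth bin size in mm (default 0.010, i.e. 10 microns).
#' @param dr Radial bin size in mm (default 0.025, i.e. 25 microns).
#' @param nz Number of depth bins; if `NULL`, chosen by [run_simulation()]
#'   to span the stack.
#' @param nr Number of radial bins (default 400, a 10 mm radial extent at
#'   the default `dr`).
#' @return An object of class `simulation_grid`.
#' @export
simulation_grid <- function(dz = 0.010, dr = 0.025, nz = NULL, nr = 400) {
  if (dz <= 0 || dr <= 0) stop("dz and dr must be positive")
  if (!is.null(nz) && nz < 1) stop("nz must be >= 1")
  if (nr < 1) stop("nr must be >= 1")
  structure(list(dz = dz, dr = dr, nz = nz, nr = as.integer(nr)),
            class = "simulation_grid")
}

#' Monte Carlo run configuration
#'
#' @param n_photons Number of photon packets to launch (default 1e6; use
#'   1e7 for publication-grade grids).
#' @param threshold Weight below which Russian roulette is played
#'   (default 1e-4).
#' @param roulette_m Roulette survival factor: a photon below threshold
#'   survives with probability `1/roulette_m` carrying `roulette_m` times
#'   its weight (default 10).
#' @param seed Integer RNG seed; recorded in every output.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_photons = 1e6, threshold = 1e-4, roulette_m = 10,
                      seed = 1) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (roulette_m < 2) stop("roulette_m must be >= 2")
  structure(list(n_photons = n_photons, threshold = threshold,
                 roulette_m = as.integer(roulette_m),
                 seed = as.numeric(seed)),
            class = "mc_config")
}

#' Sample a dimensionless free path as a physical step
#'
#' The distance between photon-tissue interaction events is exponentially
#' distributed with rate `mu_t = mu_a + mu_s`.
#'
#' @param mu_t Total interaction coefficient, per mm (> 0).
#' @param u Uniform draw(s) in the open interval (0, 1).
#' @return Step length(s) in mm, `-log(u) / mu_t`.
#' @export
sample_step <- function(mu_t, u) {
  if (any(mu_t <= 0)) stop("mu_t must be positive")
  if (any(u <= 0 | u >= 1)) stop("u must lie in the open interval (0, 1)")
  -log(u) / mu_t
}

#' Deposit the absorbed fraction of a photon packet's weight
#'
#' At each interaction a fraction `mu_a / mu_t` of the packet weight is
#' absorbed locally; the packet continues with the remainder.
#'
#' @param weight Current packet weight, in (0, 1].
#' @param mu_a,mu_s Local absorption and scattering coefficients (per mm),
#'   with `mu_a + mu_s > 0`.
#' @return List with `deposited` and `weight` (the reduced weight).
#' @export
deposit_weight <- function(weight, mu_a, mu_s) {
  mu_t <- mu_a + mu_s
  if (mu_t <= 0) stop("mu_a + mu_s must be positive")
  d <- weight * mu_a / mu_t
  list(deposited = d, weight = weight - d)
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function with
#' anisotropy `g`; `g = 0` reduces to an isotropic (uniform) deflection
#' cosine. The expected deflection cosine equals `g`.
#'
#' @param g Anisotropy factor, |g| < 1.
#' @param n Number of samples.
#' @param seed Integer seed for the sampler's RNG.
#' @return Numeric vector of `n` deflection cosines in [-1, 1].
#' @export
hg_deflection <- function(g, n, seed = 1) {
  if (abs(g) >= 1) stop("|g| must be < 1")
  .hg_cos_samples(g, n, as.numeric(seed))
}

#' Rotate a direction by a sampled scattering angle
#'
#' @param direction Unit 3-vector (x, y, z).
#' @param cos_theta Deflection cosine.
#' @param phi Azimuthal angle in radians.
#' @return New unit direction vector.
#' @export
spin_direction <- function(direction, cos_theta, phi) {
  u <- direction / sqrt(sum(direction^2))
  sint <- sqrt(max(0, 1 - cos_theta^2))
  if (abs(u[3]) > 0.99999) {
    out <- c(sint * cos(phi), sint * sin(phi),
             sign(u[3]) * cos_theta)
  } else {
    den <- sqrt(1 - u[3]^2)
    out <- c(sint * (u[1] * u[3] * cos(phi) - u[2] * sin(phi)) / den +
               u[1] * cos_theta,
             sint * (u[2] * u[3] * cos(phi) + u[1] * sin(phi)) / den +
               u[2] * cos_theta,
             -sint * cos(phi) * den + u[3] * cos_theta)
  }
  out / sqrt(sum(out^2))
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' Average of the s- and p-polarized reflectances; returns 1 beyond the
#' critical angle (total internal reflection).
#'
#' @param n1,n2 Refractive indices of the incident and transmitting media.
#' @param cos_i Cosine of the incidence angle, in [0, 1].
#' @return Reflection probability in [0, 1].
#' @examples
#' fresnel_reflectance(1.0, 1.5, 1)  # 0.04
#' @export
fresnel_reflectance <- function(n1, n2, cos_i) {
  if (cos_i < 0 || cos_i > 1) stop("cos_i must lie in [0, 1]")
  .fresnel_cpp(n1, n2, cos_i)
}

#' Russian roulette for a low-weight photon packet
#'
#' Applied only when the weight is below the configured threshold: the
#' packet survives with probability `1/m` carrying `m` times its weight,
#' preserving the expected weight.
#'
#' @param weight Current packet weight.
#' @param threshold Roulette threshold.
#' @param m Survival factor (>= 2).
#' @param u Uniform draw in (0, 1).
#' @return List with `alive` (logical) and `weight`.
#' @export
roulette <- function(weight, threshold, m, u) {
  if (weight >= threshold) return(list(alive = TRUE, weight = weight))
  if (u < 1 / m) list(alive = TRUE, weight = weight * m)
  else list(alive = FALSE, weight = 0)
}

#' Launch state of a photon packet
#'
#' Packets enter at the origin pointing straight down; the specular
#' reflection at the ambient/first-layer interface is removed from the
#' initial weight.
#'
#' @param stack A [tissue_stack()].
#' @param wavelength Wavelength in nm (to resolve the first layer's index).
#' @return List with `position`, `direction`, `weight` and `R_sp`.
#' @export
launch <- function(stack, wavelength) {
  n1 <- layer_props(stack$layers[[1]], wavelength)$n
  R_sp <- ((stack$n_above - n1) / (stack$n_above + n1))^2
  list(position = c(0, 0, 0), direction = c(0, 0, 1),
       weight = 1 - R_sp, R_sp = R_sp)
}

#' Run the layered-tissue photon Monte Carlo
#'
#' Simulates an infinitesimally narrow beam of weighted photon packets
#' through the stack (the impulse response): exponential step sampling,
#' partial-weight deposition, Henyey-Greenstein scattering, Fresnel/Snell
#' boundary interactions with the residual dimensionless step preserved
#' across interfaces, and unbiased Russian roulette. Tallies are
#' normalized per launched photon. Identical `(stack, wavelength, grid,
#' config)` including the seed reproduce bit-identical output.
#'
#' @param stack A [tissue_stack()] with properties at `wavelength`.
#' @param wavelength Wavelength in nm.
#' @param grid A [simulation_grid()]; `nz = NULL` spans the stack depth.
#' @param config An [mc_config()].
#' @return An object of class `impulse_response`: matrices `A_rz`
#'   (absorbed fraction per mm^3 per launched photon, `nr` x `nz`) and
#'   `Phi_rz` (fluence per launched unit energy, per mm^2; `NA` where the
#'   local `mu_a` is zero), scalars `R_sp`, `R_d`, `A_total`, `T_t`,
#'   `overflow_frac` (fraction of absorbed weight folded into the last
#'   radial bin), `n_photons`, `seed`, the `grid`, the per-depth-bin
#'   `mu_a_z`, and the stack's layer table.
#' @examples
#' \donttest{
#' st <- build_tumor_stack(2)
#' ir <- run_simulation(st, 808, config = mc_config(n_photons = 1e4, seed = 7))
#' ir$R_sp + ir$R_d + ir$A_total + ir$T_t  # ~1
#' }
#' @export
run_simulation <- function(stack, wavelength, grid = simulation_grid(),
                           config = mc_config()) {
  stopifnot(inherits(stack, "tissue_stack"),
            inherits(grid, "simulation_grid"), inherits(config, "mc_config"))
  props <- resolve_stack(stack, wavelength)
  depth <- sum(props$thickness)
  nz <- if (is.null(grid$nz)) as.integer(ceiling(depth / grid$dz - 1e-9))
        else as.integer(grid$nz)
  lay <- as.matrix(props[, c("thickness", "mu_a", "mu_s", "g", "n")])
  res <- .mc_kernel(lay, stack$n_above, stack$n_below,
                    grid$dz, grid$dr, nz, grid$nr,
                    config$n_photons, config$threshold, config$roulette_m,
                    config$seed)
  # per-depth-bin mu_a (bin centers), for the fluence identity Phi = A / mu_a
  zc <- (seq_len(nz) - 0.5) * grid$dz
  bounds <- c(0, cumsum(props$thickness))
  li <- pmin(findInterval(zc, bounds, rightmost.closed = TRUE), nrow(props))
  mu_a_z <- props$mu_a[li]
  Phi <- sweep(res$A_rz, 2, mu_a_z, "/")
  Phi[, mu_a_z == 0] <- NA_real_
  structure(list(A_rz = res$A_rz, Phi_rz = Phi,
                 R_sp = res$R_sp, R_d = res$R_d, T_t = res$T_t,
                 A_total = res$A_total, overflow_frac = res$overflow_frac,
                 n_photons = config$n_photons, seed = config$seed,
                 grid = list(dz = grid$dz, dr = grid$dr, nz = nz,
                             nr = grid$nr),
                 mu_a_z = mu_a_z, wavelength = wavelength,
                 layers = props),
            class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf(paste0("impulse response: %g photons at %g nm, seed %g\n",
                     "  R_sp=%.4f R_d=%.4f A=%.4f T_t=%.4f (sum %.6f)\n",
                     "  grid %d x %d (dr=%.3g mm, dz=%.3g mm), radial overflow %.3g\n"),
              x$n_photons, x$wavelength, x$seed, x$R_sp, x$R_d, x$A_total,
              x$T_t, x$R_sp + x$R_d + x$A_total + x$T_t,
              x$grid$nr, x$grid$nz, x$grid$dr, x$grid$dz, x$overflow_frac))
  invisible(x)
}
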