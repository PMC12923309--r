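# Small builders shared across the test files.

# Single homogeneous slab at a nominal 800 nm record.
slab_stack <- function(mu_a, mu_s, g = 0, n = 1, thickness = 1,
                       n_above = 1, n_below = 1) {
  props <- data.frame(wavelength_nm = 800, mu_a = mu_a, mu_s = mu_s,
                      g = g, n = n)
  tissue_stack(list(tissue_layer("slab", thickness, props)),
               n_above = n_above, n_below = n_below)
}

run_slab <- function(stack, n_photons = 1e4, seed = 1, dz = 0.01,
                     dr = 0.025, nr = 100) {
  run_simulation(stack, 800, simulation_grid(dz = dz, dr = dr, nr = nr),
                 mc_config(n_photons = n_photons, seed = seed))
}

# A minimal hand-built impulse response for convolution algebra tests:
# every radial bin carries the same value per depth row, so the convolved
# value must equal E times that value at every radius.
flat_impulse <- function(a_by_depth, nr = 80, dr = 0.05) {
  nz <- length(a_by_depth)
  A <- matrix(rep(a_by_depth, each = nr), nrow = nr)
  structure(list(A_rz = A, Phi_rz = A, R_sp = 0, R_d = 0, T_t = 0,
                 A_total = NA_real_, overflow_frac = 0, n_photons = 1,
                 seed = 1,
                 grid = list(dz = 0.1, dr = dr, nz = nz, nr = nr),
                 mu_a_z = rep(1, nz), wavelength = 800,
                 layers = NULL),
            class = "impulse_response")
}

default_agent <- function() {
  list(spectrum = gen_absorbance_spectra("j_aggregate"),
       loading = agent_loading())
}
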