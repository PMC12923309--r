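test_that("beam profiles normalize to their total energy", {
  b <- beam_profile(1, 4)
  # on-axis irradiance of the Gaussian beam: 2E/(pi R^2)
  expect_equal(beam_irradiance(b, 0), 2 / (pi * 16), tolerance = 1e-12)
  expect_equal(beam_irradiance(b, 0), 0.0398, tolerance = 1e-3)
  # numeric radial integral recovers E for both profiles
  r <- seq(0, 20, by = 1e-3)
  for (bp in list(b, beam_profile(2.5, 3, kind = "flat"))) {
    tot <- sum(beam_irradiance(bp, r) * 2 * pi * r) * 1e-3
    expect_equal(tot, bp$energy_J, tolerance = 1e-3)
  }
  # FWHM option maps to the 1/e^2 radius convention
  expect_equal(beam_profile(1, 4, radius_is_fwhm = TRUE)$radius_mm,
               4 / sqrt(2 * log(2)))
  expect_error(beam_profile(0, 4), "positive")
})

test_that("radially constant impulse convolves to E times itself", {
  a <- c(1, 0.5, 0.25, 0.1)
  imp <- flat_impulse(a)
  fm <- convolve_beam(imp, beam_profile(3, 1), r_out = c(0, 0.5, 1.5))
  for (i in 1:3)
    expect_equal(unname(fm$A[i, ]), 3 * a, tolerance = 1e-3)
})

test_that("convolution is exactly linear in beam energy", {
  st <- slab_stack(0.5, 2, g = 0.7, thickness = 2)
  ir <- run_slab(st, n_photons = 3e3, seed = 17, dz = 0.1, nr = 60)
  f1 <- convolve_beam(ir, beam_profile(1, 2))
  f2 <- convolve_beam(ir, beam_profile(2, 2))
  expect_identical(2 * f1$A, f2$A)
})

test_that("delta-beam limit reduces to E times the impulse response", {
  st <- build_tumor_stack(1)
  ir <- run_simulation(st, 808, config = mc_config(n_photons = 2e4, seed = 19))
  expect_warning(fm <- convolve_beam(ir, beam_profile(1, 0.005)),
                 "delta-beam")
  onaxis <- depth_profile(fm)$absorbed_J_mm3
  expect_equal(onaxis, unname(ir$A_rz[1, ]), tolerance = 0.01)
})

test_that("convolution conserves energy within quadrature tolerance", {
  st <- build_tumor_stack(2)
  ir <- run_simulation(st, 852, config = mc_config(n_photons = 5e4, seed = 23))
  fm <- convolve_beam(ir, beam_profile(1, 4))
  expect_equal(total_absorbed_energy(fm), 1 * ir$A_total, tolerance = 0.01)
})

test_that("convolved map decays radially outside the beam", {
  st <- slab_stack(0.3, 3, g = 0.8, thickness = 2)
  ir <- run_slab(st, n_photons = 5e3, seed = 29, dz = 0.1, dr = 0.1, nr = 100)
  fm <- convolve_beam(ir, beam_profile(1, 2))
  far <- fm$r_mm >= 4   # two beam radii out
  row <- rowSums(fm$A[far, ])
  # non-increasing up to Monte Carlo noise in the impulse tail
  expect_true(all(diff(row) <= 0.02 * max(row)))
  expect_lt(row[length(row)], 0.01 * max(row))
})

test_that("depth profiles follow Beer-Lambert in a pure absorber", {
  st <- slab_stack(1, 0, thickness = 3)
  ir <- run_slab(st, n_photons = 1e5, seed = 31, dz = 0.05, nr = 40)
  fm <- convolve_beam(ir, beam_profile(1, 1))
  prof <- depth_profile(fm)
  # absorbed density = mu_a * fluence identically
  expect_equal(prof$absorbed_J_mm3, 1 * prof$fluence_J_mm2, tolerance = 1e-12)
  # on-axis fluence ~ exp(-mu_a z): fit the log slope over the first 2 mm
  sel <- prof$z_mm <= 2
  slope <- coef(lm(log(prof$absorbed_J_mm3[sel]) ~ prof$z_mm[sel]))[[2]]
  expect_equal(slope, -1, tolerance = 0.05)
  expect_error(depth_profile(fm, radius = 1e3), "outside")
})

test_that("tumor-interface peak responds to agent, depth and wavelength", {
  cfgn <- function(s) mc_config(n_photons = 3e4, seed = s)
  peak_at <- function(x, wl, agent, s) {
    st <- build_tumor_stack(x, wavelengths = wl, agent = agent)
    ir <- run_simulation(st, wl, config = cfgn(s))
    tumor_interface_peak(st, convolve_beam(ir, beam_profile(1, 4)))
  }
  ag <- default_agent()
  # agent strictly increases the interface peak (shallow tumor)
  expect_gt(peak_at(0, 808, ag, 41), peak_at(0, 808, NULL, 41))
  # deeper tumor receives less energy
  expect_gt(peak_at(0, 852, NULL, 43), peak_at(2, 852, NULL, 43))
  expect_error(tumor_interface_peak(slab_stack(1, 1), flat_impulse(1:3)),
               "no layer")
})

test_that("depth scan emits one row per condition, reproducibly", {
  scan <- depth_scan(wavelengths = c(808, 852), fat_depths_mm = c(0, 1),
                     agent = default_agent(),
                     config = mc_config(n_photons = 2e3, seed = 5))
  expect_equal(nrow(scan), 2 * 2 * 2)
  expect_true(all(scan$peak_J_per_mm3 > 0))
  scan2 <- depth_scan(wavelengths = c(808, 852), fat_depths_mm = c(0, 1),
                      agent = default_agent(),
                      config = mc_config(n_photons = 2e3, seed = 5))
  expect_identical(scan, scan2)
})
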