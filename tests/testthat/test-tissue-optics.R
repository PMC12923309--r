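test_that("optical property and layer invariants are enforced", {
  expect_error(optical_properties(-0.1, 1, 0.9, 1.37), "nonnegative")
  expect_error(optical_properties(0.1, 1, 1.0, 1.37), "anisotropy")
  expect_error(optical_properties(0.1, 1, 0.9, 0.9), "refractive")
  expect_error(tissue_layer("x", 0, data.frame()), "positive")
  props <- data.frame(wavelength_nm = 808, mu_a = 0.1, mu_s = 1,
                      g = 0.9, n = NA)
  expect_error(tissue_layer("x", 1, props), "incomplete")
})

test_that("Beer-Lambert bridge converts molarity to per-mm absorption", {
  flat <- absorber_spectrum("flat", c(700, 900), c(1e5, 1e5))
  expect_equal(molar_to_mua(flat, 1e-5, 800), log(10) / 10, tolerance = 1e-12)
  expect_equal(molar_to_mua(flat, 0, 800), 0)
  zero <- absorber_spectrum("zero", c(700, 900), c(0, 0))
  expect_equal(molar_to_mua(zero, 1e-3, 800), 0)
  expect_error(molar_to_mua(flat, 1e-5, 950), "range")
})

test_that("property mixing is additive, order-independent, identity at zero", {
  base <- optical_properties(0.10, 1.0, 0.9, 1.37)
  expect_equal(mix_properties(base, 0.20)$mu_a, 0.30)
  m <- mix_properties(optical_properties(0.05, 1.0, 0.9, 1.37), 0.3, 0)
  expect_equal(c(m$mu_a, m$mu_s), c(0.35, 1.0))
  ident <- mix_properties(base, 0, 0)
  expect_equal(unclass(ident), unclass(base))
  expect_error(mix_properties(base, -0.1), "nonnegative")
  # order independence over random nonnegative contributions
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0, 2); b <- runif(1, 0, 2)
    expect_equal(mix_properties(mix_properties(base, a), b)$mu_a,
                 mix_properties(mix_properties(base, b), a)$mu_a,
                 tolerance = 1e-12)
  }
})

test_that("dose-to-concentration follows the uniform-distribution formula", {
  # 5 mg/kg in a 20 g mouse, 1% uptake, 50 mm^3 tumor, 775 g/mol
  expect_equal(dose_to_concentration(agent_loading()),
               2.580645e-5, tolerance = 1e-6)
  expect_error(agent_loading(uptake_fraction = 0), "positive")
  # linear in dose and uptake, inverse in tumor volume
  set.seed(21)
  for (i in 1:20) {
    d <- runif(1, 1, 10); u <- runif(1, 0.001, 0.05); v <- runif(1, 10, 200)
    c0 <- dose_to_concentration(agent_loading(d, 0.02, u, v, 775))
    expect_equal(dose_to_concentration(agent_loading(2 * d, 0.02, u, v, 775)),
                 2 * c0, tolerance = 1e-12)
    expect_equal(dose_to_concentration(agent_loading(d, 0.02, 2 * u, v, 775)),
                 2 * c0, tolerance = 1e-12)
    expect_equal(dose_to_concentration(agent_loading(d, 0.02, u, 2 * v, 775)),
                 c0 / 2, tolerance = 1e-12)
  }
})

test_that("tumor-under-fat stack geometry matches the cumulative thicknesses", {
  st <- build_tumor_stack(2)
  expect_equal(stack_boundaries(st), c(0, 0.1, 2.1, 4.1, 6.1))
  expect_equal(layer_span(st, "tumor"), c(4.1, 6.1))
  # degenerate fat: three layers, tumor top at 2.1 mm
  st0 <- build_tumor_stack(0)
  expect_length(st0$layers, 3)
  expect_equal(layer_span(st0, "tumor"), c(2.1, 4.1))
  # boundary = cumsum(thickness) for arbitrary x
  for (x in c(0.5, 1.7, 3.3, 6)) {
    stx <- build_tumor_stack(x)
    th <- vapply(stx$layers, function(l) l$thickness, numeric(1))
    expect_equal(stack_boundaries(stx), c(0, cumsum(th)))
  }
  expect_error(build_tumor_stack(7), "0, 6")
  expect_error(build_tumor_stack(2, wavelengths = 1064), "lacks")
})

test_that("agent loading raises tumor absorption only", {
  st_plain <- build_tumor_stack(2)
  st_agent <- build_tumor_stack(2, agent = default_agent())
  for (wl in c(808, 852, 890)) {
    for (lname in c("epidermis", "dermis", "fat")) {
      i <- which(vapply(st_plain$layers, `[[`, character(1), "name") == lname)
      expect_equal(st_agent$layers[[i]]$props, st_plain$layers[[i]]$props)
    }
    pa <- layer_props(st_agent$layers[[4]], wl)
    pp <- layer_props(st_plain$layers[[4]], wl)
    expect_gt(pa$mu_a, pp$mu_a)
    expect_equal(pa$mu_s, pp$mu_s)  # agent non-scattering by default
  }
})

test_that("per-cm tables are converted to internal per-mm units", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(layer = "gel", wavelength_nm = 800, mua = 1.0,
                       mus = 100, unit = "per_cm", g = 0.9, n = 1.37,
                       thickness_mm = 10),
            f, row.names = FALSE)
  tab <- read_optical_table(f)
  expect_equal(tab$mu_a, 0.1)
  expect_equal(tab$mu_s, 10)
})
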