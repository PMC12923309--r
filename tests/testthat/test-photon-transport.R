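test_that("step sampling inverts the exponential distribution", {
  expect_equal(sample_step(1, exp(-1)), 1)
  expect_equal(sample_step(2, exp(-1)), 0.5)
  set.seed(31)
  expect_equal(mean(sample_step(1, runif(1e6))), 1.0, tolerance = 0.01)
  expect_error(sample_step(0, 0.5), "positive")
  expect_error(sample_step(1, 1), "open interval")
})

test_that("weight deposition follows the local albedo", {
  d <- deposit_weight(1, 0.1, 0.9)
  expect_equal(d$deposited, 0.1)
  expect_equal(d$weight, 0.9)
  expect_equal(deposit_weight(1, 0, 1)$deposited, 0)
  expect_equal(deposit_weight(0.5, 1, 1)$deposited, 0.25)
})

test_that("Henyey-Greenstein sampler has mean cosine g", {
  for (g in c(0, 0.5, 0.9)) {
    x <- hg_deflection(g, 1e5, seed = 100 + g * 10)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g), 3 * se + 1e-12)
    expect_true(all(x >= -1 & x <= 1))
  }
})

test_that("direction spin preserves unit norm", {
  set.seed(41)
  for (i in 1:50) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    out <- spin_direction(v, runif(1, -1, 1), runif(1, 0, 2 * pi))
    expect_equal(sum(out^2), 1, tolerance = 1e-9)
  }
})

test_that("Fresnel boundary physics matches closed forms", {
  expect_equal(fresnel_reflectance(1.0, 1.5, 1), 0.04)
  expect_equal(fresnel_reflectance(1.37, 1.37, 0.3), 0)
  # beyond the critical angle sin(theta_c) = n2/n1: total internal reflection
  expect_equal(fresnel_reflectance(1.5, 1.0, 0.1), 1)
})

test_that("launch removes the specular fraction and points down", {
  st <- build_tumor_stack(2)
  l <- launch(st, 808)
  expect_equal(l$R_sp, (0.37 / 2.37)^2, tolerance = 1e-5)
  expect_equal(l$weight, 1 - l$R_sp)
  expect_equal(l$direction, c(0, 0, 1))
  matched <- slab_stack(1, 0, n = 1, n_above = 1)
  lm2 <- launch(matched, 800)
  expect_equal(lm2$R_sp, 0)
  expect_equal(lm2$weight, 1)
})

test_that("roulette preserves expected weight and ignores heavy packets", {
  expect_equal(roulette(1e-5, 1e-4, 10, 0.05)$weight, 1e-4)
  expect_false(roulette(1e-5, 1e-4, 10, 0.5)$alive)
  expect_equal(roulette(0.5, 1e-4, 10, 0.9),
               list(alive = TRUE, weight = 0.5))
  set.seed(51)
  u <- runif(1e5)
  post <- vapply(u, function(ui) roulette(1e-5, 1e-4, 10, ui)$weight,
                 numeric(1))
  expect_equal(mean(post), 1e-5, tolerance = 0.03)  # ~3 SE relative
})

test_that("pure absorber conserves and reproduces Beer-Lambert", {
  # semi-infinite pure absorber: everything is absorbed
  deep <- slab_stack(1, 0, thickness = 50)
  ir <- run_slab(deep, n_photons = 2e3, seed = 7, dz = 0.5, nr = 10)
  expect_equal(ir$A_total, 1)
  expect_equal(ir$R_d, 0)
  expect_equal(ir$T_t, 0)
  # 1 mm slab, mu_a = 1/mm: T_t = exp(-1)
  slab <- slab_stack(1, 0, thickness = 1)
  ir2 <- run_slab(slab, n_photons = 1e5, seed = 8)
  expect_equal(ir2$T_t, exp(-1), tolerance = 0.005 / exp(-1))
})

test_that("deposition depth in a scatter-free absorber is exponential", {
  deep <- slab_stack(0.5, 0, thickness = 40)
  ir <- run_slab(deep, n_photons = 5e4, seed = 9, dz = 0.2, nr = 20)
  g <- ir$grid
  vol <- 2 * pi * (seq_len(g$nr) - 0.5) * g$dr^2 * g$dz
  counts <- round(colSums(ir$A_rz * vol) * ir$n_photons)
  edges <- seq(0, g$nz) * g$dz
  p <- diff(-exp(-0.5 * edges))
  p <- c(p, 1 - sum(p))                       # lump the deep tail
  counts <- c(counts, ir$n_photons - sum(counts))
  keep <- p * ir$n_photons >= 5
  gof <- suppressWarnings(stats::chisq.test(counts[keep], p = p[keep],
                                            rescale.p = TRUE))
  expect_gt(gof$p.value, 1e-3)
})

test_that("energy is conserved and seeded runs are bit-identical", {
  st <- build_tumor_stack(1)
  ir1 <- run_simulation(st, 852, simulation_grid(nr = 200),
                        mc_config(n_photons = 2e4, seed = 77))
  expect_equal(ir1$R_sp + ir1$R_d + ir1$A_total + ir1$T_t, 1,
               tolerance = 1e-3)
  ir2 <- run_simulation(st, 852, simulation_grid(nr = 200),
                        mc_config(n_photons = 2e4, seed = 77))
  expect_identical(ir1$A_rz, ir2$A_rz)
  expect_identical(ir1$R_d, ir2$R_d)
  ir3 <- run_simulation(st, 852, simulation_grid(nr = 200),
                        mc_config(n_photons = 2e4, seed = 78))
  expect_false(identical(ir1$R_d, ir3$R_d))
})

test_that("fluence equals absorbed density over mu_a", {
  st <- slab_stack(0.5, 5, g = 0.8, n = 1.4, thickness = 2,
                   n_above = 1, n_below = 1.4)
  ir <- run_slab(st, n_photons = 5e3, seed = 13, dz = 0.1, nr = 40)
  expect_equal(ir$Phi_rz, ir$A_rz / 0.5, tolerance = 1e-12)
})

test_that("tally noise scales as 1/n_photons", {
  st <- slab_stack(0.2, 2, g = 0.5, thickness = 1)
  rd <- function(n, seeds) vapply(seeds, function(s)
    run_slab(st, n_photons = n, seed = s, dz = 0.1, nr = 20)$R_d, numeric(1))
  v1 <- var(rd(500, 1:40))
  v4 <- var(rd(2000, 101:140))
  expect_gt(v1 / v4, 2)    # expect ~4, allow wide sampling slack
  expect_lt(v1 / v4, 8)
})
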