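test_that("transport primitives match their closed forms", {
  # free path
  expect_error(sample_step(0.5, 0), "positive")
  expect_equal(sample_step(1, 10), 0)
  set.seed(41)
  u <- runif(1e5)
  s <- sample_step(u, 25)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1 / 25), 3 * se)
  expect_equal(sample_step(u, 50), s / 2)

  # Henyey-Greenstein
  expect_equal(sample_hg_cos(c(0.25, 0.5, 0.75), 0), c(-0.5, 0, 0.5))
  ct <- sample_hg_cos(runif(1e5), 0.86)
  expect_true(all(ct >= -1 & ct <= 1))
  expect_lt(abs(mean(ct) - 0.86), 3 * sd(ct) / sqrt(length(ct)))
  expect_error(sample_hg_cos(0.5, 1), "\\(-1, 1\\)")

  # Fresnel
  expect_equal(fresnel_unpolarized(1.4, 1.4, 1)$R, 0)
  expect_equal(fresnel_unpolarized(1.0, 1.55, 1)$R, (0.55 / 2.55)^2)
  expect_equal(launch_weight(1.0, 1.55), 1 - (0.55 / 2.55)^2)
  expect_equal(launch_weight(1.4, 1.4), 1)
  # beyond the critical angle for n1 > n2: total internal reflection
  expect_equal(fresnel_unpolarized(1.4, 1.0, 0.1)$R, 1)

  # absorption weight drop
  expect_equal(absorb_weight(0.5, 0, 10)$deposited, 0)
  expect_equal(absorb_weight(0.5, 10, 10)$weight, 0)
  expect_equal(absorb_weight(0.5, 3, 10)$deposited, 0.15)
  expect_error(absorb_weight(1, 11, 10), "mu_a <= mu_t")
})

test_that("roulette preserves expected weight and skips heavy packets", {
  expect_equal(roulette_weight(0.5, 0.99, 1e-4, 0.1), 0.5)  # above threshold
  expect_equal(roulette_weight(1e-5, 0.05, 1e-4, 1), 1e-5)  # chance 1: no-op
  set.seed(7)
  u <- runif(1e5)
  w <- vapply(u, function(ui) roulette_weight(5e-5, ui, 1e-4, 0.1), numeric(1))
  se <- sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - 5e-5), 3 * se)
})

test_that("fiber detection respects the hexagonal probe geometry", {
  ctr <- probe6$detector_centers_cm
  for (f in 1:6)
    expect_equal(detect_fiber(ctr[f, 1], ctr[f, 2], probe6), f)
  expect_true(is.na(detect_fiber(0, 0, probe6)))  # the source is no detector
  expect_true(is.na(detect_fiber((240 + 101) * 1e-4, 0, probe6)))
  expect_equal(detect_fiber((240 + 99) * 1e-4, 0, probe6), 1)
  # acceptance cone rejects oblique exits when configured
  pr <- probe_geometry(max_accept_deg = 30)
  expect_true(is.na(detect_fiber(ctr[1, 1], ctr[1, 2], pr, cos_exit = 0.5)))
  expect_equal(detect_fiber(ctr[1, 1], ctr[1, 2], pr, cos_exit = 0.95), 1)
})

test_that("the naive pure-R loop reproduces the engine on a shared stream", {
  cfg <- sim_config(n_photons = 300, seed = 7)
  st <- build_optical_stack(630, skin, healthy, tabs)
  a <- simulate_wavelength(st, probe6, cfg, stream_index = 3)
  b <- mc_reference_wavelength(st, probe6, cfg, stream_index = 3)
  expect_equal(a$fiber, b$fiber, tolerance = 1e-12)
  expect_equal(a$top_diffuse, b$top_diffuse, tolerance = 1e-12)
  expect_equal(a$absorbed, b$absorbed, tolerance = 1e-12)
  expect_equal(a$transmitted, b$transmitted, tolerance = 1e-12)
  expect_identical(a$n_detected, b$n_detected)
  # the uniform substreams themselves agree bitwise
  rng <- drsmethb:::mrg_new(123, 5)
  ur <- vapply(1:200, function(i) drsmethb:::mrg_next(rng), numeric(1))
  expect_identical(ur, drsmethb:::mrg_uniforms_cpp(123, 5, 200))
})

test_that("simulation is bitwise reproducible and seed-sensitive", {
  cfg <- sim_config(n_photons = 2000, seed = 42)
  st <- build_optical_stack(560, skin, healthy, tabs)
  a <- simulate_wavelength(st, probe6, cfg, 0)
  b <- simulate_wavelength(st, probe6, cfg, 0)
  expect_identical(a, b)
  c1 <- simulate_wavelength(st, probe6, cfg, 1)
  expect_false(identical(a$fiber, c1$fiber))
  cfg2 <- sim_config(n_photons = 2000, seed = 43)
  expect_false(identical(a$fiber, simulate_wavelength(st, probe6, cfg2, 0)$fiber))
})

test_that("energy is conserved and fibers are symmetric at 1e5 photons", {
  cfg <- sim_config(n_photons = 1e5, seed = 5)
  st <- build_optical_stack(700, skin, healthy, tabs)
  r <- simulate_wavelength(st, probe6, cfg, 0)
  total <- r$specular + r$top_diffuse + r$transmitted + r$absorbed
  expect_lt(abs(total - 1), 1e-3)
  expect_true(all(r$fiber >= 0) && all(r$fiber <= 1))
  # lateral homogeneity: per-fiber means pairwise equal within 4 SE
  se <- sqrt(pmax(r$fiber_sumsq - r$fiber^2, 0) / cfg$n_photons)
  for (i in 1:5) for (j in (i + 1):6)
    expect_lt(abs(r$fiber[i] - r$fiber[j]), 4 * sqrt(se[i]^2 + se[j]^2))
})

test_that("an opaque top layer extinguishes the fiber signal", {
  st <- build_optical_stack(560, skin, healthy, tabs)
  st$mua[1] <- 1e6
  r <- simulate_wavelength(st, probe6, sim_config(n_photons = 2000, seed = 2), 0)
  expect_equal(r$total, 0)
  expect_lt(r$top_diffuse, 1e-3)
})

test_that("raising dermis absorption never raises the detected signal", {
  cfg <- sim_config(n_photons = 2e4, seed = 9)
  st <- build_optical_stack(560, skin, healthy, tabs)
  tot <- vapply(c(1, 2, 4), function(k) {
    s <- st; s$mua[3] <- st$mua[3] * k
    simulate_wavelength(s, probe6, cfg, 0)$total
  }, numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("shared-trajectory reweighting agrees with the direct engine", {
  cfg <- sim_config(n_photons = 2e4, seed = 31)
  st <- build_optical_stack(560, skin, healthy, tabs)
  a <- simulate_wavelength(st, probe6, cfg, 0)
  w <- drsmethb:::mc_run_white_cpp(
    st$mus, st$g, st$n, st$thickness_cm, st$n_above, st$n_below,
    probe6$source_radius_cm, probe6$detector_centers_cm,
    probe6$detector_radius_cm, probe6$cos_accept,
    cfg$n_photons, cfg$seed, 1, matrix(st$mua, nrow = 1), cfg$max_steps)
  se_a <- sqrt(sum(pmax(a$fiber_sumsq - a$fiber^2, 0)) / cfg$n_photons)
  expect_lt(abs(a$total - sum(w$fiber[1, ])), 4 * sqrt(2) * se_a)
  # the white-engine ledger balances exactly, photon by photon
  ledger <- w$specular + w$top_diffuse[1] + w$transmitted[1] + w$absorbed[1]
  expect_equal(ledger, 1, tolerance = 1e-12)
})

test_that("spectrum simulation returns coherent fractions over the grid", {
  expect_length(sim_config()$wavelengths, 301)
  cfg <- sim_config(n_photons = 1000, seed = 17, wavelengths = seq(400, 1000, 50))
  s <- simulate_spectrum(skin, healthy, probe6, cfg, tabs, engine = "direct")
  expect_length(s$wavelengths, 13)
  expect_equal(s$total_reflectance, rowSums(s$per_fiber))
  frac <- c(s$total_reflectance, s$specular, s$transmitted, s$absorbed)
  expect_true(all(frac >= 0 & frac <= 1))
})

test_that("a healthy spectrum shows the visible-band valley structure", {
  cfg <- sim_config(n_photons = 2e4, seed = 3, wavelengths = seq(400, 600, 5))
  s <- simulate_spectrum(skin, healthy, probe6, cfg, tabs, engine = "shared")
  sm <- smooth_spectrum(drs_spectrum(s$wavelengths, s$total_reflectance))
  neg <- max(sm$reflectance) - sm$reflectance
  n <- length(neg)
  valleys <- sum(vapply(2:(n - 1), function(i)
    neg[i] > neg[i - 1] && neg[i] >= neg[i + 1], logical(1)))
  expect_gte(valleys, 2)
})
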