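test_that("chromophore power laws evaluate correctly and decrease with wavelength", {
  # direct scalar evaluation: 6.6e11 * 500^-3.33 and 7.84e8 * 500^-3.255
  expect_equal(melanin_mua(1e3) * (1e3 / 500)^3.33, melanin_mua(500))
  expect_equal(melanin_mua(500), 6.6e11 * exp(-3.33 * log(500)))
  expect_equal(baseline_mua(500), 7.84e8 * exp(-3.255 * log(500)))
  expect_gt(melanin_mua(400), melanin_mua(800))
  wl <- seq(400, 1000, by = 10)
  expect_true(all(diff(melanin_mua(wl)) < 0))
  expect_true(all(diff(baseline_mua(wl)) < 0))
  expect_true(all(baseline_mua(wl) > 0))
  expect_error(melanin_mua(399), "band")
  expect_error(baseline_mua(1001), "band")
})

test_that("hemoglobin partition conserves total hemoglobin", {
  expect_equal(methb_partition(0, 150), list(cmet = 0, c_functional = 150))
  expect_equal(methb_partition(1, 150), list(cmet = 150, c_functional = 0))
  expect_equal(methb_partition(0.4, 150), list(cmet = 60, c_functional = 90))
  for (f in seq(0, 1, by = 0.05)) {
    p <- methb_partition(f, 150)
    expect_equal(p$cmet + p$c_functional, 150)
  }
  expect_error(methb_partition(-0.1), "\\[0, 1\\]")
  expect_error(methb_partition(1.2), "\\[0, 1\\]")
})

test_that("Beer-Lambert conversion is linear with the hemoglobin molar weight", {
  expect_equal(hemoglobin_mua(5000, 0), 0)
  expect_equal(hemoglobin_mua(1, 64500), 2.303)
  expect_equal(hemoglobin_mua(1000, 150), 2.303 * (150 / 64500) * 1000)
  expect_equal(hemoglobin_mua(2 * 1000, 150), 2 * hemoglobin_mua(1000, 150))
  expect_error(hemoglobin_mua(-1, 10), "non-negative")
})

test_that("blood absorption reduces to its pure components in limiting states", {
  # pure MetHb: functional hemoglobin is zero, arterial = venous = met term
  b <- blood_state(0.98, methb_fraction = 1)
  lam <- c(450, 560, 630, 800)
  met_only <- 2 * hemoglobin_mua(ext_value(tabs$met, lam), 150)
  expect_equal(blood_mua(lam, b, tabs), met_only)
  # fully oxygenated, no MetHb: both terms are oxyhemoglobin at 150 g/L
  b2 <- blood_state(1, 0, svo2 = 1)
  oxy_only <- 2 * hemoglobin_mua(ext_value(tabs$oxy, lam), 150)
  expect_equal(blood_mua(lam, b2, tabs), oxy_only)
  # arterial_fraction 0.5 averages the two branches
  b3 <- blood_state(0.9, 0.2)
  expect_equal(blood_mua(560, b3, tabs, arterial_fraction = 0.5),
               blood_mua(560, b3, tabs) / 2)
})

test_that("blood absorption matches a term-by-term hand evaluation at 560 nm", {
  # spreadsheet-style oracle straight from the bundled tables
  eo <- tsv_value("eps_oxyhb_synthetic.tsv", 560)
  ed <- tsv_value("eps_deoxyhb_synthetic.tsv", 560)
  em <- tsv_value("eps_methb_synthetic.tsv", 560)
  cf <- 150 - 0.1 * 150
  k <- 2.303 / 64500
  art <- 0.98 * k * cf * eo + 0.02 * k * cf * ed + k * 15 * em
  ven <- 0.88 * k * cf * eo + 0.12 * k * cf * ed + k * 15 * em
  expect_equal(blood_mua(560, blood_state(0.98, 0.1), tabs), art + ven,
               tolerance = 1e-12)
})

test_that("MetHb raises blood absorption at its 630 nm signature band", {
  # at 630 nm the MetHb coefficient dominates oxyhemoglobin at high SaO2,
  # so absorption grows with the MetHb fraction
  vals <- vapply(seq(0, 1, 0.25), function(f)
    blood_mua(630, blood_state(0.98, f), tabs), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("layer absorption collapses to the baseline without chromophores", {
  lam <- c(420, 560, 700, 950)
  sc0 <- layer_spec("stratum_corneum", 20, vfw = 0)
  expect_equal(layer_mua(lam, sc0, healthy, tabs), baseline_mua(lam))
  ep0 <- layer_spec("epidermis", 80, vfw = 0, vfme = 0)
  expect_equal(layer_mua(lam, ep0, healthy, tabs), baseline_mua(lam))
  bad <- layer_spec("unknown_layer", 10)
  expect_error(layer_mua(560, bad, healthy, tabs), "unknown layer")
})

test_that("dermis absorption matches the printed mixture, term by term", {
  lay <- skin$layers$dermis
  lam <- 560
  oracle <- 0.002 * blood_mua(lam, healthy, tabs) +
    0.65 * tsv_value("mua_water_synthetic.tsv", lam) +
    2.3 * 1.71e-6 * tsv_value("eps_bilirubin_synthetic.tsv", lam) +
    tsv_value("mua_betacarotene_synthetic.tsv", lam) +
    (1 - (0.002 + 0.65)) * 7.84e8 * lam^-3.255
  expect_equal(layer_mua(lam, lay, healthy, tabs), oracle, tolerance = 1e-12)
})

test_that("layer absorption is affine in each volume fraction", {
  mk <- function(vfw) layer_spec("epidermis", 80, vfw = vfw, vfme = 0.025)
  lam <- 500
  f <- function(vfw) layer_mua(lam, mk(vfw), healthy, tabs)
  # midpoint value equals the average of the endpoints for a linear map
  expect_equal(f(0.2), (f(0.1) + f(0.3)) / 2, tolerance = 1e-12)
  mk2 <- function(vfbl) layer_spec("dermis", 2000, vfw = 0.65, vfbl = vfbl)
  g <- function(vfbl) layer_mua(lam, mk2(vfbl), healthy, tabs)
  expect_equal(g(0.02), (g(0.01) + g(0.03)) / 2, tolerance = 1e-12)
})

test_that("Rayleigh-Mie scattering law evaluates at its anchors", {
  derm <- skin$layers$dermis
  expect_equal(layer_mus(500, derm)$mus * (1 - 0.86), 43.6)
  epi <- skin$layers$epidermis
  oracle <- 66.7 * (0.29 * 1.6^-4 + 0.71 * 1.6^-0.689)
  expect_equal(layer_mus(800, epi)$mus, oracle / 0.14, tolerance = 1e-12)
  bad <- layer_spec("dermis", 100, g = 0.99)
  bad$g <- 1
  expect_error(layer_mus(500, bad), "undefined")
})

test_that("optical stacks are positive, deterministic and wavelength-coherent", {
  for (lam in seq(400, 1000, by = 100)) {
    st <- build_optical_stack(lam, skin, healthy, tabs)
    expect_length(st$mua, 4)
    expect_true(all(st$mua > 0))
    expect_true(all(st$mus > 0))
  }
  s1 <- build_optical_stack(560, skin, healthy, tabs)
  s2 <- build_optical_stack(560, skin, healthy, tabs)
  expect_identical(s1, s2)
  # hemoglobin makes the dermis far more absorbing at 560 than at 900 nm
  s900 <- build_optical_stack(900, skin, healthy, tabs)
  expect_gt(s1$mua[["dermis"]], s900$mua[["dermis"]])
})

test_that("extinction tables validate their invariants", {
  expect_error(extinction_table(c(500, 500), c(1, 1), "x"), "increasing")
  expect_error(extinction_table(c(500, 510), c(-1, 1), "x"), "non-negative")
  expect_error(ext_value(tabs$oxy, 350), "range")
  expect_error(ext_value(tabs$water, 1200), "range")
  # all seven bundled tables cover the analysis band
  for (tb in tabs) {
    expect_true(min(tb$wavelength_nm) <= 400 && max(tb$wavelength_nm) >= 1000)
    expect_true(all(ext_value(tb, seq(400, 1000, 7)) >= 0))
  }
})
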