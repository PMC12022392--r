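test_that("Savitzky-Golay smoothing is exact on polynomials and reduces noise", {
  wl <- seq(400, 1000, by = 2)
  u <- (wl - 700) / 300
  cubic <- drs_spectrum(wl, 2 + u + u^2 + 0.5 * u^3)
  sm <- smooth_spectrum(cubic, window = 11, polyorder = 3)
  expect_equal(sm$reflectance, cubic$reflectance, tolerance = 1e-10)
  const <- drs_spectrum(wl, rep(0.3, length(wl)))
  expect_equal(smooth_spectrum(const)$reflectance, const$reflectance,
               tolerance = 1e-12)
  # paired-variance comparison about the clean signal
  clean <- 1.5 + 0.5 * sin(wl / 40)
  set.seed(11)
  noisy <- drs_spectrum(wl, clean + rnorm(length(wl), sd = 0.05))
  smn <- smooth_spectrum(noisy)
  expect_lt(var(smn$reflectance - clean), var(noisy$reflectance - clean))
  expect_error(smooth_spectrum(cubic, window = 10), "odd")
  expect_error(smooth_spectrum(cubic, window = 11, polyorder = 11), "smaller")
  expect_error(smooth_spectrum(drs_spectrum(wl[1:8], rep(1, 8)), window = 11),
               "exceeds")
})

test_that("peak analysis recovers a Gaussian bump and flags degenerate input", {
  s <- gauss_spectrum(center = 560, sigma = 20, amp = 0.5, base = 0)
  pf <- peak_features(s)
  expect_lt(abs(pf[["peak_location"]] - 560), 2)        # one grid step
  expect_equal(pf[["peak_amplitude"]], 0.5, tolerance = 1e-6)
  fwhm <- 2 * sqrt(2 * log(2)) * 20
  expect_lt(abs(pf[["width_half_height"]] - fwhm), 2)
  # on a zero baseline the prominence is the amplitude and the
  # half-prominence width coincides with the FWHM
  expect_equal(pf[["prominence"]], 0.5, tolerance = 1e-6)
  expect_lt(abs(pf[["width_half_prominence"]] - fwhm), 2)

  mono <- drs_spectrum(seq(400, 1000, 2), seq(0.1, 0.7, length.out = 301))
  expect_warning(pf2 <- peak_features(mono), "degenerate")
  expect_equal(unname(pf2), rep(0, 5))
})

test_that("the most prominent of several peaks is selected", {
  wl <- seq(400, 1000, by = 2)
  two <- drs_spectrum(wl, 0.05 +
    0.2 * exp(-(wl - 480)^2 / (2 * 15^2)) +
    0.5 * exp(-(wl - 700)^2 / (2 * 30^2)))
  pf <- peak_features(two)
  expect_lt(abs(pf[["peak_location"]] - 700), 2)
})

test_that("signal power follows its definition", {
  expect_equal(signal_power(rep(0, 5)), 0)
  expect_equal(signal_power(rep(3, 7)), 9)
  expect_equal(signal_power(c(3, 4)), 12.5)
  x <- runif(50)
  expect_equal(signal_power(x), mean(x^2))
})

test_that("the energy operator matches its closed forms and a brute-force loop", {
  expect_equal(kte_profile(rep(2, 10)), rep(0, 8))
  expect_equal(kte_profile(1:10), rep(1, 8))         # ramp: n^2-(n-1)(n+1)=1
  n <- 1:200; A <- 1.7; om <- 0.23
  x <- A * sin(om * n)
  expect_equal(kte_profile(x), rep(A^2 * sin(om)^2, 198), tolerance = 1e-9)
  expect_error(kte_profile(c(1, 2)), "3 samples")
  # exact agreement with an index-by-index loop
  set.seed(5)
  for (len in c(3, 7, 50)) {
    y <- rnorm(len)
    brute <- vapply(2:(len - 1), function(i) y[i]^2 - y[i - 1] * y[i + 1],
                    numeric(1))
    expect_identical(kte_profile(y), brute)
  }
})

test_that("energy-profile statistics follow textbook conventions", {
  st <- kte_stats(rep(4, 10))
  expect_equal(unname(st[c("kte_variance", "kte_sd")]), c(0, 0))
  expect_equal(st[["kte_mean"]], 4)
  expect_equal(st[["kte_rms"]], 4)
  # hand-computed oracle for [1, 2, 3, 4]:
  # mean 2.5; var (n-1) 5/3; sd sqrt(5/3); rms sqrt(30/4);
  # population moments m2 = 1.25, m3 = 0, m4 = 2.5625 -> skew 0, kurt 1.64
  st2 <- kte_stats(1:4)
  expect_equal(unname(st2), c(0, 5 / 3, 1.64, 2.5, sqrt(7.5), sqrt(5 / 3)),
               tolerance = 1e-12)
  sym <- c(-(5:1), 0, 1:5)  # mirror-symmetric profile
  expect_equal(kte_stats(sym)[["kte_skewness"]], 0, tolerance = 1e-10)
  expect_error(kte_stats(1), "at least 2")
})

test_that("the assembled descriptor has 12 entries and composes its parts", {
  s <- gauss_spectrum(base = 0.05)
  fv <- assemble_features(s)
  expect_length(fv, 12)
  expect_identical(names(fv), drs_feature_names)
  expect_identical(fv, assemble_features(s))
  sm <- smooth_spectrum(s, 11, 3)
  manual <- c(peak_features(sm), signal_power = signal_power(sm$reflectance),
              kte_stats(kte_profile(sm$reflectance)))
  expect_equal(fv, manual)
})

test_that("features scale covariantly with reflectance amplitude", {
  wl <- seq(400, 1000, by = 2)
  set.seed(21)
  base <- 0.2 + 0.1 * sin(wl / 55) + 0.3 * exp(-(wl - 540)^2 / (2 * 25^2))
  s1 <- drs_spectrum(wl, base)
  c <- 3.7
  s2 <- drs_spectrum(wl, c * base)
  f1 <- assemble_features(s1); f2 <- assemble_features(s2)
  lin <- c("peak_amplitude", "prominence")
  quad <- c("signal_power", "kte_mean", "kte_rms", "kte_sd")
  inv <- c("peak_location", "width_half_height", "width_half_prominence",
           "kte_skewness", "kte_kurtosis")
  expect_equal(f2[lin], c * f1[lin], tolerance = 1e-8)
  expect_equal(f2[quad], c^2 * f1[quad], tolerance = 1e-8)
  expect_equal(f2[["kte_variance"]], c^4 * f1[["kte_variance"]], tolerance = 1e-8)
  expect_equal(f2[inv], f1[inv], tolerance = 1e-8)
})

test_that("greedy CFS prefers informative, non-redundant features", {
  set.seed(31)
  n <- 80
  y <- cbind(runif(n), runif(n))
  x <- cbind(y[, 1] + y[, 2],              # exactly target-aligned
             rnorm(n), rnorm(n), rnorm(n)) # pure noise
  expect_equal(cfs_select(x, y, k = 1), 1L)

  # duplicated informative columns: the pair is not taken twice before an
  # unrelated informative feature; verified against exhaustive enumeration
  x2 <- cbind(a = y[, 1], b = y[, 1], c = y[, 2], d = rnorm(n))
  sel2 <- cfs_select(x2, y, k = 2)
  expect_setequal(sel2, c(1L, 3L))
  abs_cor <- function(p, q) if (sd(p) == 0 || sd(q) == 0) 0 else abs(cor(p, q))
  merit <- function(cols) {
    rcf <- mean(vapply(cols, function(j)
      mean(c(abs_cor(x2[, j], y[, 1]), abs_cor(x2[, j], y[, 2]))), numeric(1)))
    m <- length(cols)
    rff <- if (m > 1) mean(apply(utils::combn(cols, 2), 2, function(p)
      abs_cor(x2[, p[1]], x2[, p[2]]))) else 0
    m * rcf / sqrt(m + m * (m - 1) * rff)
  }
  pairs <- utils::combn(4, 2)
  merits <- apply(pairs, 2, merit)
  expect_setequal(sel2, pairs[, which.max(merits)])

  # k = p returns every feature; constant columns rank last
  x3 <- cbind(y[, 1], rnorm(n), rep(1, n))
  sel3 <- cfs_select(x3, y, k = 3)
  expect_setequal(sel3, 1:3)
  expect_equal(sel3[1], 1L)
  expect_equal(sel3[3], 3L)

  # invariance to sample order
  perm <- sample(n)
  expect_identical(cfs_select(x2[perm, ], y[perm, ], k = 2), sel2)
})
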