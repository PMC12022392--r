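# Fiber-probe Monte Carlo photon transport: R-facing constructors and
# wrappers around the compiled engine, plus a deliberately naive pure-R
# reference loop that shares the engine's RNG stream bit for bit.

#' Fiber probe geometry
#'
#' One central illumination fiber surrounded by collection fibers on a
#' hexagonal ring (one per 60 degrees by default).
#'
#' @param source_radius_um Illumination fiber radius (um).
#' @param sds_um Center-to-center source-detector separation (um).
#' @param detector_radius_um Collection fiber radius (um).
#' @param n_detectors Number of collection fibers, equally spaced in angle.
#' @param max_accept_deg Maximum polar exit angle accepted by the collection
#'   fibers, in degrees; `NULL` accepts the full hemisphere.
#' @return An object of class `probe_geometry` (lengths stored in cm).
#' @export
probe_geometry <- function(source_radius_um = 100, sds_um = 240,
                           detector_radius_um = 100, n_detectors = 6,
                           max_accept_deg = NULL) {
  if (source_radius_um <= 0 || detector_radius_um <= 0 || sds_um <= 0)
    stop("probe radii and separation must be positive")
  ang <- 2 * pi * (seq_len(n_detectors) - 1) / n_detectors
  centers <- cbind(x = sds_um * 1e-4 * cos(ang), y = sds_um * 1e-4 * sin(ang))
  overlap <- sds_um < source_radius_um + detector_radius_um
  if (overlap)
    warning("detector discs overlap the source disc; geometry kept as requested")
  structure(list(source_radius_cm = source_radius_um * 1e-4,
                 detector_radius_cm = detector_radius_um * 1e-4,
                 sds_cm = sds_um * 1e-4,
                 detector_centers_cm = centers,
                 cos_accept = if (is.null(max_accept_deg)) -1
                              else cos(max_accept_deg * pi / 180),
                 overlap = overlap),
            class = "probe_geometry")
}

#' Simulation configuration
#'
#' @param n_photons Photon packets per wavelength.
#' @param seed Master seed; each wavelength uses an independent substream
#'   derived from `(seed, stream index)`.
#' @param wavelengths Wavelength grid in nm (default 400--1000 at 2 nm).
#' @param roulette_threshold Packet weight below which roulette triggers.
#' @param roulette_chance Roulette survival probability.
#' @param spatial_bin_cm Bin size for optional deposition maps (kept as
#'   metadata; transport itself is layered, not voxelized).
#' @param max_steps Safety cap on interactions per packet.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_photons = 2e4, seed = 1,
                       wavelengths = seq(400, 1000, by = 2),
                       roulette_threshold = 1e-4, roulette_chance = 0.1,
                       spatial_bin_cm = 0.005, max_steps = 5e6) {
  if (n_photons < 1) stop("n_photons must be at least 1")
  if (roulette_chance <= 0 || roulette_chance > 1)
    stop("roulette_chance must lie in (0, 1]")
  if (seed < 0 || seed != round(seed)) stop("seed must be a non-negative integer")
  structure(list(n_photons = as.integer(n_photons), seed = seed,
                 wavelengths = wavelengths,
                 roulette_threshold = roulette_threshold,
                 roulette_chance = roulette_chance,
                 spatial_bin_cm = spatial_bin_cm,
                 max_steps = as.integer(max_steps)),
            class = "sim_config")
}

# ---- RNG: MRG32k3a in pure R, bit-identical to the compiled engine ----

mrg_new <- function(seed, stream) {
  h <- ((seed + 20010927 * (stream + 1)) %% 2147483646) + 1
  st <- numeric(6)
  for (i in 1:6) {
    h <- (16807 * h) %% 2147483647
    st[i] <- h
  }
  e <- new.env(parent = emptyenv())
  e$s <- st
  for (i in 1:8) mrg_next(e)
  e
}

mrg_next <- function(e) {
  m1 <- 4294967087; m2 <- 4294944443
  s <- e$s
  p1 <- 1403580 * s[2] - 810728 * s[1]
  k <- trunc(p1 / m1); p1 <- p1 - k * m1
  if (p1 < 0) p1 <- p1 + m1
  s[1] <- s[2]; s[2] <- s[3]; s[3] <- p1
  p2 <- 527612 * s[6] - 1370589 * s[4]
  k <- trunc(p2 / m2); p2 <- p2 - k * m2
  if (p2 < 0) p2 <- p2 + m2
  s[4] <- s[5]; s[5] <- s[6]; s[6] <- p2
  e$s <- s
  v <- p1 - p2
  if (v <= 0) v <- v + m1
  v * 2.328306549295727688e-10
}

# ---- pure transport primitives (also the naive loop's building blocks) ----

#' Exponential free-path sampling
#'
#' Transforms a uniform draw into a step length `-log(u)/mu_t`.
#'
#' @param u Uniform draws in (0, 1\].
#' @param mu_t Total interaction coefficient, cm^-1 (> 0).
#' @return Step lengths in cm.
#' @export
sample_step <- function(u, mu_t) {
  if (any(mu_t <= 0)) stop("mu_t must be positive")
  -log(u) / mu_t
}

#' Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the scattering deflection cosine; `g = 0` reduces
#' to isotropic `2u - 1`.
#'
#' @param u Uniform draws in (0, 1).
#' @param g Anisotropy factor in (-1, 1).
#' @return Deflection cosines in \[-1, 1\].
#' @export
sample_hg_cos <- function(u, g) {
  if (abs(g) >= 1) stop("g must lie in (-1, 1)")
  if (g == 0) return(2 * u - 1)
  tmp <- (1 - g^2) / (1 - g + 2 * g * u)
  (1 + g^2 - tmp^2) / (2 * g)
}

#' Unpolarized Fresnel reflectance
#'
#' @param n1,n2 Refractive indices of the incident and transmitting media.
#' @param cos_i Cosine of the incidence angle (>= 0).
#' @return List with `R` (reflectance, 1 under total internal reflection)
#'   and `cos_t` (cosine of the refraction angle).
#' @export
fresnel_unpolarized <- function(n1, n2, cos_i) {
  if (cos_i > 0.999999) {
    r <- (n1 - n2) / (n1 + n2)
    return(list(R = r * r, cos_t = 1))
  }
  sin_i <- sqrt(1 - cos_i^2)
  sin_t <- sin_i * n1 / n2
  if (sin_t >= 1) return(list(R = 1, cos_t = 0))
  ct <- sqrt(1 - sin_t^2)
  rs <- (n1 * cos_i - n2 * ct) / (n1 * cos_i + n2 * ct)
  rp <- (n1 * ct - n2 * cos_i) / (n1 * ct + n2 * cos_i)
  list(R = 0.5 * (rs^2 + rp^2), cos_t = ct)
}

#' Launch weight after specular loss
#'
#' Packet weight after normal-incidence specular reflection at the
#' air-tissue interface.
#'
#' @param n_above,n_top Refractive indices above and in the top layer.
#' @return Initial packet weight in \[0, 1\].
#' @export
launch_weight <- function(n_above, n_top) {
  1 - ((n_above - n_top) / (n_above + n_top))^2
}

#' Absorption weight drop
#'
#' Discrete absorption weighting: one interaction deposits
#' `weight * mu_a / mu_t`.
#'
#' @param weight Packet weight.
#' @param mu_a,mu_t Absorption and total interaction coefficients (cm^-1),
#'   with `0 <= mu_a <= mu_t`.
#' @return List with the updated `weight` and the `deposited` fraction.
#' @export
absorb_weight <- function(weight, mu_a, mu_t) {
  if (any(mu_a < 0) || any(mu_a > mu_t))
    stop("require 0 <= mu_a <= mu_t")
  dep <- weight * mu_a / mu_t
  list(weight = weight - dep, deposited = dep)
}

#' Roulette survival
#'
#' Unbiased low-weight termination: given a uniform draw, the packet
#' survives with probability `chance` and its weight is scaled by
#' `1/chance`; otherwise weight 0 (dead). Packets at or above `threshold`
#' are returned unchanged.
#'
#' @param weight Packet weight.
#' @param u Uniform draw in (0, 1).
#' @param threshold Roulette trigger weight.
#' @param chance Survival probability in (0, 1\].
#' @return Updated weight (0 when the packet is terminated).
#' @export
roulette_weight <- function(weight, u, threshold, chance) {
  if (weight >= threshold) return(weight)
  if (u < chance) weight / chance else 0
}

#' Detector lookup for an exiting photon
#'
#' @param x,y Exit position on the top surface, cm.
#' @param probe A [probe_geometry()].
#' @param cos_exit Cosine of the exit polar angle (checked against the
#'   probe's acceptance; default normal exit).
#' @return Fiber index (1-based) or `NA` when no fiber collects the photon.
#' @export
detect_fiber <- function(x, y, probe, cos_exit = 1) {
  if (probe$cos_accept > -1 && abs(cos_exit) < probe$cos_accept) return(NA_integer_)
  d2 <- (x - probe$detector_centers_cm[, 1])^2 +
        (y - probe$detector_centers_cm[, 2])^2
  hit <- which(d2 <= probe$detector_radius_cm^2)
  if (length(hit)) hit[1] else NA_integer_
}

# ---- engine wrappers ----

.stack_ok <- function(stack) {
  stopifnot(inherits(stack, "optical_stack"))
  if (any(stack$mua < 0) || any(stack$mus < 0) ||
      any(stack$mua + stack$mus <= 0))
    stop("stack must have mua, mus >= 0 with mua + mus > 0 in every layer")
  invisible(stack)
}

#' Simulate one wavelength
#'
#' Runs `n_photons` hop-drop-spin packets through the layered stack and
#' returns collected fiber weights and the energy ledger. Bitwise
#' reproducible for a given `(seed, stream_index)`.
#'
#' @param stack An [build_optical_stack()] result.
#' @param probe A [probe_geometry()].
#' @param config A [sim_config()].
#' @param stream_index RNG substream index (one per wavelength).
#' @return List with `fiber` (per-fiber detected fractions), `total`
#'   (their sum), `fiber_sumsq` (per-fiber mean squared detected weight,
#'   for standard errors), `top_diffuse`, `transmitted`, `absorbed`,
#'   `specular`, `n_detected`, `n_capped`.
#' @export
simulate_wavelength <- function(stack, probe, config, stream_index = 0) {
  .stack_ok(stack)
  out <- mc_run_wavelength_cpp(
    stack$mua, stack$mus, stack$g, stack$n, stack$thickness_cm,
    stack$n_above, stack$n_below,
    probe$source_radius_cm, probe$detector_centers_cm,
    probe$detector_radius_cm, probe$cos_accept,
    config$n_photons, config$seed, stream_index,
    config$roulette_threshold, config$roulette_chance, config$max_steps)
  out$total <- sum(out$fiber)
  out
}

#' Naive reference photon loop (one wavelength)
#'
#' A deliberately plain, unoptimized pure-R transcription of the transport
#' loop, consuming the same RNG stream as the compiled engine. Intended as
#' an independent oracle for validating the engine at small photon counts.
#'
#' @inheritParams simulate_wavelength
#' @return Same aggregate list as [simulate_wavelength()].
#' @export
mc_reference_wavelength <- function(stack, probe, config, stream_index = 0) {
  .stack_ok(stack)
  stack$mua <- unname(stack$mua)
  stack$mus <- unname(stack$mus)
  stack$g <- unname(stack$g)
  L <- length(stack$mua)
  zb <- c(0, cumsum(unname(stack$thickness_cm)))
  mut <- stack$mua + stack$mus
  nvec <- unname(stack$n)
  rsp <- ((stack$n_above - nvec[1]) / (stack$n_above + nvec[1]))^2
  det <- probe$detector_centers_cm
  detr2 <- probe$detector_radius_cm^2
  nd <- nrow(det)
  rng <- mrg_new(config$seed, stream_index)

  fiber <- numeric(nd); fiber_sq <- numeric(nd)
  top_diffuse <- 0; transmitted <- 0; absorbed <- 0
  n_detected <- 0L; n_capped <- 0L

  for (ip in seq_len(config$n_photons)) {
    u <- mrg_next(rng); r <- probe$source_radius_cm * sqrt(u)
    u <- mrg_next(rng); phi0 <- 2 * pi * u
    x <- r * cos(phi0); y <- r * sin(phi0); z <- 0
    ux <- 0; uy <- 0; uz <- 1
    w <- 1 - rsp
    lay <- 1L
    alive <- TRUE
    steps <- 0L

    while (alive) {
      steps <- steps + 1L
      if (steps > config$max_steps) {
        n_capped <- n_capped + 1L; absorbed <- absorbed + w; break
      }
      u <- mrg_next(rng)
      s <- -log(u) / mut[lay]
      repeat {
        db <- if (uz > 0) (zb[lay + 1] - z) / uz
              else if (uz < 0) (zb[lay] - z) / uz
              else 1e300
        if (s < db) {
          x <- x + s * ux; y <- y + s * uy; z <- z + s * uz
          break
        }
        x <- x + db * ux; y <- y + db * uy
        s <- s - db
        up <- uz < 0
        z <- if (up) zb[lay] else zb[lay + 1]
        n1 <- nvec[lay]
        n2 <- if (up) { if (lay == 1L) stack$n_above else nvec[lay - 1L] }
              else    { if (lay == L)  stack$n_below else nvec[lay + 1L] }
        fr <- fresnel_unpolarized(n1, n2, abs(uz))
        u <- mrg_next(rng)
        if (u > fr$R) {
          if (up && lay == 1L) {
            top_diffuse <- top_diffuse + w
            f <- detect_fiber(x, y, probe, cos_exit = fr$cos_t)
            if (!is.na(f)) {
              fiber[f] <- fiber[f] + w
              fiber_sq[f] <- fiber_sq[f] + w^2
              n_detected <- n_detected + 1L
            }
            alive <- FALSE
            break
          }
          if (!up && lay == L) {
            transmitted <- transmitted + w
            alive <- FALSE
            break
          }
          scale <- n1 / n2
          ux <- ux * scale; uy <- uy * scale
          uz <- if (up) -fr$cos_t else fr$cos_t
          nl <- if (up) lay - 1L else lay + 1L
          s <- s * (mut[lay] / mut[nl])
          lay <- nl
        } else {
          uz <- -uz
        }
      }
      if (!alive) break
      ab <- absorb_weight(w, stack$mua[lay], mut[lay])
      w <- ab$weight
      absorbed <- absorbed + ab$deposited
      u <- mrg_next(rng)
      cost <- sample_hg_cos(u, stack$g[lay])
      u <- mrg_next(rng)
      phi <- 2 * pi * u
      sint <- sqrt(1 - cost^2); cosp <- cos(phi); sinp <- sin(phi)
      if (abs(uz) > 0.99999) {
        ux <- sint * cosp
        uy <- sint * sinp
        uz <- if (uz >= 0) cost else -cost
      } else {
        tmp <- sqrt(1 - uz^2)
        nux <- sint * (ux * uz * cosp - uy * sinp) / tmp + ux * cost
        nuy <- sint * (uy * uz * cosp + ux * sinp) / tmp + uy * cost
        nuz <- -sint * cosp * tmp + uz * cost
        ux <- nux; uy <- nuy; uz <- nuz
      }
      if (w < config$roulette_threshold) {
        u <- mrg_next(rng)
        w <- roulette_weight(w, u, config$roulette_threshold,
                             config$roulette_chance)
        if (w == 0) alive <- FALSE
      }
    }
  }

  np <- config$n_photons
  list(fiber = fiber / np, fiber_sumsq = fiber_sq / np,
       top_diffuse = top_diffuse / np, transmitted = transmitted / np,
       absorbed = absorbed / np, specular = rsp,
       n_detected = n_detected, n_capped = n_capped,
       total = sum(fiber) / np)
}

#' Simulate a diffuse reflectance spectrum
#'
#' Builds the optical stack at every wavelength of the configuration grid and
#' runs the Monte Carlo engine, one RNG substream per wavelength. The total
#' diffuse reflectance at each wavelength is the sum over the collection
#' fibers.
#'
#' @param model A [tissue_model()].
#' @param blood A [blood_state()].
#' @param probe A [probe_geometry()].
#' @param config A [sim_config()].
#' @param tables Chromophore tables ([chromophore_tables()]).
#' @param engine `"direct"` for discrete absorption weighting (classic
#'   hop-drop-spin), `"shared"` for scattering-only trajectories with
#'   analytic Beer-Lambert absorption weighting (identical expectation,
#'   different variance structure).
#' @param arterial_fraction Passed to [blood_mua()].
#' @return An object of class `spectrum_result`: data frame-like list with
#'   `wavelengths`, `total_reflectance`, `per_fiber` (n_lambda x 6),
#'   `specular`, `transmitted`, `absorbed`, `top_diffuse` and simulation
#'   metadata (`n_photons`, `seed`, `engine`).
#' @export
simulate_spectrum <- function(model, blood, probe = probe_geometry(),
                              config = sim_config(),
                              tables = chromophore_tables(),
                              engine = c("direct", "shared"),
                              arterial_fraction = NULL) {
  engine <- match.arg(engine)
  wl <- config$wavelengths
  nl <- length(wl)
  nf <- nrow(probe$detector_centers_cm)
  per_fiber <- matrix(0, nl, nf)
  specular <- transmitted <- absorbed <- top_diffuse <- numeric(nl)
  for (i in seq_len(nl)) {
    stack <- build_optical_stack(wl[i], model, blood, tables,
                                 arterial_fraction)
    if (engine == "direct") {
      res <- simulate_wavelength(stack, probe, config, stream_index = i - 1)
      per_fiber[i, ] <- res$fiber
    } else {
      res <- mc_run_white_cpp(
        stack$mus, stack$g, stack$n, stack$thickness_cm,
        stack$n_above, stack$n_below,
        probe$source_radius_cm, probe$detector_centers_cm,
        probe$detector_radius_cm, probe$cos_accept,
        config$n_photons, config$seed, i - 1,
        matrix(stack$mua, nrow = 1), config$max_steps)
      per_fiber[i, ] <- res$fiber[1, ]
      res$top_diffuse <- res$top_diffuse[1]
      res$transmitted <- res$transmitted[1]
      res$absorbed <- res$absorbed[1]
    }
    specular[i] <- res$specular
    transmitted[i] <- res$transmitted
    absorbed[i] <- res$absorbed
    top_diffuse[i] <- res$top_diffuse
  }
  structure(list(wavelengths = wl,
                 total_reflectance = rowSums(per_fiber),
                 per_fiber = per_fiber,
                 specular = specular, transmitted = transmitted,
                 absorbed = absorbed, top_diffuse = top_diffuse,
                 n_photons = config$n_photons, seed = config$seed,
                 engine = engine,
                 blood = blood),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf(paste0("<spectrum_result> %d wavelengths (%g-%g nm), ",
                     "%d photons/wavelength, seed %g, engine '%s'\n"),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$n_photons, x$seed, x$engine))
  cat(sprintf("  total reflectance: %.4g-%.4g\n",
              min(x$total_reflectance), max(x$total_reflectance)))
  invisible(x)
}
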