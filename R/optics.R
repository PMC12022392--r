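# Wavelength-resolved optical properties of the four-layer skin model:
# per-layer absorption as volume-fraction-weighted chromophore mixtures and
# reduced scattering as a 500-nm-normalized Rayleigh + Mie power law.

GRAM_MOL_WEIGHT_HB <- 64500   # g/mol, hemoglobin tetramer
BILIRUBIN_MOLARITY <- 1.71e-6 # mol/L in dermis

.check_band <- function(lambda_nm) {
  if (any(lambda_nm < 400 | lambda_nm > 1000))
    stop("wavelength outside the 400-1000 nm analysis band")
  lambda_nm
}

#' Melanin absorption coefficient
#'
#' Power-law melanosome absorption, `6.6e11 * lambda^-3.33` cm^-1.
#'
#' @param lambda_nm Wavelengths in nm, within 400--1000.
#' @return Absorption coefficient in cm^-1.
#' @export
melanin_mua <- function(lambda_nm) {
  .check_band(lambda_nm)
  6.6e11 * lambda_nm^-3.33
}

#' Baseline (bloodless tissue) absorption coefficient
#'
#' Absorption of the dermal sublayer in the absence of any named chromophore,
#' `7.84e8 * lambda^-3.255` cm^-1.
#'
#' @inheritParams melanin_mua
#' @return Absorption coefficient in cm^-1.
#' @export
baseline_mua <- function(lambda_nm) {
  .check_band(lambda_nm)
  7.84e8 * lambda_nm^-3.255
}

#' Partition total hemoglobin into MetHb and functional hemoglobin
#'
#' `cmet = fraction * total_hb`; the remainder is functional (oxy + deoxy)
#' hemoglobin. The two always sum to `total_hb`.
#'
#' @param methb_fraction Fraction of total hemoglobin present as MetHb, in
#'   \[0, 1\].
#' @param total_hb Total hemoglobin concentration in g/L (default 150).
#' @return List with `cmet` and `c_functional`, both g/L.
#' @export
methb_partition <- function(methb_fraction, total_hb = 150) {
  if (any(methb_fraction < 0 | methb_fraction > 1))
    stop("methb_fraction must lie in [0, 1]")
  if (any(total_hb < 0)) stop("total_hb must be non-negative")
  cmet <- methb_fraction * total_hb
  list(cmet = cmet, c_functional = total_hb - cmet)
}

#' Hemoglobin-derivative absorption coefficient
#'
#' Beer-Lambert conversion of a molar extinction coefficient to an absorption
#' coefficient: `2.303 * (c / 64500) * epsilon`.
#'
#' @param epsilon Molar extinction, L mol^-1 cm^-1 (per 64500 g/mol).
#' @param c Concentration in g/L.
#' @return Absorption coefficient in cm^-1.
#' @export
hemoglobin_mua <- function(epsilon, c) {
  if (any(epsilon < 0) || any(c < 0))
    stop("epsilon and c must be non-negative")
  2.303 * (c / GRAM_MOL_WEIGHT_HB) * epsilon
}

#' Blood state
#'
#' Arterial/venous oxygen saturation and MetHb fraction of total hemoglobin.
#' Unless given, venous saturation is derived as `max(SaO2 - 0.10, 0)`.
#'
#' @param sao2 Arterial oxygen saturation, fraction in \[0, 1\].
#' @param methb_fraction MetHb as a fraction of total hemoglobin, in \[0, 1\].
#' @param svo2 Venous oxygen saturation; `NULL` derives it from `sao2`.
#' @param total_hb Total hemoglobin, g/L.
#' @return An object of class `blood_state`.
#' @export
blood_state <- function(sao2, methb_fraction = 0, svo2 = NULL, total_hb = 150) {
  if (is.null(svo2)) svo2 <- max(sao2 - 0.10, 0)
  vals <- c(sao2 = sao2, svo2 = svo2, methb_fraction = methb_fraction)
  if (any(vals < 0 | vals > 1))
    stop("sao2, svo2 and methb_fraction must lie in [0, 1]")
  structure(list(sao2 = sao2, svo2 = svo2,
                 methb_fraction = methb_fraction, total_hb = total_hb),
            class = "blood_state")
}

#' @export
print.blood_state <- function(x, ...) {
  cat(sprintf("<blood_state> SaO2 %.1f%%, SvO2 %.1f%%, MetHb %.1f%%, tHb %g g/L\n",
              100 * x$sao2, 100 * x$svo2, 100 * x$methb_fraction, x$total_hb))
  invisible(x)
}

#' Whole-blood absorption coefficient
#'
#' Sum of the arterial and venous blood absorption coefficients. Each term
#' weighs oxy- and deoxyhemoglobin by its saturation at the functional
#' hemoglobin concentration and adds the MetHb contribution at `cmet`.
#' By default the arterial and venous terms are added as printed; an
#' `arterial_fraction` f instead combines them as `f*A + (1-f)*V`.
#'
#' @inheritParams melanin_mua
#' @param blood A [blood_state()].
#' @param tables Chromophore tables from [chromophore_tables()].
#' @param arterial_fraction `NULL` for the plain sum (default), otherwise a
#'   fraction in \[0, 1\].
#' @return Absorption coefficient in cm^-1.
#' @export
blood_mua <- function(lambda_nm, blood, tables, arterial_fraction = NULL) {
  stopifnot(inherits(blood, "blood_state"))
  part <- methb_partition(blood$methb_fraction, blood$total_hb)
  mua_oxy <- hemoglobin_mua(ext_value(tables$oxy, lambda_nm), part$c_functional)
  mua_deoxy <- hemoglobin_mua(ext_value(tables$deoxy, lambda_nm), part$c_functional)
  mua_met <- hemoglobin_mua(ext_value(tables$met, lambda_nm), part$cmet)
  arterial <- blood$sao2 * mua_oxy + (1 - blood$sao2) * mua_deoxy + mua_met
  venous <- blood$svo2 * mua_oxy + (1 - blood$svo2) * mua_deoxy + mua_met
  if (is.null(arterial_fraction)) {
    arterial + venous
  } else {
    if (arterial_fraction < 0 || arterial_fraction > 1)
      stop("arterial_fraction must lie in [0, 1]")
    arterial_fraction * arterial + (1 - arterial_fraction) * venous
  }
}

#' Skin layer specification
#'
#' @param name One of `"stratum_corneum"`, `"epidermis"`, `"dermis"`,
#'   `"subcutaneous_fat"`; selects the layer's absorption mixture.
#' @param thickness_um Thickness in micrometers.
#' @param vfw,vfme,vfbl,vff Volume fractions of water, melanin, blood and fat.
#' @param n Refractive index (constant, or a function of wavelength in nm).
#' @param a_prime Reduced scattering at 500 nm, cm^-1.
#' @param f_ray Rayleigh fraction of the scattering power law.
#' @param b_mie Mie scattering power.
#' @param g Scattering anisotropy factor.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(name, thickness_um, vfw = 0, vfme = 0, vfbl = 0, vff = 0,
                       n = 1.4, a_prime = 43.6, f_ray = 0.41, b_mie = 0.562,
                       g = 0.86) {
  if (thickness_um <= 0) stop("thickness must be positive")
  vf <- c(vfw = vfw, vfme = vfme, vfbl = vfbl, vff = vff)
  if (any(vf < 0 | vf > 1) || sum(vf) > 1)
    stop("volume fractions must lie in [0, 1] and sum to at most 1")
  if (abs(g) >= 1) stop("anisotropy g must lie in (-1, 1)")
  structure(list(name = name, thickness_um = thickness_um,
                 vfw = vfw, vfme = vfme, vfbl = vfbl, vff = vff,
                 n = n, a_prime = a_prime, f_ray = f_ray, b_mie = b_mie, g = g),
            class = "layer_spec")
}

#' Four-layer skin tissue model
#'
#' Ordered layer stack, top to bottom, with the refractive indices of the
#' ambient media above (air) and below (scored as transmission).
#'
#' @param layers List of [layer_spec()] objects, top first.
#' @param n_above Refractive index above the tissue (air, 1.0).
#' @param n_below Refractive index below the bottom layer. The default
#'   matches the subcutaneous fat layer so photons reaching the bottom are
#'   scored as transmitted without an artificial index step.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(layers = default_skin_layers(), n_above = 1.0,
                         n_below = 1.44) {
  if (length(layers) < 1) stop("at least one layer is required")
  stopifnot(all(vapply(layers, inherits, logical(1), "layer_spec")))
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  structure(list(layers = layers, n_above = n_above, n_below = n_below),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> %d layers (top to bottom):\n", length(x$layers)))
  for (l in x$layers)
    cat(sprintf("  %-16s %6g um  vfw=%g vfme=%g vfbl=%g vff=%g n=%g\n",
                l$name, l$thickness_um, l$vfw, l$vfme, l$vfbl, l$vff,
                if (is.function(l$n)) NA else l$n))
  invisible(x)
}

#' Default skin layer stack
#'
#' Stratum corneum (20 um), epidermis (80 um), dermis (2000 um) and
#' subcutaneous fat (6000 um) with the standard volume fractions and
#' Rayleigh/Mie scattering parameters. The stratum corneum reuses the
#' epidermal scattering parameters (its own are not separately tabulated and
#' the layer is only 20 um thick).
#'
#' @return List of four [layer_spec()] objects.
#' @export
default_skin_layers <- function() {
  list(
    layer_spec("stratum_corneum", 20, vfw = 0.05,
               n = 1.55, a_prime = 66.7, f_ray = 0.29, b_mie = 0.689),
    layer_spec("epidermis", 80, vfw = 0.20, vfme = 0.025,
               n = 1.40, a_prime = 66.7, f_ray = 0.29, b_mie = 0.689),
    layer_spec("dermis", 2000, vfw = 0.65, vfbl = 0.002,
               n = 1.40, a_prime = 43.6, f_ray = 0.41, b_mie = 0.562),
    layer_spec("subcutaneous_fat", 6000, vfw = 0.15, vfbl = 0.07, vff = 0.60,
               n = 1.44, a_prime = 34.2, f_ray = 0.26, b_mie = 0.567)
  )
}

#' Default four-layer skin model
#' @return A [tissue_model()] with the default stack.
#' @export
default_skin_model <- function() tissue_model(default_skin_layers())

#' Layer absorption coefficient
#'
#' Volume-fraction-weighted chromophore mixture for one named skin layer:
#' stratum corneum (water + baseline), epidermis (water + melanin + baseline),
#' dermis (blood + water + bilirubin + beta-carotene + baseline) and
#' subcutaneous fat (blood + water + fat + baseline). The baseline is always
#' weighted by one minus the layer's named volume fractions.
#'
#' @inheritParams blood_mua
#' @param layer A [layer_spec()].
#' @return Absorption coefficient in cm^-1.
#' @export
layer_mua <- function(lambda_nm, layer, blood, tables,
                      arterial_fraction = NULL) {
  stopifnot(inherits(layer, "layer_spec"))
  base <- baseline_mua(lambda_nm)
  w <- function() layer$vfw * ext_value(tables$water, lambda_nm)
  switch(layer$name,
    stratum_corneum = w() + (1 - layer$vfw) * base,
    epidermis = w() + layer$vfme * melanin_mua(lambda_nm) +
      (1 - (layer$vfme + layer$vfw)) * base,
    dermis = layer$vfbl * blood_mua(lambda_nm, blood, tables, arterial_fraction) +
      w() +
      2.3 * BILIRUBIN_MOLARITY * ext_value(tables$bilirubin, lambda_nm) +
      ext_value(tables$betacarotene, lambda_nm) +
      (1 - (layer$vfbl + layer$vfw)) * base,
    subcutaneous_fat = layer$vfbl *
      blood_mua(lambda_nm, blood, tables, arterial_fraction) +
      w() + layer$vff * ext_value(tables$fat, lambda_nm) +
      (1 - (layer$vfbl + layer$vfw + layer$vff)) * base,
    stop(sprintf("unknown layer name '%s'", layer$name))
  )
}

#' Layer scattering coefficient
#'
#' 500-nm-normalized Rayleigh + Mie reduced scattering,
#' `mus' = a' * (f_ray * (lambda/500)^-4 + (1 - f_ray) * (lambda/500)^-b_mie)`,
#' converted to the scattering coefficient by the similarity relation
#' `mus = mus' / (1 - g)`.
#'
#' @inheritParams melanin_mua
#' @param layer A [layer_spec()].
#' @return List with `mus` (cm^-1) and `g`.
#' @export
layer_mus <- function(lambda_nm, layer) {
  stopifnot(inherits(layer, "layer_spec"))
  if (layer$g == 1) stop("anisotropy g = 1 leaves the scattering coefficient undefined")
  x <- lambda_nm / 500
  musp <- layer$a_prime * (layer$f_ray * x^-4 + (1 - layer$f_ray) * x^-layer$b_mie)
  list(mus = musp / (1 - layer$g), g = layer$g)
}

#' Assemble the optical stack at one wavelength
#'
#' Evaluates absorption, scattering, anisotropy, refractive index and
#' thickness (cm) for every layer of a tissue model at a single wavelength,
#' in the form consumed by the Monte Carlo engine.
#'
#' @inheritParams blood_mua
#' @param model A [tissue_model()].
#' @return An object of class `optical_stack`: list with vectors `mua`,
#'   `mus`, `g`, `n`, `thickness_cm` plus `n_above`, `n_below`, `lambda_nm`.
#' @export
build_optical_stack <- function(lambda_nm, model, blood, tables,
                                arterial_fraction = NULL) {
  stopifnot(inherits(model, "tissue_model"), length(lambda_nm) == 1)
  layers <- model$layers
  mua <- vapply(layers, function(l)
    layer_mua(lambda_nm, l, blood, tables, arterial_fraction), numeric(1))
  sc <- lapply(layers, function(l) layer_mus(lambda_nm, l))
  n <- vapply(layers, function(l)
    if (is.function(l$n)) l$n(lambda_nm) else l$n, numeric(1))
  structure(list(
    lambda_nm = lambda_nm,
    layer = names(layers),
    mua = mua,
    mus = vapply(sc, `[[`, numeric(1), "mus"),
    g = vapply(sc, `[[`, numeric(1), "g"),
    n = n,
    thickness_cm = vapply(layers, `[[`, numeric(1), "thickness_um") * 1e-4,
    n_above = model$n_above,
    n_below = model$n_below
  ), class = "optical_stack")
}

#' @export
print.optical_stack <- function(x, ...) {
  cat(sprintf("<optical_stack> at %g nm\n", x$lambda_nm))
  print(data.frame(layer = x$layer, mua = x$mua, mus = x$mus, g = x$g,
                   n = x$n, thickness_cm = x$thickness_cm,
                   row.names = NULL))
  invisible(x)
}
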