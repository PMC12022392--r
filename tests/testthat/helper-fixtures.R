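# shared fixtures: bundled tables and default geometry, loaded once
tabs <- chromophore_tables()
skin <- default_skin_model()
probe6 <- probe_geometry()

healthy <- blood_state(0.98, 0)

# direct linear interpolation into a bundled TSV, independent of the
# extinction_table query path
tsv_value <- function(file, lambda) {
  d <- utils::read.delim(system.file("extdata", file, package = "drsmethb"),
                         comment.char = "#")
  stats::approx(d$wavelength_nm, d$value, xout = lambda)$y
}

# Gaussian bump spectrum on a flat baseline
gauss_spectrum <- function(center = 560, sigma = 20, amp = 0.5, base = 0,
                           wl = seq(400, 1000, by = 2)) {
  drs_spectrum(wl, base + amp * exp(-(wl - center)^2 / (2 * sigma^2)))
}
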