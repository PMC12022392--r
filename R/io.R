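# Plain-text readers/writers for simulated spectra and feature tables.

#' Write a simulated spectrum to CSV
#'
#' Columns `wavelength_nm`, `total_reflectance`, `fiber_1..fiber_k`,
#' `specular`, `transmitted`, `absorbed`, `top_diffuse`, preceded by
#' `#`-comment metadata lines (`seed`, `n_photons`, `engine`, blood state).
#'
#' @param x A `spectrum_result` from [simulate_spectrum()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_result <- function(x, path) {
  stopifnot(inherits(x, "spectrum_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed=%g", x$seed),
               sprintf("# n_photons=%d", x$n_photons),
               sprintf("# engine=%s", x$engine),
               sprintf("# methb_fraction=%g", x$blood$methb_fraction),
               sprintf("# sao2=%g", x$blood$sao2)), con)
  d <- data.frame(wavelength_nm = x$wavelengths,
                  total_reflectance = x$total_reflectance)
  pf <- as.data.frame(x$per_fiber)
  names(pf) <- paste0("fiber_", seq_len(ncol(pf)))
  d <- cbind(d, pf,
             specular = x$specular, transmitted = x$transmitted,
             absorbed = x$absorbed, top_diffuse = x$top_diffuse)
  utils::write.table(d, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulated spectrum written by [write_spectrum_result()]
#'
#' @param path CSV file.
#' @return A `spectrum_result`.
#' @export
read_spectrum_result <- function(path) {
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  d <- utils::read.csv(path, comment.char = "#")
  fib <- as.matrix(d[grep("^fiber_", names(d))])
  blood <- blood_state(as.numeric(meta$sao2 %||% 0.98),
                       as.numeric(meta$methb_fraction %||% 0))
  structure(list(wavelengths = d$wavelength_nm,
                 total_reflectance = d$total_reflectance,
                 per_fiber = fib,
                 specular = d$specular, transmitted = d$transmitted,
                 absorbed = d$absorbed, top_diffuse = d$top_diffuse,
                 n_photons = as.integer(meta$n_photons %||% NA),
                 seed = as.numeric(meta$seed %||% NA),
                 engine = meta$engine %||% "unknown",
                 blood = blood),
            class = "spectrum_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature table to CSV
#'
#' The 12 feature columns in canonical order plus the label columns
#' `methb_fraction` and `sao2`.
#'
#' @param features Data frame from [featurize_manifest()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  need <- c(drs_feature_names, "methb_fraction", "sao2")
  missing <- setdiff(need, names(features))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  utils::write.csv(features[need], path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV file.
#' @return Data frame.
#' @export
read_feature_table <- function(path) utils::read.csv(path)

#' Read a structured experiment configuration
#'
#' YAML document with optional sections `tissue` (per-layer fields),
#' `blood_grid` (`methb_levels`, `sao2_levels`), `probe`, `simulation`,
#' `features` and `training`; missing sections fall back to the package
#' defaults.
#'
#' @param path YAML file.
#' @return List with `model`, `grid`, `probe`, `config`, `features`,
#'   `training`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  model <- if (!is.null(cfg$tissue)) {
    layers <- lapply(cfg$tissue$layers, function(l)
      do.call(layer_spec, l))
    tissue_model(layers,
                 n_above = cfg$tissue$n_above %||% 1.0,
                 n_below = cfg$tissue$n_below %||% 1.44)
  } else default_skin_model()
  grid <- experiment_grid(
    methb_levels = cfg$blood_grid$methb_levels %||% seq(0, 1, 0.1),
    sao2_levels = cfg$blood_grid$sao2_levels %||% c(.98, .97, .85, .70, .56, .43))
  probe <- do.call(probe_geometry, cfg$probe %||% list())
  sim <- cfg$simulation %||% list()
  if (!is.null(sim$wavelength_step_nm)) {
    sim$wavelengths <- seq(sim$wavelength_min_nm %||% 400,
                           sim$wavelength_max_nm %||% 1000,
                           by = sim$wavelength_step_nm)
    sim$wavelength_step_nm <- NULL
    sim$wavelength_min_nm <- NULL
    sim$wavelength_max_nm <- NULL
  }
  config <- do.call(sim_config, sim)
  list(model = model, grid = grid, probe = probe, config = config,
       features = cfg$features %||% list(window = 11, polyorder = 3),
       training = cfg$training %||% list())
}
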