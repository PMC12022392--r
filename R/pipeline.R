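# Experiment orchestration: the MetHb x SaO2 condition grid, batch spectrum
# generation, featurization, the four feature-set network variants and
# prediction on external spectra.

#' MetHb/SaO2 experiment grid
#'
#' Cartesian product of MetHb fractions and arterial saturation levels;
#' the defaults are 11 MetHb levels (0 to 1 by 0.1) times 6 saturation
#' levels (0.98, 0.97, 0.85, 0.70, 0.56, 0.43), 66 conditions.
#'
#' @param methb_levels MetHb fractions of total hemoglobin.
#' @param sao2_levels Arterial saturation fractions.
#' @return Data frame with columns `methb_fraction` and `sao2`, one row per
#'   grid cell.
#' @export
experiment_grid <- function(methb_levels = seq(0, 1, by = 0.1),
                            sao2_levels = c(0.98, 0.97, 0.85, 0.70, 0.56, 0.43)) {
  g <- expand.grid(methb_fraction = methb_levels, sao2 = sao2_levels,
                   KEEP.OUT.ATTRS = FALSE)
  g[] <- lapply(g, as.numeric)
  g
}

#' Generate the simulated spectrum dataset
#'
#' Runs the Monte Carlo simulation for every grid condition over the
#' configured wavelength grid and writes one spectrum CSV per condition
#' plus a `manifest.csv`. With the default `"shared"` engine, one
#' scattering-only trajectory set per wavelength is reweighted analytically
#' for every blood condition (the conditions share scattering exactly, so
#' this is an exact-expectation variance-reduction; see the package
#' vignette). The `"direct"` engine runs an independent classic
#' hop-drop-spin simulation per condition with substreams derived from
#' `(seed, cell index)`.
#'
#' @param grid An [experiment_grid()].
#' @param model A [tissue_model()].
#' @param probe A [probe_geometry()].
#' @param config A [sim_config()]; its `seed` is the master seed.
#' @param tables Chromophore tables.
#' @param out_dir Output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @param engine `"shared"` or `"direct"` (see above).
#' @return Invisibly, a list with `manifest` (data frame: file,
#'   methb_fraction, sao2, seed, n_photons, engine) and `spectra`
#'   (list of `spectrum_result`).
#' @export
generate_dataset <- function(grid, model = default_skin_model(),
                             probe = probe_geometry(),
                             config = sim_config(),
                             tables = chromophore_tables(),
                             out_dir = NULL,
                             engine = c("shared", "direct")) {
  engine <- match.arg(engine)
  nc <- nrow(grid)
  wl <- config$wavelengths
  nl <- length(wl)
  nf <- nrow(probe$detector_centers_cm)
  bloods <- lapply(seq_len(nc), function(i)
    blood_state(grid$sao2[i], grid$methb_fraction[i]))

  if (engine == "shared") {
    per_fiber <- array(0, c(nc, nl, nf))
    specular <- matrix(0, nc, nl)
    transmitted <- matrix(0, nc, nl)
    absorbed <- matrix(0, nc, nl)
    top_diffuse <- matrix(0, nc, nl)
    for (i in seq_len(nl)) {
      stacks <- lapply(bloods, function(b)
        build_optical_stack(wl[i], model, b, tables))
      s0 <- stacks[[1]]
      mua_mat <- t(vapply(stacks, `[[`, numeric(length(s0$mua)), "mua"))
      res <- mc_run_white_cpp(
        s0$mus, s0$g, s0$n, s0$thickness_cm, s0$n_above, s0$n_below,
        probe$source_radius_cm, probe$detector_centers_cm,
        probe$detector_radius_cm, probe$cos_accept,
        config$n_photons, config$seed, i - 1, mua_mat, config$max_steps)
      per_fiber[, i, ] <- res$fiber
      specular[, i] <- res$specular
      transmitted[, i] <- res$transmitted
      absorbed[, i] <- res$absorbed
      top_diffuse[, i] <- res$top_diffuse
    }
    spectra <- lapply(seq_len(nc), function(c) {
      pf <- matrix(per_fiber[c, , ], nl, nf)
      structure(list(wavelengths = wl, total_reflectance = rowSums(pf),
                     per_fiber = pf, specular = specular[c, ],
                     transmitted = transmitted[c, ], absorbed = absorbed[c, ],
                     top_diffuse = top_diffuse[c, ],
                     n_photons = config$n_photons, seed = config$seed,
                     engine = "shared", blood = bloods[[c]]),
                class = "spectrum_result")
    })
  } else {
    spectra <- lapply(seq_len(nc), function(c) {
      cfg <- config
      # one substream block per grid cell so cells are independent
      cfg$seed <- config$seed + 1000003 * c
      simulate_spectrum(model, bloods[[c]], probe, cfg, tables,
                        engine = "direct")
    })
  }

  files <- rep(NA_character_, nc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(out_dir, sprintf("spectrum_%03d.csv", seq_len(nc)))
    for (c in seq_len(nc)) write_spectrum_result(spectra[[c]], files[c])
  }
  manifest <- data.frame(file = files,
                         methb_fraction = grid$methb_fraction,
                         sao2 = grid$sao2,
                         seed = config$seed,
                         n_photons = config$n_photons,
                         engine = engine)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  invisible(list(manifest = manifest, spectra = spectra))
}

#' Extract features for every spectrum of a dataset
#'
#' @param dataset Result of [generate_dataset()], or a manifest data frame
#'   whose `file` column points at spectrum CSVs.
#' @param window,polyorder Savitzky-Golay parameters.
#' @return Data frame with the 12 feature columns plus `methb_fraction`
#'   and `sao2`.
#' @export
featurize_manifest <- function(dataset, window = 11, polyorder = 3) {
  if (is.data.frame(dataset)) {
    missing <- dataset$file[!file.exists(dataset$file)]
    if (length(missing))
      stop("manifest refers to missing spectra: ",
           paste(missing, collapse = ", "))
    spectra <- lapply(dataset$file, read_spectrum_result)
    manifest <- dataset
  } else {
    spectra <- dataset$spectra
    manifest <- dataset$manifest
  }
  feats <- t(vapply(spectra, function(s)
    assemble_features(as_drs_spectrum(s), window, polyorder), numeric(12)))
  out <- as.data.frame(feats)
  names(out) <- drs_feature_names
  out$methb_fraction <- manifest$methb_fraction
  out$sao2 <- manifest$sao2
  out
}

#' Train and evaluate one feature-set network variant
#'
#' Subsets the feature table per the chosen variant (`all` = 12 features,
#' `peaks` = 5, `power_kte` = 7, `cfs` = correlation-selected 6, chosen on
#' the training split only), trains the network on a seeded 80/20 split and
#' evaluates the five criteria on the held-out test samples.
#'
#' @param features Feature table from [featurize_manifest()] (or a dataset /
#'   manifest, which is featurized first).
#' @param feature_set One of `"all"`, `"peaks"`, `"power_kte"`, `"cfs"`.
#' @param train_fraction Training fraction (default 0.8).
#' @param split_seed,init_seed Seeds for the split and the weight
#'   initialization.
#' @param hidden,decay,maxit Network hyperparameters (see [drs_ann()]).
#' @param cfs_k Number of features kept by the `cfs` variant.
#' @param window,polyorder Savitzky-Golay parameters used when `features`
#'   is a dataset/manifest still to be featurized (recorded in the report
#'   so [predict_external()] can replay the preprocessing).
#' @return List of class `experiment_report`: `feature_set`, `columns`,
#'   `model`, `split`, `metrics` (test-set `drs_metrics`), `fits`
#'   (per-output [regression_fit()]), `predicted`, `actual`.
#' @export
run_experiment <- function(features, feature_set = c("all", "peaks",
                                                     "power_kte", "cfs"),
                           train_fraction = 0.8, split_seed = 1,
                           init_seed = 1, hidden = 10, decay = 1e-3,
                           maxit = 2000, cfs_k = 6, window = 11,
                           polyorder = 3) {
  feature_set <- match.arg(feature_set)
  wavelengths <- NULL
  if (!is.data.frame(features) || !"methb_fraction" %in% names(features)) {
    if (is.list(features) && !is.null(features$spectra))
      wavelengths <- features$spectra[[1]]$wavelengths
    features <- featurize_manifest(features, window, polyorder)
  }
  x_all <- as.matrix(features[drs_feature_names])
  y <- as.matrix(features[c("methb_fraction", "sao2")])
  sp <- split_data(nrow(x_all), train_fraction, split_seed)
  cols <- if (feature_set == "cfs") {
    sort(cfs_select(x_all[sp$train, ], y[sp$train, ], k = cfs_k))
  } else feature_subset(feature_set)
  x <- x_all[, cols, drop = FALSE]
  model <- drs_ann(x[sp$train, , drop = FALSE], y[sp$train, , drop = FALSE],
                   hidden = hidden, decay = decay, maxit = maxit,
                   init_seed = init_seed)
  pred <- predict(model, x[sp$test, , drop = FALSE])
  metrics <- evaluate_predictions(y[sp$test, , drop = FALSE], pred)
  fits <- lapply(seq_len(ncol(y)), function(j)
    regression_fit(y[sp$test, j], pred[, j]))
  names(fits) <- colnames(y)
  structure(list(feature_set = feature_set, columns = cols,
                 model = model, split = sp, metrics = metrics, fits = fits,
                 predicted = pred, actual = y[sp$test, , drop = FALSE]),
            class = "experiment_report",
            meta = list(wavelengths = wavelengths, window = window,
                        polyorder = polyorder))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> feature set '%s' (%d inputs), %d/%d split\n",
              x$feature_set, length(x$columns),
              length(x$split$train), length(x$split$test)))
  print(x$metrics)
  invisible(x)
}

#' Collect reports into the criteria grid
#'
#' @param reports Named list of `experiment_report`s (one per feature set).
#' @return Nested list feature set -> output -> criterion, suitable for
#'   [jsonlite::write_json()].
#' @export
report_grid <- function(reports) {
  lapply(reports, function(r) {
    m <- r$metrics
    out <- lapply(seq_len(nrow(m)), function(i)
      list(mae = m$mae[i], mape = m$mape[i], mse = m$mse[i],
           rmse = m$rmse[i], r2 = m$r2[i]))
    names(out) <- m$output
    out
  })
}

#' Predict blood parameters from an external measured spectrum
#'
#' Resamples a two-column reflectance spectrum onto the model's training
#' wavelength grid (linear interpolation), smooths, featurizes and
#' predicts. The input must cover the training band entirely.
#'
#' @param report An `experiment_report` (its model and preprocessing are
#'   reused), or a `drs_ann` with attributes `wavelengths`, `window`,
#'   `polyorder`, `columns`.
#' @param spectrum Data frame with columns `wavelength_nm` and
#'   `reflectance`, or the path of such a CSV.
#' @return List with `methb_percent`, `sao2_percent`, `clipped` (logical),
#'   and the raw `fraction` predictions.
#' @export
predict_external <- function(report, spectrum) {
  if (inherits(report, "experiment_report")) {
    model <- report$model
    cols <- report$columns
    meta <- attr(report, "meta") %||%
      list(wavelengths = NULL, window = 11, polyorder = 3)
  } else stop("report must be an experiment_report")
  if (is.character(spectrum)) spectrum <- utils::read.csv(spectrum)
  wl_col <- grep("wavelength", names(spectrum))[1]
  if (is.na(wl_col)) stop("spectrum needs a wavelength_nm column")
  wl_in <- spectrum[[wl_col]]
  refl_in <- spectrum$reflectance %||% spectrum[[2]]
  grid <- meta$wavelengths
  if (is.null(grid))
    stop("the report carries no training wavelength grid")
  if (min(wl_in) > min(grid) || max(wl_in) < max(grid))
    stop(sprintf("spectrum covers %g-%g nm but the model needs %g-%g nm",
                 min(wl_in), max(wl_in), min(grid), max(grid)))
  refl <- stats::approx(wl_in, refl_in, xout = grid)$y
  fv <- assemble_features(drs_spectrum(grid, pmax(refl, 0)),
                          meta$window, meta$polyorder)
  pred <- predict(model, matrix(fv[cols], nrow = 1))
  list(methb_percent = 100 * pred[1, 1], sao2_percent = 100 * pred[1, 2],
       clipped = any(attr(pred, "clipped")),
       fraction = pred[1, ])
}

#' Synthetic fixtures for validation
#'
#' Deterministic toy inputs with known ground truth: `toy_spectra` are
#' Gaussian bumps on flat baselines (known center, width, amplitude);
#' `analytic_media` are one-layer stacks with simple limits (matched-index
#' non-scattering absorber, matched-index scatterer); `linear_ml` is a
#' synthetic feature/target table generated by a known linear map.
#'
#' @param kind One of `"toy_spectra"`, `"analytic_media"`, `"linear_ml"`.
#' @param seed RNG seed for the stochastic parts.
#' @param out_dir Optional directory; fixtures with a natural file form are
#'   also written there as CSV.
#' @return A list describing the fixture (elements depend on `kind`).
#' @export
make_fixtures <- function(kind = c("toy_spectra", "analytic_media", "linear_ml"),
                          seed = 1, out_dir = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
    toy_spectra = {
      wl <- seq(400, 1000, by = 2)
      mk <- function(center, sigma, amp, base)
        list(center = center, sigma = sigma, amplitude = amp, baseline = base,
             spectrum = drs_spectrum(wl, base + amp * exp(-(wl - center)^2 /
                                                            (2 * sigma^2))))
      list(bump560 = mk(560, 20, 0.5, 0.05),
           bump650 = mk(650, 35, 0.3, 0.02),
           flat = list(center = NA, sigma = NA, amplitude = 0, baseline = 0.1,
                       spectrum = drs_spectrum(wl, rep(0.1, length(wl)))))
    },
    analytic_media = {
      mk_stack <- function(mua, mus, g, n, thick_cm, n_amb)
        structure(list(lambda_nm = NA_real_, layer = "slab",
                       mua = mua, mus = mus, g = g, n = n,
                       thickness_cm = thick_cm,
                       n_above = n_amb, n_below = n_amb),
                  class = "optical_stack")
      list(absorber_matched = mk_stack(10, 0, 0, 1.4, 1, 1.4),
           scatterer_matched = mk_stack(0.1, 100, 0.86, 1.4, 1, 1.4),
           scatterer_mismatched = mk_stack(0.1, 100, 0.86, 1.4, 1, 1.0))
    },
    linear_ml = {
      .with_seed(seed, {
        n <- 500; p <- 6
        x <- matrix(stats::rnorm(n * p), n, p)
        w <- matrix(stats::runif(p * 2, -0.05, 0.05), p, 2)
        y <- 0.5 + x %*% w
        y <- pmin(pmax(y, 0), 1)
        colnames(y) <- c("methb_fraction", "sao2")
        list(x = x, y = y, w = w)
      })
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (kind == "toy_spectra") {
      for (nm in names(out)) {
        s <- out[[nm]]$spectrum
        utils::write.csv(data.frame(wavelength_nm = s$wavelength_nm,
                                    reflectance = s$reflectance),
                         file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    if (kind == "linear_ml") {
      utils::write.csv(cbind(as.data.frame(out$x), out$y),
                       file.path(out_dir, "linear_ml.csv"), row.names = FALSE)
    }
  }
  out
}
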