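#' Random Karger model generator
#'
#' Draws a valid N-compartment Karger model for testing: water fractions
#' from a flat simplex draw with a floor of 0.05 per compartment,
#' diffusivities log-uniform on \[0.2, 3\] um^2/ms, and exchange built
#' from symmetric non-negative conductances (`R[m,n] = c[m,n] / f[n]`),
#' so detailed balance holds exactly by construction. Conductances are
#' drawn log-uniform so the implied rates span the tens-per-second range
#' typical of brain tissue, and a fraction of pairs may be disconnected.
#'
#' @param n_compartments Number of compartments, at least 2.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   model.
#' @param connect_prob Probability that a compartment pair exchanges
#'   directly (default 1: fully connected).
#' @return A [karger_model()].
#' @export
random_km <- function(n_compartments, seed = NULL, connect_prob = 1) {
  if (n_compartments < 2L) stop("need at least 2 compartments",
                                call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- n_compartments
  floor_f <- 0.05
  raw <- stats::rexp(n)                      # flat simplex via normalized Exp
  f <- floor_f + (1 - n * floor_f) * raw / sum(raw)
  d <- exp(stats::runif(n, log(0.2), log(3)))
  cmat <- matrix(0, n, n)
  up <- upper.tri(cmat)
  nc <- sum(up)
  con <- stats::runif(nc) < connect_prob
  cval <- exp(stats::runif(nc, log(5e-4), log(0.02)))  # fraction/ms
  cmat[up] <- ifelse(con, cval, 0)
  karger_model_from_conductances(f, d, cmat)
}

#' Simulate noisy ROI MD/MK time series from a model
#'
#' Forward-simulates the summary statistics a diffusional-kurtosis-imaging
#' ROI analysis would produce under a Karger model: `MK(t)` is the exact
#' model kurtosis plus additive Gaussian noise, and `MD(t)` is the
#' (time-independent) total diffusivity plus additive Gaussian noise,
#' independently per animal and time point. Noise acts on the ROI summary
#' values, not on the dMRI signal.
#'
#' @param model A [karger_model()] or [neurite_system()].
#' @param times Diffusion times in ms; default the four-point design
#'   `c(18, 22, 26, 30)`.
#' @param noise_sd_mk,noise_sd_md Additive Gaussian SDs for MK and MD
#'   (default 0: exact values).
#' @param n_animals Number of replicate animals (default 3).
#' @param region,group Labels attached to every row.
#' @param seed Optional master seed; per-animal noise streams are drawn
#'   sequentially from it, so a given seed fixes the whole collection.
#' @return A data frame of class `"roi_timeseries"`.
#' @export
simulate_roi_series <- function(model, times = c(18, 22, 26, 30),
                                noise_sd_mk = 0, noise_sd_md = 0,
                                n_animals = 3L, region = "ROI",
                                group = "sim", seed = NULL) {
  if (noise_sd_mk < 0 || noise_sd_md < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  if (any(times <= 0)) stop("diffusion times must be positive",
                            call. = FALSE)
  if (inherits(model, "neurite_system")) {
    kt <- neurite_closed_form(model, times)$kurtosis
    dbar <- model$fex * model$Dex +
      (model$fin / model$Nc) * sum(model$neurite_diffusivities)
  } else if (inherits(model, "karger_model")) {
    modes <- spectral_modes(build_generator(model), model$fractions,
                            model$diffusivities)
    kt <- kurtosis_time_course(modes, times)
    dbar <- modes$total_diffusivity
  } else {
    stop("'model' must be a karger_model or neurite_system", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nt <- length(times)
  rows <- lapply(seq_len(n_animals), function(a) {
    data.frame(region = region, group = group,
               animal = sprintf("a%02d", a), delta_ms = times,
               md = dbar + stats::rnorm(nt, 0, noise_sd_md),
               mk = kt + stats::rnorm(nt, 0, noise_sd_mk),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roi_timeseries", "data.frame")
  out
}
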