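#' Construct a multi-compartment Karger model
#'
#' A Karger model (KM) describes water hopping between `N` well-mixed
#' compartments, each with its own effective diffusivity, while diffusion
#' within a compartment is otherwise free. The model is specified by the
#' water fractions `f_m`, the compartmental diffusivities `D_m`, and the
#' exchange-rate matrix `R`, whose off-diagonal entry `R[m, n]` is the
#' transition rate from compartment `n` to compartment `m`.
#'
#' Water conservation requires each column of `R` to sum to zero; the
#' diagonal is therefore filled in automatically when the supplied matrix
#' has a zero diagonal, and validated otherwise. Detailed balance,
#' `R[m, n] * f[n] == R[n, m] * f[m]`, is required for the symmetrized
#' exchange generator to be symmetric and is enforced at construction
#' (relative tolerance `1e-9`); violations are errors, not warnings.
#'
#' @param fractions Numeric vector of water fractions; must be positive and
#'   sum to 1.
#' @param diffusivities Numeric vector of compartmental diffusivities in
#'   um^2/ms; non-negative, same length as `fractions`.
#' @param exchange_rates Square numeric matrix of transition rates in 1/ms.
#'   Off-diagonal entries must be non-negative. A zero diagonal is filled
#'   in so that columns sum to zero.
#' @param rate_unit Unit of the exchange rates, `"1/ms"` (default) or
#'   `"1/s"`. Rates in 1/s are converted to the internal 1/ms convention,
#'   matching diffusion times in ms.
#'
#' @return An object of class `"karger_model"`: a list with elements
#'   `n_compartments`, `fractions`, `diffusivities`, `exchange_rates`
#'   (always in 1/ms).
#'
#' @seealso [karger_model_from_conductances()] for a parameterization that
#'   guarantees detailed balance, [build_generator()], [spectral_modes()].
#' @examples
#' m <- karger_model(
#'   fractions = c(0.5, 0.5),
#'   diffusivities = c(1, 3),
#'   exchange_rates = matrix(c(0, 0.02, 0.02, 0), 2, 2)
#' )
#' mean_exchange_rate(spectral_modes(build_generator(m),
#'                                   m$fractions, m$diffusivities))
#' @export
karger_model <- function(fractions, diffusivities, exchange_rates,
                         rate_unit = c("1/ms", "1/s")) {
  rate_unit <- match.arg(rate_unit)
  fractions <- as.numeric(fractions)
  diffusivities <- as.numeric(diffusivities)
  n <- length(fractions)
  if (n < 2L)
    stop("a Karger model needs at least 2 compartments", call. = FALSE)
  if (length(diffusivities) != n)
    stop("'diffusivities' must have the same length as 'fractions'",
         call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions <= 0))
    stop("all water fractions must be positive", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("water fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  if (any(!is.finite(diffusivities)) || any(diffusivities < 0))
    stop("diffusivities must be finite and non-negative", call. = FALSE)

  R <- as.matrix(exchange_rates)
  if (!is.numeric(R) || nrow(R) != n || ncol(R) != n)
    stop("'exchange_rates' must be a numeric ", n, "x", n, " matrix",
         call. = FALSE)
  if (rate_unit == "1/s") R <- R / 1000
  off <- R; diag(off) <- 0
  if (any(off < 0))
    stop("off-diagonal exchange rates must be non-negative", call. = FALSE)
  if (all(diag(R) == 0)) {
    diag(R) <- -colSums(off)
  } else if (max(abs(colSums(R))) > 1e-9 * max(abs(R), 1e-300)) {
    stop("columns of the exchange-rate matrix must sum to 0 ",
         "(water conservation)", call. = FALSE)
  }

  # detailed balance: R_mn f_n = R_nm f_m
  flux <- off * rep(fractions, each = n)  # flux[m, n] = R_mn * f_n
  imbalance <- abs(flux - t(flux))
  scale <- pmax(flux, t(flux))
  bad <- imbalance > 1e-9 * pmax(scale, max(scale)) & scale > 0
  if (any(bad))
    stop("exchange rates violate detailed balance ",
         "(R[m,n]*f[n] != R[n,m]*f[m]); the exchange generator would not ",
         "be symmetric", call. = FALSE)

  structure(
    list(n_compartments = n, fractions = fractions,
         diffusivities = diffusivities, exchange_rates = R),
    class = "karger_model")
}

#' Construct a Karger model from symmetric conductances
#'
#' Parameterizes exchange through a symmetric non-negative conductance
#' matrix `c` with `R[m, n] = c[m, n] / f[n]`, which satisfies detailed
#' balance by construction (`R[m,n] f[n] = c[m,n] = R[n,m] f[m]`).
#'
#' @inheritParams karger_model
#' @param conductances Symmetric non-negative matrix (diagonal ignored), in
#'   units of fraction/ms. Only the upper triangle is read.
#' @return A `"karger_model"` object.
#' @export
karger_model_from_conductances <- function(fractions, diffusivities,
                                           conductances) {
  n <- length(fractions)
  cmat <- as.matrix(conductances)
  if (nrow(cmat) != n || ncol(cmat) != n)
    stop("'conductances' must be a ", n, "x", n, " matrix", call. = FALSE)
  cmat[lower.tri(cmat, diag = TRUE)] <- 0
  cmat <- cmat + t(cmat)
  if (any(cmat < 0))
    stop("conductances must be non-negative", call. = FALSE)
  R <- cmat / rep(fractions, each = n)  # R[m, n] = c[m, n] / f[n]
  diag(R) <- 0
  karger_model(fractions, diffusivities, R)
}

#' @export
print.karger_model <- function(x, ...) {
  cat("Karger model with", x$n_compartments, "compartments\n")
  cat("  fractions:    ", paste(signif(x$fractions, 4), collapse = ", "),
      "\n")
  cat("  diffusivities:", paste(signif(x$diffusivities, 4), collapse = ", "),
      "um^2/ms\n")
  k <- x$exchange_rates; diag(k) <- 0
  cat("  max exchange rate:", signif(max(k), 4), "1/ms\n")
  invisible(x)
}

#' Read a Karger model specification from a JSON file
#'
#' The file must contain `fractions` and `diffusivities` arrays and either
#' a full `exchange_rates` matrix (1/ms) or a symmetric `conductances`
#' matrix (fraction/ms, upper triangle used). Unknown keys are rejected so
#' that typos do not silently produce a no-exchange model.
#'
#' @param path Path to a JSON file.
#' @return A `"karger_model"` object.
#' @export
read_km_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("fractions", "diffusivities", "exchange_rates",
               "conductances", "rate_unit")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    stop("unknown keys in KM config: ", paste(extra, collapse = ", "),
         call. = FALSE)
  need <- c("fractions", "diffusivities")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("KM config missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_r <- "exchange_rates" %in% names(cfg)
  has_c <- "conductances" %in% names(cfg)
  if (has_r == has_c)
    stop("KM config needs exactly one of 'exchange_rates' or 'conductances'",
         call. = FALSE)
  if (has_r) {
    karger_model(cfg$fractions, cfg$diffusivities,
                 as.matrix(cfg$exchange_rates),
                 rate_unit = if (is.null(cfg$rate_unit)) "1/ms"
                             else cfg$rate_unit)
  } else {
    karger_model_from_conductances(cfg$fractions, cfg$diffusivities,
                                   as.matrix(cfg$conductances))
  }
}
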