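#' Symmetrized exchange generator of a Karger model
#'
#' Returns the similarity transform `G = S^{-1} R S` with
#' `S = diag(sqrt(f))`. Under detailed balance `G` is symmetric and
#' negative semi-definite, and annihilates the equilibrium vector
#' `eta = sqrt(f)`: `G %*% sqrt(f) = 0`.
#'
#' @param model A [karger_model()].
#' @return A symmetric N x N matrix (1/ms).
#' @export
build_generator <- function(model) {
  stopifnot(inherits(model, "karger_model"))
  s <- sqrt(model$fractions)
  G <- model$exchange_rates * ((1 / s) %o% s)  # G[m,n] = R[m,n] sqrt(f_n/f_m)
  asym <- max(abs(G - t(G)))
  if (asym > 1e-9 * max(abs(G), 1e-300))
    stop("exchange generator is not symmetric: detailed balance violated",
         call. = FALSE)
  (G + t(G)) / 2
}

#' Spectral exchange statistics of a Karger model generator
#'
#' Diagonalizes the symmetric generator `G` and assembles the quantities
#' that govern the kurtosis time course: eigenvalues `lambda_n` sorted
#' non-increasing (`lambda_1 = 0`, eigenvector `eta = sqrt(f)`), exchange
#' times `tau_n = -1/lambda_n`, the partial kurtoses
#' `kappa_n = (3/Dbar^2) (eta' diag(D) nu_n)^2`, the zero-time kurtosis
#' `K0 = sum_{n>=2} kappa_n`, and the (time-independent) total diffusivity
#' `Dbar = sum f_n D_n`.
#'
#' Eigenvalues within `1e-12 * max|lambda|` of zero are clamped to exactly
#' zero (`tau = Inf`). When the null space has dimension greater than one
#' (fully disconnected compartments), its basis is rotated so that the
#' first eigenvector is exactly `eta`; this keeps the sum rule
#' `sum_{n>=2} kappa_n = K0` intact, since `kappa_1` is the equilibrium
#' mode and carries no kurtosis information.
#'
#' @param G Symmetric negative semi-definite matrix from
#'   [build_generator()].
#' @param fractions,diffusivities The model's water fractions and
#'   diffusivities.
#' @return An object of class `"spectral_modes"`: list with `eigenvalues`,
#'   `eigenvectors` (columns), `exchange_times`, `partial_kurtoses`,
#'   `total_initial_kurtosis`, `total_diffusivity`.
#' @export
spectral_modes <- function(G, fractions, diffusivities) {
  n <- length(fractions)
  stopifnot(is.matrix(G), nrow(G) == n, length(diffusivities) == n)
  eta <- sqrt(fractions)
  es <- eigen(G, symmetric = TRUE)  # eigenvalues in decreasing order
  lam <- es$values
  vec <- es$vectors
  scale <- max(abs(lam), 1e-300)
  if (lam[1] > 1e-10 * scale)
    stop("generator has a positive eigenvalue (", format(lam[1]),
         "): not a valid Karger model generator", call. = FALSE)
  lam[abs(lam) < 1e-12 * scale] <- 0
  lam[lam > 0] <- 0

  nzero <- sum(lam == 0)
  if (nzero == 0L)
    stop("generator has no zero eigenvalue; it should annihilate sqrt(f)",
         call. = FALSE)
  if (nzero == 1L) {
    # align sign (and guard against rounding) by replacing with exact eta
    vec[, 1] <- eta
  } else {
    # rotate the null-space block so its first basis vector is exactly eta
    idx <- seq_len(nzero)
    basis <- qr.Q(qr(cbind(eta, vec[, idx, drop = FALSE])))[, idx,
                                                            drop = FALSE]
    basis[, 1] <- basis[, 1] * sign(sum(basis[, 1] * eta))
    vec[, idx] <- basis
  }

  dbar <- sum(fractions * diffusivities)
  if (dbar <= 0)
    stop("total diffusivity is zero; partial kurtoses are undefined",
         call. = FALSE)
  overlaps <- as.numeric(crossprod(eta * diffusivities, vec))  # eta' D nu_n
  kappa <- 3 * overlaps^2 / dbar^2
  tau <- ifelse(lam == 0, Inf, -1 / lam)

  structure(
    list(eigenvalues = lam, eigenvectors = vec, exchange_times = tau,
         partial_kurtoses = kappa,
         total_initial_kurtosis = sum(kappa[-1L]),
         total_diffusivity = dbar),
    class = "spectral_modes")
}

#' @export
print.spectral_modes <- function(x, ...) {
  n <- length(x$eigenvalues)
  cat("Karger model spectral modes (", n, " compartments)\n", sep = "")
  cat("  K0 =", signif(x$total_initial_kurtosis, 6),
      "  Dbar =", signif(x$total_diffusivity, 6), "um^2/ms\n")
  cat("  eigenvalues (1/ms):",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Zero-time diffusional kurtosis of a compartment mixture
#'
#' `K0 = 3 Var_f(D) / Dbar^2`: three times the squared coefficient of
#' variation of the compartmental diffusivities under the water-fraction
#' weights, a measure of diffusional heterogeneity.
#'
#' @inheritParams spectral_modes
#' @return Non-negative scalar.
#' @export
initial_kurtosis <- function(fractions, diffusivities) {
  stopifnot(length(fractions) == length(diffusivities))
  dbar <- sum(fractions * diffusivities)
  if (dbar <= 0)
    stop("all compartmental diffusivities are zero; K0 is undefined",
         call. = FALSE)
  3 * sum(fractions * (diffusivities - dbar)^2) / dbar^2
}

#' Mean Karger-model water exchange rate
#'
#' The kurtosis-weighted average of the inverse modal exchange times,
#' `R_KM = sum_{n>=2} (kappa_n / K0) / tau_n`. Modes with infinite
#' exchange time (zero eigenvalue) contribute nothing.
#'
#' @param modes A [spectral_modes()] object.
#' @return Exchange rate in 1/ms (multiply by 1000 for 1/s).
#' @export
mean_exchange_rate <- function(modes) {
  stopifnot(inherits(modes, "spectral_modes"))
  k0 <- modes$total_initial_kurtosis
  if (k0 <= 1e-12)  # numerically homogeneous: kurtosis is pure round-off
    stop("K0 = 0: a diffusionally homogeneous system has no kurtosis ",
         "decay, so the mean exchange rate is undefined", call. = FALSE)
  kap <- modes$partial_kurtoses[-1L]
  tau <- modes$exchange_times[-1L]
  rate <- ifelse(is.finite(tau), kap / tau, 0)
  sum(rate) / k0
}
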