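#' Thin cylindrical neurite system
#'
#' A Karger model consisting of one extra-neurite compartment (fraction
#' `fex`, diffusivity `Dex`) exchanging with `Nc` identical thin
#' cylindrical neurites. The m-th neurite, oriented at angle `theta_m` to
#' the diffusion direction, has effective diffusivity `Din cos^2 theta_m`;
#' neurite fractions are equal, `fin / Nc` with `fin = 1 - fex`. Direct
#' exchange is only between each neurite and the extra-neurite space, with
#' per-neurite exit rate `Rin`.
#'
#' Either `angles` (radians) or explicit per-neurite `diffusivities` may
#' be supplied; no orientation averaging is performed — the model applies
#' per effective diffusion direction, and equally to direction-averaged
#' kurtosis.
#'
#' @param fex Extra-neurite water fraction, strictly inside (0, 1).
#' @param Dex Extra-neurite diffusivity (um^2/ms).
#' @param Din Intrinsic neurite diffusivity (um^2/ms); required with
#'   `angles`.
#' @param angles Neurite orientation angles in radians (length `Nc`).
#' @param diffusivities Alternative to `angles`: per-neurite effective
#'   diffusivities directly.
#' @param Rin Exit rate from an individual neurite (1/ms).
#' @return An object of class `"neurite_system"`.
#' @export
neurite_system <- function(fex, Dex, Din = NULL, angles = NULL,
                           diffusivities = NULL, Rin) {
  if (!is.numeric(fex) || length(fex) != 1L || fex <= 0 || fex >= 1)
    stop("'fex' must lie strictly between 0 and 1; the boundary values ",
         "give a degenerate (single-compartment) model", call. = FALSE)
  if (Dex < 0) stop("'Dex' must be non-negative", call. = FALSE)
  if (Rin < 0) stop("'Rin' must be non-negative", call. = FALSE)
  if (is.null(diffusivities)) {
    if (is.null(angles) || is.null(Din))
      stop("supply either 'diffusivities' or both 'angles' and 'Din'",
           call. = FALSE)
    diffusivities <- Din * cos(angles)^2
  } else if (!is.null(angles)) {
    stop("supply 'angles' or 'diffusivities', not both", call. = FALSE)
  }
  if (length(diffusivities) < 1L || any(diffusivities < 0))
    stop("need at least one neurite with non-negative diffusivity",
         call. = FALSE)
  structure(
    list(fex = fex, fin = 1 - fex, Dex = Dex,
         neurite_diffusivities = as.numeric(diffusivities),
         Rin = Rin, Nc = length(diffusivities), angles = angles),
    class = "neurite_system")
}

#' @export
print.neurite_system <- function(x, ...) {
  cat("Thin cylindrical neurite system:", x$Nc, "neurites\n")
  cat("  fex =", x$fex, " Dex =", x$Dex, " Rin =", x$Rin, "1/ms\n")
  cat("  neurite diffusivities:",
      paste(signif(x$neurite_diffusivities, 4), collapse = ", "),
      "um^2/ms\n")
  invisible(x)
}

#' Exchange generator of a neurite system
#'
#' The `(Nc + 1) x (Nc + 1)` symmetric generator: the extra-neurite
#' compartment (index 1) couples to every neurite with off-diagonal
#' element `Rin * sqrt(fin / (Nc * fex))`; each neurite has diagonal
#' `-Rin` and the extra-neurite diagonal is `-fin * Rin / fex`. Its
#' spectrum is `0`, `Nc - 1` copies of `-Rin`, and `-Rin / fex`.
#'
#' @param system A [neurite_system()].
#' @return Symmetric matrix (1/ms).
#' @export
neurite_generator <- function(system) {
  stopifnot(inherits(system, "neurite_system"))
  nc <- system$Nc
  g <- matrix(0, nc + 1L, nc + 1L)
  off <- system$Rin * sqrt(system$fin / (nc * system$fex))
  g[1L, -1L] <- off
  g[-1L, 1L] <- off
  diag(g) <- c(-system$fin * system$Rin / system$fex, rep(-system$Rin, nc))
  g
}

#' Represent a neurite system as a general Karger model
#'
#' @param system A [neurite_system()].
#' @return A [karger_model()] with compartment 1 the extra-neurite space.
#' @export
as_karger_model <- function(system) {
  stopifnot(inherits(system, "neurite_system"))
  nc <- system$Nc
  fr <- c(system$fex, rep(system$fin / nc, nc))
  dv <- c(system$Dex, system$neurite_diffusivities)
  R <- matrix(0, nc + 1L, nc + 1L)
  R[1L, -1L] <- system$Rin                          # neurite -> ex
  R[-1L, 1L] <- system$Rin * system$fin / (nc * system$fex)  # ex -> neurite
  karger_model(fr, dv, R)
}

#' Closed-form kurtosis time course of a neurite system
#'
#' Because the generator has only two non-trivial distinct eigenvalues,
#' the kurtosis collapses to two decay terms:
#' `K(t) = (K0 - kappaN) Upsilon(Rin t) + kappaN Upsilon(Rin t / fex)`,
#' with `K0` the heterogeneity kurtosis of the full mixture and `kappaN`
#' the partial kurtosis of the slowest mode,
#' `kappaN = 3 fex fin (Dex - mean(Dn))^2 / Dbar^2`.
#'
#' @param system A [neurite_system()].
#' @param times Non-negative diffusion times (ms).
#' @return List with `kurtosis` (vector `K(t)`), `K0`, `kappaN`.
#' @export
neurite_closed_form <- function(system, times) {
  stopifnot(inherits(system, "neurite_system"))
  times <- as.numeric(times)
  if (any(times < 0))
    stop("diffusion times must be non-negative", call. = FALSE)
  dn <- system$neurite_diffusivities
  dbar <- system$fex * system$Dex + (system$fin / system$Nc) * sum(dn)
  if (dbar <= 0)
    stop("total diffusivity is zero; kurtosis undefined", call. = FALSE)
  k0 <- 3 * system$fex * (system$Dex / dbar - 1)^2 +
    3 * (system$fin / system$Nc) * sum((dn / dbar - 1)^2)
  kapn <- 3 * system$fex * system$fin / dbar^2 *
    (system$Dex - mean(dn))^2
  kt <- (k0 - kapn) * upsilon(system$Rin * times) +
    kapn * upsilon(system$Rin * times / system$fex)
  list(kurtosis = kt, K0 = k0, kappaN = kapn)
}

#' Mean exchange rate of a neurite system, closed form
#'
#' `R_KM = Rin * (1 + fin * kappaN / (fex * K0))`, which always lies
#' between `Rin` and `Rin / fex`.
#'
#' @param system A [neurite_system()].
#' @return Rate in 1/ms.
#' @export
neurite_rkm <- function(system) {
  cf <- neurite_closed_form(system, 0)
  if (cf$K0 <= 0)
    stop("K0 = 0: homogeneous system, mean exchange rate undefined",
         call. = FALSE)
  system$Rin * (1 + system$fin * cf$kappaN / (system$fex * cf$K0))
}

# dimensionless observable x(u) = R_KM* t* as a function of u = Rin t*,
# for given fex and kappa_ratio = kappaN / K0 (scale-free form of the
# closed-form kurtosis)
neurite_x_of_u <- function(u, fex, kappa_ratio) {
  num <- (1 - kappa_ratio) * upsilon_prime(u) +
    (kappa_ratio / fex) * upsilon_prime(u / fex)
  den <- (1 - kappa_ratio) * upsilon(u) + kappa_ratio * upsilon(u / fex)
  -3 * u * num / den
}

#' Solve for the dimensionless exchange rate at a target bound product
#'
#' Inverts the monotone map `u -> x(u)`, where `u = Rin t^*` and
#' `x = R_KM^* t^*` is the pointwise log-derivative bound of the
#' closed-form neurite kurtosis, by bracketed root finding (tolerance
#' 1e-10). Only the dimensionless shape parameters matter: the
#' extra-neurite fraction and the kurtosis ratio `kappaN / K0`.
#'
#' @param x_target Target `R_KM^* t^*`, in (0, 3).
#' @param fex Extra-neurite fraction in (0, 1).
#' @param kappa_ratio `kappaN / K0` in \[0, 1\].
#' @return Scalar `u = Rin t^*`.
#' @export
solve_dimensionless_rate <- function(x_target, fex, kappa_ratio) {
  if (x_target <= 0 || x_target >= 3)
    stop("'x_target' must lie in (0, 3)", call. = FALSE)
  if (kappa_ratio < 0 || kappa_ratio > 1)
    stop("'kappa_ratio' must lie in [0, 1]", call. = FALSE)
  lo <- 1e-12
  hi <- 1
  while (neurite_x_of_u(hi, fex, kappa_ratio) < x_target) {
    hi <- hi * 2
    if (hi > 1e10)
      stop("x_target = ", format(x_target), " is not attainable for ",
           "fex = ", fex, ", kappa_ratio = ", kappa_ratio, call. = FALSE)
  }
  stats::uniroot(function(u) neurite_x_of_u(u, fex, kappa_ratio) - x_target,
                 lower = lo, upper = hi, tol = 1e-10, maxiter = 200L)$root
}

#' Bound accuracies for the neurite model at one parameter point
#'
#' For a given observable `x = R_KM^* t^*`, extra-neurite fraction, and
#' kurtosis ratio, solves the dimensionless rate and returns the accuracy
#' of the plain bound, `R_KM^*/R_KM = x / (u (1 + kappa_ratio fin/fex))`,
#' and of the enhanced bound, `V(x)` times that.
#'
#' @inheritParams solve_dimensionless_rate
#' @param x Observable `R_KM^* t^*` in (0, 3).
#' @return Named numeric vector `c(acc_star, acc_hat)`, both in (0, 1].
#' @export
accuracy_at <- function(x, fex, kappa_ratio) {
  u <- solve_dimensionless_rate(x, fex, kappa_ratio)
  rkm_t <- u * (1 + kappa_ratio * (1 - fex) / fex)
  acc_star <- x / rkm_t
  c(acc_star = acc_star, acc_hat = v_exact(x) * acc_star)
}

#' Bound-accuracy grid for the thin neurite model
#'
#' Evaluates [accuracy_at()] over a grid of `x = R_KM^* t^*`,
#' extra-neurite fractions, and kurtosis ratios. Values of `x` above 2
#' are admissible but flagged: there the enhancement factor grows rapidly
#' and experimental errors are strongly amplified.
#'
#' @param x_values Grid of `R_KM^* t^*` values in (0, 3).
#' @param fex_values Extra-neurite fractions; default the survey grid
#'   `c(0.2, 0.4, 0.6, 0.8)`.
#' @param kappa_values Kurtosis ratios; default `seq(0, 1, by = 0.2)`.
#' @return A data frame of class `"accuracy_grid"` with columns `x`,
#'   `fex`, `kappa_ratio`, `acc_star`, `acc_hat`.
#' @export
accuracy_grid <- function(x_values,
                          fex_values = c(0.2, 0.4, 0.6, 0.8),
                          kappa_values = seq(0, 1, by = 0.2)) {
  if (any(x_values > 2))
    warning("x > 2: enhancement factor grows quickly; ",
            "low-precision territory", call. = FALSE)
  grid <- expand.grid(kappa_ratio = kappa_values, fex = fex_values,
                      x = x_values, KEEP.OUT.ATTRS = FALSE)
  acc <- t(mapply(accuracy_at, grid$x, grid$fex, grid$kappa_ratio))
  out <- data.frame(x = grid$x, fex = grid$fex,
                    kappa_ratio = grid$kappa_ratio,
                    acc_star = acc[, "acc_star"], acc_hat = acc[, "acc_hat"])
  class(out) <- c("accuracy_grid", "data.frame")
  out
}

#' @export
print.accuracy_grid <- function(x, ...) {
  cat("Neurite-model bound accuracy grid:", nrow(x), "cells\n")
  cat("  min R_KM*/R_KM =", signif(min(x$acc_star), 4),
      "  min R^_KM/R_KM =", signif(min(x$acc_hat), 4), "\n")
  NextMethod()
}

#' @export
plot.accuracy_grid <- function(x, which = c("acc_star", "acc_hat"), ...) {
  which <- match.arg(which)
  fexes <- sort(unique(x$fex))
  op <- graphics::par(mfrow = c(ceiling(length(fexes) / 2),
                                min(2L, length(fexes))))
  on.exit(graphics::par(op))
  for (fe in fexes) {
    sub <- x[x$fex == fe, ]
    kap <- sort(unique(sub$kappa_ratio))
    graphics::plot(NULL, xlim = range(sub$x), ylim = c(0, 1),
                   xlab = "R_KM* t*", ylab = which,
                   main = paste0("fex = ", fe))
    for (i in seq_along(kap)) {
      s2 <- sub[sub$kappa_ratio == kap[i], ]
      graphics::lines(s2$x[order(s2$x)], s2[[which]][order(s2$x)],
                      col = i)
    }
  }
  invisible(x)
}
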