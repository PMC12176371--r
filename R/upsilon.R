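#' Kurtosis decay kernel
#'
#' The universal decay shape of each kurtosis mode,
#' `Upsilon(x) = 2 * integral_0^1 (1-s) exp(-s x) ds
#'             = (2/x) * (1 - (1 - exp(-x))/x)`,
#' evaluated in closed form for `x >= 0.05` and by its Taylor series
#' `sum_{k>=0} 2 (-x)^k / (k+2)!` below that threshold, where the closed
#' form loses precision to cancellation. `Upsilon` decreases strictly from
#' `Upsilon(0) = 1` and behaves as `2/x` for large `x`.
#'
#' @param x Non-negative numeric vector (dimensionless time ratio
#'   `t / tau`).
#' @return Values in `(0, 1]`.
#' @export
upsilon <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0, na.rm = TRUE))
    stop("upsilon() is defined for x >= 0 only", call. = FALSE)
  out <- x
  small <- x < 0.05
  if (any(small)) {
    xs <- x[small]
    # 2 (-x)^k / (k+2)!, k = 0..6; truncation error < 1e-17 at x = 0.05
    out[small] <- 1 - xs / 3 + xs^2 / 12 - xs^3 / 60 + xs^4 / 360 -
      xs^5 / 2520 + xs^6 / 20160
  }
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- (2 / xl) * (1 - (1 - exp(-xl)) / xl)
  }
  out
}

#' Derivative of the kurtosis decay kernel
#'
#' `d Upsilon / dx`, with the same series-switch threshold as [upsilon()].
#' Always negative for `x >= 0`; `Upsilon'(0) = -1/3`.
#'
#' @inheritParams upsilon
#' @return Negative numeric vector.
#' @export
upsilon_prime <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0, na.rm = TRUE))
    stop("upsilon_prime() is defined for x >= 0 only", call. = FALSE)
  out <- x
  small <- x < 0.05
  if (any(small)) {
    xs <- x[small]
    out[small] <- -1 / 3 + xs / 6 - xs^2 / 20 + xs^3 / 90 - xs^4 / 504 +
      xs^5 / 3360
  }
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- -2 / xl^2 - 2 * exp(-xl) / xl^2 +
      4 * (1 - exp(-xl)) / xl^3
  }
  out
}

#' Exact kurtosis time course of a Karger model
#'
#' `K(t) = sum_{n>=2} kappa_n * Upsilon(t / tau_n)`. Modes with infinite
#' exchange time contribute a constant `kappa_n`. `K(0) = K0`, `K(t)` is
#' monotonically decreasing, and `log K(t)` is convex.
#'
#' @param modes A [spectral_modes()] object.
#' @param times Non-negative diffusion times, in ms (same time unit as the
#'   generator's rates are inverse to).
#' @return Numeric vector `K(t)` of the same length as `times`.
#' @export
kurtosis_time_course <- function(modes, times) {
  stopifnot(inherits(modes, "spectral_modes"))
  times <- as.numeric(times)
  if (any(times < 0))
    stop("diffusion times must be non-negative", call. = FALSE)
  kap <- modes$partial_kurtoses[-1L]
  tau <- modes$exchange_times[-1L]
  vapply(times, function(t) {
    ratio <- ifelse(is.finite(tau), t / tau, 0)
    sum(kap * upsilon(ratio))
  }, numeric(1))
}

#' Pointwise log-derivative bound at a single time
#'
#' Evaluates `-3 d ln K / dt` at `t_star` analytically from the spectral
#' modes. On exact model kurtosis this is the plain lower bound on the
#' mean exchange rate at that diffusion time; it converges to the mean
#' exchange rate as `t_star -> 0`.
#'
#' @param modes A [spectral_modes()] object.
#' @param t_star Diffusion time in ms (scalar, > 0 allowed to be small).
#' @return Rate in 1/ms.
#' @export
rkm_star_at <- function(modes, t_star) {
  stopifnot(inherits(modes, "spectral_modes"), length(t_star) == 1L,
            t_star >= 0)
  kap <- modes$partial_kurtoses[-1L]
  tau <- modes$exchange_times[-1L]
  ratio <- ifelse(is.finite(tau), t_star / tau, 0)
  num <- sum(ifelse(is.finite(tau), kap * upsilon_prime(ratio) / tau, 0))
  den <- sum(kap * upsilon(ratio))
  if (den <= 0)
    stop("kurtosis is zero at t_star; log-derivative undefined",
         call. = FALSE)
  -3 * num / den
}
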