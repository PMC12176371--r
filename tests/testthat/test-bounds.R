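# -- small power-series helpers used as an independent oracle -------------

poly_mul <- function(a, b, n) {
  out <- numeric(n)
  for (i in seq_len(min(length(a), n))) {
    j <- seq_len(min(length(b), n - i + 1))
    out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
  }
  out
}

poly_inv <- function(c0, n) {
  # reciprocal of a series with c0[1] != 0
  inv <- numeric(n)
  inv[1] <- 1 / c0[1]
  for (k in 2:n)
    inv[k] <- -sum(c0[2:k] * inv[(k - 1):1]) / c0[1]
  inv
}

beta_series_coeffs <- function(n) {
  # Taylor coefficients of beta(y)/y about 0, from the closed form's
  # numerator y^3 * A(y) and denominator y^2 * C(y)
  a <- vapply(0:(n + 2), function(j) {
    jj <- j + 3
    (jj == 1) + (-1)^(jj - 1) / factorial(jj - 1) + 2 * (-1)^jj /
      factorial(jj)
  }, numeric(1))
  c0 <- vapply(0:(n + 2), function(j) {
    jj <- j + 2
    (-1)^jj / factorial(jj)
  }, numeric(1))
  3 * poly_mul(a, poly_inv(c0, n), n)  # beta(y) = y * this series
}

# product of two series with no constant term, both indexed by power 1..n
poly_mul_nc <- function(a, b, n) {
  out <- numeric(n)
  for (i in seq_len(n - 1)) {
    j <- seq_len(n - i)
    out[i + j] <- out[i + j] + a[i] * b[j]
  }
  out
}

series_revert <- function(b, n) {
  # given x = sum b_k y^k with b_1 = 1, return r with y = sum r_k x^k
  r <- numeric(n)
  r[1] <- 1
  for (k in 2:n) {
    # impose that the coefficient of x^k in b(r(x)) vanishes
    ypow <- r
    term <- ypow
    acc <- b[1] * term
    for (m in 2:k) {
      term <- poly_mul_nc(term, ypow, n)
      acc <- acc + b[m] * term
    }
    r[k] <- -acc[k]
  }
  r
}

test_that("beta has the stated shape: series, monotonicity, saturation at 3", {
  b <- beta_series_coeffs(8)
  expect_equal(b[1], 1, tolerance = 1e-12)
  expect_equal(b[2], -1 / 6, tolerance = 1e-12)
  # implementation agrees with the oracle series near 0
  for (y in c(1e-4, 0.01, 0.049)) {
    expect_equal(km_beta(y), sum(b[1:8] * y^(1:8)) * 1, tolerance = 1e-12)
  }
  # both branches agree where they meet: series value at the threshold
  # versus the closed form evaluated directly
  closed <- function(y) 3 * (y - 2 + (y + 2) * exp(-y)) /
    (y - 1 + exp(-y))
  expect_equal(km_beta(0.049), closed(0.049), tolerance = 1e-11)
  ys <- seq(0.05, 40, by = 0.05)
  expect_true(all(diff(km_beta(ys)) > 0))
  expect_lt(km_beta(1e3), 3)
  expect_equal(km_beta(1e3), 3, tolerance = 1e-2)
  # identity with the kurtosis kernel: beta(y) = -3 y Upsilon'(y)/Upsilon(y)
  for (y in c(0.3, 1, 2.5, 7))
    expect_equal(km_beta(y), -3 * y * upsilon_prime(y) / upsilon(y),
                 tolerance = 1e-12)
  expect_error(km_beta(-1), "y >= 0")
})

test_that("V(x) inverts beta to high precision over the physical range", {
  expect_equal(v_exact(0), 1)
  xs <- c(0.01, seq(0.05, 2.99, by = 0.07))
  err <- abs(km_beta(xs * v_exact(xs)) - xs)
  expect_lt(max(err), 1e-9)
  expect_true(all(diff(v_exact(xs)) > 0))
  expect_gt(v_exact(2.999), 50)  # divergence approaching the singularity
  expect_error(v_exact(3), "singular")
  expect_error(v_exact(-0.2), "x >= 0")
})

test_that("printed improvement percentages reproduce at one decimal", {
  expect_equal(round(improvement_percent(0.5), 1), 9.6)
  expect_equal(round(improvement_percent(1.0), 1), 23.0)
  expect_equal(round(improvement_percent(1.5), 1), 43.3)
  expect_equal(round(improvement_percent(2.0), 1), 79.7)
  expect_equal(improvement_percent(0), 0)
})

test_that("series coefficients match independent reversion of beta", {
  b <- beta_series_coeffs(7)
  r <- series_revert(b, 7)  # y = beta^{-1}(x) = sum r_k x^k; V_k = r_{k+1}
  frozen <- c(1, 1 / 6, 2 / 45, 7 / 540, 113 / 28350, 43 / 34020,
              149 / 364500)
  expect_equal(r, frozen, tolerance = 1e-12)
  # and v_series evaluates that polynomial
  for (x in c(0.1, 0.7, 1.9))
    expect_equal(v_series(x), sum(frozen * x^(0:6)), tolerance = 1e-14)
})

test_that("sixth-order series stays within 3% of exact V below x = 2", {
  xs <- seq(0.001, 1.999, by = 0.001)
  rel <- abs(v_series(xs) - v_exact(xs)) / v_exact(xs)
  expect_lte(max(rel), 0.03)
})

test_that("semi-log slope estimator recovers exponential decay exactly", {
  r <- 0.04  # 1/ms
  tt <- c(18, 22, 26, 30)
  kk <- 0.9 * exp(-r * tt / 3)
  est <- estimate_rkm_star(tt, kk)
  expect_equal(est$rkm_star, r, tolerance = 1e-12)
  expect_equal(est$t_star, 24)
  expect_equal(est$slope_se, 0, tolerance = 1e-10)
  # constant kurtosis: zero bound
  expect_equal(estimate_rkm_star(tt, rep(0.8, 4))$rkm_star, 0,
               tolerance = 1e-14)
  expect_error(estimate_rkm_star(c(20, 20), c(0.9, 0.8)), "distinct")
  expect_error(estimate_rkm_star(tt, c(0.9, -0.1, 0.5, 0.4)), "positive")
})

test_that("regression bound never exceeds the true rate on exact kurtosis", {
  tt <- c(18, 22, 26, 30)
  for (seed in 1:100) {
    m <- random_km(2 + seed %% 7, seed = seed)
    md <- modes_of(m)
    kt <- kurtosis_time_course(md, tt)
    if (md$total_initial_kurtosis <= 0 || any(kt <= 0)) next
    est <- estimate_rkm_star(tt, kt)
    expect_lte(est$rkm_star, mean_exchange_rate(md) * (1 + 1e-9))
  }
})

test_that("enhanced bound reproduces the in vivo report chain", {
  dh <- enhanced_bound(38.3 / 1000, 24)  # s^-1 -> 1/ms, t* in ms
  expect_equal(round(dh$enhancement, 2), 1.20)
  expect_equal(round(dh$rkm_hat * 1000, 1), 46.1)
  cx <- enhanced_bound(18.9 / 1000, 24)
  expect_equal(round(cx$enhancement, 2), 1.09)
  expect_equal(round(cx$rkm_hat * 1000, 1), 20.5)
  z <- enhanced_bound(0, 24)
  expect_equal(z$enhancement, 1)
  expect_equal(z$rkm_hat, 0)
  expect_error(enhanced_bound(0.2, 24), ">= 3")
})

test_that("bound chain holds pointwise for seeded random models", {
  t_star <- 24
  for (seed in 1:100) {
    m <- random_km(2 + seed %% 7, seed = seed + 500)
    md <- modes_of(m)
    if (md$total_initial_kurtosis <= 0) next
    rkm <- mean_exchange_rate(md)
    rs <- rkm_star_at(md, t_star)
    x <- rs * t_star
    if (x >= 3) next
    rh <- v_exact(x) * rs
    expect_lte(rs, rh + 1e-12)
    expect_lte(rh, rkm * (1 + 1e-9))
  }
})

test_that("the enhanced bound is exact for two-compartment models", {
  for (seed in 1:20) {
    set.seed(seed)
    f1 <- runif(1, 0.1, 0.9)
    cmat <- matrix(0, 2, 2); cmat[1, 2] <- runif(1, 1e-4, 0.01)
    m <- karger_model_from_conductances(
      c(f1, 1 - f1), sort(runif(2, 0.3, 3)), cmat)
    md <- modes_of(m)
    rkm <- mean_exchange_rate(md)
    for (ts in c(5, 24, 60)) {
      rs <- rkm_star_at(md, ts)
      x <- rs * ts
      if (x >= 3) next
      expect_equal(v_exact(x) * rs, rkm, tolerance = 1e-8)
    }
  }
})

test_that("shorter evaluation times give tighter enhanced bounds", {
  m <- random_km(5, seed = 77)
  md <- modes_of(m)
  ts <- c(2, 8, 24, 60, 150)
  rh <- vapply(ts, function(t) {
    rs <- rkm_star_at(md, t)
    v_exact(min(rs * t, 2.999)) * rs
  }, numeric(1))
  expect_true(all(diff(rh) <= 1e-12))
})

test_that("diffusion elasticity recovers power laws and constants", {
  tt <- c(18, 22, 26, 30)
  el <- diffusion_elasticity(tt, 1.1 * tt^-0.04)
  expect_equal(el$xi, -0.04, tolerance = 1e-12)
  expect_equal(diffusion_elasticity(tt, rep(0.9, 4))$xi, 0,
               tolerance = 1e-14)
  expect_error(diffusion_elasticity(tt, c(1, 1, -1, 1)), "positive")
})
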