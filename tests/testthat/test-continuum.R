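test_that("drift and diffusion match their closed forms and the discrete rates", {
  p <- competition_params(100, w = 1)
  expect_equal(drift(p, 0.5), 0)
  expect_equal(diffusion(p, 0.5), 100 / 4)
  expect_equal(drift(p, 0.75), 100 * (2 * 0.75 - 1) / 2)
  expect_equal(drift(competition_params(100, w = 4), 1 / 3), 0,
               tolerance = 1e-12)

  # continuum limit of the tabulated rates: error shrinks like 1/N
  gap <- vapply(c(100, 200), function(N) {
    pp <- competition_params(N, w = 2.5)
    ch <- spatial_rates(pp)
    n <- 1:(N - 1)
    max(abs((ch$up_rate - ch$down_rate)[n + 1] - drift(pp, n / N))) / N
  }, numeric(1))
  expect_lt(gap[2], gap[1])
  expect_lt(gap[1], 2 / 100)
})

test_that("the equiprobable abundance is the positive root of the drift", {
  for (w in c(1, 1.5, 10, 100)) {
    feq <- equiprobable_abundance(w)
    expect_lt(abs((w - 1) * feq^2 + 2 * feq - 1), 1e-12)
  }
  expect_equal(equiprobable_abundance(1), 0.5)
  expect_equal(equiprobable_abundance(4), 1 / 3)
  w <- c(1, 2, 10, 100, 1e6)
  expect_true(all(diff(equiprobable_abundance(w)) < 0))
  expect_lt(equiprobable_abundance(1e8), 1e-3)
})

test_that("closed-form potential agrees with numerical quadrature of A/B", {
  for (w in c(1, 1.5, 10)) {
    p <- competition_params(50, w = w)
    feq <- equiprobable_abundance(w)
    for (f in c(0.05, 0.3, 0.62, 0.95)) {
      u_num <- -2 * p$N * stats::integrate(
        function(y) drift(p, y) / diffusion(p, y),
        feq, f, rel.tol = 1e-12)$value
      expect_equal(fp_potential(p, f), u_num, tolerance = 1e-8)
    }
  }
})

test_that("the neutral potential has its known closed form and curvature", {
  N <- 100
  p <- competition_params(N, w = 1)
  f <- seq(0.01, 0.99, by = 0.07)
  expect_equal(fp_potential(p, f), -N * log(2 * (2 * f^2 - 2 * f + 1)),
               tolerance = 1e-10)
  expect_equal(fp_potential(p, 0.5) - fp_potential(p, 0), N * log(2),
               tolerance = 1e-10)
  h <- 1e-4
  curv <- (fp_potential(p, 0.5 + h) - 2 * fp_potential(p, 0.5) +
             fp_potential(p, 0.5 - h)) / h^2
  expect_equal(curv, -8 * N, tolerance = 1e-4)
})

test_that("the potential is unimodal with its peak at f_eq", {
  f <- seq(0.001, 0.999, length.out = 501)
  for (w in c(1, 1.5, 10, 100)) for (N in c(20, 100)) {
    p <- competition_params(N, w = w)
    U <- fp_potential(p, f)
    feq <- equiprobable_abundance(w)
    expect_true(all(U <= 1e-9))
    expect_true(all(diff(U[f < feq]) > 0))   # rising below the peak
    expect_true(all(diff(U[f > feq]) < 0))   # falling above it
  }
})

test_that("tau_det is the exact deterministic fixation time", {
  p <- competition_params(100, w = 1)
  expect_equal(tau_det(p, 0.75), log(2))
  expect_error(tau_det(p, 0.5), "diverges")
  for (w in c(1, 4, 100)) {
    pw <- competition_params(100, w = w)
    expect_equal(tau_det(pw, c(0, 1)), c(0, 0), tolerance = 1e-12)
    # solves -1 = A(f)/N tau' (derivative taken by central difference)
    feq <- equiprobable_abundance(w)
    f <- seq(0.02, 0.98, by = 0.02)
    f <- f[abs(f - feq) > 0.015]
    h <- 1e-7
    dtau <- (tau_det(pw, f + h) - tau_det(pw, f - h)) / (2 * h)
    expect_equal(drift(pw, f) / pw$N * dtau, rep(-1, length(f)),
                 tolerance = 1e-5)
  }
  # basal rate only rescales time
  expect_equal(tau_det(competition_params(10, w = 1, r = 2), 0.75),
               log(2) / 2)
})

test_that("the stochastic region shrinks as N^(-1/2) around f_eq", {
  p100 <- competition_params(100, w = 1)
  ft <- stochastic_region(p100)
  delta <- sqrt(1 / (8 * pi * 100))
  expect_equal(unname(ft), c(0.5 - delta, 0.5 + delta), tolerance = 1e-3)

  ft400 <- stochastic_region(competition_params(400, w = 1))
  ratio <- diff(unname(ft)) / diff(unname(ft400))
  expect_lt(abs(ratio - 2), 0.3)  # width halves when N quadruples

  for (w in c(1, 1.5, 10, 100)) {
    ftw <- stochastic_region(competition_params(100, w = w))
    feq <- equiprobable_abundance(w)
    expect_lt(ftw[1], feq)
    expect_gt(ftw[2], feq)
  }
})

test_that("continuum fixation probability matches exact solutions", {
  # Moran neutral: flat potential, linear solution
  p <- competition_params(50, w = 1)
  g <- seq(0, 1, length.out = 21)
  expect_equal(fp_fixation_probability(p, g, model = "moran"), g,
               tolerance = 1e-10)
  # spatial neutral: symmetric sigmoid through (1/2, 1/2)
  expect_equal(fp_fixation_probability(p, 0.5), 0.5, tolerance = 1e-6)

  # converges to the discrete solution as N grows
  gap <- vapply(c(100, 1000), function(N) {
    pp <- competition_params(N, w = 1)
    max(abs(fp_fixation_probability(pp, (0:N) / N) -
              fixation_probability(spatial_rates(pp))))
  }, numeric(1))
  expect_lt(gap[1], 0.02)
  expect_lt(gap[2], gap[1])
})

test_that("continuum MFPT collapses across N away from the balance point", {
  p <- competition_params(100, w = 1)
  expect_equal(fp_mfpt(p, c(0, 1)), c(0, 0))

  g <- seq(0, 1, length.out = 201)
  curves <- sapply(c(10, 100, 1000), function(N)
    fp_mfpt(competition_params(N, w = 1), g))
  away <- abs(g - 0.5) > 0.1 & g > 0.02 & g < 0.98
  rel <- apply(curves[away, 2:3], 1, function(v) diff(range(v)) / max(v))
  expect_lt(max(rel), 0.05)
  # the smallest channel still sits on the same curve to within the
  # O(1/N) corrections expected at N = 10
  rel10 <- apply(curves[away, ], 1, function(v) diff(range(v)) / max(v))
  expect_lt(max(rel10), 0.2)

  # agreement with the exact discrete MFPT at moderate N
  N <- 100
  tau_d <- mfpt_unconditional(spatial_rates(competition_params(N, w = 1)))
  tau_c <- fp_mfpt(competition_params(N, w = 1), (0:N) / N)
  interior <- 10:(N - 10)
  expect_lt(max(abs(tau_c[interior] - tau_d[interior]) / tau_d[interior]),
            0.05)
})

test_that("continuum and discrete solutions converge together in N", {
  gaps <- t(vapply(c(50, 200, 800), function(N) {
    pp <- competition_params(N, w = 2)
    f <- (0:N) / N
    pgap <- max(abs(fp_fixation_probability(pp, f) -
                      fixation_probability(spatial_rates(pp))))
    tau_d <- mfpt_unconditional(spatial_rates(pp))
    tau_c <- fp_mfpt(pp, f)
    mid <- round(N * 0.3):round(N * 0.7)
    tgap <- max(abs(tau_c[mid] - tau_d[mid]) / tau_d[mid])
    c(pgap, tgap)
  }, numeric(2)))
  expect_true(all(diff(gaps[, 1]) < 0))
  expect_true(all(diff(gaps[, 2]) < 0))
})

test_that("the diffusive residual is ~0.4 and independent of N and w", {
  est <- estimate_tau_dif(competition_params(100, w = 1),
                          N_list = c(500, 1000, 2000))
  expect_lt(abs(est$tau_dif - 0.4), 0.15)
  expect_lt(diff(range(est$residuals)), 0.1)

  est10 <- estimate_tau_dif(competition_params(100, w = 10),
                            N_list = c(500, 1000, 2000))
  expect_lt(abs(est10$tau_dif - est$tau_dif), 0.15)
  expect_error(estimate_tau_dif(competition_params(100), N_list = c(100, 200)),
               "at least 3")
})

test_that("the asymptotic decomposition approximates the maximal MFPT", {
  for (w in c(1, 10)) {
    p <- competition_params(1000, w = w)
    dec <- tau_max_approx(p, tau_dif = 0.42)
    exact <- max(mfpt_unconditional(spatial_rates(p)))
    expect_lt(abs(dec$tau_a - exact) / exact, 0.1)
    expect_equal(dec$tau_a, dec$tau_det_at_boundary + dec$tau_dif)
    expect_lt(dec$f_t_minus, dec$f_eq)
    expect_gt(dec$f_t_plus, dec$f_eq)
  }
  # mirror symmetry of the neutral escape: both exits cost the same
  p <- competition_params(500, w = 1)
  ft <- stochastic_region(p)
  expect_equal(tau_det(p, ft[[1]]), tau_det(p, ft[[2]]), tolerance = 1e-9)

  # tau_a grows with slope 1/2 in log N
  Ns <- c(200, 400, 800, 1600, 3200, 6400)
  ta <- vapply(Ns, function(N)
    tau_max_approx(competition_params(N, w = 1), tau_dif = 0.42)$tau_a,
    numeric(1))
  slope <- unname(stats::coef(stats::lm(ta ~ log(Ns)))[2])
  expect_gt(slope, 0.4)
  expect_lt(slope, 0.6)
})

test_that("maximal spatial MFPT is sublinear in N", {
  Ns <- c(100, 200, 400, 800, 1600, 3200)
  mx <- vapply(Ns, function(N)
    max(mfpt_unconditional(spatial_rates(competition_params(N, w = 1)))),
    numeric(1))
  expect_lt(power_exponent(Ns, mx), 0.3)
})
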