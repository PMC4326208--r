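test_that("micro-constant derivation matches ratio identities and an eigen oracle", {
  # ratio identity: CL = V_c makes K10 exactly 1/h; Q = 0 decouples
  m <- derive_micro(pk_params(CL = 2.5, V_c = 2.5, Q = 0, V_p = 5))
  expect_identical(m$K10, 1)
  expect_identical(m$K12, 0)
  expect_identical(m$K21, 0)

  # K12 = 0 collapses the discriminant to |K10 - K21|
  m <- micro_constants(K10 = 1, K12 = 0, K21 = 0.5)
  expect_equal(m$alpha, 1)
  expect_equal(m$beta, 0.5)

  # reference parameter set vs generic eigen-solver on the disposition
  # matrix [[-(K10+K12), K21], [K12, -K21]]
  m <- derive_micro(ref_params())
  A <- matrix(c(-(m$K10 + m$K12), m$K12, m$K21, -m$K21), 2, 2)
  lam <- sort(-eigen(A)$values)
  expect_equal(m$beta, lam[1], tolerance = 1e-12)
  expect_equal(m$alpha, lam[2], tolerance = 1e-12)

  # inverse mapping recovers the clearances
  p <- ref_params()
  expect_equal(m$K10 * p$V_c, p$CL, tolerance = 1e-12)
  expect_equal(m$K21 * p$V_p, p$Q, tolerance = 1e-12)

  expect_error(pk_params(CL = -1, V_c = 3, Q = 0.1, V_p = 8), "CL")
  expect_error(pk_params(CL = 1, V_c = 0, Q = 0.1, V_p = 8), "V_c")
})

test_that("hybrid-rate identities hold across random parameter sets", {
  set.seed(101)
  for (i in 1:50) {
    p <- random_params()
    m <- derive_micro(p)
    s <- m$K10 + m$K12 + m$K21
    expect_lt(abs(m$alpha + m$beta - s) / s, 1e-10)
    expect_lt(abs(m$alpha * m$beta - m$K10 * m$K21) /
                max(m$K10 * m$K21, 1e-300), 1e-10)
    expect_true(m$alpha >= m$beta && m$beta > 0)
  }
})

test_that("single-dose solution honors initial conditions and mass balance", {
  m <- derive_micro(ref_params())
  st <- amounts_single_dose(0, 25000, m)
  expect_equal(st$X_c, 25000)
  expect_equal(st$X_p, 0)

  # K12 = 0: pure mono-exponential central decay, nothing peripheral
  m0 <- micro_constants(K10 = 0.4, K12 = 0, K21 = 0.1)
  tt <- c(0, 0.5, 1, 3, 12)
  st <- amounts_single_dose(tt, 1000, m0)
  expect_equal(st$X_c, 1000 * exp(-0.4 * tt), tolerance = 1e-12)
  expect_equal(st$X_p, rep(0, length(tt)))

  # total amount never exceeds the dose and vanishes eventually (the
  # terminal beta phase is slow: half-life ~ 37 h at the reference set)
  st <- amounts_single_dose(seq(0, 600, by = 1), 25000, m)
  expect_true(all(st$X_c + st$X_p <= 25000 * (1 + 1e-12)))
  expect_true(all(st$X_c >= 0 & st$X_p >= 0))
  expect_lt(st$X_c[nrow(st)] + st$X_p[nrow(st)], 25000 * 1e-3)

  expect_error(amounts_single_dose(-1, 100, m), "nonnegative")
  expect_error(amounts_single_dose(1, 0, m), "positive")
})

test_that("single-dose closed form agrees with the ODE integrator", {
  p <- ref_params()
  h <- dosing_history(0, 25000)
  tt <- c(0.25, 0.5, 1, 2, 5, 10, 24)
  ode <- attr(ode_profile(h, p, tt), "amounts")
  cf <- amounts_single_dose(tt, 25000, derive_micro(p))
  expect_equal(ode$X_c, cf$X_c, tolerance = 1e-8)
  expect_equal(ode$X_p, cf$X_p, tolerance = 1e-8)
})

test_that("multidose superposition is the exact sum of single-dose terms", {
  m <- derive_micro(ref_params())
  h <- dosing_history(c(0, 0.2, 1.1), c(24805, 8516, 3000), t_neu = 2)
  tt <- c(0.1, 0.5, 1.5, 1.9)
  got <- amounts_multidose(tt, h, m)
  # identical floating-point expression, not just close
  Xc <- rowSums(sapply(1:3, function(i)
    ifelse(tt >= h$times[i],
           .subset2(amounts_single_dose(pmax(tt - h$times[i], 0),
                                        h$amounts[i], m), "X_c"), 0)))
  expect_identical(got$X_c, Xc)

  # single-element history reduces to amounts_single_dose
  h1 <- dosing_history(0, 24805)
  expect_identical(amounts_multidose(tt, h1, m)$X_c,
                   amounts_single_dose(tt, 24805, m)$X_c)

  # linearity: doubling every dose doubles both compartments
  h2 <- dosing_history(h$times, 2 * h$amounts, t_neu = 2)
  expect_equal(amounts_multidose(tt, h2, m)$X_c, 2 * got$X_c,
               tolerance = 1e-14)
  expect_equal(amounts_multidose(tt, h2, m)$X_p, 2 * got$X_p,
               tolerance = 1e-14)

  # empty history: nothing on board
  h0 <- dosing_history()
  expect_equal(amounts_multidose(tt, h0, m)$X_c, rep(0, length(tt)))

  # two-bolus case against the ODE oracle with impulse events
  p <- ref_params()
  hh <- dosing_history(c(0, 0.2), c(24805, 8516))
  ode <- attr(ode_profile(hh, p, 2), "amounts")
  cf <- amounts_multidose(2, hh, derive_micro(p))
  expect_equal(ode$X_c, cf$X_c, tolerance = 1e-8)
  expect_equal(ode$X_p, cf$X_p, tolerance = 1e-8)
})

test_that("post-neutralization branch resets, rebounds and matches the ODE", {
  p <- ref_params()
  m <- derive_micro(p)
  B <- 2500

  # reset initial condition
  st <- amounts_post_neutralization(2.04, B, 2.04, m)
  expect_equal(st$X_c, 0)
  expect_equal(st$X_p, B)

  # no peripheral mass, no rebound
  st <- amounts_post_neutralization(c(2.04, 5, 20), 0, 2.04, m)
  expect_equal(st$X_c, rep(0, 3))
  expect_equal(st$X_p, rep(0, 3))

  # single interior maximum: rises then falls
  tt <- seq(2.04, 50, by = 0.01)
  xc <- amounts_post_neutralization(tt, B, 2.04, m)$X_c
  i <- which.max(xc)
  expect_gt(i, 1)
  expect_lt(i, length(tt))
  expect_true(all(diff(xc[1:i]) > 0))
  expect_true(all(diff(xc[i:length(xc)]) < 0))

  # ODE restarted from (0, B) agrees at 7.43 h after the reset
  hist <- dosing_history(0, 1, t_neu = 2.04)  # dummy; integrate manually
  deriv <- function(t, y, pr)
    list(c(pr[3] * y[2] - (pr[2] + pr[1]) * y[1],
           pr[2] * y[1] - pr[3] * y[2]))
  sol <- deSolve::lsoda(c(0, B), c(0, 7.43), deriv,
                        parms = c(m$K10, m$K12, m$K21),
                        rtol = 1e-11, atol = 1e-12)
  cf <- amounts_post_neutralization(2.04 + 7.43, B, 2.04, m)
  expect_equal(sol[2, 2], cf$X_c, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sol[2, 3], cf$X_p, tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(amounts_post_neutralization(1, B, 2.04, m), ">= t_neu")
  expect_error(amounts_post_neutralization(3, -5, 2.04, m),
               "nonnegative")
})

test_that("peripheral amount is continuous at the reset; central drops to zero", {
  p <- ref_params()
  m <- derive_micro(p)
  h <- typical_history()
  eps <- 1e-9
  left <- amounts_multidose(2.04 - eps, h, m)
  B <- amounts_multidose(2.04, h, m)$X_p
  right <- amounts_post_neutralization(2.04, B, 2.04, m)
  expect_lt(abs(left$X_p - right$X_p) / right$X_p, 1e-6)
  expect_equal(right$X_c, 0)
  expect_equal(concentration(2.04, h, p), 0)
})

test_that("piecewise concentration has the documented branch behavior", {
  p <- ref_params()
  h <- dosing_history(c(0.5, 1), c(20000, 5000), t_neu = 2.04)

  expect_equal(concentration(0.25, h, p), 0)  # before the first dose
  expect_equal(concentration(2.04, h, p), 0)  # instant at the reset
  expect_error(concentration(-0.1, h, p), "nonnegative")

  # dose exactly at an output time contributes fully (state after bolus)
  expect_equal(concentration(0.5, h, p), 20000 / 3.04 / 1000,
               tolerance = 1e-12)

  # typical-subject post-neutralization maximum on a dense 0.01-h grid
  hh <- typical_history()
  tt <- seq(2.04, 2.04 + 48, by = 0.01)
  cc <- concentration(tt, hh, p)
  expect_equal(max(cc), 0.0336, tolerance = 0.01)
  # grid argmax agrees with the closed-form peak time
  pk <- rebound_peak(hh, p)
  expect_equal(tt[which.max(cc)], pk$time, tolerance = 1e-2)
  expect_equal(max(cc), pk$conc, tolerance = 1e-6)
})

test_that("rebound peak has the closed-form maximizer and dominates the grid", {
  p <- ref_params()
  h <- typical_history()
  m <- derive_micro(p)
  pk <- rebound_peak(h, p)
  expect_equal(pk$time - 2.04, log(m$alpha / m$beta) / (m$alpha - m$beta),
               tolerance = 1e-12)
  expect_equal(pk$time - 2.04, 7.4, tolerance = 0.01)
  grid <- concentration(seq(2.04, 50, by = 0.01), h, p)
  expect_gte(pk$conc, max(grid) - 1e-12)

  # among the scheduled post-operative samples the 8-h one is maximal
  sched <- 2.04 + c(2, 4, 8, 12, 24)
  cs <- concentration(sched, h, p)
  expect_equal(c(2, 4, 8, 12, 24)[which.max(cs)], 8)

  expect_error(rebound_peak(dosing_history(0, 100), p), "neutralization")
})

test_that("concentration is strictly decreasing beyond the rebound peak", {
  set.seed(77)
  for (i in 1:10) {
    p <- random_params()
    h <- random_history()
    pk <- rebound_peak(h, p)
    tt <- seq(pk$time + 0.01, pk$time + 48, by = 0.25)
    cc <- concentration(tt, h, p)
    expect_true(all(diff(cc) < 0))
  }
})

test_that("repeated-root guard evaluates the degenerate limit stably", {
  # K12 ~ 0 and K10 == K21 makes alpha == beta (up to roundoff)
  m <- micro_constants(K10 = 0.3, K12 = 1e-20, K21 = 0.3)
  expect_lt((m$alpha - m$beta) / m$alpha, 1e-9)
  tt <- c(0, 0.5, 2, 10)
  st <- amounts_single_dose(tt, 1000, m)
  # mono-exponential limit with lambda = 0.3 when K12 -> 0
  expect_equal(st$X_c, 1000 * exp(-0.3 * tt), tolerance = 1e-5)
  expect_true(all(is.finite(st$X_p)))
})

test_that("mg-to-IU dose conversion uses the 125 IU/mg label factor", {
  expect_equal(ufh_dose_iu(3), 375)
  expect_equal(ufh_dose_iu(1), 125)
})
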