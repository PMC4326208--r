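test_that("bolus-only regimen reproduces the core piecewise model", {
  p <- ref_params()
  h <- typical_history()
  prof <- simulate_regimen(h, p, protamine_regimen("bolus_only"),
                           horizon = 30)
  expect_equal(prof$conc, concentration(prof$time, h, p),
               tolerance = 1e-12)
  # consistency with the closed-form rebound peak
  m <- rebound_metrics(prof)
  pk <- rebound_peak(h, p)
  expect_equal(m$peak, pk$conc, tolerance = 1e-4)
  expect_equal(m$t_peak + 2.04, pk$time, tolerance = 0.01)
})

test_that("the clamp holds the central compartment at zero and drains X_p at K21", {
  p <- ref_params()
  h <- typical_history()
  m <- derive_micro(p)
  reg <- protamine_regimen("bolus_plus_infusion", rate = 25,
                           duration = 6)
  prof <- simulate_regimen(h, p, reg, horizon = 40)
  during <- prof$time >= 2.04 & prof$time <= 8.04
  expect_true(all(prof$conc[during] == 0))

  # mass accounting: X_p at infusion end vs the ODE on the clamped
  # system (central pinned at zero => dXp/dt = -K21 Xp)
  B0 <- amounts_multidose(2.04, h, m)$X_p
  Bend_closed <- B0 * exp(-m$K21 * 6)
  sol <- deSolve::lsoda(c(Xp = B0), c(0, 6),
                        function(t, y, k) list(-k * y), m$K21,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(Bend_closed, sol[2, 2], tolerance = 1e-8,
               ignore_attr = TRUE)

  # post-infusion peak matches the closed form at t* after infusion end
  a <- m$alpha; b <- m$beta
  tstar <- log(a / b) / (a - b)
  peak_closed <- m$K21 * Bend_closed *
    (exp(-b * tstar) - exp(-a * tstar)) / ((a - b) * p$V_c * 1000)
  mm <- rebound_metrics(prof)
  expect_equal(mm$peak, peak_closed, tolerance = 1e-4)
  expect_gte(mm$t_peak, 6)   # peak cannot precede the infusion end
})

test_that("degenerate regimens behave as documented", {
  p <- ref_params()
  h <- typical_history()
  # an infusion covering the whole horizon keeps concentration at zero
  reg <- protamine_regimen("bolus_plus_infusion", duration = 48)
  prof <- simulate_regimen(h, p, reg, horizon = 48)
  expect_true(all(prof$conc[prof$time >= 2.04] == 0))
  m <- rebound_metrics(prof)
  expect_equal(m$peak, 0)
  expect_equal(m$time_above, 0)

  expect_error(simulate_regimen(h, p, reg, horizon = 12), "horizon")
  expect_error(protamine_regimen("bolus_only", duration = 2),
               "duration 0")
  expect_error(rebound_metrics(conc_profile(c(0, 1, 2), h, p),
                               t_neu = 2.04), "24 h")
})

test_that("rebound metrics integrate threshold occupancy on the grid", {
  # synthetic triangular profile: above 0.5 between t = 11 and t = 13
  tt <- seq(0, 40, by = 0.5)
  cc <- pmax(0, 1 - abs(tt - 12) / 2)
  prof <- structure(data.frame(time = tt, conc = cc),
                    class = c("concentration_profile", "data.frame"))
  m <- rebound_metrics(prof, t_neu = 2, threshold = 0.5)
  expect_equal(m$peak, 1)
  expect_equal(m$t_peak, 10)          # absolute 12, 10 after t_neu
  expect_equal(m$time_above, 2, tolerance = 1e-10)
  expect_equal(m$conc_24h, 0)         # t = 26 is past the triangle

  zero <- structure(data.frame(time = tt, conc = 0 * tt),
                    class = c("concentration_profile", "data.frame"))
  mz <- rebound_metrics(zero, t_neu = 2)
  expect_equal(mz$peak, 0)
  expect_equal(mz$conc_24h, 0)
  expect_equal(mz$time_above, 0)
})

test_that("rebound peak decreases strictly with infusion duration", {
  p <- ref_params()
  h <- typical_history()
  cmp <- compare_regimens(h, p, default_regimens(), horizon = 48)
  met <- cmp$metrics
  expect_equal(met$label[1], "bolus only")
  infusions <- met[met$mode == "bolus_plus_infusion", ]
  expect_equal(infusions$duration, c(6, 8, 12, 16, 24))
  expect_true(all(diff(infusions$peak) < 0))
  expect_true(all(infusions$peak < met$peak[met$label == "bolus only"]))

  # monotonicity also holds on random parameter sets
  set.seed(55)
  for (i in 1:5) {
    pr <- random_params()
    cm <- compare_regimens(h, pr, default_regimens(), horizon = 48,
                           dt = 0.02)
    inf <- cm$metrics[cm$metrics$mode == "bolus_plus_infusion", ]
    expect_true(all(diff(inf$peak) < 0))
  }

  expect_error(compare_regimens(h, p, list(protamine_regimen("bolus_only"))),
               "at least two")
})
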