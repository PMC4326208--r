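# sparse design used for likelihood-oracle toys: one sample an hour
# during CPB, three post-operative samples
sparse_config <- function(n) trial_config(n_subjects = n,
  sampling = list(first_sample = 10 / 60, intra_interval = 1,
                  post_times = c(2, 8, 24), jitter_sd = 0))

test_that("OFV reduces to the closed-form normal likelihood without IIV", {
  tr <- data.frame(ID = 1L, TIME = c(0, 1, 2), EVID = c(1L, 0L, 2L),
                   AMT = c(10000, NA, NA), DV = c(NA, 2.9, NA),
                   BLQ = 0L, WT = 66, AGE = 50, SEX = 0L)
  pop <- noiiv_model(sigma2_pro = 0.1)
  f <- concentration(1, dosing_history(0, 10000, t_neu = 2),
                     ref_params())
  v <- 0.1 * f^2
  expect_equal(ofv(tr, pop), log(2 * pi) + log(v) + (2.9 - f)^2 / v,
               tolerance = 1e-12)
})

test_that("OFV is additive over subjects and invariant to relabeling", {
  pop <- ufh_reference_model()
  tr <- generate_trial(small_config(5), pop, seed = 61)
  base <- ofv(tr, pop)

  # duplicating every subject under fresh ids doubles the OFV exactly
  dup <- tr
  dup$ID <- dup$ID + 100L
  both <- rbind(tr, dup)
  class(both) <- c("trial_dataset", "data.frame")
  expect_equal(ofv(both, pop), 2 * base, tolerance = 1e-12)

  # permuting subject order leaves the OFV unchanged
  perm <- do.call(rbind, lapply(c(3, 5, 1, 4, 2),
                                function(i) tr[tr$ID == i, ]))
  class(perm) <- c("trial_dataset", "data.frame")
  expect_lt(abs(ofv(perm, pop) - base), 1e-8)
})

test_that("FOCE OFV agrees with adaptive Gauss-Hermite quadrature on toys", {
  # low-noise toys isolate implementation agreement: both
  # approximations converge to the same marginal likelihood as the
  # residual noise shrinks
  pop1 <- population_model(1.18, 3.04, 0.171, 8.01,
                           omega2 = c(CL = 0.05), sigma2_pro = 0.005)
  for (s in 1:5) {
    tr <- generate_trial(sparse_config(3), pop1, seed = s)
    expect_lt(abs(ofv(tr, pop1) - agq_ofv(tr, pop1)), 0.15)
  }
  pop2 <- population_model(1.18, 3.04, 0.171, 8.01,
                           omega2 = c(CL = 0.05, V_c = 0.05),
                           sigma2_pro = 0.005)
  for (s in 51:55) {
    tr <- generate_trial(sparse_config(5), pop2, seed = s)
    expect_lt(abs(ofv(tr, pop2) - agq_ofv(tr, pop2)), 0.5)
  }
})

test_that("noise-free data are refit to the generating parameters", {
  # deterministic least-squares limit: all variances zero, residual
  # variance held at a fixed nominal value
  pop0 <- population_model(1.18, 3.04, 0.171, 8.01)
  tr <- generate_trial(small_config(10), pop0, seed = 41)
  init <- population_model(1.18 * 1.5, 3.04 * 0.5, 0.171 * 1.5,
                           8.01 * 0.6, sigma2_pro = 1e-6)
  fit <- foce_fit(tr, init, fixed = "sigma2_pro", compute_se = FALSE)
  expect_true(fit$convergence$converged)
  truth <- c(CL = 1.18, V_c = 3.04, Q = 0.171, V_p = 8.01)
  expect_equal(unname(fit$theta), unname(truth), tolerance = 1e-3)
  expect_lt(max(abs(fit$theta - truth) / truth), 0.001)
})

test_that("a small FOCE fit converges with finite standard errors", {
  pop <- population_model(1.18, 3.04, 0.171, 8.01,
                          omega2 = c(CL = 0.122, V_c = 0.105),
                          sigma2_pro = 0.05)
  tr <- generate_trial(small_config(12), pop, seed = 71)
  init <- population_model(1.18 * 1.4, 3.04 * 0.7, 0.171 * 1.4,
                           8.01 * 0.7,
                           omega2 = c(CL = 0.08, V_c = 0.08),
                           sigma2_pro = 0.08)
  fit <- foce_fit(tr, init, compute_se = TRUE)
  expect_true(fit$convergence$converged)
  # estimates in a physiologic neighborhood of the truth
  expect_lt(abs(log(fit$theta[["CL"]] / 1.18)), log(1.6))
  expect_lt(abs(log(fit$theta[["V_c"]] / 3.04)), log(1.6))
  # SEs from the OFV/2 Hessian: positive, finite, plausible RSE
  expect_true(all(is.finite(fit$se)))
  expect_true(all(fit$se > 0))
  expect_equal(unname(fit$rse["theta_CL"]),
               unname(100 * fit$se["theta_CL"] / fit$theta[["CL"]]))
  # zero-fixed variance components stay at zero
  expect_identical(fit$omega2[["Q"]], 0)
  expect_identical(fit$omega2[["V_p"]], 0)
  expect_identical(unname(fit$sigma2["add"]), 0)
})

test_that("fit input validation catches degenerate problems", {
  pop <- noiiv_model()
  tr <- generate_trial(small_config(1), pop, seed = 3)
  one_obs <- tr[c(which(tr$EVID == 1), which(tr$EVID == 0)[1],
                  which(tr$EVID == 2)), ]
  one_obs <- one_obs[order(one_obs$TIME), ]
  class(one_obs) <- c("trial_dataset", "data.frame")
  expect_error(foce_fit(one_obs, pop), "fewer observations")

  # zero residual variance at an observation is a domain error naming
  # the record
  bad <- population_model(1.18, 3.04, 0.171, 8.01, sigma2_pro = 0)
  expect_error(ofv(tr, bad), "zero residual variance.*subject",
               perl = TRUE)
})

test_that("stepwise selection uses the chi-squared thresholds and finds a real effect", {
  expect_equal(round(ofv_threshold(0.01), 2), 6.63)
  expect_equal(round(ofv_threshold(0.001), 2), 10.83)

  # simulate a strong body-weight effect on clearance, no IIV
  gen <- population_model(1.18, 3.04, 0.171, 8.01, sigma2_pro = 0.01,
                          covariates = list(covariate_effect(
                            "CL", "weight", "continuous",
                            coefficient = -0.012, reference = 66)))
  tr <- generate_trial(trial_config(n_subjects = 40), gen, seed = 81)
  base <- population_model(1.18, 3.04, 0.171, 8.01, sigma2_pro = 0.02)
  cands <- list(
    covariate_effect("CL", "weight", "continuous", coefficient = 0,
                     reference = 66),
    covariate_effect("CL", "age", "continuous", coefficient = 0,
                     reference = 53.4))
  sw <- stepwise_covariates(tr, base, cands)
  kept <- sw$model$pop$covariates
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$covariate, "weight")
  expect_equal(kept[[1]]$parameter, "CL")
  expect_equal(unname(kept[[1]]$coefficient), -0.012, tolerance = 0.15)
  # the trace records forward ranking, inclusion and backward retention
  expect_true(any(sw$trace$phase == "forward-rank"))
  expect_true(any(sw$trace$decision == "include"))
  expect_true(all(sw$trace$delta_ofv[sw$trace$decision == "include"] >
                    6.63))
  expect_true(all(sw$trace$delta_ofv[sw$trace$decision == "retain"] >
                    10.83))
})
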