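test_that("subject covariates respect the configured ranges and determinism", {
  cfg <- trial_config(n_subjects = 200)
  set.seed(5)
  s <- generate_subjects(cfg)
  expect_true(all(s$weight >= 41 & s$weight <= 82))
  expect_true(all(s$age >= 18 & s$age <= 74))
  expect_true(all(s$sex %in% c(0, 1)))

  set.seed(5)
  expect_identical(generate_subjects(cfg), s)

  # law of large numbers on the configured center
  cfg <- trial_config(n_subjects = 1000)
  set.seed(6)
  s <- generate_subjects(cfg)
  expect_lt(abs(mean(s$weight) - 66), 2)
  expect_error(trial_config(n_subjects = 0), "at least 1")
})

test_that("dosing follows the weight-based rules and precedes neutralization", {
  cfg <- trial_config()
  sub <- subject_covariates(66, 53, 0)
  set.seed(9)
  for (i in 1:20) {
    h <- generate_dosing(sub, cfg)
    expect_equal(h$amounts[1], 375 * 66)  # 24750 IU initial bolus
    expect_equal(h$amounts[2], 125 * 66)  # 8250 IU priming bolus
    expect_true(all(h$times < h$t_neu))
    expect_true(h$t_neu >= 0.95 && h$t_neu <= 3.29)
    expect_true(length(h$times) <= 4)
  }
})

test_that("sampling schedule covers CPB every 30 min and the post-op times", {
  cfg <- small_config(jitter_sd = 0)
  h <- dosing_history(c(0, 0), c(24750, 8250), t_neu = 2.04)
  tt <- generate_sampling(h, cfg)
  intra <- tt[tt < 2.04]
  post <- tt[tt > 2.04]
  expect_gte(length(intra), 4)   # 0.5-h grid points inside (10/60, 2.04]
  expect_equal(diff(intra), rep(0.5, length(intra) - 1))
  expect_equal(post, 2.04 + c(2, 4, 8, 12, 24))  # exact without jitter

  # jitter keeps order and positivity
  cfg <- small_config(jitter_sd = 0.1)
  set.seed(3)
  tt <- generate_sampling(h, cfg)
  expect_true(!is.unsorted(tt[tt > 2.04]))
  expect_true(all(tt > 0))
})

test_that("assay dilutes pre-neutralization samples 1:29 and censors the window", {
  cfg <- trial_config()
  # 6 IU/mL dilutes to 0.2, inside the window, back-calculates to 6
  r <- assay_observe(6, "pre_neutralization", cfg)
  expect_false(r$blq)
  expect_equal(r$observed, 6)
  # true zero falls at the lower bound: below quantitation
  r <- assay_observe(0, "post_neutralization", cfg)
  expect_true(r$blq)
  expect_true(is.na(r$observed))
  # rebound-range activities are far inside the undiluted window
  r <- assay_observe(c(0.02, 0.04), "post_neutralization", cfg)
  expect_equal(r$observed, c(0.02, 0.04))
  # above the diluted ceiling: re-assayed at higher dilution, so the
  # proportional-error report is the unclamped value
  r <- assay_observe(30, "pre_neutralization", cfg)
  expect_equal(r$observed, 30)
  # neat post-neutralization reads cap at the window ceiling
  r <- assay_observe(0.9, "post_neutralization", cfg)
  expect_equal(r$observed, 0.6)
  expect_error(assay_observe(-1, "pre_neutralization", cfg), "nonnegative")
})

test_that("a noise-free trial reproduces the closed-form concentrations", {
  cfg <- small_config(n = 1, jitter_sd = 0)
  pop <- population_model(CL = 1.18, V_c = 3.04, Q = 0.171, V_p = 8.01)
  tr <- generate_trial(cfg, pop, seed = 21)
  obs <- tr[tr$EVID == 0 & tr$BLQ == 0, ]
  dose <- tr[tr$EVID == 1, ]
  t_neu <- tr$TIME[tr$EVID == 2]
  h <- dosing_history(dose$TIME, dose$AMT, t_neu = t_neu)
  p <- pk_params(1.18, 3.04, 0.171, 8.01)
  expect_equal(obs$DV, concentration(obs$TIME, h, p), tolerance = 1e-12)
})

test_that("generated trials have the event structure of the study design", {
  cfg <- trial_config(n_subjects = 32)
  tr <- generate_trial(cfg, ufh_reference_model(), seed = 4)
  expect_s3_class(tr, "trial_dataset")
  expect_equal(length(unique(tr$ID)), 32)
  for (id in unique(tr$ID)) {
    d <- tr[tr$ID == id, ]
    expect_equal(sum(d$EVID == 2), 1)
    expect_true(all(d$TIME[d$EVID == 1] < d$TIME[d$EVID == 2]))
    expect_true(!is.unsorted(d$TIME))
  }
  # determinism: same config and seed give the identical dataset
  expect_identical(generate_trial(cfg, ufh_reference_model(), seed = 4),
                   tr)
})

test_that("intra-CPB activities mostly fall in the therapeutic plateau", {
  cfg <- trial_config(n_subjects = 100)
  tr <- generate_trial(cfg, ufh_reference_model(), seed = 15)
  t_neu <- setNames(tr$TIME[tr$EVID == 2], tr$ID[tr$EVID == 2])
  obs <- tr[tr$EVID == 0 & tr$BLQ == 0, ]
  intra <- obs[obs$TIME < t_neu[as.character(obs$ID)], ]
  in_plateau <- mean(intra$DV >= 2 & intra$DV <= 19)
  expect_gte(in_plateau, 0.9)
})
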