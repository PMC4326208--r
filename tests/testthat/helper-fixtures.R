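# shared fixtures: the reference parameter set, the typical-subject
# dosing scenario, and small helper constructors used across test files

ref_params <- function() pk_params(CL = 1.18, V_c = 3.04, Q = 0.171,
                                   V_p = 8.01)

# mean first dose + mean priming dose at time zero, neutralization at
# the mean CPB time
typical_history <- function() dosing_history(c(0, 0), c(24805, 8516),
                                             t_neu = 2.04)

# random positive parameter set log-uniform within factor 10 of the
# reference values (caller controls the RNG seed)
random_params <- function() {
  r <- function(x) x * exp(runif(1, log(0.1), log(10)))
  pk_params(CL = r(1.18), V_c = r(3.04), Q = r(0.171), V_p = r(8.01))
}

# random 1-5 bolus history inside (0, t_neu)
random_history <- function(t_neu = runif(1, 1, 3)) {
  n <- sample(1:5, 1)
  times <- sort(c(0, runif(n - 1, 0, t_neu * 0.95)))
  dosing_history(times, runif(n, 2000, 30000), t_neu = t_neu)
}

# small population model without IIV (fast deterministic-limit fits)
noiiv_model <- function(sigma2_pro = 0.02)
  population_model(CL = 1.18, V_c = 3.04, Q = 0.171, V_p = 8.01,
                   sigma2_pro = sigma2_pro)

# trial config scaled down for fast tests
small_config <- function(n = 8, jitter_sd = 0.1)
  trial_config(n_subjects = n,
               sampling = list(first_sample = 10 / 60,
                               intra_interval = 0.5,
                               post_times = c(2, 4, 8, 12, 24),
                               jitter_sd = jitter_sd))
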