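#' Synthetic CPB trial configuration
#'
#' Study-design settings for the virtual trial generator, defaulting to
#' the adult CPB study the package emulates: 32 completers; body weight
#' truncated-normal mean 66 kg, sd 9, bounds 41--82; age mean 53.4 y, sd
#' 13, bounds 18--74; 19/32 female; an initial bolus of 375 IU/kg at time
#' zero, a 125 IU/kg pump-priming bolus at CPB start (also time zero),
#' and 0--2 irregular intra-operative boluses of 1000--5000 IU; CPB
#' duration truncated-normal mean 2.04 h, sd 0.5, bounds 0.95--3.29;
#' samples every 0.5 h during CPB starting 10 min after the first dose
#' and at 2, 4, 8, 12 and 24 h after neutralization with Gaussian jitter
#' (sd 0.1 h); a 1:29 dilution (1 part plasma + 29 parts pooled plasma,
#' so divide by 30) of pre-neutralization samples into the 0.0--0.6
#' IU/mL measurable window of the anti-FIIa assay.
#'
#' @param n_subjects number of subjects (>= 1)
#' @param seed default seed used by [generate_trial()]
#' @param weight,age lists with `mean`, `sd`, `min`, `max` (truncated
#'   normal)
#' @param female_fraction Bernoulli probability of female sex
#' @param dose list with `initial_iu_per_kg`, `priming_iu_per_kg`,
#'   `extra_count` (integer vector of possible counts), `extra_range`
#'   (IU, length 2)
#' @param cpb list with `mean`, `sd`, `min`, `max` for CPB duration, h
#' @param sampling list with `first_sample` (h after the initial dose),
#'   `intra_interval` (h), `post_times` (h after neutralization),
#'   `jitter_sd` (h)
#' @param assay list with `dilution_parts` (diluent parts added to one
#'   part plasma) and `window` (length-2 measurable range, IU/mL)
#' @return an object of class `trial_config`
#' @export
trial_config <- function(n_subjects = 32, seed = 1,
                         weight = list(mean = 66, sd = 9, min = 41,
                                       max = 82),
                         age = list(mean = 53.4, sd = 13, min = 18,
                                    max = 74),
                         female_fraction = 19 / 32,
                         dose = list(initial_iu_per_kg = 375,
                                     priming_iu_per_kg = 125,
                                     extra_count = 0:2,
                                     extra_range = c(1000, 5000)),
                         cpb = list(mean = 2.04, sd = 0.5, min = 0.95,
                                    max = 3.29),
                         sampling = list(first_sample = 10 / 60,
                                         intra_interval = 0.5,
                                         post_times = c(2, 4, 8, 12, 24),
                                         jitter_sd = 0.1),
                         assay = list(dilution_parts = 29,
                                      window = c(0, 0.6))) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("'n_subjects' must be at least 1", call. = FALSE)
  for (rng in list(weight, age, cpb))
    if (rng$min >= rng$max || rng$sd <= 0)
      stop("distribution ranges must be nonempty with positive sd",
           call. = FALSE)
  if (female_fraction < 0 || female_fraction > 1)
    stop("'female_fraction' must be in [0, 1]", call. = FALSE)
  if (assay$window[1] < 0 || assay$window[1] >= assay$window[2])
    stop("assay window must be an increasing range with lower bound >= 0",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), seed = seed,
                 weight = weight, age = age,
                 female_fraction = female_fraction, dose = dose,
                 cpb = cpb, sampling = sampling, assay = assay),
            class = "trial_config")
}

# inverse-CDF truncated normal draw (deterministic given the RNG stream)
.rtruncnorm <- function(n, mean, sd, min, max) {
  lo <- pnorm(min, mean, sd); hi <- pnorm(max, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Generate subject covariates
#'
#' Draws body weight and age from truncated normal distributions and sex
#' from a Bernoulli, per the trial configuration.  Uses the current R
#' RNG stream (seed it, or call through [generate_trial()]).
#'
#' @param config a [trial_config()]
#' @return data frame with columns `id`, `weight`, `age`, `sex`
#' @export
generate_subjects <- function(config) {
  if (!inherits(config, "trial_config"))
    stop("'config' must be a trial_config", call. = FALSE)
  n <- config$n_subjects
  data.frame(
    id = seq_len(n),
    weight = .rtruncnorm(n, config$weight$mean, config$weight$sd,
                         config$weight$min, config$weight$max),
    age = .rtruncnorm(n, config$age$mean, config$age$sd,
                      config$age$min, config$age$max),
    sex = rbinom(n, 1, config$female_fraction))
}

#' Generate a subject's dosing history
#'
#' Weight-based initial bolus (default 375 IU/kg) at time zero, the
#' pump-priming bolus (default 125 IU/kg) at CPB start (collapsed to time
#' zero), and a random number of irregular intra-operative boluses at
#' uniform times strictly inside the bypass period.  The neutralization
#' time is the CPB duration draw.
#'
#' @param subject a [subject_covariates()] object (or a list/one-row data
#'   frame with `weight`)
#' @param config a [trial_config()]
#' @return a [dosing_history()] with `t_neu` set
#' @export
generate_dosing <- function(subject, config) {
  if (!inherits(config, "trial_config"))
    stop("'config' must be a trial_config", call. = FALSE)
  wt <- subject$weight
  t_neu <- .rtruncnorm(1, config$cpb$mean, config$cpb$sd,
                       config$cpb$min, config$cpb$max)
  times <- c(0, 0)
  amounts <- c(config$dose$initial_iu_per_kg * wt,
               config$dose$priming_iu_per_kg * wt)
  n_extra <- if (length(config$dose$extra_count) > 1L)
    sample(config$dose$extra_count, 1L) else config$dose$extra_count
  if (n_extra > 0) {
    tt <- sort(runif(n_extra, 0, t_neu))
    # strictly inside (CPB start, t_neu)
    tt <- pmin(pmax(tt, 1e-6), t_neu - 1e-6)
    aa <- runif(n_extra, config$dose$extra_range[1],
                config$dose$extra_range[2])
    times <- c(times, tt); amounts <- c(amounts, aa)
  }
  o <- order(times)
  dosing_history(times[o], amounts[o], t_neu = t_neu)
}

#' Generate a subject's sampling schedule
#'
#' Samples every `intra_interval` hours from the first-sample time (10
#' min after the initial dose by default) up to the neutralization time,
#' then at the nominal post-operative times (2, 4, 8, 12, 24 h after
#' neutralization) with Gaussian jitter, truncated to stay after the
#' neutralization and re-ordered.
#'
#' @param history a [dosing_history()] with `t_neu`
#' @param config a [trial_config()]
#' @return numeric vector of sampling times, h
#' @export
generate_sampling <- function(history, config) {
  if (!inherits(history, "dosing_history") || is.null(history$t_neu))
    stop("'history' must be a dosing_history with a neutralization time",
         call. = FALSE)
  sm <- config$sampling
  intra <- seq(sm$first_sample, history$t_neu, by = sm$intra_interval)
  post_nom <- history$t_neu + sm$post_times
  jit <- if (sm$jitter_sd > 0)
    rnorm(length(post_nom), 0, sm$jitter_sd) else 0
  post <- pmax(post_nom + jit, history$t_neu + 1e-3)
  c(intra, sort(post))
}

#' Assay observation with dilution, residual error and window censoring
#'
#' Pre-neutralization plasma runs far above the assay's measurable
#' window, so those samples are diluted 1 part plasma + `dilution_parts`
#' parts pooled normal plasma (default 29, i.e. divide by 30) before
#' measurement and back-calculated afterwards; post-neutralization
#' samples are measured neat.  Residual error (the hybrid model of
#' [apply_residual()]) acts on the measured (diluted) scale.  Readings
#' at or below the window's lower bound are flagged below the limit of
#' quantitation (observation blank).  Diluted (pre-neutralization)
#' readings above the upper bound are treated as re-assayed at a higher
#' dilution, standard practice for over-range samples -- under
#' proportional error the dilution factor cancels, so the re-assayed
#' report equals the unclamped back-calculated value; neat
#' (post-neutralization) readings above the bound are reported at the
#' bound.
#'
#' @param true_conc true plasma activity(ies), IU/mL (>= 0)
#' @param phase `"pre_neutralization"` or `"post_neutralization"`
#' @param config a [trial_config()]
#' @param sigma2_pro,sigma2_add residual variance components; 0 for a
#'   noise-free read
#' @return data frame with columns `observed` (IU/mL, `NA` when below
#'   quantitation) and `blq` (logical)
#' @export
assay_observe <- function(true_conc,
                          phase = c("pre_neutralization",
                                    "post_neutralization"),
                          config, sigma2_pro = 0, sigma2_add = 0) {
  phase <- match.arg(phase)
  if (any(!is.finite(true_conc)) || any(true_conc < 0))
    stop("'true_conc' must be finite and nonnegative", call. = FALSE)
  dil <- if (phase == "pre_neutralization")
    config$assay$dilution_parts + 1 else 1
  n <- length(true_conc)
  eps1 <- if (sigma2_pro > 0) rnorm(n, 0, sqrt(sigma2_pro)) else 0
  eps2 <- if (sigma2_add > 0) rnorm(n, 0, sqrt(sigma2_add)) else 0
  measured <- apply_residual(true_conc / dil, eps1, eps2)
  win <- config$assay$window
  blq <- measured <= win[1]
  if (phase == "post_neutralization")
    measured <- pmin(measured, win[2])   # neat reads cap at the window
  observed <- ifelse(blq, NA_real_, measured * dil)
  data.frame(observed = observed, blq = blq)
}

#' Generate a complete synthetic CPB trial
#'
#' Composes the covariate, dosing, sampling and assay generators with the
#' structural and population models into a NONMEM-style rectangular event
#' dataset.  Per subject: random effects are drawn from the population
#' model, true activities follow the piecewise two-compartment model, and
#' observations pass through the residual-error and assay-window model.
#' With all variance components zero the observations equal the
#' closed-form concentrations exactly.
#'
#' @param config a [trial_config()]
#' @param pop a [population_model()]
#' @param seed integer seed; defaults to `config$seed`.  The same
#'   (config, pop, seed) always yields the identical dataset.
#' @return a `trial_dataset` data frame with columns `ID`, `TIME` (h),
#'   `EVID` (0 observation, 1 dose, 2 neutralization), `AMT` (IU), `DV`
#'   (IU/mL), `BLQ` (0/1), `WT` (kg), `AGE` (y), `SEX` (0/1)
#' @examples
#' tr <- generate_trial(trial_config(n_subjects = 4), ufh_reference_model())
#' head(tr)
#' @export
generate_trial <- function(config, pop, seed = config$seed) {
  if (!inherits(config, "trial_config"))
    stop("'config' must be a trial_config", call. = FALSE)
  if (!inherits(pop, "population_model"))
    stop("'pop' must be a population_model", call. = FALSE)
  set.seed(seed)
  subjects <- generate_subjects(config)
  rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sub <- subjects[i, ]
    cov <- subject_covariates(sub$weight, sub$age, sub$sex)
    history <- generate_dosing(cov, config)
    times <- generate_sampling(history, config)
    eta <- .draw_eta(pop)
    params <- individual_parameters(pop, cov, eta)
    true_conc <- concentration(times, history, params)
    pre <- times < history$t_neu
    obs <- rbind(
      if (any(pre))
        assay_observe(true_conc[pre], "pre_neutralization", config,
                      pop$sigma2_pro, pop$sigma2_add),
      if (any(!pre))
        assay_observe(true_conc[!pre], "post_neutralization", config,
                      pop$sigma2_pro, pop$sigma2_add))
    sub_rows <- rbind(
      data.frame(TIME = history$times, EVID = 1L, AMT = history$amounts,
                 DV = NA_real_, BLQ = 0L),
      data.frame(TIME = times[pre], EVID = 0L, AMT = NA_real_,
                 DV = obs$observed[pre], BLQ = as.integer(obs$blq[pre])),
      data.frame(TIME = history$t_neu, EVID = 2L, AMT = NA_real_,
                 DV = NA_real_, BLQ = 0L),
      data.frame(TIME = times[!pre], EVID = 0L, AMT = NA_real_,
                 DV = obs$observed[!pre],
                 BLQ = as.integer(obs$blq[!pre])))
    # stable sort: doses first at equal times, neutralization after the
    # last intra-CPB sample
    sub_rows <- sub_rows[order(sub_rows$TIME), , drop = FALSE]
    sub_rows <- cbind(ID = sub$id, sub_rows, WT = sub$weight,
                      AGE = sub$age, SEX = sub$sex)
    rows[[i]] <- sub_rows
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trial_dataset", "data.frame")
  out
}
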