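#' Post-operative protamine regimen
#'
#' Either the reference bolus-only neutralization (nothing after the
#' intra-operative protamine bolus) or the bolus followed by a continuous
#' protamine infusion.  Under the clamp mechanism (see
#' [simulate_regimen()]) the infusion rate is carried as metadata: any
#' rate sufficient for neutralization behaves identically, so regimens
#' are distinguished by their duration.
#'
#' @param mode `"bolus_only"` or `"bolus_plus_infusion"`
#' @param rate infusion rate, mg/h (metadata under the clamp model)
#' @param duration infusion duration, h (0 for bolus-only)
#' @param start infusion start, h; `NULL` means the neutralization time
#' @return an object of class `protamine_regimen`
#' @export
protamine_regimen <- function(mode = c("bolus_only",
                                       "bolus_plus_infusion"),
                              rate = 25, duration = 0, start = NULL) {
  mode <- match.arg(mode)
  if (rate < 0 || duration < 0)
    stop("'rate' and 'duration' must be nonnegative", call. = FALSE)
  if (mode == "bolus_only" && duration != 0)
    stop("bolus-only regimens have duration 0", call. = FALSE)
  if (mode == "bolus_plus_infusion" && duration <= 0)
    stop("infusion regimens need a positive duration", call. = FALSE)
  structure(list(mode = mode, rate = rate, duration = duration,
                 start = start), class = "protamine_regimen")
}

#' Simulate a protamine regimen on the fitted UFH model
#'
#' Bolus-only regimens reproduce the piecewise model of
#' [concentration()].  Infusion regimens use the clamp mechanism: while
#' the infusion runs, any UFH re-entering the central compartment is
#' neutralized instantly, so the central concentration is held at zero
#' and the peripheral amount drains at rate `K21`
#' (`X_p(t) = X_p(start) * exp(-K21 (t - start))`); after the infusion
#' ends, rebound restarts from the remaining peripheral amount exactly as
#' after the intra-operative bolus.  This is the minimal extension of the
#' instantaneous-neutralization assumption used for the bolus itself.
#'
#' @param history a [dosing_history()] with a neutralization time
#' @param params a [pk_params()] object
#' @param regimen a [protamine_regimen()]
#' @param horizon profile length after neutralization, h; must reach the
#'   infusion end
#' @param dt grid resolution, h (default 0.01)
#' @return a `concentration_profile` data frame covering `[0, t_neu +
#'   horizon]` with the regimen attached as an attribute
#' @examples
#' h <- dosing_history(c(0, 0), c(24805, 8516), t_neu = 2.04)
#' p <- pk_params(CL = 1.18, V_c = 3.04, Q = 0.171, V_p = 8.01)
#' prof <- simulate_regimen(h, p,
#'   protamine_regimen("bolus_plus_infusion", duration = 6), horizon = 30)
#' rebound_metrics(prof, t_neu = 2.04)
#' @export
simulate_regimen <- function(history, params, regimen, horizon = 48,
                             dt = 0.01) {
  if (!inherits(history, "dosing_history") || is.null(history$t_neu))
    stop("'history' must be a dosing_history with a neutralization time",
         call. = FALSE)
  if (!inherits(regimen, "protamine_regimen"))
    stop("'regimen' must be a protamine_regimen", call. = FALSE)
  t_neu <- history$t_neu
  start <- if (is.null(regimen$start)) t_neu else regimen$start
  if (start < t_neu)
    stop("infusion cannot start before neutralization", call. = FALSE)
  end <- start + regimen$duration
  if (t_neu + horizon < end)
    stop("'horizon' must reach the infusion end", call. = FALSE)
  times <- sort(unique(c(seq(0, t_neu + horizon, by = dt),
                         t_neu, start, end, t_neu + horizon)))
  conc <- concentration(times, history, params)
  if (regimen$duration > 0) {
    micro <- derive_micro(params)
    # peripheral amount when the clamp begins
    B0 <- amounts_multidose(t_neu, history, micro)$X_p
    Bstart <- if (start > t_neu)
      .post_neut_amounts(start - t_neu, B0, micro)$X_p else B0
    Bend <- Bstart * exp(-micro$K21 * regimen$duration)
    during <- times >= start & times <= end
    conc[during] <- 0
    after <- times > end
    if (any(after))
      conc[after] <- .post_neut_amounts(times[after] - end, Bend,
                                        micro)$X_c /
        (params$V_c / params$F) / 1000
  }
  structure(data.frame(time = times, conc = conc),
            class = c("concentration_profile", "data.frame"),
            t_neu = t_neu, regimen = regimen)
}

#' Heparin rebound metrics of a concentration profile
#'
#' Summarizes the post-neutralization part of a profile: peak
#' concentration and its time (grid argmax, earliest time on ties), the
#' concentration exactly 24 h after neutralization (linear
#' interpolation), and the time spent above a threshold (piecewise-linear
#' occupancy of the grid, crossing points interpolated).
#'
#' @param profile a `concentration_profile` (e.g. from
#'   [simulate_regimen()] or [conc_profile()])
#' @param t_neu neutralization time, h; defaults to the profile attribute
#' @param threshold rebound threshold, IU/mL (default 0.02, the
#'   persistence level used to call residual heparinization)
#' @return list of class `rebound_metrics`: `peak` (IU/mL), `t_peak` (h
#'   after neutralization), `conc_24h` (IU/mL), `time_above` (h)
#' @export
rebound_metrics <- function(profile, t_neu = attr(profile, "t_neu"),
                            threshold = 0.02) {
  if (is.null(t_neu))
    stop("'t_neu' is required (not found as a profile attribute)",
         call. = FALSE)
  tt <- profile$time; cc <- profile$conc
  if (max(tt) < t_neu + 24)
    stop("profile must cover at least 24 h after neutralization",
         call. = FALSE)
  post <- tt >= t_neu
  tp <- tt[post]; cp <- cc[post]
  i <- which.max(cp)           # which.max takes the earliest maximum
  conc24 <- approx(tt, cc, xout = t_neu + 24)$y
  # piecewise-linear time above threshold over the post segment
  above <- 0
  for (j in seq_len(length(tp) - 1)) {
    c1 <- cp[j]; c2 <- cp[j + 1]; w <- tp[j + 1] - tp[j]
    if (c1 > threshold && c2 > threshold) above <- above + w
    else if (c1 > threshold || c2 > threshold) {
      frac <- abs(max(c1, c2) - threshold) / abs(c2 - c1)
      above <- above + w * frac
    }
  }
  structure(list(peak = cp[i], t_peak = tp[i] - t_neu,
                 conc_24h = conc24, time_above = above,
                 threshold = threshold),
            class = "rebound_metrics")
}

#' @export
print.rebound_metrics <- function(x, ...) {
  cat(sprintf(
    "Rebound: peak %.4f IU/mL at %.2f h after neutralization;\n",
    x$peak, x$t_peak))
  cat(sprintf("  24-h concentration %.4f IU/mL; %.2f h above %g IU/mL\n",
              x$conc_24h, x$time_above, x$threshold))
  invisible(x)
}

#' Compare protamine regimens by rebound metrics
#'
#' Simulates every regimen (plus the bolus-only baseline, added
#' automatically) for the same subject and returns one metrics row per
#' regimen.  The default regimen set is a 25 mg/h infusion for 6, 8, 12,
#' 16 and 24 h.  Use [plot_regimens()] on the result for the overlay of
#' baseline and infusion curves.
#'
#' @param history a [dosing_history()] with a neutralization time
#' @param params a [pk_params()] object
#' @param regimens list of [protamine_regimen()] objects (>= 2 including
#'   the baseline; the baseline is prepended if absent)
#' @param horizon,dt passed to [simulate_regimen()]
#' @param threshold passed to [rebound_metrics()]
#' @return an object of class `regimen_comparison`: `metrics` data frame
#'   (label, mode, rate, duration, peak, t_peak, conc_24h, time_above)
#'   and the simulated `profiles`
#' @export
compare_regimens <- function(history, params,
                             regimens = default_regimens(),
                             horizon = 48, dt = 0.01,
                             threshold = 0.02) {
  if (length(regimens) < 2)
    stop("supply at least two regimens to compare", call. = FALSE)
  has_baseline <- any(vapply(regimens, function(r)
    r$mode == "bolus_only", TRUE))
  if (!has_baseline)
    regimens <- c(list(protamine_regimen("bolus_only")), regimens)
  labels <- vapply(regimens, function(r)
    if (r$mode == "bolus_only") "bolus only"
    else sprintf("%g mg/h x %g h", r$rate, r$duration), "")
  profiles <- lapply(regimens, function(r)
    simulate_regimen(history, params, r, horizon = horizon, dt = dt))
  metrics <- do.call(rbind, lapply(seq_along(regimens), function(i) {
    m <- rebound_metrics(profiles[[i]], threshold = threshold)
    data.frame(label = labels[i], mode = regimens[[i]]$mode,
               rate = regimens[[i]]$rate,
               duration = regimens[[i]]$duration,
               peak = m$peak, t_peak = m$t_peak,
               conc_24h = m$conc_24h, time_above = m$time_above)
  }))
  structure(list(metrics = metrics, profiles = profiles,
                 labels = labels, threshold = threshold),
            class = "regimen_comparison")
}

#' Default protamine infusion regimen set
#'
#' A 25 mg/h continuous infusion lasting 6, 8, 12, 16 or 24 h, started
#' at the neutralization time.
#'
#' @return list of [protamine_regimen()] objects
#' @export
default_regimens <- function() {
  lapply(c(6, 8, 12, 16, 24), function(d)
    protamine_regimen("bolus_plus_infusion", rate = 25, duration = d))
}

#' @export
print.regimen_comparison <- function(x, ...) {
  cat("Protamine regimen comparison (rebound metrics):\n")
  tab <- x$metrics
  tab$peak <- signif(tab$peak, 3)
  tab$t_peak <- signif(tab$t_peak, 3)
  tab$conc_24h <- signif(tab$conc_24h, 3)
  tab$time_above <- signif(tab$time_above, 3)
  print(tab[, c("label", "peak", "t_peak", "conc_24h", "time_above")],
        row.names = FALSE)
  invisible(x)
}
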