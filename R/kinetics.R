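#' Compartment amounts after a single intravenous bolus
#'
#' Closed-form solution of the two-compartment disposition system with
#' initial condition `X_c(0) = D`, `X_p(0) = 0`:
#' \deqn{X_c(t) = D\frac{(\alpha - K_{21})e^{-\alpha t} +
#'   (K_{21}-\beta)e^{-\beta t}}{\alpha-\beta}, \qquad
#'   X_p(t) = D K_{12}\frac{e^{-\beta t} - e^{-\alpha t}}{\alpha-\beta}.}
#' When the hybrid rates coincide to within 1e-9 relative the limit forms
#' `D e^{-\lambda t}(1 + (K21-\lambda)t)` and `D K12 t e^{-\lambda t}` are
#' used instead to avoid cancellation.
#'
#' @param t time(s) since the dose, h (>= 0); vectorized
#' @param D dose amount, IU (> 0)
#' @param micro a [micro_constants()] object
#' @return a data frame of class `compartment_state` with columns `t`,
#'   `X_c`, `X_p` (amounts, IU)
#' @export
amounts_single_dose <- function(t, D, micro) {
  if (!inherits(micro, "micro_constants"))
    stop("'micro' must be a micro_constants object", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and nonnegative", call. = FALSE)
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("'D' must be a single positive dose", call. = FALSE)
  st <- .single_dose_amounts(t, D, micro)
  .compartment_state(t, st$X_c, st$X_p)
}

# core single-dose evaluator (no validation, reused by superposition)
.single_dose_amounts <- function(t, D, micro) {
  a <- micro$alpha; b <- micro$beta
  K21 <- micro$K21; K12 <- micro$K12
  if (.repeated_root(micro)) {
    lam <- (a + b) / 2
    el <- exp(-lam * t)
    list(X_c = D * el * (1 + (K21 - lam) * t),
         X_p = D * K12 * t * el)
  } else {
    ea <- exp(-a * t); eb <- exp(-b * t)
    list(X_c = D * ((a - K21) * ea + (K21 - b) * eb) / (a - b),
         X_p = D * K12 * (eb - ea) / (a - b))
  }
}

#' Compartment amounts under irregular multiple bolus dosing
#'
#' Superposition of single-dose solutions: each bolus `D_i` at time
#' `tau_i` contributes the shifted single-dose amounts for `t >= tau_i`
#' and nothing before.  A dose falling exactly at an evaluation time
#' contributes fully at that time (the state *after* the bolus, matching
#' the NONMEM event-record convention).
#'
#' @param t time(s), h (>= 0); vectorized
#' @param history a [dosing_history()] (its `t_neu`, if any, is ignored
#'   here; see [concentration()] for the piecewise model)
#' @param micro a [micro_constants()] object
#' @return a `compartment_state` data frame
#' @export
amounts_multidose <- function(t, history, micro) {
  if (!inherits(history, "dosing_history"))
    stop("'history' must be a dosing_history object", call. = FALSE)
  if (!inherits(micro, "micro_constants"))
    stop("'micro' must be a micro_constants object", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and nonnegative", call. = FALSE)
  X_c <- numeric(length(t)); X_p <- numeric(length(t))
  for (i in seq_along(history$times)) {
    on <- t >= history$times[i]
    if (!any(on)) next
    st <- .single_dose_amounts(t[on] - history$times[i],
                               history$amounts[i], micro)
    X_c[on] <- X_c[on] + st$X_c
    X_p[on] <- X_p[on] + st$X_p
  }
  .compartment_state(t, X_c, X_p)
}

#' Compartment amounts after protamine neutralization
#'
#' At the neutralization time `t_neu` the central amount is reset to zero
#' while the peripheral amount `B` is unaffected.  From that initial
#' condition the central compartment refills by back-distribution and
#' drains again (heparin rebound):
#' \deqn{X_c(t) = \frac{K_{21} B\,(e^{-\beta\tau} - e^{-\alpha\tau})}
#'   {\alpha-\beta}, \qquad
#'   X_p(t) = \frac{B\left[(\alpha-K_{21})e^{-\beta\tau} -
#'   (\beta-K_{21})e^{-\alpha\tau}\right]}{\alpha-\beta}}
#' with \eqn{\tau = t - t_{neu}}.  (Because \eqn{\alpha+\beta =
#' K_{10}+K_{12}+K_{21}}, exponents written as
#' \eqn{\beta - K_{10} - K_{12} - K_{21}} equal \eqn{-\alpha} and vice
#' versa; this is the simplified equivalent form.)
#'
#' @param t time(s), h, all `>= t_neu`; vectorized
#' @param B peripheral amount at neutralization, IU (>= 0)
#' @param t_neu neutralization time, h
#' @param micro a [micro_constants()] object
#' @return a `compartment_state` data frame
#' @export
amounts_post_neutralization <- function(t, B, t_neu, micro) {
  if (!inherits(micro, "micro_constants"))
    stop("'micro' must be a micro_constants object", call. = FALSE)
  if (any(!is.finite(t)) || any(t < t_neu))
    stop("'t' must be finite and >= t_neu", call. = FALSE)
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B < 0)
    stop("'B' must be a single nonnegative amount", call. = FALSE)
  st <- .post_neut_amounts(t - t_neu, B, micro)
  .compartment_state(t, st$X_c, st$X_p)
}

# tau = t - t_neu >= 0
.post_neut_amounts <- function(tau, B, micro) {
  a <- micro$alpha; b <- micro$beta; K21 <- micro$K21
  if (.repeated_root(micro)) {
    lam <- (a + b) / 2
    el <- exp(-lam * tau)
    list(X_c = K21 * B * tau * el,
         X_p = B * el * (1 + (lam - K21) * tau))
  } else {
    ea <- exp(-a * tau); eb <- exp(-b * tau)
    list(X_c = K21 * B * (eb - ea) / (a - b),
         X_p = B * ((a - K21) * eb - (b - K21) * ea) / (a - b))
  }
}

#' Plasma UFH concentration during and after CPB
#'
#' The piecewise time course of central-compartment concentration: bolus
#' superposition before the neutralization time and the
#' back-distribution (rebound) solution afterwards, with the central
#' amount dropping discontinuously to zero exactly at `t_neu`.
#' Amounts are IU, the central volume is L, and the returned activity is
#' IU/mL (one division by 1000 at this boundary).
#'
#' @param t time(s), h (>= 0); vectorized
#' @param history a [dosing_history()]; if it has no `t_neu` the
#'   pre-neutralization branch applies everywhere
#' @param params a [pk_params()] object
#' @return numeric vector of concentrations, IU/mL
#' @examples
#' h <- dosing_history(c(0, 0), c(24805, 8516), t_neu = 2.04)
#' p <- pk_params(CL = 1.18, V_c = 3.04, Q = 0.171, V_p = 8.01)
#' concentration(c(1, 2.04, 2.04 + c(2, 8, 24)), h, p)
#' @export
concentration <- function(t, history, params) {
  if (!inherits(history, "dosing_history"))
    stop("'history' must be a dosing_history object", call. = FALSE)
  if (!inherits(params, "pk_params"))
    stop("'params' must be a pk_params object", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and nonnegative", call. = FALSE)
  micro <- derive_micro(params)
  conc <- numeric(length(t))
  t_neu <- history$t_neu
  pre <- if (is.null(t_neu)) rep(TRUE, length(t)) else t < t_neu
  if (any(pre))
    conc[pre] <- amounts_multidose(t[pre], history, micro)$X_c
  if (any(!pre)) {
    B <- amounts_multidose(t_neu, history, micro)$X_p
    conc[!pre] <- .post_neut_amounts(t[!pre] - t_neu, B, micro)$X_c
  }
  conc / (params$V_c / params$F) / 1000
}

#' Concentration profile over a time grid
#'
#' Evaluates [concentration()] on a time grid and returns a
#' `concentration_profile` data frame with columns `time` (h) and `conc`
#' (IU/mL).
#'
#' @inheritParams concentration
#' @param times evaluation times, h (sorted ascending)
#' @return a data frame of class `concentration_profile`
#' @export
conc_profile <- function(times, history, params) {
  if (is.unsorted(times))
    stop("'times' must be sorted ascending", call. = FALSE)
  structure(data.frame(time = times,
                       conc = concentration(times, history, params)),
            class = c("concentration_profile", "data.frame"),
            t_neu = history$t_neu)
}

#' Heparin rebound peak after neutralization
#'
#' With peripheral amount `B` at the reset, the post-neutralization
#' central concentration is proportional to
#' \eqn{e^{-\beta\tau} - e^{-\alpha\tau}}, maximized at
#' \eqn{\tau^* = \ln(\alpha/\beta)/(\alpha-\beta)} (or \eqn{1/\lambda}
#' in the repeated-root limit).  Returns the continuous-time maximizer
#' and the concentration there; degenerate `B = 0` gives a zero peak at
#' `t_neu`.
#'
#' @param history a [dosing_history()] with a neutralization time
#' @param params a [pk_params()] object
#' @return list with elements `time` (h, absolute) and `conc` (IU/mL)
#' @export
rebound_peak <- function(history, params) {
  if (!inherits(history, "dosing_history"))
    stop("'history' must be a dosing_history object", call. = FALSE)
  if (is.null(history$t_neu))
    stop("rebound is undefined without a neutralization event",
         call. = FALSE)
  micro <- derive_micro(params)
  B <- amounts_multidose(history$t_neu, history, micro)$X_p
  if (B <= 0) return(list(time = history$t_neu, conc = 0))
  a <- micro$alpha; b <- micro$beta
  tau_star <- if (.repeated_root(micro)) 2 / (a + b) else
    log(a / b) / (a - b)
  t_star <- history$t_neu + tau_star
  list(time = t_star, conc = concentration(t_star, history, params))
}
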