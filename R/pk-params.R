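#' Structural pharmacokinetic parameters (clearance--volume form)
#'
#' A two-compartment intravenous model parameterized as clearances and
#' volumes: systemic clearance `CL` (L/h), central volume `V_c` (L),
#' inter-compartmental clearance `Q` (L/h) and peripheral volume `V_p` (L).
#' Bioavailability `F` is fixed at 1 for intravenous bolus dosing and kept
#' only so that concentrations read `X_c / (V_c / F)`.
#'
#' @param CL systemic clearance, L/h (> 0)
#' @param V_c central volume of distribution, L (> 0)
#' @param Q inter-compartmental clearance, L/h (>= 0)
#' @param V_p peripheral volume of distribution, L (> 0)
#' @param F bioavailability fraction; must be 1 (intravenous dosing)
#' @return an object of class `pk_params`
#' @seealso [derive_micro()]
#' @examples
#' p <- pk_params(CL = 1.18, V_c = 3.04, Q = 0.171, V_p = 8.01)
#' derive_micro(p)
#' @export
pk_params <- function(CL, V_c, Q, V_p, F = 1) {
  if (!is.numeric(CL) || length(CL) != 1L || !is.finite(CL) || CL <= 0)
    stop("'CL' must be a single positive number", call. = FALSE)
  if (!is.numeric(V_c) || length(V_c) != 1L || !is.finite(V_c) || V_c <= 0)
    stop("'V_c' must be a single positive number", call. = FALSE)
  if (!is.numeric(Q) || length(Q) != 1L || !is.finite(Q) || Q < 0)
    stop("'Q' must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(V_p) || length(V_p) != 1L || !is.finite(V_p) || V_p <= 0)
    stop("'V_p' must be a single positive number", call. = FALSE)
  if (!identical(as.numeric(F), 1))
    stop("'F' is fixed at 1 for intravenous bolus dosing", call. = FALSE)
  structure(list(CL = CL, V_c = V_c, Q = Q, V_p = V_p, F = 1),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment PK parameters (IV bolus):\n")
  cat(sprintf("  CL  = %g L/h\n  V_c = %g L\n  Q   = %g L/h\n  V_p = %g L\n",
              x$CL, x$V_c, x$Q, x$V_p))
  invisible(x)
}

#' Micro rate constants and hybrid rates of the two-compartment model
#'
#' Constructs the rate-constant form from first-order constants: `K10`
#' (elimination from central), `K12` (central to peripheral), `K21`
#' (peripheral to central), all 1/h.  The hybrid disposition rates are
#' \deqn{\alpha,\beta = \frac{(K_{10}+K_{12}+K_{21}) \pm
#'   \sqrt{(K_{10}+K_{12}+K_{21})^2 - 4K_{10}K_{21}}}{2},}
#' the eigenvalue magnitudes of the disposition matrix, satisfying
#' `alpha + beta == K10 + K12 + K21` and `alpha * beta == K10 * K21`.
#'
#' @param K10,K12,K21 first-order rate constants, 1/h (nonnegative)
#' @return an object of class `micro_constants` with fields `K10`, `K12`,
#'   `K21`, `alpha`, `beta`
#' @export
micro_constants <- function(K10, K12, K21) {
  for (nm in c("K10", "K12", "K21")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single nonnegative number", nm),
           call. = FALSE)
  }
  s <- K10 + K12 + K21
  disc <- s * s - 4 * K10 * K21
  disc <- sqrt(max(disc, 0))   # roundoff guard; analytically >= 0
  structure(list(K10 = K10, K12 = K12, K21 = K21,
                 alpha = (s + disc) / 2, beta = (s - disc) / 2),
            class = "micro_constants")
}

#' @export
print.micro_constants <- function(x, ...) {
  cat("Two-compartment micro constants (1/h):\n")
  cat(sprintf("  K10 = %g, K12 = %g, K21 = %g\n", x$K10, x$K12, x$K21))
  cat(sprintf("  alpha = %g, beta = %g\n", x$alpha, x$beta))
  invisible(x)
}

#' Derive micro constants from clearance--volume parameters
#'
#' Standard mapping `K10 = CL/V_c`, `K12 = Q/V_c`, `K21 = Q/V_p`, then the
#' hybrid rates alpha and beta of [micro_constants()].  The inverse map
#' (`CL = K10 V_c`, `Q = K21 V_p`) recovers the clearances exactly.
#'
#' @param params a [pk_params()] object
#' @return a [micro_constants()] object
#' @export
derive_micro <- function(params) {
  if (!inherits(params, "pk_params"))
    stop("'params' must be a pk_params object", call. = FALSE)
  micro_constants(K10 = params$CL / params$V_c,
                  K12 = params$Q / params$V_c,
                  K21 = params$Q / params$V_p)
}

# near-repeated hybrid roots: switch to the L'Hopital limit forms
.repeated_root <- function(micro, tol = 1e-9) {
  (micro$alpha - micro$beta) < tol * micro$alpha
}

#' Dosing history with an optional neutralization event
#'
#' An ordered record of intravenous UFH boluses plus, optionally, the time
#' `t_neu` at which circulating heparin is neutralized with excess
#' protamine (central compartment reset to zero).  All doses must precede
#' the neutralization: the piecewise model defines no dosing branch after
#' the reset.
#'
#' @param times bolus times, h (nondecreasing, >= 0)
#' @param amounts bolus amounts, IU (> 0), same length as `times`
#' @param t_neu optional neutralization time, h; when given, every dose
#'   time must be strictly smaller
#' @return an object of class `dosing_history`
#' @examples
#' dosing_history(c(0, 0), c(24805, 8516), t_neu = 2.04)
#' @export
dosing_history <- function(times = numeric(), amounts = numeric(),
                           t_neu = NULL) {
  times <- as.numeric(times); amounts <- as.numeric(amounts)
  if (length(times) != length(amounts))
    stop("'times' and 'amounts' must have equal length", call. = FALSE)
  if (length(times)) {
    if (any(!is.finite(times)) || any(times < 0))
      stop("dose times must be finite and nonnegative", call. = FALSE)
    if (is.unsorted(times))
      stop("dose times must be nondecreasing", call. = FALSE)
    if (any(!is.finite(amounts)) || any(amounts <= 0))
      stop("dose amounts must be positive", call. = FALSE)
  }
  if (!is.null(t_neu)) {
    if (!is.numeric(t_neu) || length(t_neu) != 1L || !is.finite(t_neu) ||
        t_neu <= 0)
      stop("'t_neu' must be a single positive time", call. = FALSE)
    if (length(times) && any(times >= t_neu))
      stop("all dose times must precede the neutralization time ",
           "(no dosing branch is defined after the reset)", call. = FALSE)
  }
  structure(list(times = times, amounts = amounts, t_neu = t_neu),
            class = "dosing_history")
}

#' @export
print.dosing_history <- function(x, ...) {
  cat(sprintf("Dosing history: %d bolus(es)", length(x$times)))
  if (length(x$times))
    cat(sprintf(" [%s IU at %s h]",
                paste(signif(x$amounts, 6), collapse = ", "),
                paste(signif(x$times, 4), collapse = ", ")))
  if (!is.null(x$t_neu))
    cat(sprintf("; neutralization at %g h", x$t_neu))
  cat("\n")
  invisible(x)
}

.compartment_state <- function(t, X_c, X_p) {
  structure(data.frame(t = t, X_c = X_c, X_p = X_p),
            class = c("compartment_state", "data.frame"))
}

#' Convert a heparin dose from mg to IU
#'
#' UFH labels state 1 mg = 125 IU, so the conventional 3 mg/kg loading
#' dose is 375 IU/kg and the 1 mg/kg pump-priming dose is 125 IU/kg.
#'
#' @param mg dose in milligrams (may be per kg)
#' @param iu_per_mg label conversion factor, default 125 IU/mg
#' @return dose in IU (same per-kg basis as the input)
#' @examples
#' ufh_dose_iu(3)   # 3 mg/kg loading dose -> 375 IU/kg
#' @export
ufh_dose_iu <- function(mg, iu_per_mg = 125) {
  stopifnot(is.numeric(mg), is.numeric(iu_per_mg), iu_per_mg > 0)
  mg * iu_per_mg
}
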