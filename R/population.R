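#' Population pharmacokinetic model
#'
#' Typical-value parameters plus the random-effect structure: exponential
#' (log-normal) inter-individual variability `P_i = P_pop * exp(eta_i)`,
#' `eta_i ~ N(0, omega2)` per parameter with a diagonal variance matrix,
#' and a hybrid residual model `C_obs = C_pred*(1 + eps1) + eps2` with
#' `eps1 ~ N(0, sigma2_pro)` and `eps2 ~ N(0, sigma2_add)`.  Variance
#' components set to 0 are treated as fixed at zero (no random effect /
#' no additive error term).
#'
#' @param CL,V_c,Q,V_p typical-value (population) structural parameters;
#'   see [pk_params()]
#' @param omega2 named numeric vector of inter-individual variances on
#'   the log scale for a subset of `c("CL","V_c","Q","V_p")`; omitted
#'   parameters get 0
#' @param sigma2_pro proportional residual variance (dimensionless)
#' @param sigma2_add additive residual variance, (IU/mL)^2
#' @param covariates list of [covariate_effect()] objects
#' @return an object of class `population_model`
#' @examples
#' ufh_reference_model()
#' @export
population_model <- function(CL, V_c, Q, V_p,
                             omega2 = c(CL = 0, V_c = 0, Q = 0, V_p = 0),
                             sigma2_pro = 0, sigma2_add = 0,
                             covariates = list()) {
  theta <- c(CL = CL, V_c = V_c, Q = Q, V_p = V_p)
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("typical values must all be positive and finite", call. = FALSE)
  om <- c(CL = 0, V_c = 0, Q = 0, V_p = 0)
  if (length(omega2)) {
    if (is.null(names(omega2)) || !all(names(omega2) %in% names(om)))
      stop("'omega2' must be named with a subset of CL, V_c, Q, V_p",
           call. = FALSE)
    om[names(omega2)] <- omega2
  }
  if (any(!is.finite(om)) || any(om < 0))
    stop("'omega2' entries must be nonnegative", call. = FALSE)
  if (!is.finite(sigma2_pro) || sigma2_pro < 0 ||
      !is.finite(sigma2_add) || sigma2_add < 0)
    stop("residual variances must be nonnegative", call. = FALSE)
  if (!is.list(covariates) ||
      !all(vapply(covariates, inherits, TRUE, "covariate_effect")))
    stop("'covariates' must be a list of covariate_effect objects",
         call. = FALSE)
  structure(list(theta = theta, omega2 = om, sigma2_pro = sigma2_pro,
                 sigma2_add = sigma2_add, covariates = covariates),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (two-compartment IV, exponential IIV,",
      "hybrid residual)\n")
  tab <- rbind(theta = x$theta, omega2 = x$omega2)
  print(signif(tab, 4))
  cat(sprintf("sigma2_pro = %g, sigma2_add = %g\n",
              x$sigma2_pro, x$sigma2_add))
  if (length(x$covariates)) {
    cat("Covariate effects:\n")
    for (ce in x$covariates)
      cat(sprintf("  %s on %s (%s), coefficient %g\n",
                  ce$covariate, ce$parameter, ce$kind, ce$coefficient))
  }
  invisible(x)
}

#' Reference adult CPB population model
#'
#' The published final population estimates for UFH in adult CPB patients
#' that the synthetic trials in this package emulate: CL 1.18 L/h, V_c
#' 3.04 L, Q 0.171 L/h, V_p 8.01 L; inter-individual variances 0.122
#' (CL), 0.105 (V_c), 0.0978 (Q), 0 fixed (V_p); proportional residual
#' variance 0.139 with the additive component fixed at 0.
#'
#' @return a [population_model()]
#' @export
ufh_reference_model <- function() {
  population_model(CL = 1.18, V_c = 3.04, Q = 0.171, V_p = 8.01,
                   omega2 = c(CL = 0.122, V_c = 0.105, Q = 0.0978,
                              V_p = 0),
                   sigma2_pro = 0.139, sigma2_add = 0)
}

#' Covariate effect on a structural parameter
#'
#' Continuous covariates (body weight, age) act linearly:
#' `P_i = P_pop * (1 + coefficient * (reference - COV_i))`, centred on a
#' reference value (typically the sample mean); the coefficient is signed.
#' Categorical covariates (sex) act conditionally:
#' `P_i = P_pop * coefficient^COV_i`, i.e. multiplier 1 at the reference
#' level (male, coded 0) and `coefficient` otherwise.
#'
#' @param parameter target structural parameter, one of `"CL"`, `"V_c"`,
#'   `"Q"`, `"V_p"`
#' @param covariate covariate name, one of `"weight"`, `"age"`, `"sex"`
#' @param kind `"continuous"` or `"categorical"`
#' @param coefficient signed slope (continuous) or positive multiplier
#'   (categorical)
#' @param reference centring value for continuous covariates (e.g. the
#'   sample mean); ignored for categorical
#' @return an object of class `covariate_effect`
#' @export
covariate_effect <- function(parameter, covariate,
                             kind = c("continuous", "categorical"),
                             coefficient = 0, reference = NULL) {
  kind <- match.arg(kind)
  parameter <- match.arg(parameter, c("CL", "V_c", "Q", "V_p"))
  covariate <- match.arg(covariate, c("weight", "age", "sex"))
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      !is.finite(coefficient))
    stop("'coefficient' must be a single finite number", call. = FALSE)
  if (kind == "categorical") {
    if (coefficient <= 0)
      stop("categorical multiplier must be positive", call. = FALSE)
    reference <- NULL
  } else {
    if (is.null(reference))
      stop("continuous covariate effects need a 'reference' value",
           call. = FALSE)
    if (!is.numeric(reference) || length(reference) != 1L ||
        !is.finite(reference))
      stop("'reference' must be a single finite number", call. = FALSE)
  }
  structure(list(parameter = parameter, covariate = covariate,
                 kind = kind, coefficient = coefficient,
                 reference = reference),
            class = "covariate_effect")
}

#' Subject covariates
#'
#' @param weight body weight, kg (> 0)
#' @param age age, years (> 0)
#' @param sex 0 for male, 1 for female
#' @return an object of class `subject_covariates`
#' @export
subject_covariates <- function(weight, age, sex) {
  if (!is.numeric(weight) || weight <= 0 || !is.finite(weight))
    stop("'weight' must be positive", call. = FALSE)
  if (!is.numeric(age) || age <= 0 || !is.finite(age))
    stop("'age' must be positive", call. = FALSE)
  if (!sex %in% c(0, 1))
    stop("'sex' must be 0 (male) or 1 (female)", call. = FALSE)
  structure(list(weight = weight, age = age, sex = sex),
            class = "subject_covariates")
}

# multiplier each covariate effect contributes for one subject
.covariate_multipliers <- function(pop, cov) {
  mult <- c(CL = 1, V_c = 1, Q = 1, V_p = 1)
  for (ce in pop$covariates) {
    v <- cov[[ce$covariate]]
    m <- if (ce$kind == "continuous")
      1 + ce$coefficient * (ce$reference - v)
    else if (v == 0) 1 else ce$coefficient
    mult[ce$parameter] <- mult[ce$parameter] * m
  }
  mult
}

#' Individual parameters from the population model
#'
#' Applies covariate multipliers and the exponential random effects:
#' `P_i = P_pop * covariate multipliers * exp(eta)`.  A covariate effect
#' that drives any parameter to zero or below is a model-validity error.
#'
#' @param pop a [population_model()]
#' @param cov a [subject_covariates()] object
#' @param eta named numeric vector of random effects for a subset of
#'   `c("CL","V_c","Q","V_p")`; omitted entries are 0
#' @return a [pk_params()] object
#' @examples
#' pop <- ufh_reference_model()
#' individual_parameters(pop, subject_covariates(66, 53.4, 0))
#' @export
individual_parameters <- function(pop, cov, eta = numeric()) {
  if (!inherits(pop, "population_model"))
    stop("'pop' must be a population_model", call. = FALSE)
  if (!inherits(cov, "subject_covariates"))
    stop("'cov' must be a subject_covariates object", call. = FALSE)
  e <- c(CL = 0, V_c = 0, Q = 0, V_p = 0)
  if (length(eta)) {
    if (is.null(names(eta)) || !all(names(eta) %in% names(e)))
      stop("'eta' must be named with a subset of CL, V_c, Q, V_p",
           call. = FALSE)
    if (any(!is.finite(eta)))
      stop("'eta' must be finite", call. = FALSE)
    e[names(eta)] <- eta
  }
  mult <- .covariate_multipliers(pop, cov)
  if (any(mult <= 0))
    stop("covariate effect drives a parameter to a nonpositive value",
         call. = FALSE)
  p <- pop$theta * mult * exp(e)
  pk_params(CL = p[["CL"]], V_c = p[["V_c"]], Q = p[["Q"]],
            V_p = p[["V_p"]])
}

#' Hybrid residual error model
#'
#' `C_obs = C_pred * (1 + eps1) + eps2`; at a given prediction the
#' observation variance is `sigma2_pro * C_pred^2 + sigma2_add`.
#' Negative results are possible and retained; censoring against the
#' assay window is the assay model's job ([assay_observe()]).
#'
#' @param c_pred predicted concentration(s), IU/mL (>= 0)
#' @param eps1 proportional error draw(s), dimensionless
#' @param eps2 additive error draw(s), IU/mL
#' @return observed concentration(s), IU/mL
#' @export
apply_residual <- function(c_pred, eps1, eps2) {
  if (any(c_pred < 0))
    stop("'c_pred' must be nonnegative", call. = FALSE)
  c_pred * (1 + eps1) + eps2
}

# draw per-subject random effects for parameters with omega2 > 0
.draw_eta <- function(pop) {
  idx <- pop$omega2 > 0
  e <- setNames(numeric(sum(idx)), names(pop$omega2)[idx])
  if (length(e)) e[] <- rnorm(length(e), 0, sqrt(pop$omega2[idx]))
  e
}
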