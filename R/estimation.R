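#' Control settings for FOCE estimation
#'
#' @param outer_rel_tol relative objective-function tolerance of the
#'   outer (population) optimization
#' @param inner_rel_tol relative tolerance of the per-subject empirical
#'   Bayes optimization
#' @param outer_iter_max,outer_eval_max outer iteration/evaluation caps
#' @param se_rel_step relative step of the central-difference Hessian
#'   used for standard errors
#' @return a list of class `foce_control`
#' @export
foce_control <- function(outer_rel_tol = 1e-6, inner_rel_tol = 1e-8,
                         outer_iter_max = 300, outer_eval_max = 1200,
                         se_rel_step = 1e-4) {
  structure(list(outer_rel_tol = outer_rel_tol,
                 inner_rel_tol = inner_rel_tol,
                 outer_iter_max = outer_iter_max,
                 outer_eval_max = outer_eval_max,
                 se_rel_step = se_rel_step),
            class = "foce_control")
}

# ---- dataset preparation -------------------------------------------------

# Precompute per-subject structures for fast repeated likelihood
# evaluation.  Observations flagged BLQ are discarded (M1 convention).
.split_subjects <- function(dataset, drop_blq = TRUE) {
  dataset <- as_trial_dataset(dataset)
  ids <- unique(dataset$ID)
  lapply(ids, function(id) {
    d <- dataset[dataset$ID == id, , drop = FALSE]
    dose <- d[d$EVID == 1L, , drop = FALSE]
    t_neu <- d$TIME[d$EVID == 2L]
    obs <- d[d$EVID == 0L, , drop = FALSE]
    if (drop_blq) obs <- obs[obs$BLQ == 0L, , drop = FALSE]
    obs <- obs[is.finite(obs$DV), , drop = FALSE]
    o <- order(obs$TIME)
    t_obs <- obs$TIME[o]; y <- obs$DV[o]
    pre <- t_obs < t_neu
    tau <- dose$TIME; D <- dose$AMT
    DTpre <- outer(t_obs[pre], tau, "-")
    DTpre[DTpre < 0] <- Inf   # future doses: exp(-rate*Inf) = 0
    list(id = id, y = y, t_obs = t_obs, n = length(y),
         tau = tau, D = D, t_neu = t_neu,
         pre = pre, DTpre = DTpre,
         dtn = t_neu - tau, tau_post = t_obs[!pre] - t_neu,
         cov = list(weight = d$WT[1], age = d$AGE[1], sex = d$SEX[1]),
         rows = d)
  })
}

# fast central-concentration evaluator on a subject structure; returns
# predictions in the subject's observation order (pre block, post block)
.conc_subject <- function(st, CL, V_c, Q, V_p) {
  K10 <- CL / V_c; K12 <- Q / V_c; K21 <- Q / V_p
  s <- K10 + K12 + K21
  disc <- sqrt(max(s * s - 4 * K10 * K21, 0))
  a <- (s + disc) / 2; b <- (s - disc) / 2
  if (a - b < 1e-12) a <- b + 1e-12     # unreachable physiologically
  f <- numeric(st$n)
  if (any(st$pre)) {
    Sa <- exp(-a * st$DTpre) %*% st$D
    Sb <- exp(-b * st$DTpre) %*% st$D
    f[st$pre] <- ((a - K21) * Sa + (K21 - b) * Sb) / (a - b)
  }
  if (any(!st$pre)) {
    B <- K12 * sum(st$D * (exp(-b * st$dtn) - exp(-a * st$dtn))) / (a - b)
    f[!st$pre] <- K21 * B *
      (exp(-b * st$tau_post) - exp(-a * st$tau_post)) / (a - b)
  }
  f / V_c / 1000
}

# individual parameters for a subject structure given eta over est_names
.subject_params <- function(st, pop, eta, est_names) {
  mult <- .covariate_multipliers(pop, st$cov)
  p <- pop$theta * mult
  if (length(est_names)) p[est_names] <- p[est_names] * exp(eta)
  p
}

.BIG <- 1e10

# FOCE-with-interaction contribution of one subject.
# Returns ofv, empirical Bayes eta, and linearization pieces for CWRES.
.subject_foce <- function(st, pop, eta0, inner_rel_tol = 1e-8,
                          want_lin = FALSE) {
  est_names <- names(pop$omega2)[pop$omega2 > 0]
  k <- length(est_names)
  om <- pop$omega2[est_names]
  s1 <- pop$sigma2_pro; s2 <- pop$sigma2_add
  # covariate multipliers are eta-free: assemble the subject's base
  # parameters once, outside the inner-optimization hot path
  base <- unname(pop$theta * .covariate_multipliers(pop, st$cov))
  est_idx <- match(est_names, names(pop$theta))
  f_eta <- function(eta) {
    p <- base
    p[est_idx] <- p[est_idx] * exp(eta)
    if (any(!is.finite(p)) || any(p <= 0)) return(NULL)
    .conc_subject(st, p[1], p[2], p[3], p[4])
  }
  if (any(!is.finite(base)) || any(base <= 0))
    return(list(ofv = .BIG, eta = setNames(numeric(k), est_names)))
  if (st$n == 0L)
    return(list(ofv = 0, eta = setNames(numeric(k), est_names)))

  if (k == 0L) {
    f <- f_eta(numeric(0))
    if (is.null(f)) return(list(ofv = .BIG, eta = numeric(0)))
    v <- s1 * f^2 + s2
    if (any(v <= 0))
      stop(sprintf(
        "zero residual variance at observation (subject %s, time %g)",
        st$id, st$t_obs[which(v <= 0)[1]]), call. = FALSE)
    r <- st$y - f
    out <- list(ofv = sum(log(2 * pi) + log(v) + r^2 / v),
                eta = numeric(0))
    if (want_lin) {
      out$f <- f; out$v <- v
      out$cwres <- r / sqrt(v)
    }
    return(out)
  }

  # inner: penalized (joint) -2 log-likelihood in eta, constants dropped
  q <- function(eta) {
    f <- f_eta(eta)
    if (is.null(f)) return(.BIG)
    v <- s1 * f^2 + s2
    if (any(v <= 0) || any(!is.finite(v))) return(.BIG)
    sum(log(v) + (st$y - f)^2 / v) + sum(eta^2 / om)
  }
  eta_hat <- .inner_newton(st, f_eta, q, eta0, om, s1, s2,
                           tol = inner_rel_tol)
  f <- f_eta(eta_hat)
  if (is.null(f))
    return(list(ofv = .BIG, eta = setNames(eta_hat, est_names)))
  v <- s1 * f^2 + s2
  if (any(v <= 0))
    stop(sprintf(
      "zero residual variance at observation (subject %s, time %g)",
      st$id, st$t_obs[which(v <= 0)[1]]), call. = FALSE)

  # linearize f about eta_hat (central differences)
  G <- matrix(0, st$n, k)
  h <- 1e-4
  for (j in seq_len(k)) {
    ep <- eta_hat; ep[j] <- ep[j] + h
    em <- eta_hat; em[j] <- em[j] - h
    fp <- f_eta(ep); fm <- f_eta(em)
    if (is.null(fp) || is.null(fm))
      return(list(ofv = .BIG, eta = setNames(eta_hat, est_names)))
    G[, j] <- (fp - fm) / (2 * h)
  }
  r <- st$y - f + drop(G %*% eta_hat)
  V <- diag(v, st$n) + G %*% (om * t(G))
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R))
    return(list(ofv = .BIG, eta = setNames(eta_hat, est_names)))
  z <- backsolve(R, r, transpose = TRUE)
  out <- list(ofv = st$n * log(2 * pi) + 2 * sum(log(diag(R))) +
                sum(z^2),
              eta = setNames(eta_hat, est_names))
  if (want_lin) {
    out$f <- f; out$v <- v; out$G <- G
    out$cwres <- z
  }
  out
}

# Empirical Bayes mode by damped Gauss-Newton with a gradient-norm stop.
# Solving the inner problem to a stationary point (not a
# function-decrease heuristic) makes the outer objective a smooth,
# path-independent function of the population parameters, which the
# quasi-Newton outer optimizer requires.  Falls back to nlminb if the
# Gauss-Newton direction stalls.
.inner_newton <- function(st, f_eta, q, eta0, om, s1, s2,
                          tol = 1e-8, max_iter = 60) {
  k <- length(om)
  eta <- eta0
  qcur <- q(eta)
  if (qcur >= .BIG) {
    eta <- rep(0, k)
    qcur <- q(eta)
    if (qcur >= .BIG) return(eta)
  }
  h <- 1e-5
  for (it in seq_len(max_iter)) {
    f <- f_eta(eta)
    if (is.null(f)) break
    v <- s1 * f^2 + s2
    if (any(v <= 0)) break
    G <- matrix(0, st$n, k)
    for (j in seq_len(k)) {
      ep <- eta; ep[j] <- ep[j] + h
      em <- eta; em[j] <- em[j] - h
      fp <- f_eta(ep); fm <- f_eta(em)
      if (is.null(fp) || is.null(fm)) return(eta)
      G[, j] <- (fp - fm) / (2 * h)
    }
    r <- st$y - f
    w <- 2 * s1 * f / v - 2 * r / v - 2 * s1 * f * r^2 / v^2
    grad <- drop(crossprod(G, w)) + 2 * eta / om
    if (sum(grad^2) < tol^2) return(eta)
    H <- 2 * crossprod(G, G / v) + diag(2 / om, k)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      qn <- q(eta - lam * step)
      if (qn <= qcur + 1e-10 || lam < 1e-6) break
      lam <- lam / 2
    }
    if (qn > qcur + 1e-10) break   # no progress along the direction
    eta <- eta - lam * step
    qcur <- qn
  }
  # fallback: generic quasi-Newton from the best point found
  opt <- nlminb(eta, q, control = list(rel.tol = 1e-12, iter.max = 300))
  opt$par
}

#' FOCE objective function value
#'
#' Minus twice the approximate log marginal likelihood of the population
#' model given the dataset, by first-order conditional estimation with
#' interaction: per subject, the random effects are set to their
#' empirical Bayes mode, the prediction is linearized there, and the
#' marginal Gaussian likelihood of the linearized model (residual
#' variance evaluated at the individual prediction) is accumulated.  The
#' `log(2*pi)` constants are included, so small closed-form cases match
#' textbook normal likelihoods exactly; differences in OFV are unaffected
#' by the convention.
#'
#' The value is additive over subjects and invariant to subject
#' relabeling or reordering.
#'
#' @param dataset a `trial_dataset` (see [generate_trial()],
#'   [read_dataset()])
#' @param pop a [population_model()]
#' @param control a [foce_control()]
#' @return the objective function value (dimensionless)
#' @export
ofv <- function(dataset, pop, control = foce_control()) {
  structs <- .split_subjects(dataset)
  est_names <- names(pop$omega2)[pop$omega2 > 0]
  eta0 <- setNames(numeric(length(est_names)), est_names)
  sum(vapply(structs, function(st)
    .subject_foce(st, pop, eta0, control$inner_rel_tol)$ofv, 0))
}

# ---- parameter packing ---------------------------------------------------

# Parameters with positive initial variance are estimated (log scale);
# zero-variance components stay fixed at zero.  'fixed' lists additional
# names to hold at their initial values: structural ("CL", "V_c", "Q",
# "V_p"), variances ("omega2_CL", ..., "sigma2_pro", "sigma2_add") or
# covariate coefficients ("beta_<param>_<covariate>").
.pack_spec <- function(pop, fixed = character()) {
  spec <- list()
  for (nm in names(pop$theta))
    if (!nm %in% fixed)
      spec[[paste0("theta_", nm)]] <-
        list(kind = "theta", name = nm, trans = "log")
  for (i in seq_along(pop$covariates)) {
    ce <- pop$covariates[[i]]
    lbl <- paste0("beta_", ce$parameter, "_", ce$covariate)
    if (!lbl %in% fixed)
      spec[[lbl]] <- list(kind = "cov", index = i,
                          trans = if (ce$kind == "categorical")
                            "log" else "identity")
  }
  for (nm in names(pop$omega2))
    if (pop$omega2[nm] > 0 && !paste0("omega2_", nm) %in% fixed)
      spec[[paste0("omega2_", nm)]] <-
        list(kind = "omega2", name = nm, trans = "log")
  if (pop$sigma2_pro > 0 && !"sigma2_pro" %in% fixed)
    spec[["sigma2_pro"]] <- list(kind = "sigma2_pro", trans = "log")
  if (pop$sigma2_add > 0 && !"sigma2_add" %in% fixed)
    spec[["sigma2_add"]] <- list(kind = "sigma2_add", trans = "log")
  spec
}

.pop_value <- function(pop, s) {
  switch(s$kind,
         theta = pop$theta[[s$name]],
         cov = pop$covariates[[s$index]]$coefficient,
         omega2 = pop$omega2[[s$name]],
         sigma2_pro = pop$sigma2_pro,
         sigma2_add = pop$sigma2_add)
}

.pop_assign <- function(pop, s, value) {
  switch(s$kind,
         theta = pop$theta[[s$name]] <- value,
         cov = pop$covariates[[s$index]]$coefficient <- value,
         omega2 = pop$omega2[[s$name]] <- value,
         sigma2_pro = pop$sigma2_pro <- value,
         sigma2_add = pop$sigma2_add <- value)
  pop
}

.pack <- function(pop, spec) {
  vapply(spec, function(s) {
    v <- .pop_value(pop, s)
    if (s$trans == "log") log(v) else v
  }, 0)
}

.unpack <- function(par, pop, spec) {
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    v <- unname(if (s$trans == "log") exp(par[i]) else par[i])
    pop <- .pop_assign(pop, s, v)
  }
  pop
}

.pack_natural <- function(pop, spec)
  vapply(spec, function(s) .pop_value(pop, s), 0)

.unpack_natural <- function(x, pop, spec) {
  for (i in seq_along(spec))
    pop <- .pop_assign(pop, spec[[i]], unname(x[i]))
  pop
}

# ---- fitting -------------------------------------------------------------

#' Fit the population model by FOCE
#'
#' Maximizes the FOCE-approximated marginal likelihood (minimizes
#' [ofv()]) over the typical values, covariate coefficients and variance
#' components.  Structural parameters and variances are optimized on the
#' log scale; continuous covariate coefficients on the natural scale.
#' Variance components initialized at zero (`omega2` entries, or
#' `sigma2_add`) are held fixed at zero, matching the convention of
#' reporting them as "0 (FIX)".  Per-subject empirical Bayes etas are
#' warm-started across outer iterations.
#'
#' Standard errors come from the inverse central-difference Hessian of
#' OFV/2 with respect to the natural-scale parameters; when that Hessian
#' is not positive definite the fit is still returned with the standard
#' errors marked unavailable.
#'
#' @param dataset a `trial_dataset`
#' @param pop_init a [population_model()] holding the initial values
#' @param fixed character vector of parameter labels to hold at their
#'   initial values (e.g. `"sigma2_pro"`, `"V_p"`,
#'   `"beta_CL_weight"`)
#' @param control a [foce_control()]
#' @param compute_se compute standard errors (adds one Hessian
#'   evaluation, which can dominate run time on large datasets)
#' @return an object of class `fit_result`: final `pop`, `theta`,
#'   `omega2`, `sigma2`, `coefficients`, `ofv`, `se`, `rse` (percent),
#'   per-subject `eta` matrix, `convergence` diagnostics and `vcov`
#' @examples
#' \donttest{
#' tr <- generate_trial(trial_config(n_subjects = 12), ufh_reference_model(),
#'                      seed = 7)
#' fit <- foce_fit(tr, ufh_reference_model(), compute_se = FALSE)
#' fit
#' }
#' @export
foce_fit <- function(dataset, pop_init, fixed = character(),
                     control = foce_control(), compute_se = TRUE) {
  if (!inherits(pop_init, "population_model"))
    stop("'pop_init' must be a population_model", call. = FALSE)
  structs <- .split_subjects(dataset)
  n_obs <- sum(vapply(structs, function(s) s$n, 0L))
  spec <- .pack_spec(pop_init, fixed)
  if (n_obs < length(spec))
    stop("fewer observations than estimated parameters", call. = FALSE)
  est_names <- names(pop_init$omega2)[pop_init$omega2 > 0]
  k <- length(est_names)

  # warm-started empirical Bayes etas
  eta_store <- matrix(0, length(structs), k)
  total_ofv <- function(pop) {
    tot <- 0
    for (i in seq_along(structs)) {
      res <- .subject_foce(structs[[i]], pop, eta_store[i, ],
                           control$inner_rel_tol)
      eta_store[i, ] <<- res$eta
      tot <- tot + res$ofv
    }
    tot
  }
  objective <- function(par) {
    pop <- .unpack(par, pop_init, spec)
    v <- tryCatch(total_ofv(pop), error = function(e) .BIG)
    if (!is.finite(v)) .BIG else v
  }

  # outer quasi-Newton with restarts: PORT can report false convergence
  # on nested-optimization surfaces well before stationarity, so rerun
  # from the incumbent until the OFV stabilizes
  par <- .pack(pop_init, spec)
  last <- Inf; iters <- 0L; evals <- 0L; opt <- NULL
  for (round in seq_len(8L)) {
    opt <- nlminb(par, objective,
                  control = list(rel.tol = control$outer_rel_tol,
                                 iter.max = control$outer_iter_max,
                                 eval.max = control$outer_eval_max))
    par <- opt$par
    iters <- iters + opt$iterations
    evals <- evals + opt$evaluations[["function"]]
    stabilized <- last - opt$objective < 1e-4
    last <- opt$objective
    if (opt$convergence == 0 || stabilized) break
  }
  converged <- opt$convergence == 0 || stabilized
  pop_hat <- .unpack(par, pop_init, spec)

  # final pass: exact OFV, empirical Bayes etas at the optimum
  eta_hat <- matrix(0, length(structs), k,
                    dimnames = list(vapply(structs, function(s)
                      as.character(s$id), ""), est_names))
  ofv_final <- 0
  for (i in seq_along(structs)) {
    res <- .subject_foce(structs[[i]], pop_hat, eta_store[i, ],
                         control$inner_rel_tol)
    eta_hat[i, ] <- res$eta
    ofv_final <- ofv_final + res$ofv
  }

  est_nat <- .pack_natural(pop_hat, spec)
  se <- rep(NA_real_, length(spec))
  vcov <- NULL
  se_note <- if (compute_se) NULL else "standard errors not requested"
  if (compute_se && length(spec)) {
    H <- tryCatch(
      .ofv_hessian(function(x) {
        pop <- .unpack_natural(x, pop_init, spec)
        tryCatch(total_ofv(pop) / 2, error = function(e) .BIG)
      }, est_nat, rel_step = control$se_rel_step),
      error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc) && all(is.finite(diag(vc))) &&
          all(diag(vc) > 0)) {
        vcov <- vc
        se <- sqrt(diag(vc))
      } else {
        se_note <- "Hessian not positive definite; SEs unavailable"
      }
    } else {
      se_note <- "Hessian evaluation failed; SEs unavailable"
    }
  }
  names(se) <- names(spec)
  rse <- ifelse(est_nat != 0, 100 * se / abs(est_nat), NA_real_)

  structure(list(
    pop = pop_hat,
    theta = pop_hat$theta,
    omega2 = pop_hat$omega2,
    sigma2 = c(pro = pop_hat$sigma2_pro, add = pop_hat$sigma2_add),
    coefficients = setNames(est_nat, names(spec)),
    ofv = ofv_final,
    se = se, rse = setNames(rse, names(spec)), vcov = vcov,
    eta = eta_hat,
    n_subjects = length(structs), n_obs = n_obs,
    convergence = list(code = opt$convergence,
                       message = opt$message,
                       iterations = iters,
                       evaluations = evals,
                       converged = converged,
                       se_note = se_note),
    fixed = fixed, spec = spec), class = "fit_result")
}

# central-difference Hessian of a scalar function (OFV/2), relative step
.ofv_hessian <- function(fn, x, rel_step = 1e-4) {
  p <- length(x)
  h <- rel_step * pmax(abs(x), 1e-4)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      H[i, j] <- H[j, i] <-
        (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Evaluate a model on a dataset without re-estimating
#'
#' Computes the FOCE objective and per-subject empirical Bayes random
#' effects at fixed population parameters, returning a `fit_result`
#' usable with [gof_table()].  Useful for diagnostics at known
#' (e.g. simulation-true) parameter values.
#'
#' @inheritParams foce_fit
#' @param pop a [population_model()]
#' @return a `fit_result` with `convergence$message = "evaluated"`
#' @export
eval_model <- function(dataset, pop, control = foce_control()) {
  structs <- .split_subjects(dataset)
  est_names <- names(pop$omega2)[pop$omega2 > 0]
  k <- length(est_names)
  eta_hat <- matrix(0, length(structs), k,
                    dimnames = list(vapply(structs, function(s)
                      as.character(s$id), ""), est_names))
  total <- 0
  for (i in seq_along(structs)) {
    res <- .subject_foce(structs[[i]], pop, rep(0, k),
                         control$inner_rel_tol)
    eta_hat[i, ] <- res$eta
    total <- total + res$ofv
  }
  spec <- .pack_spec(pop)
  structure(list(
    pop = pop, theta = pop$theta, omega2 = pop$omega2,
    sigma2 = c(pro = pop$sigma2_pro, add = pop$sigma2_add),
    coefficients = setNames(.pack_natural(pop, spec), names(spec)),
    ofv = total, se = NULL, rse = NULL, vcov = NULL, eta = eta_hat,
    n_subjects = length(structs),
    n_obs = sum(vapply(structs, function(s) s$n, 0L)),
    convergence = list(code = 0, message = "evaluated",
                       iterations = 0, evaluations = 0,
                       converged = TRUE, se_note = NULL),
    fixed = character(), spec = spec), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("FOCE fit:", x$n_subjects, "subjects,", x$n_obs, "observations\n")
  cat(sprintf("OFV = %.3f (%s, %d iterations)\n", x$ofv,
              if (isTRUE(x$convergence$converged)) "converged"
              else paste("NOT converged:", x$convergence$message),
              x$convergence$iterations))
  est <- x$coefficients
  tab <- data.frame(estimate = signif(est, 4))
  if (!is.null(x$se) && length(x$se) == length(est)) {
    tab$se <- signif(x$se, 3)
    tab$`rse%` <- signif(x$rse, 3)
  }
  print(tab)
  if (!is.null(x$convergence$se_note))
    cat("note:", x$convergence$se_note, "\n")
  invisible(x)
}

#' Chi-squared OFV threshold for covariate selection
#'
#' Critical value of the chi-squared distribution used to judge a change
#' in objective function when one parameter is added or removed:
#' `qchisq(1 - p, df)`.  At `df = 1` this is 6.63 for p = 0.01 (forward
#' inclusion) and 10.83 for p = 0.001 (backward elimination).
#'
#' @param p significance level
#' @param df degrees of freedom (parameters added/removed)
#' @return the OFV threshold
#' @export
ofv_threshold <- function(p, df = 1) qchisq(1 - p, df)
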