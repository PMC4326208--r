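#' Nonparametric bootstrap of the population model
#'
#' Resamples subjects with replacement to the original subject count,
#' refits the model on each replicate, and summarizes the replicate
#' estimates by their median and percentile interval at the requested
#' coverage.  Replicates whose fit throws an error or returns non-finite
#' estimates are counted as minimization failures and excluded from the
#' summaries -- never silently dropped.
#'
#' @param dataset a `trial_dataset`
#' @param pop_init a [population_model()] of initial values (typically
#'   the final estimates)
#' @param n_rep number of bootstrap replicates (default 1000)
#' @param coverage interval coverage in (0, 1); default 0.95, with 0.90
#'   also conventional
#' @param seed integer seed for the resampling
#' @param fixed,control passed to [foce_fit()]
#' @return an object of class `bootstrap_result`: `estimates` (replicate
#'   x parameter matrix with failed rows `NA`), `median`, `lower`,
#'   `upper`, `coverage`, `n_success`, `n_fail`
#' @export
bootstrap_model <- function(dataset, pop_init, n_rep = 1000,
                            coverage = 0.95, seed = 1,
                            fixed = character(),
                            control = foce_control()) {
  if (n_rep < 1) stop("'n_rep' must be at least 1", call. = FALSE)
  if (coverage <= 0 || coverage >= 1)
    stop("'coverage' must be strictly between 0 and 1", call. = FALSE)
  dataset <- as_trial_dataset(dataset)
  ids <- unique(dataset$ID)
  spec <- .pack_spec(pop_init, fixed)
  set.seed(seed)
  est <- matrix(NA_real_, n_rep, length(spec),
                dimnames = list(NULL, names(spec)))
  ok <- logical(n_rep)
  blocks <- split(seq_len(nrow(dataset)), dataset$ID)
  for (r in seq_len(n_rep)) {
    pick <- sample(as.character(ids), length(ids), replace = TRUE)
    parts <- lapply(seq_along(pick), function(j) {
      d <- dataset[blocks[[pick[j]]], , drop = FALSE]
      d$ID <- j
      d
    })
    boot_data <- do.call(rbind, parts)
    class(boot_data) <- c("trial_dataset", "data.frame")
    fit <- tryCatch(foce_fit(boot_data, pop_init, fixed = fixed,
                             control = control, compute_se = FALSE),
                    error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$coefficients)) &&
        is.finite(fit$ofv) && fit$ofv < .BIG / 2) {
      est[r, ] <- fit$coefficients
      ok[r] <- TRUE
    }
  }
  if (!any(ok))
    stop("all bootstrap replicates failed to fit", call. = FALSE)
  a <- (1 - coverage) / 2
  succ <- est[ok, , drop = FALSE]
  structure(list(
    estimates = est,
    median = apply(succ, 2, median),
    lower = apply(succ, 2, quantile, probs = a),
    upper = apply(succ, 2, quantile, probs = 1 - a),
    coverage = coverage,
    n_success = sum(ok), n_fail = sum(!ok), seed = seed),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d successful / %d failed replicates\n",
              x$n_success, x$n_fail))
  tab <- data.frame(median = signif(x$median, 4),
                    lower = signif(x$lower, 4),
                    upper = signif(x$upper, 4))
  names(tab)[2:3] <- sprintf("%s%%", 100 * c((1 - x$coverage) / 2,
                                             1 - (1 - x$coverage) / 2))
  print(tab)
  invisible(x)
}

# assign each observation to its nominal design time bin: the 0.5-h
# intra-CPB grid (absolute time) or the nearest nominal post-operative
# offset after that subject's neutralization
.vpc_bins <- function(t_obs, t_neu, intra_start = 10 / 60,
                      intra_interval = 0.5,
                      post_times = c(2, 4, 8, 12, 24)) {
  pre <- t_obs < t_neu
  bin <- character(length(t_obs))
  tc <- numeric(length(t_obs))
  if (any(pre)) {
    g <- pmax(round((t_obs[pre] - intra_start) / intra_interval), 0)
    tc[pre] <- intra_start + g * intra_interval
    bin[pre] <- sprintf("cpb_%.2fh", tc[pre])
  }
  if (any(!pre)) {
    off <- t_obs[!pre] - t_neu[!pre]
    nearest <- vapply(off, function(o)
      post_times[which.min(abs(post_times - o))], 0)
    tc[!pre] <- nearest
    bin[!pre] <- sprintf("post_%gh", nearest)
  }
  list(bin = bin, nominal = tc, pre = pre)
}

#' Visual predictive check
#'
#' Simulates the dataset `n_sim` times from the population model, reusing
#' every subject's exact dosing history, sampling times and covariates,
#' and compares observed percentiles (default 5/50/95) per time bin with
#' the distribution of the same percentiles across simulations (median
#' and a confidence band, default 90%).  Bins are the nominal design
#' times: the 0.5-h intra-CPB grid and the nominal post-operative offsets
#' after each subject's neutralization, with jittered actual times
#' assigned to the nearest nominal time.  Empty bins are dropped with a
#' warning.
#'
#' @param dataset a `trial_dataset`
#' @param pop a [population_model()]
#' @param n_sim number of simulation replicates (default 1000)
#' @param seed integer seed
#' @param probs the observation percentiles summarized per bin
#' @param band confidence level of the simulation band
#' @return an object of class `vpc_result`: a data frame with one row
#'   per bin holding observed percentiles and, for each percentile, the
#'   simulated median and band bounds; plus attributes `n_sim`, `probs`,
#'   `band`
#' @export
vpc <- function(dataset, pop, n_sim = 1000, seed = 1,
                probs = c(0.05, 0.5, 0.95), band = 0.9) {
  if (n_sim < 1) stop("'n_sim' must be at least 1", call. = FALSE)
  structs <- .split_subjects(dataset, drop_blq = TRUE)
  structs <- structs[vapply(structs, function(s) s$n > 0L, TRUE)]
  t_obs <- unlist(lapply(structs, function(s) s$t_obs))
  t_neu <- unlist(lapply(structs, function(s) rep(s$t_neu, s$n)))
  y_obs <- unlist(lapply(structs, function(s) s$y))
  bins <- .vpc_bins(t_obs, t_neu)
  ub <- unique(data.frame(bin = bins$bin, nominal = bins$nominal,
                          pre = bins$pre))
  ub <- ub[order(!ub$pre, ub$nominal), , drop = FALSE]

  est_names <- names(pop$omega2)[pop$omega2 > 0]
  set.seed(seed)
  # simulated percentile per bin per replicate
  sim_q <- array(NA_real_, c(n_sim, nrow(ub), length(probs)))
  for (s in seq_len(n_sim)) {
    y_sim <- unlist(lapply(structs, function(st) {
      eta <- .draw_eta(pop)
      p <- individual_parameters(
        pop, structure(st$cov, class = "subject_covariates"), eta)
      f <- .conc_subject(st, p$CL, p$V_c, p$Q, p$V_p)
      eps1 <- if (pop$sigma2_pro > 0)
        rnorm(st$n, 0, sqrt(pop$sigma2_pro)) else 0
      eps2 <- if (pop$sigma2_add > 0)
        rnorm(st$n, 0, sqrt(pop$sigma2_add)) else 0
      apply_residual(f, eps1, eps2)
    }))
    for (b in seq_len(nrow(ub))) {
      in_bin <- bins$bin == ub$bin[b]
      sim_q[s, b, ] <- quantile(y_sim[in_bin], probs, names = FALSE)
    }
  }
  a <- (1 - band) / 2
  out <- ub
  out$n <- vapply(ub$bin, function(b) sum(bins$bin == b), 0L)
  empty <- out$n == 0L
  if (any(empty)) {
    warning(sum(empty), " empty VPC bin(s) dropped")
    out <- out[!empty, , drop = FALSE]
  }
  for (j in seq_along(probs)) {
    pc <- sprintf("p%g", 100 * probs[j])
    out[[paste0("obs_", pc)]] <- vapply(out$bin, function(b)
      quantile(y_obs[bins$bin == b], probs[j], names = FALSE), 0)
    bi <- match(out$bin, ub$bin)
    out[[paste0("sim_", pc, "_med")]] <-
      apply(sim_q[, bi, j, drop = FALSE], 2, median)
    out[[paste0("sim_", pc, "_lo")]] <-
      apply(sim_q[, bi, j, drop = FALSE], 2, quantile, probs = a)
    out[[paste0("sim_", pc, "_hi")]] <-
      apply(sim_q[, bi, j, drop = FALSE], 2, quantile, probs = 1 - a)
  }
  rownames(out) <- NULL
  structure(out, class = c("vpc_result", "data.frame"),
            n_sim = n_sim, probs = probs, band = band, seed = seed)
}

#' Goodness-of-fit table: PRED, IPRED and CWRES
#'
#' Per observation: the population prediction `PRED` (all random effects
#' zero), the individual prediction `IPRED` (empirical Bayes etas), and
#' conditional weighted residuals `CWRES` computed under the FOCE
#' linearization: the observed-minus-population-linearized residual
#' standardized by the Cholesky factor of the linearized marginal
#' covariance, so a well-specified model gives approximately standard
#' normal CWRES.
#'
#' @param dataset the `trial_dataset` that was fitted
#' @param fit a `fit_result` from [foce_fit()] or [eval_model()]
#' @return a data frame of class `gof_table` with columns `ID`, `TIME`,
#'   `DV`, `PRED`, `IPRED`, `CWRES`
#' @export
gof_table <- function(dataset, fit) {
  if (!inherits(fit, "fit_result"))
    stop("'fit' must be a fit_result", call. = FALSE)
  if (!isTRUE(fit$convergence$converged))
    stop("fit did not converge; refit before computing diagnostics",
         call. = FALSE)
  structs <- .split_subjects(dataset, drop_blq = TRUE)
  pop <- fit$pop
  est_names <- names(pop$omega2)[pop$omega2 > 0]
  out <- lapply(structs, function(st) {
    if (st$n == 0L) return(NULL)
    key <- as.character(st$id)
    if (!key %in% rownames(fit$eta))
      stop("no empirical Bayes etas for subject ", key,
           "; refit the model on this dataset", call. = FALSE)
    eta <- fit$eta[key, ]
    p0 <- .subject_params(st, pop, rep(0, length(est_names)), est_names)
    pred <- .conc_subject(st, p0[["CL"]], p0[["V_c"]], p0[["Q"]],
                          p0[["V_p"]])
    res <- .subject_foce(st, pop, eta, want_lin = TRUE)
    data.frame(ID = st$id, TIME = st$t_obs, DV = st$y, PRED = pred,
               IPRED = res$f, CWRES = as.numeric(res$cwres))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("gof_table", "data.frame")
  out
}
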