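#' Stepwise covariate selection by objective-function value
#'
#' Forward inclusion followed by backward elimination.  In the forward
#' phase every candidate effect is first tested one at a time on the base
#' model and candidates are ranked by their OFV drop; they are then added
#' to the growing model in that order, each retained if it still lowers
#' the OFV by more than the chi-squared(1) critical value at
#' `forward_p` (6.63 at p = 0.01).  In the backward phase each retained
#' effect is removed in turn from the full model and kept only if its
#' removal raises the OFV by more than the critical value at
#' `backward_p` (10.83 at p = 0.001); elimination repeats until all
#' retained effects are significant.  Any candidate whose fit fails is
#' skipped and logged in the trace.
#'
#' @param dataset a `trial_dataset`
#' @param base a [population_model()] without the candidate effects
#' @param candidates list of [covariate_effect()] objects to test; give
#'   continuous effects a starting coefficient of 0 and categorical ones
#'   a starting multiplier of 1 so each test starts from the base model
#' @param forward_p,backward_p significance levels of the inclusion and
#'   elimination tests
#' @param fixed,control passed to [foce_fit()]
#' @return list with `model` (the final [foce_fit()] result), `base_fit`,
#'   and `trace`, a data frame recording every test: candidate label,
#'   phase, delta OFV and decision
#' @export
stepwise_covariates <- function(dataset, base, candidates,
                                forward_p = 0.01, backward_p = 0.001,
                                fixed = character(),
                                control = foce_control()) {
  if (!length(candidates))
    stop("no candidate covariate effects supplied", call. = FALSE)
  thr_f <- ofv_threshold(forward_p)
  thr_b <- ofv_threshold(backward_p)
  lbl <- function(ce) paste0("beta_", ce$parameter, "_", ce$covariate)
  trace <- data.frame(candidate = character(), phase = character(),
                      delta_ofv = numeric(), decision = character(),
                      stringsAsFactors = FALSE)
  note <- function(cand, phase, dofv, decision)
    trace[nrow(trace) + 1L, ] <<- list(cand, phase, dofv, decision)

  fit_with <- function(pop) foce_fit(dataset, pop, fixed = fixed,
                                     control = control,
                                     compute_se = FALSE)
  base_fit <- fit_with(base)

  add_effect <- function(pop_fitted, ce) {
    pop <- pop_fitted
    pop$covariates <- c(pop$covariates, list(ce))
    pop
  }

  # ranking pass: each candidate alone on the base model
  drops <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    f <- tryCatch(fit_with(add_effect(base_fit$pop, candidates[[i]])),
                  error = function(e) NULL)
    if (is.null(f)) {
      note(lbl(candidates[[i]]), "forward-rank", NA_real_, "failed")
    } else {
      drops[i] <- base_fit$ofv - f$ofv
      note(lbl(candidates[[i]]), "forward-rank", drops[i],
           if (drops[i] > thr_f) "eligible" else "not eligible")
    }
  }
  order_idx <- order(drops, decreasing = TRUE, na.last = NA)

  # sequential forward additions in ranked order
  current <- base_fit
  included <- list()
  for (i in order_idx) {
    ce <- candidates[[i]]
    f <- tryCatch(fit_with(add_effect(current$pop, ce)),
                  error = function(e) NULL)
    if (is.null(f)) { note(lbl(ce), "forward", NA_real_, "failed"); next }
    dofv <- current$ofv - f$ofv
    if (dofv > thr_f) {
      note(lbl(ce), "forward", dofv, "include")
      current <- f
      included <- c(included, list(ce))
    } else {
      note(lbl(ce), "forward", dofv, "exclude")
    }
  }

  # backward elimination until all retained effects are significant
  repeat {
    if (!length(included)) break
    dofvs <- rep(NA_real_, length(included))
    for (j in seq_along(included)) {
      pop <- current$pop
      keep <- setdiff(seq_along(pop$covariates),
                      .match_effect(pop$covariates, included[[j]]))
      pop$covariates <- pop$covariates[keep]
      f <- tryCatch(fit_with(pop), error = function(e) NULL)
      if (is.null(f)) {
        note(lbl(included[[j]]), "backward", NA_real_, "failed")
        dofvs[j] <- Inf   # cannot assess; keep the effect
      } else {
        dofvs[j] <- f$ofv - current$ofv
      }
    }
    worst <- which.min(dofvs)
    if (dofvs[worst] > thr_b) {
      for (j in seq_along(included))
        if (is.finite(dofvs[j]))
          note(lbl(included[[j]]), "backward", dofvs[j], "retain")
      break
    }
    note(lbl(included[[worst]]), "backward", dofvs[worst], "remove")
    pop <- current$pop
    keep <- setdiff(seq_along(pop$covariates),
                    .match_effect(pop$covariates, included[[worst]]))
    pop$covariates <- pop$covariates[keep]
    current <- fit_with(pop)
    included <- included[-worst]
  }

  list(model = current, base_fit = base_fit, trace = trace)
}

# index of the effect in a covariate list matching parameter+covariate
.match_effect <- function(effects, ce) {
  which(vapply(effects, function(e)
    e$parameter == ce$parameter && e$covariate == ce$covariate, TRUE))
}
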