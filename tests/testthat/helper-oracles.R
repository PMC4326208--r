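# Independent adaptive Gauss-Hermite oracle for -2 log marginal
# likelihood of the nonlinear mixed-effects model.  Shares nothing with
# the package's FOCE path: the integrand is the exact joint density and
# the integral is done by tensor-product quadrature centred and scaled
# at the numerically located joint mode.

# -2 log joint density of one subject's data and eta
.oracle_m2lj <- function(eta, y, f_of_eta, om, s1, s2) {
  f <- f_of_eta(eta)
  v <- s1 * f^2 + s2
  sum(log(2 * pi * v) + (y - f)^2 / v) +
    sum(log(2 * pi * om) + eta^2 / om)
}

# -2 log marginal likelihood of one subject by adaptive GH quadrature
agq_subject_m2ll <- function(y, f_of_eta, om, s1, s2, n_nodes = 21) {
  k <- length(om)
  gh <- pracma::gaussHermite(n_nodes)
  obj <- function(eta) .oracle_m2lj(eta, y, f_of_eta, om, s1, s2)
  mode <- nlminb(rep(0, k), obj)$par
  # Hessian of -log joint at the mode (central differences)
  hess <- matrix(0, k, k)
  h <- 1e-4
  half <- function(eta) obj(eta) / 2
  f0 <- half(mode)
  for (i in seq_len(k)) {
    ep <- mode; ep[i] <- ep[i] + h
    em <- mode; em[i] <- em[i] - h
    hess[i, i] <- (half(ep) - 2 * f0 + half(em)) / h^2
    if (i > 1) for (j in seq_len(i - 1)) {
      epp <- mode; epp[c(i, j)] <- epp[c(i, j)] + h
      epm <- mode; epm[i] <- epm[i] + h; epm[j] <- epm[j] - h
      emp <- mode; emp[i] <- emp[i] - h; emp[j] <- emp[j] + h
      emm <- mode; emm[c(i, j)] <- emm[c(i, j)] - h
      hess[i, j] <- hess[j, i] <-
        (half(epp) - half(epm) - half(emp) + half(emm)) / (4 * h^2)
    }
  }
  ev <- eigen(hess, symmetric = TRUE)
  A <- ev$vectors %*% diag(1 / sqrt(ev$values), k) %*% t(ev$vectors)
  log_detA <- -sum(log(ev$values)) / 2
  # tensor-product nodes
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(seq_len(n_nodes)), k)))
  log_terms <- apply(grid, 1, function(idx) {
    x <- gh$x[idx]
    eta <- mode + sqrt(2) * drop(A %*% x)
    sum(log(gh$w[idx])) + sum(x^2) - obj(eta) / 2
  })
  M <- max(log_terms)
  log_L <- (k / 2) * log(2) + log_detA + M + log(sum(exp(log_terms - M)))
  -2 * log_L
}

# AGQ -2 log marginal likelihood for a whole dataset under a
# population_model (independent re-implementation of the data walk)
agq_ofv <- function(dataset, pop, n_nodes = 21) {
  est <- names(pop$omega2)[pop$omega2 > 0]
  om <- pop$omega2[est]
  total <- 0
  for (id in unique(dataset$ID)) {
    d <- dataset[dataset$ID == id, ]
    dose <- d[d$EVID == 1, ]
    t_neu <- d$TIME[d$EVID == 2]
    obs <- d[d$EVID == 0 & d$BLQ == 0 & is.finite(d$DV), ]
    hist <- dosing_history(dose$TIME, dose$AMT, t_neu = t_neu)
    cov <- subject_covariates(d$WT[1], d$AGE[1], d$SEX[1])
    f_of_eta <- function(eta) {
      p <- individual_parameters(pop, cov, setNames(eta, est))
      concentration(obs$TIME, hist, p)
    }
    total <- total + agq_subject_m2ll(obs$DV, f_of_eta, om,
                                      pop$sigma2_pro, pop$sigma2_add)
  }
  total
}
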