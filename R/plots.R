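#' Visual predictive check plot
#'
#' Observed percentiles (points/lines) over the simulated percentile
#' bands, split into the intra-CPB and post-neutralization panels (the
#' two phases live on very different concentration scales).
#'
#' @param x a `vpc_result` from [vpc()]
#' @return a ggplot object
#' @export
plot_vpc <- function(x) {
  if (!inherits(x, "vpc_result")) stop("'x' must be a vpc_result",
                                       call. = FALSE)
  d <- as.data.frame(x)
  d$phase <- ifelse(d$pre, "during CPB", "after neutralization")
  ggplot2::ggplot(d, ggplot2::aes(x = nominal)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p5_lo, ymax = sim_p5_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p95_lo,
                                      ymax = sim_p95_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p50_lo,
                                      ymax = sim_p50_hi),
                         fill = "salmon", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = sim_p50_med),
                       color = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = obs_p50), color = "black") +
    ggplot2::geom_line(ggplot2::aes(y = obs_p5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p95), linetype = 2) +
    ggplot2::facet_wrap(~phase, scales = "free") +
    ggplot2::labs(x = "nominal time (h; post panel: h after neutralization)",
                  y = "anti-FIIa activity (IU/mL)",
                  title = "Visual predictive check") +
    ggplot2::theme_bw()
}

#' Goodness-of-fit panels
#'
#' The four standard diagnostic panels: observed vs population
#' predictions, observed vs individual predictions, conditional weighted
#' residuals vs population predictions, and CWRES vs time.
#'
#' @param x a `gof_table` from [gof_table()]
#' @return a ggplot object (facetted four-panel figure)
#' @export
plot_gof <- function(x) {
  if (!inherits(x, "gof_table")) stop("'x' must be a gof_table",
                                      call. = FALSE)
  d <- rbind(
    data.frame(panel = "OBS vs PRED", xv = x$PRED, yv = x$DV),
    data.frame(panel = "OBS vs IPRED", xv = x$IPRED, yv = x$DV),
    data.frame(panel = "CWRES vs PRED", xv = x$PRED, yv = x$CWRES),
    data.frame(panel = "CWRES vs time", xv = x$TIME, yv = x$CWRES))
  ggplot2::ggplot(d, ggplot2::aes(xv, yv)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "red", linewidth = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Goodness-of-fit diagnostics") +
    ggplot2::theme_bw()
}

#' Protamine regimen overlay plot
#'
#' Baseline (no follow-up protamine) and regimen concentration curves
#' after neutralization, one panel per infusion regimen.
#'
#' @param x a `regimen_comparison` from [compare_regimens()]
#' @return a ggplot object
#' @export
plot_regimens <- function(x) {
  if (!inherits(x, "regimen_comparison"))
    stop("'x' must be a regimen_comparison", call. = FALSE)
  base_idx <- which(x$metrics$mode == "bolus_only")[1]
  base <- x$profiles[[base_idx]]
  panels <- setdiff(seq_along(x$profiles), base_idx)
  d <- do.call(rbind, lapply(panels, function(i) {
    rbind(data.frame(panel = x$labels[i], time = base$time,
                     conc = base$conc, curve = "no follow-up protamine"),
          data.frame(panel = x$labels[i], time = x$profiles[[i]]$time,
                     conc = x$profiles[[i]]$conc, curve = "with infusion"))
  }))
  ggplot2::ggplot(d, ggplot2::aes(time, conc, color = curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c("no follow-up protamine" =
                                             "steelblue",
                                           "with infusion" = "firebrick")) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "time (h)", y = "anti-FIIa activity (IU/mL)",
                  title = "Simulated heparin rebound under protamine infusions") +
    ggplot2::theme_bw()
}

utils::globalVariables(c("sim_p5_lo", "sim_p5_hi", "sim_p95_lo",
                         "sim_p95_hi", "sim_p50_lo", "sim_p50_hi",
                         "sim_p50_med", "obs_p50", "obs_p5", "obs_p95",
                         "nominal", "xv", "yv", "time", "conc", "curve",
                         "phase"))
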