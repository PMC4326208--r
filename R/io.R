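.DATASET_COLS <- c("ID", "TIME", "EVID", "AMT", "DV", "BLQ", "WT",
                   "AGE", "SEX")

#' Validate and classify a rectangular event dataset
#'
#' Checks the NONMEM-style event schema used throughout the package:
#' columns `ID`, `TIME` (h), `EVID` (0 observation, 1 dose, 2
#' neutralization), `AMT` (IU, doses only), `DV` (IU/mL, observations
#' only; blank for below-quantitation records), `BLQ` (0/1), `WT` (kg),
#' `AGE` (y), `SEX` (0/1).  Per subject, times must be nondecreasing,
#' exactly one neutralization event must exist, and all doses must
#' precede it.  Violations raise errors naming the offending row.
#'
#' @param x a data frame in the dataset schema
#' @return `x` with class `trial_dataset`
#' @export
as_trial_dataset <- function(x) {
  if (inherits(x, "trial_dataset")) return(x)
  if (!is.data.frame(x)) stop("expected a data frame", call. = FALSE)
  unknown <- setdiff(names(x), .DATASET_COLS)
  if (length(unknown))
    stop("unknown dataset column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(.DATASET_COLS, names(x))
  if (length(missing))
    stop("missing dataset column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x$TIME)) || any(x$TIME < 0))
    stop("row ", which(!is.finite(x$TIME) | x$TIME < 0)[1],
         ": times must be nonnegative finite numbers", call. = FALSE)
  if (!all(x$EVID %in% c(0L, 1L, 2L)))
    stop("row ", which(!x$EVID %in% c(0L, 1L, 2L))[1],
         ": EVID must be 0 (observation), 1 (dose) or 2 (neutralization)",
         call. = FALSE)
  bad <- x$EVID == 1L & (!is.finite(x$AMT) | x$AMT <= 0)
  if (any(bad))
    stop("row ", which(bad)[1], ": dose rows need a positive AMT",
         call. = FALSE)
  bad <- x$EVID == 0L & x$BLQ == 0L & !is.finite(x$DV)
  if (any(bad))
    stop("row ", which(bad)[1],
         ": observation rows need DV (or the BLQ flag)", call. = FALSE)
  bad <- x$EVID != 0L & is.finite(x$DV) | x$EVID != 1L & is.finite(x$AMT)
  if (any(bad))
    stop("row ", which(bad)[1],
         ": exactly one of AMT (doses) / DV (observations) may be set",
         call. = FALSE)
  for (id in unique(x$ID)) {
    rows <- which(x$ID == id)
    d <- x[rows, , drop = FALSE]
    if (is.unsorted(d$TIME))
      stop("row ", rows[which(diff(d$TIME) < 0)[1] + 1L],
           ": times within subject ", id, " are not nondecreasing",
           call. = FALSE)
    neu <- which(d$EVID == 2L)
    if (length(neu) != 1L)
      stop("subject ", id, " must have exactly one neutralization ",
           "event (found ", length(neu), ")", call. = FALSE)
    late <- d$EVID == 1L & d$TIME >= d$TIME[neu]
    if (any(late))
      stop("row ", rows[which(late)[1]],
           ": dose after the neutralization event of subject ", id,
           call. = FALSE)
  }
  class(x) <- c("trial_dataset", "data.frame")
  x
}

#' Read an event dataset from CSV
#'
#' @param path CSV file written by [write_dataset()] (header `ID, TIME,
#'   EVID, AMT, DV, BLQ, WT, AGE, SEX`; blank cells for not-applicable
#'   fields)
#' @return a validated `trial_dataset`
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read.csv(path, colClasses = c(ID = "integer", TIME = "numeric",
                                     EVID = "integer", AMT = "numeric",
                                     DV = "numeric", BLQ = "integer",
                                     WT = "numeric", AGE = "numeric",
                                     SEX = "integer"))
  as_trial_dataset(x)
}

#' Write an event dataset to CSV
#'
#' Canonical serialization: fixed column order, 15 significant digits,
#' blank cells for not-applicable fields.  `write_dataset()` then
#' [read_dataset()] round-trips to an equal dataset, and re-writing a
#' read file reproduces it byte-identically.
#'
#' @param dataset a `trial_dataset`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_dataset <- function(dataset, path) {
  dataset <- as_trial_dataset(dataset)
  out <- dataset[, .DATASET_COLS]
  for (col in c("TIME", "AMT", "DV", "WT", "AGE")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.finite(v), sprintf("%.15g", v), "")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---- run configuration ---------------------------------------------------

.CONFIG_SCHEMA <- list(
  seed = NULL, output_dir = NULL,
  trial = c("n_subjects", "seed", "weight", "age", "female_fraction",
            "dose", "cpb", "sampling", "assay"),
  model = c("CL", "V_c", "Q", "V_p", "omega2", "sigma2_pro",
            "sigma2_add", "covariates"),
  estimation = c("fixed", "outer_rel_tol", "inner_rel_tol",
                 "outer_iter_max", "outer_eval_max", "se_rel_step",
                 "compute_se", "data"),
  validation = c("n_rep", "n_sim", "coverage", "band", "data"),
  regimen = c("rate", "durations", "horizon", "threshold", "weight"))

#' Read and validate a run configuration
#'
#' YAML configuration with blocks `trial`, `model`, `estimation`,
#' `validation`, `regimen` plus global `seed` and `output_dir`.  The
#' schema is closed: unknown top-level blocks or unknown keys inside a
#' block fail fast, before any computation.
#'
#' @param path YAML file
#' @return the configuration list, classed `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (blk in intersect(names(cfg), c("trial", "model", "estimation",
                                      "validation", "regimen"))) {
    bad <- setdiff(names(cfg[[blk]]), .CONFIG_SCHEMA[[blk]])
    if (length(bad))
      stop("unknown key(s) in config block '", blk, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

# build package objects from config blocks (reference defaults)
.config_trial <- function(cfg) {
  args <- cfg$trial
  if (is.null(args)) return(trial_config())
  do.call(trial_config, args)
}

.config_model <- function(cfg) {
  m <- cfg$model
  if (is.null(m)) return(ufh_reference_model())
  ref <- ufh_reference_model()
  covs <- lapply(m$covariates, function(ce) do.call(covariate_effect, ce))
  population_model(
    CL = m$CL %||% ref$theta[["CL"]],
    V_c = m$V_c %||% ref$theta[["V_c"]],
    Q = m$Q %||% ref$theta[["Q"]],
    V_p = m$V_p %||% ref$theta[["V_p"]],
    omega2 = if (is.null(m$omega2)) ref$omega2 else unlist(m$omega2),
    sigma2_pro = m$sigma2_pro %||% ref$sigma2_pro,
    sigma2_add = m$sigma2_add %||% ref$sigma2_add,
    covariates = covs %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
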