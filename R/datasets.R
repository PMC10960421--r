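#' Construct a decay dataset
#'
#' One experiment: conditions plus observed (time, fraction remaining)
#' pairs of the oleic acid decay.
#'
#' @param dataset_id character id
#' @param cond named condition vector from [conditions()]
#' @param time_s strictly increasing observation times (s)
#' @param fraction_remaining observed fractions in (0, 1]
#' @param note optional provenance note
#' @return A list of class `decay_dataset` with fields `dataset_id`,
#'   `conditions`, `observations` (tibble), `note`.
#' @export
decay_dataset <- function(dataset_id, cond, time_s, fraction_remaining,
                          note = NULL) {
  stopifnot(length(time_s) >= 2, length(time_s) == length(fraction_remaining))
  if (any(diff(time_s) <= 0)) stop("observation times must strictly increase")
  if (any(fraction_remaining <= 0 | fraction_remaining > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  structure(list(dataset_id = as.character(dataset_id), conditions = cond,
                 observations = tibble::tibble(
                   time_s = as.numeric(time_s),
                   fraction_remaining = as.numeric(fraction_remaining)),
                 note = note),
            class = "decay_dataset")
}

#' @export
print.decay_dataset <- function(x, ...) {
  cat("<decay_dataset>", x$dataset_id, "-", nrow(x$observations),
      "observations\n")
  cat(sprintf("  r_p = %.3g cm, [O3]_g,0 = %.3g cm-3, [OL]_b,0 = %.3g cm-3\n",
              x$conditions[["r_p"]], x$conditions[["O3_g0"]],
              x$conditions[["OL_b0"]]))
  invisible(x)
}

#' Observed reaction-progress times of a dataset
#'
#' Converts the measured decay to the nine-point progress-time
#' representation by monotone interpolation, linear in (log time, fraction).
#' An implicit anchor (t -> 0, fraction = 1) is prepended so early progress
#' levels between the first observation and 1 are reachable only when
#' observed. Progress levels below the last observed fraction are `NA`
#' (not reached by the experiment).
#'
#' @param ds a [decay_dataset()]
#' @return Named numeric vector of length 9, seconds, `NA` = not observed.
#' @export
observed_progress_times <- function(ds) {
  obs <- ds$observations
  curve <- tibble::tibble(
    time_s = c(0, obs$time_s),
    fraction_remaining = pmin(c(1, cummin(obs$fraction_remaining)), 1))
  pt <- progress_times(curve, t_max = max(obs$time_s))
  # levels above the first measured fraction cannot be interpolated against
  # data; they extrapolate the initial anchor and are kept (fraction starts
  # at 1 by normalization), but levels never reached are censored already
  pt
}

#' Mean squared logarithmic error between nine-point outputs
#'
#' Distance metric for fit acceptance: mean over compared progress levels of
#' squared natural-log differences of the progress times. Levels missing
#' (censored) in the observation are excluded; levels censored in the model
#' but observed contribute the capped penalty `log(t_max / t_obs)^2`.
#' Symmetric in its arguments when both are uncensored.
#'
#' @param model_pt nine-point model progress times (s), `NA` = censored
#' @param obs_pt nine-point observed progress times (s), `NA` = not observed
#' @param t_max censoring horizon used for the capped penalty (s)
#' @param eps floor applied to times before taking logs
#' @return Non-negative scalar error.
#' @export
msle <- function(model_pt, obs_pt, t_max = 1e6, eps = 1e-12) {
  use <- !is.na(obs_pt)
  if (!any(use)) stop("no comparable progress levels")
  m <- model_pt[use]
  o <- pmax(obs_pt[use], eps)
  d2 <- ifelse(is.na(m), log(t_max / o)^2, log(pmax(m, eps) / o)^2)
  mean(d2)
}

# matrix variant of msle: rows of M against one observation vector
msle_rows <- function(M, obs_pt, t_max = 1e6, eps = 1e-12) {
  use <- !is.na(obs_pt)
  if (!any(use)) stop("no comparable progress levels")
  o <- pmax(obs_pt[use], eps)
  Lm <- log(pmax(M[, use, drop = FALSE], eps))
  Lm[is.na(M[, use, drop = FALSE])] <- log(t_max)
  rowMeans(sweep(Lm, 2, log(o))^2)
}

#' Joint error of a parameter set against several datasets
#'
#' Unweighted mean of the per-dataset MSLE. Recomputed jointly whenever the
#' dataset collection changes, which is what lets previously rejected fits
#' re-enter the ensemble ("revival") when new data arrive.
#'
#' @param params kinetic parameter vector
#' @param datasets list of [decay_dataset()]
#' @param cfg model configuration
#' @param evaluator function `(params, cond) ->` nine progress times;
#'   defaults to the kinetic model
#' @param bail_above optional early-exit threshold: return `Inf` as soon as
#'   the running mean cannot fall below it (used by rejection sampling)
#' @return Scalar error (possibly `Inf` when bailing out early).
#' @export
total_error <- function(params, datasets, cfg = model_config(),
                        evaluator = NULL, bail_above = NULL) {
  if (is.null(evaluator)) {
    evaluator <- function(p, cond) km_progress(p, cond, cfg)
  }
  n <- length(datasets)
  if (n == 0) stop("no datasets")
  tot <- 0
  for (i in seq_len(n)) {
    ds <- datasets[[i]]
    obs_pt <- attr(ds, "progress_cache")
    if (is.null(obs_pt)) obs_pt <- observed_progress_times(ds)
    pt <- evaluator(params, ds$conditions)
    tot <- tot + msle(pt, obs_pt, t_max = cfg$t_max)
    if (!is.null(bail_above) && tot / n > bail_above) return(Inf)
  }
  tot / n
}

#' Cache observed progress times on a dataset list
#'
#' @param datasets list of [decay_dataset()]
#' @return The list with per-dataset progress times precomputed.
#' @export
cache_progress <- function(datasets) {
  lapply(datasets, function(ds) {
    attr(ds, "progress_cache") <- observed_progress_times(ds)
    ds
  })
}

#' Write / read decay datasets
#'
#' CSV with columns `time_s`, `fraction_remaining` plus a JSON sidecar
#' (same path with extension `.json`) holding id, conditions and note.
#'
#' @param ds a [decay_dataset()]
#' @param path CSV file path
#' @return `write_decay_dataset` the path, invisibly; `read_decay_dataset`
#'   a [decay_dataset()].
#' @export
write_decay_dataset <- function(ds, path) {
  readr::write_csv(ds$observations, path)
  meta <- list(dataset_id = ds$dataset_id,
               conditions = as.list(ds$conditions), note = ds$note)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_decay_dataset
#' @export
read_decay_dataset <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  decay_dataset(meta$dataset_id, unlist(meta$conditions),
                obs$time_s, obs$fraction_remaining, note = meta$note)
}
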