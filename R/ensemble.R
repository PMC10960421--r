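#' Acquire a fit ensemble by rejection sampling
#'
#' Draws kinetic parameter sets log-uniformly within bounds, evaluates the
#' model against the datasets, and keeps draws whose joint MSLE falls below
#' the acceptance threshold, until `n_target` fits are accepted or
#' `max_draws` candidates have been tested. The accepted collection — the
#' fit ensemble — is a sampled representation of the model's solution space
#' (an approximate posterior in the rejection-ABC sense).
#'
#' @param datasets list of [decay_dataset()]
#' @param theta acceptance threshold on the joint MSLE (default 0.0105)
#' @param n_target number of accepted fits wanted (500 for full-scale work;
#'   scale down for quick studies)
#' @param max_draws candidate budget
#' @param bounds bounds tibble, see [default_bounds()]
#' @param cfg model configuration
#' @param evaluator optional `(params, cond) -> nine progress times`
#'   function; defaults to the kinetic model. Swap in a surrogate via
#'   [sm_evaluator()].
#' @param seed RNG seed; recorded in the ensemble
#' @param progress print a progress line every 500 draws
#' @return A `fit_ensemble`: list with `fits` (tibble: `fit_id`, the seven
#'   kinetic parameters, `error`, `accepted`), `theta`, `bounds`, `seed`,
#'   `dataset_ids`, `n_draws`, `acceptance_rate`.
#' @export
acquire_fit_ensemble <- function(datasets, theta = 0.0105, n_target = 500,
                                 max_draws = 200 * n_target,
                                 bounds = default_bounds(),
                                 cfg = model_config(), evaluator = NULL,
                                 seed = 1L, progress = FALSE) {
  stopifnot(n_target >= 1, theta > 0)
  datasets <- cache_progress(datasets)
  set.seed(seed)
  kin <- kinetic_parameter_names()
  accepted <- vector("list", n_target)
  n_acc <- 0L
  n_draws <- 0L
  batch_fn <- attr(evaluator, "batch")
  chunk <- if (is.null(batch_fn)) 256L else 8192L
  while (n_acc < n_target && n_draws < max_draws) {
    draws <- sample_params(min(chunk, max_draws - n_draws), bounds,
                           kind = "kinetic")
    if (!is.null(batch_fn)) {
      # vectorized path: evaluate the whole chunk per dataset at once
      P <- as.matrix(draws[kin])
      tot <- numeric(nrow(P))
      for (ds in datasets) {
        obs_pt <- attr(ds, "progress_cache")
        if (is.null(obs_pt)) obs_pt <- observed_progress_times(ds)
        M <- batch_fn(P, ds$conditions)
        tot <- tot + msle_rows(M, obs_pt, t_max = cfg$t_max)
      }
      errv <- tot / length(datasets)
      n_draws <- n_draws + nrow(P)
      for (i in which(errv < theta)) {
        n_acc <- n_acc + 1L
        accepted[[n_acc]] <- c(P[i, ], error = errv[[i]])
        if (n_acc >= n_target) break
      }
      if (progress) message(sprintf("draws %d, accepted %d", n_draws, n_acc))
      next
    }
    for (i in seq_len(nrow(draws))) {
      n_draws <- n_draws + 1L
      p <- unlist(draws[i, kin])
      err <- tryCatch(
        total_error(p, datasets, cfg, evaluator, bail_above = theta),
        error = function(e) Inf)
      if (is.finite(err) && err < theta) {
        n_acc <- n_acc + 1L
        accepted[[n_acc]] <- c(p, error = err)
        if (n_acc >= n_target) break
      }
      if (progress && n_draws %% 500 == 0) {
        message(sprintf("draws %d, accepted %d", n_draws, n_acc))
      }
    }
  }
  if (n_acc == 0L) {
    stop(sprintf(paste0("no fits accepted after %d draws ",
                        "(acceptance rate 0); threshold theta = %g may be ",
                        "too strict for these data"), n_draws, theta))
  }
  fits <- dplyr::bind_rows(lapply(accepted[seq_len(n_acc)], function(x) {
    tibble::as_tibble(as.list(x))
  }))
  fits <- dplyr::mutate(fits, fit_id = dplyr::row_number(),
                        accepted = TRUE, .before = 1)
  structure(list(fits = fits, theta = theta, bounds = bounds, seed = seed,
                 dataset_ids = vapply(datasets, `[[`, "", "dataset_id"),
                 n_draws = n_draws,
                 acceptance_rate = n_acc / n_draws),
            class = "fit_ensemble")
}

#' @export
print.fit_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<fit_ensemble> %d fits (%d accepted), theta = %g, ",
                     "%d datasets\n"),
              nrow(x$fits), sum(x$fits$accepted), x$theta,
              length(x$dataset_ids)))
  invisible(x)
}

#' @export
tidy.fit_ensemble <- function(x, log10 = TRUE, ...) {
  out <- x$fits
  if (log10) {
    kin <- kinetic_parameter_names()
    out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(kin), base::log10))
  }
  out
}

#' @export
glance.fit_ensemble <- function(x, ...) {
  acc <- x$fits$error[x$fits$accepted]
  tibble::tibble(n_fits = nrow(x$fits), n_accepted = sum(x$fits$accepted),
                 theta = x$theta, min_error = min(x$fits$error),
                 median_accepted_error =
                   if (length(acc)) median(acc) else NA_real_,
                 acceptance_rate = x$acceptance_rate %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-filter a fit ensemble against a dataset collection
#'
#' Recomputes the joint error of EVERY stored fit — including previously
#' rejected ones — against the full dataset collection and re-flags
#' acceptance. Fits whose joint error drops back below threshold are
#' "revived". Nothing is ever deleted.
#'
#' @param fe a `fit_ensemble`
#' @param datasets full dataset collection (old plus new)
#' @param theta acceptance threshold; defaults to the ensemble's
#' @param cfg model configuration
#' @param evaluator optional nine-point evaluator (default kinetic model)
#' @return A new `fit_ensemble` with updated errors and flags and an
#'   attribute `counts`: named vector `accepted`, `rejected`, `revived`,
#'   where `rejected`/`revived` count flag changes relative to the input.
#' @export
filter_ensemble <- function(fe, datasets, theta = fe$theta,
                            cfg = model_config(), evaluator = NULL) {
  datasets <- cache_progress(datasets)
  kin <- kinetic_parameter_names()
  before <- fe$fits$accepted
  batch_fn <- if (!is.null(evaluator)) attr(evaluator, "batch")
  if (!is.null(batch_fn)) {
    P <- as.matrix(fe$fits[kin])
    tot <- numeric(nrow(P))
    for (ds in datasets) {
      tot <- tot + msle_rows(batch_fn(P, ds$conditions),
                             attr(ds, "progress_cache"), t_max = cfg$t_max)
    }
    errs <- tot / length(datasets)
  } else {
    errs <- vapply(seq_len(nrow(fe$fits)), function(i) {
      p <- unlist(fe$fits[i, kin])
      tryCatch(total_error(p, datasets, cfg, evaluator),
               error = function(e) Inf)
    }, numeric(1))
  }
  fits <- dplyr::mutate(fe$fits, error = errs, accepted = errs < theta)
  out <- fe
  out$fits <- fits
  out$theta <- theta
  out$dataset_ids <- vapply(datasets, `[[`, "", "dataset_id")
  attr(out, "counts") <- c(accepted = sum(fits$accepted),
                           rejected = sum(before & !fits$accepted),
                           revived = sum(!before & fits$accepted))
  out
}

#' Ensemble solution at one experimental condition
#'
#' Evaluates the nine-point model output for every accepted fit at the given
#' condition. The resulting matrix — one row per fit — is the object all
#' constraint metrics consume.
#'
#' @param fe a `fit_ensemble`
#' @param cond condition vector from [conditions()]
#' @param cfg model configuration
#' @param evaluator optional nine-point evaluator; default kinetic model
#' @param fit_ids evaluate only these fits (default: all accepted)
#' @return An `ensemble_solution`: list with `condition`, `outputs`
#'   (n x 9 matrix of progress times in seconds, `NA` = censored) and
#'   `fit_ids` aligned to rows.
#' @export
ensemble_solution <- function(fe, cond, cfg = model_config(),
                              evaluator = NULL, fit_ids = NULL) {
  if (is.null(evaluator)) {
    evaluator <- function(p, cc) km_progress(p, cc, cfg)
  }
  kin <- kinetic_parameter_names()
  if (is.null(fit_ids)) fit_ids <- fe$fits$fit_id[fe$fits$accepted]
  rows <- match(fit_ids, fe$fits$fit_id)
  batch_fn <- attr(evaluator, "batch")
  if (!is.null(batch_fn)) {
    outputs <- unname(batch_fn(as.matrix(fe$fits[rows, kin]), cond))
  } else {
    outputs <- t(vapply(rows, function(i) {
      evaluator(unlist(fe$fits[i, kin]), cond)
    }, numeric(9)))
  }
  colnames(outputs) <- paste0("t", format(progress_fractions()))
  structure(list(condition = cond, outputs = outputs, fit_ids = fit_ids),
            class = "ensemble_solution")
}

#' Write / read a fit ensemble
#'
#' Tab-separated fit table (log10 parameter columns, error, accepted flag)
#' plus a JSON metadata sidecar (theta, seed, bounds, dataset ids).
#'
#' @param fe a `fit_ensemble`
#' @param path TSV file path
#' @return The path invisibly / a `fit_ensemble`.
#' @export
write_fit_ensemble <- function(fe, path) {
  readr::write_tsv(tidy(fe, log10 = TRUE), path)
  meta <- list(theta = fe$theta, seed = fe$seed,
               dataset_ids = as.list(fe$dataset_ids),
               n_draws = fe$n_draws,
               acceptance_rate = fe$acceptance_rate,
               bounds = fe$bounds)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fit_ensemble
#' @export
read_fit_ensemble <- function(path) {
  fits <- readr::read_tsv(path, show_col_types = FALSE)
  kin <- kinetic_parameter_names()
  fits <- dplyr::mutate(fits, dplyr::across(dplyr::all_of(kin),
                                            function(x) 10^x))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(fits = fits, theta = meta$theta,
                 bounds = tibble::as_tibble(meta$bounds), seed = meta$seed,
                 dataset_ids = meta$dataset_ids, n_draws = meta$n_draws,
                 acceptance_rate = meta$acceptance_rate),
            class = "fit_ensemble")
}
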