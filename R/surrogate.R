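#' Generate surrogate training data from the kinetic model
#'
#' Draws all ten parameters (seven kinetic plus three experimental)
#' log-uniformly within bounds, evaluates the kinetic model for each draw,
#' and stores log10 inputs and log10 progress-time targets. Draws with any
#' censored output (progress level not reached before the horizon, or a
#' failed solve) are flagged and excluded from the retained set; the
#' retention fraction is recorded.
#'
#' The default configuration is a reduced-cost discretization (fewer shells
#' and output times than the reference configuration): the surrogate is an
#' approximation by construction and its held-out error — which feeds into
#' threshold calibration — dominates the extra discretization error.
#'
#' @param n number of draws (desk-scale default 5e4)
#' @param bounds bounds tibble, see [default_bounds()]
#' @param cfg model configuration for the generating runs
#' @param seed RNG seed
#' @param progress print a line every 5000 draws
#' @return A `surrogate_training_set`: list with `inputs` (retained n x 10
#'   log10 matrix), `targets` (retained n x 9 log10 matrix), `censored`
#'   (logical, all draws), `retention`, `n_requested`, `seed`, `bounds`,
#'   `cfg`.
#' @export
generate_training_data <- function(n = 5e4, bounds = default_bounds(),
                                   cfg = model_config(n_layers = 24,
                                                      n_times = 80),
                                   seed = 1L, progress = FALSE) {
  set.seed(seed)
  nm10 <- c(kinetic_parameter_names(), experimental_parameter_names())
  if (n == 0) {
    return(structure(list(
      inputs = matrix(numeric(), 0, 10, dimnames = list(NULL, nm10)),
      targets = matrix(numeric(), 0, 9),
      censored = logical(), retention = NA_real_, n_requested = 0L,
      seed = seed, bounds = bounds, cfg = cfg),
      class = "surrogate_training_set"))
  }
  draws <- sample_params(n, bounds, kind = "all")
  pm <- as.matrix(draws[nm10])
  kin <- kinetic_parameter_names()
  targets <- matrix(NA_real_, n, 9)
  for (i in seq_len(n)) {
    pt <- tryCatch(
      km_progress(pm[i, kin], pm[i, experimental_parameter_names()], cfg),
      error = function(e) rep(NA_real_, 9))
    targets[i, ] <- pt
    if (progress && i %% 5000 == 0) message("draw ", i, " / ", n)
  }
  colnames(targets) <- paste0("t", format(progress_fractions()))
  censored <- !stats::complete.cases(targets)
  structure(list(inputs = log10(pm[!censored, , drop = FALSE]),
                 targets = log10(targets[!censored, , drop = FALSE]),
                 censored = censored, retention = mean(!censored),
                 n_requested = as.integer(n), seed = seed, bounds = bounds,
                 cfg = cfg),
            class = "surrogate_training_set")
}

#' @export
print.surrogate_training_set <- function(x, ...) {
  cat(sprintf("<surrogate_training_set> %d retained of %d draws (%.1f%%)\n",
              nrow(x$inputs), x$n_requested, 100 * (x$retention %||% NA)))
  invisible(x)
}

#' Train the neural-network surrogate
#'
#' Fully-connected feed-forward network (rectifier hidden layers, linear
#' output) from the ten log10 inputs to the nine log10 progress times,
#' trained by mini-batch Adam on standardized data with a held-out split
#' and early stopping on the held-out loss.
#'
#' @param ts a [generate_training_data()] result
#' @param hidden hidden layer sizes (default four layers of 128)
#' @param epochs maximum training epochs
#' @param batch mini-batch size
#' @param lr Adam learning rate
#' @param val_frac held-out fraction
#' @param patience early-stopping patience (epochs without held-out
#'   improvement)
#' @param r2_floor minimum acceptable held-out R^2 per output column;
#'   falling below warns (does not error)
#' @param seed seed for split, initialization, and shuffling
#' @return A `surrogate_model`: weights, standardization constants, layer
#'   sizes, per-column held-out metrics (`metrics` tibble: rmse and r2 in
#'   log10 units), `median_abs_log10_error`, `best_epoch`, `seed`.
#' @export
train_surrogate <- function(ts, hidden = c(128, 128, 128, 128),
                            epochs = 200, batch = 128, lr = 1e-3,
                            val_frac = 0.1, patience = 10, r2_floor = 0.5,
                            seed = 1L) {
  n <- nrow(ts$inputs)
  if (n < 10) stop("training set too small")
  set.seed(seed)
  n_val <- max(1L, round(val_frac * n))
  val <- sample.int(n, n_val)
  Xtr <- ts$inputs[-val, , drop = FALSE]
  Ytr <- ts$targets[-val, , drop = FALSE]
  Xva <- ts$inputs[val, , drop = FALSE]
  Yva <- ts$targets[val, , drop = FALSE]

  xc <- colMeans(Xtr); xs <- apply(Xtr, 2, sd)
  yc <- colMeans(Ytr); ys <- apply(Ytr, 2, sd)
  xs[xs == 0] <- 1; ys[ys == 0] <- 1
  std <- function(M, c, s) sweep(sweep(M, 2, c), 2, s, "/")

  w <- .Call("mlp_train", std(Xtr, xc, xs), std(Ytr, yc, ys),
             as.integer(hidden), as.integer(epochs), as.integer(batch),
             as.numeric(lr), as.integer(seed),
             std(Xva, xc, xs), std(Yva, yc, ys), as.integer(patience),
             PACKAGE = "kincompass")
  if (!all(vapply(w, function(m) all(is.finite(m)), logical(1)))) {
    stop("training diverged: non-finite weights")
  }
  pred_std <- .Call("mlp_predict", w, std(Xva, xc, xs),
                    PACKAGE = "kincompass")
  pred <- sweep(sweep(pred_std, 2, ys, "*"), 2, yc, "+")
  res <- pred - Yva
  metrics <- tibble::tibble(
    output = colnames(ts$targets),
    rmse = sqrt(colMeans(res^2)),
    r2 = 1 - colMeans(res^2) / apply(Yva, 2, function(v) mean((v - mean(v))^2)))
  if (any(metrics$r2 < r2_floor)) {
    warning(sprintf("held-out R^2 below %.2f for: %s", r2_floor,
                    paste(metrics$output[metrics$r2 < r2_floor],
                          collapse = ", ")))
  }
  structure(list(weights = w[names(w)], hidden = as.integer(hidden),
                 x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
                 metrics = metrics,
                 median_abs_log10_error = median(abs(res)),
                 val_msle = (log(10))^2 * mean(res^2),
                 best_epoch = attr(w, "best_epoch"),
                 val_history = attr(w, "val_history"),
                 seed = seed),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf(paste0("<surrogate_model> 10 -> %s -> 9, best epoch %d, ",
                     "median |log10 err| = %.3g\n"),
              paste(x$hidden, collapse = "x"), x$best_epoch,
              x$median_abs_log10_error))
  invisible(x)
}

#' @export
glance.surrogate_model <- function(x, ...) {
  tibble::tibble(n_hidden_layers = length(x$hidden),
                 units = paste(x$hidden, collapse = "x"),
                 best_epoch = x$best_epoch,
                 median_abs_log10_error = x$median_abs_log10_error,
                 val_msle = x$val_msle,
                 min_r2 = min(x$metrics$r2),
                 max_rmse = max(x$metrics$rmse))
}

#' Predict progress times with the surrogate
#'
#' Vectorized over parameter sets. Progress times must increase with
#' reaction progress; raw network outputs that violate this are re-ordered
#' by a per-row sort, and the number of re-ordered rows is attached as
#' attribute `n_reordered` (the warning counter).
#'
#' @param sm a [train_surrogate()] model
#' @param params named kinetic parameter vector, or a matrix/data frame of
#'   the seven kinetic parameters (one row per set; linear units)
#' @param cond condition vector from [conditions()], recycled over rows.
#'   May be omitted when `params` already has all ten columns.
#' @return Named 9-vector of progress times in seconds for a single set;
#'   otherwise an n x 9 matrix. Attribute `n_reordered` counts rows whose
#'   column order had to be restored.
#' @export
sm_predict <- function(sm, params, cond = NULL) {
  single <- is.null(dim(params))
  P <- if (single) matrix(params, 1, dimnames = list(NULL, names(params)))
       else as.matrix(params)
  nm10 <- names(sm$x_center)
  if (!is.null(cond)) {
    P <- cbind(P[, kinetic_parameter_names(), drop = FALSE],
               matrix(rep(unlist(cond)[experimental_parameter_names()],
                          each = nrow(P)), nrow(P), 3,
                      dimnames = list(NULL, experimental_parameter_names())))
  }
  X <- log10(P[, nm10, drop = FALSE])
  Xs <- sweep(sweep(X, 2, sm$x_center), 2, sm$x_scale, "/")
  Z <- .Call("mlp_predict", sm$weights, Xs, PACKAGE = "kincompass")
  Z <- sweep(sweep(Z, 2, sm$y_scale, "*"), 2, sm$y_center, "+")
  unsorted <- rowSums(Z[, -1, drop = FALSE] <
                        Z[, -ncol(Z), drop = FALSE]) > 0
  if (any(unsorted)) {
    Z[unsorted, ] <- t(apply(Z[unsorted, , drop = FALSE], 1, sort))
  }
  out <- 10^Z
  colnames(out) <- paste0("t", format(progress_fractions()))
  if (single) {
    out <- structure(out[1, ], n_reordered = sum(unsorted))
  } else {
    attr(out, "n_reordered") <- sum(unsorted)
  }
  out
}

#' Surrogate as a drop-in model evaluator
#'
#' Wraps a surrogate model as the `(params, cond) -> nine progress times`
#' evaluator the ensemble and map functions accept. The returned function
#' carries a `batch` attribute — `(param matrix, cond) -> n x 9 matrix` —
#' which the rejection sampler and grid evaluators use to amortize
#' prediction cost over thousands of draws.
#'
#' @param sm a [train_surrogate()] model
#' @return An evaluator function with attribute `batch`.
#' @export
sm_evaluator <- function(sm) {
  f <- function(p, cc) sm_predict(sm, p, cc)
  attr(f, "batch") <- function(P, cc) sm_predict(sm, P, cc)
  f
}

#' Write / read a surrogate model
#'
#' Single JSON bundle (full-precision numbers) with weights,
#' standardization constants, and training metadata.
#'
#' @param sm a `surrogate_model`
#' @param path JSON file path
#' @return The path invisibly / a `surrogate_model`.
#' @export
write_surrogate <- function(sm, path) {
  payload <- list(hidden = sm$hidden,
                  weights = lapply(sm$weights, unclass),
                  x_center = as.list(sm$x_center),
                  x_scale = as.list(sm$x_scale),
                  y_center = as.list(sm$y_center),
                  y_scale = as.list(sm$y_scale),
                  metrics = sm$metrics,
                  median_abs_log10_error = sm$median_abs_log10_error,
                  val_msle = sm$val_msle, best_epoch = sm$best_epoch,
                  seed = sm$seed)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(p$weights, function(m) {
    if (is.null(dim(m))) matrix(m, ncol = 1) else m
  })
  # bias vectors serialize as plain arrays; restore column-vector shape
  for (i in seq_along(weights)) {
    if (grepl("^b", names(weights)[i])) {
      weights[[i]] <- matrix(as.numeric(weights[[i]]), ncol = 1)
    }
  }
  structure(list(weights = weights, hidden = as.integer(p$hidden),
                 x_center = unlist(p$x_center),
                 x_scale = unlist(p$x_scale),
                 y_center = unlist(p$y_center),
                 y_scale = unlist(p$y_scale),
                 metrics = tibble::as_tibble(p$metrics),
                 median_abs_log10_error = p$median_abs_log10_error,
                 val_msle = p$val_msle, best_epoch = p$best_epoch,
                 seed = p$seed),
            class = "surrogate_model")
}
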