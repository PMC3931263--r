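#' Options controlling the least-squares fit
#'
#' @param max_iterations Iteration cap for the Levenberg-Marquardt search.
#' @param ftol,ptol Relative stopping tolerances on the sum of squares and
#'   on the parameter vector.
#' @param rescale If `TRUE` (default) the trace is rescaled to span
#'   \[0, 1\] in x and y before fitting, so the SSE <= 0.001 success
#'   criterion is scale-free across models and units; fitted parameters are
#'   reported back-transformed to original units.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_iterations = 1000L, ftol = 1e-8, ptol = 1e-8,
                        rescale = TRUE) {
  if (max_iterations < 1L || ftol <= 0 || ptol <= 0) {
    rlang::abort("Iterations must be >= 1 and tolerances > 0.",
                 class = "sweepkit_error_argument")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 ftol = ftol, ptol = ptol, rescale = isTRUE(rescale)),
            class = "fit_options")
}

#' Affine transform mapping a fit window onto the unit square
#'
#' @param trace A [trace()].
#' @param region Fit [region()] (defaults to the whole trace).
#' @return A list of class `rescale_transform` with fields `x_offset`,
#'   `x_scale`, `y_offset`, `y_scale`; [apply_rescale()] and
#'   [invert_rescale()] apply and undo it.
#' @export
rescale_transform <- function(trace, region = NULL) {
  stopifnot(is_trace(trace))
  if (is.null(region)) region <- region(1L, length(trace$samples))
  check_region(region, trace, min_len = 2L)
  y <- trace$samples[region_indices(region)]
  yr <- diff(range(y))
  structure(list(
    x_offset = trace$t0 + (region$start - 1L) * trace$dt,
    x_scale = (region$end - region$start) * trace$dt,
    y_offset = min(y),
    y_scale = if (yr > 0) yr else 1
  ), class = "rescale_transform")
}

#' @rdname rescale_transform
#' @param transform A `rescale_transform`.
#' @export
apply_rescale <- function(trace, transform) {
  trace((trace$samples - transform$y_offset) / transform$y_scale,
        dt = trace$dt / transform$x_scale, y_unit = "1",
        t0 = (trace$t0 - transform$x_offset) / transform$x_scale)
}

#' @rdname rescale_transform
#' @export
invert_rescale <- function(trace, transform) {
  trace(trace$samples * transform$y_scale + transform$y_offset,
        dt = trace$dt * transform$x_scale, y_unit = "1",
        t0 = trace$t0 * transform$x_scale + transform$x_offset)
}

#' Fit a model to a trace region by Levenberg-Marquardt least squares
#'
#' Minimizes the sum of squared errors between the trace and the model over
#' the fit region, starting from measurement-derived initial estimates
#' (`initial = "auto"`, see [init_params()]) or a user-supplied parameter
#' vector. Model time runs from 0 at the first sample of the region. With
#' `options$rescale` the residuals are computed on the \[0, 1\]-normalized
#' trace, and a fit is flagged successful when that normalized SSE is at
#' most 0.001 — an unsuccessful fit is one trapped away from the global
#' minimum.
#'
#' @param trace A [trace()].
#' @param model A `sweep_model` or model name (see [get_model()]).
#' @param region Fit [region()]; default the whole trace.
#' @param initial `"auto"` or a named numeric vector of starting values.
#' @param options A [fit_options()].
#' @return A `sweep_fit` object; see [tidy.sweep_fit()] and
#'   [glance.sweep_fit()].
#' @examples
#' tr <- gen_gaussian_pulse(A = 2, mu = 5, sigma = 1, n = 2000, dt = 0.01)
#' fit <- fit_model(tr, "gaussian")
#' glance(fit)
#' @export
fit_model <- function(trace, model, region = NULL, initial = "auto",
                      options = fit_options()) {
  stopifnot(is_trace(trace))
  if (is.character(model)) model <- get_model(model)
  if (is.null(region)) region <- region(1L, length(trace$samples))
  check_region(region, trace, min_len = length(model$param_names) + 1L)

  idx <- region_indices(region)
  y <- trace$samples[idx]
  t <- (seq_along(idx) - 1) * trace$dt
  tf <- rescale_transform(trace, region)
  yscale <- if (options$rescale) tf$y_scale else 1

  if (identical(initial, "auto")) {
    start <- init_params(model, trace, region)
  } else {
    start <- clip_params(as.numeric(initial[model$param_names]) |>
                           stats::setNames(model$param_names), model)
    if (anyNA(start)) {
      rlang::abort("`initial` must name every model parameter.",
                   class = "sweepkit_error_argument")
    }
  }

  resid_fun <- function(p) {
    r <- (model$fun(as.list(stats::setNames(p, model$param_names)), t) - y) / yscale
    r[!is.finite(r)] <- 1e6
    r
  }
  res <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = model$lower, upper = model$upper,
    control = minpack.lm::nls.lm.control(
      maxiter = min(options$max_iterations, 1024L),
      ftol = options$ftol, ptol = options$ptol)
  )
  params <- stats::setNames(as.numeric(res$par), model$param_names)
  r_scaled <- (model$fun(as.list(params), t) - y) / tf$y_scale
  sse_scaled <- sum(r_scaled^2)
  sse_raw <- sum((r_scaled * tf$y_scale)^2)
  converged <- res$info %in% 1:4
  structure(list(
    model = model, params = params, initial_params = start,
    sse = sse_scaled, sse_raw = sse_raw,
    iterations = res$niter, converged = converged,
    success = converged && sse_scaled <= 1e-3,
    region = region, transform = tf,
    times = t + trace$t0 + (region$start - 1L) * trace$dt,
    observed = y, fitted = model$fun(as.list(params), t),
    info = res$info, message = res$message
  ), class = "sweep_fit")
}

#' @export
print.sweep_fit <- function(x, ...) {
  cat(sprintf("<sweep_fit> %s: SSE(normalized) = %.3g, %d iterations, %s\n",
              x$model$name, x$sse, x$iterations,
              if (x$success) "successful" else "NOT successful"))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted model
#'
#' @param x A `sweep_fit` from [fit_model()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `initial`.
#' @method tidy sweep_fit
#' @export
tidy.sweep_fit <- function(x, ...) {
  tibble::tibble(term = x$model$param_names,
                 estimate = unname(x$params),
                 initial = unname(x$initial_params))
}

#' One-row fit summary
#'
#' @param x A `sweep_fit`.
#' @param ... Unused.
#' @return Tibble: `model`, `sse` (normalized), `sse_raw`, `iterations`,
#'   `converged`, `success`.
#' @method glance sweep_fit
#' @export
glance.sweep_fit <- function(x, ...) {
  tibble::tibble(model = x$model$name, sse = x$sse, sse_raw = x$sse_raw,
                 iterations = x$iterations, converged = x$converged,
                 success = x$success)
}

#' Validate fit convergence over a randomized parameter grid
#'
#' Reproduces the convergence benchmark for initial-estimate strategies:
#' noise-free traces are generated from the model with every parameter
#' multiplied by an independent N(1, cv) draw (redrawn until inside the
#' model's constraints), then fitted either with measurement-derived initial
#' estimates (`init = "measurements"`) or with every fit started at the mean
#' parameter vector of the whole grid (`init = "average_of_grid"`, the
#' contrast condition). A trace counts as unsuccessful when its normalized
#' SSE exceeds 0.001 or the fit errors out.
#'
#' @param model A `sweep_model` or name.
#' @param n_traces Number of randomized traces.
#' @param seed Optional RNG seed for reproducible grids.
#' @param init `"measurements"` or `"average_of_grid"`.
#' @param cv SD of the multiplicative parameter randomization.
#' @return Tibble: `model`, `init`, `traces_tested`, `mean_sse`,
#'   `pct_unsuccessful`.
#' @export
validate_fit_grid <- function(model, n_traces = 200L, seed = NULL,
                              init = c("measurements", "average_of_grid"),
                              cv = 0.3) {
  if (is.character(model)) model <- get_model(model)
  init <- match.arg(init)
  if (n_traces < 1L) {
    rlang::abort("`n_traces` must be >= 1.", class = "sweepkit_error_argument")
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- randomize_params(model$reference, cv = cv, count = n_traces,
                           lower = model$lower, upper = model$upper)
  n <- round(model$val_tmax / model$val_dt)
  t <- (seq_len(n) - 1) * model$val_dt
  avg <- colMeans(do.call(rbind, grid))
  sses <- purrr::map_dbl(grid, function(p) {
    tr <- trace(model$fun(as.list(p), t), dt = model$val_dt, t0 = 0)
    fit <- tryCatch(
      fit_model(tr, model,
                initial = if (init == "measurements") "auto" else avg),
      error = function(e) NULL)
    if (is.null(fit)) Inf else fit$sse
  })
  tibble::tibble(model = model$name, init = init,
                 traces_tested = n_traces,
                 mean_sse = mean(sses[is.finite(sses)]),
                 pct_unsuccessful = 100 * mean(!(sses <= 1e-3)))
}
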