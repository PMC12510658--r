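# Latin-hypercube multistart bounded least-squares calibration and AICc
# model comparison.

#' Prior bounds on the free rate constants
#'
#' Box bounds on the log10 scale covering biologically feasible rates,
#' 1e-4 to 1e2 (per second, or per molecule-per-platelet per second for the
#' bilinear rates) for every free parameter. The fixed rates `th1` and `r3`
#' are excluded.
#'
#' @param model `ppi_model` or variant id.
#' @param lower,upper log10 bounds applied to every free parameter.
#' @return List of class `ppi_bounds` with named `lower` and `upper`
#'   log10 vectors.
#' @export
ppi_bounds <- function(model = "A0", lower = -4, upper = 2) {
  model <- .ppi_as_model(model)
  if (lower >= upper) stop("lower bound must be below upper bound")
  structure(list(
    lower = setNames(rep(lower, model$K), model$free_parameters),
    upper = setNames(rep(upper, model$K), model$free_parameters),
    variant = model$variant
  ), class = "ppi_bounds")
}

#' Latin hypercube start points
#'
#' Stratified sample of start points in the log10 prior box: each marginal is
#' divided into `n_starts` equal log-width bins holding exactly one point.
#'
#' @param bounds [ppi_bounds()].
#' @param n_starts Number of start points, >= 1.
#' @param seed Integer RNG seed.
#' @return Matrix (`n_starts` x K) of log10 rate constants, columns named by
#'   parameter.
#' @export
ppi_lhs <- function(bounds, n_starts, seed = 1) {
  stopifnot(inherits(bounds, "ppi_bounds"), n_starts >= 1)
  k <- length(bounds$lower)
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, k)
  pts <- sweep(u, 2, bounds$upper - bounds$lower, `*`)
  pts <- sweep(pts, 2, bounds$lower, `+`)
  colnames(pts) <- names(bounds$lower)
  pts
}

#' Normalised sum of squared errors
#'
#' Cost of a parameter set against the mean view of a dataset:
#' \deqn{SSE = \sum_{ij} (\hat y_{ij} - d_{ij})^2} over the 7 x 6 grid of
#' (timepoint, observed species) cells, where both the model prediction and
#' the data for species j are first divided by that species' maximum
#' observed mean. The normalisation makes pools whose copy numbers differ by
#' three orders of magnitude commensurate. Unobserved states (Pp, Ip, IP3,
#' PIc) do not enter; where a variant splits an observed pool, the free and
#' bound parts are summed before comparison.
#'
#' @param model `ppi_model` or variant id.
#' @param params Full rate-constant vector.
#' @param data [ppi_data()] dataset covering the six species.
#' @param stim Stimulus parameters.
#' @param settings Solver settings.
#' @return Dimensionless cost (`Inf` with attribute `failed = TRUE` if the
#'   integration fails).
#' @export
ppi_sse <- function(model, params, data, stim = ppi_stimulus_params(),
                    settings = ppi_solver_settings()) {
  r <- .ppi_residuals(model, params, data, stim, settings)
  if (is.null(r)) return(structure(Inf, failed = TRUE))
  sum(r^2)
}

# normalised residual vector over the 42 cells (NULL on solver failure)
.ppi_residuals <- function(model, params, data, stim, settings) {
  model <- .ppi_as_model(model)
  tr <- tryCatch(
    suppressWarnings(
      ppi_integrate(model, params, stim = stim, times = data$times,
                    settings = settings)),
    error = function(e) NULL)
  if (is.null(tr)) return(NULL)
  pred <- .ppi_observe(tr$states, model)
  scale <- apply(data$means, 2, max)
  scale[scale <= 0] <- 1
  as.vector(sweep(pred - data$means, 2, scale, `/`))
}

#' Corrected Akaike information criterion
#'
#' \deqn{AICc = n \ln(SSE/n) + 2K + 2K(K+1)/(n-K-1)} for a least-squares fit
#' with `K` free parameters and `n` observations; the correction term
#' penalises complexity more strongly for small samples.
#'
#' @param sse Positive sum of squared errors.
#' @param n Number of observations (42 on the default grid).
#' @param K Number of free parameters; requires `n > K + 1`.
#' @return AICc value (comparable only across models fitted to the same
#'   data).
#' @export
ppi_aicc <- function(sse, n, K) {
  if (any(sse <= 0)) stop("sse must be positive")
  if (n <= K + 1) stop("AICc undefined for n <= K + 1")
  n * log(sse / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Single bounded local fit
#'
#' Levenberg-Marquardt least squares on the log10 parameter scale from one
#' start point, with box bounds equal to the priors. Convergence follows the
#' optimiser's relative-improvement test (ftol 1e-8) within 500 iterations;
#' a failed integration during the search scores a large constant residual
#' so the run continues.
#'
#' @param model `ppi_model` or variant id.
#' @param start Named log10 start vector inside the bounds.
#' @param data [ppi_data()] dataset.
#' @param bounds [ppi_bounds()].
#' @param stim Stimulus parameters.
#' @param settings Solver settings.
#' @return List: `par` (natural-scale free rates), `log10_par`, `sse`,
#'   `converged`, `iterations`, `failed` (integration never succeeded).
#' @export
ppi_fit_once <- function(model, start, data, bounds = NULL,
                         stim = ppi_stimulus_params(),
                         settings = ppi_solver_settings()) {
  model <- .ppi_as_model(model)
  if (is.null(bounds)) bounds <- ppi_bounds(model)
  start <- start[model$free_parameters]
  if (any(is.na(start)))
    stop("start must name every free parameter of ", model$variant)
  if (any(start < bounds$lower - 1e-9) || any(start > bounds$upper + 1e-9))
    stop("start lies outside the prior bounds")
  ncell <- length(data$means)
  fail_resid <- rep(1e4, ncell)
  resfun <- function(lp) {
    p <- ppi_parameters(model, setNames(10^lp, model$free_parameters))
    r <- .ppi_residuals(model, p, data, stim, settings)
    if (is.null(r) || any(!is.finite(r))) fail_resid else r
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = unname(bounds$lower), upper = unname(bounds$upper),
    fn = resfun,
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-8, ptol = 1e-8, maxfev = 20000)
  )
  lp <- setNames(pmin(pmax(coef(fit), bounds$lower), bounds$upper),
                 model$free_parameters)
  r <- resfun(lp)
  sse <- sum(r^2)
  list(par = setNames(10^lp, model$free_parameters), log10_par = lp,
       sse = sse, converged = fit$info %in% 1:4,
       iterations = fit$niter, failed = identical(r, fail_resid))
}

#' Fit a model variant to time-course data
#'
#' The central calibration routine: `n_starts` Latin-hypercube start points
#' in the log10 prior box, each refined by bounded Levenberg-Marquardt least
#' squares against the dataset's mean view, ranked by the normalised SSE.
#' Returns the full multistart ensemble; the best 10 fits form the
#' simulation ensemble and the best 100 the parameter-uncertainty ranges.
#'
#' @param model `ppi_model` or variant id.
#' @param data [ppi_data()] dataset (fitting consumes the mean view; the
#'   replicates only inform the noise model).
#' @param n_starts Number of multistart points (the full study used 20,000;
#'   200 gives a usable desk-scale ensemble).
#' @param seed Integer seed for the Latin hypercube.
#' @param bounds [ppi_bounds()].
#' @param stim Stimulus parameters used during calibration.
#' @param settings Solver settings.
#' @param starts Optional explicit matrix of log10 start points (overrides
#'   `n_starts`/`seed`).
#' @return Object of class `ppi_fit`: a ranked ensemble with components
#'   `fits` (data frame: start id, sse, aicc, converged, failed, one column
#'   per log10 parameter), `best` (best single fit), `model`, `data`,
#'   `bounds`, `n` (42), `K`, `stim`, `settings`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' d <- ppi_generate(noise = ppi_noise(seed = 2))
#' f <- ppi_fit("A0", d, n_starts = 20, seed = 1)
#' coef(f)
#' }
#' @export
ppi_fit <- function(model, data, n_starts = 200, seed = 1, bounds = NULL,
                    stim = ppi_stimulus_params(),
                    settings = ppi_solver_settings(), starts = NULL) {
  model <- .ppi_as_model(model)
  stopifnot(inherits(data, "ppi_data"))
  if (is.null(bounds)) bounds <- ppi_bounds(model)
  if (is.null(starts)) starts <- ppi_lhs(bounds, n_starts, seed)
  n_starts <- nrow(starts)
  n <- length(data$means)
  K <- model$K

  res <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    res[[i]] <- ppi_fit_once(model, starts[i, ], data, bounds,
                             stim, settings)
  }
  ok <- !vapply(res, `[[`, logical(1), "failed")
  if (!any(ok))
    stop("all ", n_starts, " starts failed to integrate for ",
         model$variant)
  sse <- vapply(res, `[[`, numeric(1), "sse")
  ord <- order(sse)
  lp <- do.call(rbind, lapply(res, `[[`, "log10_par"))
  fits <- data.frame(
    start = ord,
    sse = sse[ord],
    aicc = ppi_aicc(pmax(sse[ord], .Machine$double.xmin), n, K),
    converged = vapply(res, `[[`, logical(1), "converged")[ord],
    failed = !ok[ord]
  )
  fits <- cbind(fits, as.data.frame(lp[ord, , drop = FALSE]))
  rownames(fits) <- NULL
  structure(list(
    fits = fits, best = res[[ord[1]]], model = model,
    data = data, bounds = bounds, n = n, K = K,
    n_starts = n_starts, seed = seed, stim = stim, settings = settings
  ), class = "ppi_fit")
}

# natural-scale full parameter vector of the fit ranked `rank`
.ppi_fit_params <- function(object, rank = 1) {
  lp <- unlist(object$fits[rank, object$model$free_parameters])
  ppi_parameters(object$model,
                 setNames(10^lp, object$model$free_parameters))
}

#' Parameter uncertainty ranges
#'
#' Quantile bands of the best `top_k` fits per free parameter on the log10
#' scale: the median and the 5-95, 25-75 and 45-55 intervals. A parameter
#' whose 5-95 band spans at least five of the six prior decades is flagged
#' non-identifiable (its value is not constrained by the data).
#'
#' @param object `ppi_fit` ensemble.
#' @param top_k Number of best fits forming the ranges (all fits, with a
#'   warning, if the ensemble is smaller).
#' @return Data frame: parameter, median and quantile columns (log10),
#'   `non_identifiable` flag.
#' @export
ppi_uncertainty <- function(object, top_k = 100) {
  stopifnot(inherits(object, "ppi_fit"))
  k <- min(top_k, nrow(object$fits))
  if (k < top_k)
    warning("ensemble has only ", k, " fits; using all of them")
  lp <- as.matrix(object$fits[seq_len(k), object$model$free_parameters,
                              drop = FALSE])
  qs <- apply(lp, 2, quantile, probs = c(0.05, 0.25, 0.45, 0.5, 0.55,
                                         0.75, 0.95), names = FALSE)
  span <- diff(range(object$bounds$upper[1], object$bounds$lower[1]))
  out <- data.frame(
    parameter = colnames(lp),
    q05 = qs[1, ], q25 = qs[2, ], q45 = qs[3, ], median = qs[4, ],
    q55 = qs[5, ], q75 = qs[6, ], q95 = qs[7, ],
    row.names = NULL
  )
  out$non_identifiable <- (out$q95 - out$q05) >= 5
  out
}

#' Rank fitted model variants by AICc
#'
#' Builds the model-comparison table from ensembles fitted to the same
#' dataset: per variant the minimum SSE/n, the median SSE/n of the best 100
#' fits, the minimum AICc and the free-parameter count, ranked by ascending
#' AICc (ties broken by smaller K, then variant id).
#'
#' @param ... `ppi_fit` objects (or a single list of them).
#' @return Data frame of class `ppi_ranking`, ordered by rank.
#' @export
ppi_rank <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "ppi_fit"))
    fits <- fits[[1]]
  if (length(fits) < 2) stop("need at least two fitted variants to rank")
  stopifnot(all(vapply(fits, inherits, logical(1), "ppi_fit")))
  ref <- fits[[1]]$data$means
  for (f in fits[-1])
    if (!isTRUE(all.equal(f$data$means, ref)))
      stop("all ensembles must be fitted to the same dataset")
  rows <- lapply(fits, function(f) {
    k100 <- min(100, nrow(f$fits))
    data.frame(
      variant = f$model$variant,
      min_sse_n = min(f$fits$sse) / f$n,
      median_sse_n = median(f$fits$sse[seq_len(k100)]) / f$n,
      min_aicc = min(f$fits$aicc),
      K = f$K,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$min_aicc, tab$K, tab$variant)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("ppi_ranking", "data.frame")
  tab
}

#' @export
print.ppi_ranking <- function(x, ...) {
  cat("Model comparison (ascending AICc):\n")
  y <- as.data.frame(x)
  y$min_sse_n <- signif(y$min_sse_n, 3)
  y$median_sse_n <- signif(y$median_sse_n, 3)
  y$min_aicc <- round(y$min_aicc, 1)
  print(y, row.names = FALSE)
  cat("ranking:", paste(x$variant, collapse = " < "), "\n")
  invisible(x)
}

#' Export a fit ensemble to CSV
#'
#' One row per multistart fit: variant, start index, SSE, AICc, convergence
#' flag and the log10 parameters.
#' @param object `ppi_fit`.
#' @param path CSV path.
#' @export
ppi_write_ensemble <- function(object, path) {
  stopifnot(inherits(object, "ppi_fit"))
  df <- cbind(variant = object$model$variant, object$fits)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
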