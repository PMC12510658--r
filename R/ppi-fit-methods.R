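# Standard model-object methods for ppi_fit ensembles.

#' @export
print.ppi_fit <- function(x, ...) {
  cat("Multistart calibration of", x$model$variant, "(",
      x$n_starts, "starts )\n")
  cat("  n =", x$n, "observations, K =", x$K, "free rate constants\n")
  cat("  best SSE/n =", signif(min(x$fits$sse) / x$n, 4),
      "  min AICc =", round(min(x$fits$aicc), 1), "\n")
  cat("  converged:", sum(x$fits$converged), "of", nrow(x$fits), "\n")
  invisible(x)
}

#' @export
summary.ppi_fit <- function(object, top_k = 100, ...) {
  unc <- ppi_uncertainty(object,
                         top_k = min(top_k, nrow(object$fits)))
  structure(list(
    variant = object$model$variant,
    n_starts = object$n_starts,
    n = object$n, K = object$K,
    min_sse_n = min(object$fits$sse) / object$n,
    median_sse_n = median(object$fits$sse[
      seq_len(min(100, nrow(object$fits)))]) / object$n,
    min_aicc = min(object$fits$aicc),
    uncertainty = unc
  ), class = "summary.ppi_fit")
}

#' @export
print.summary.ppi_fit <- function(x, ...) {
  cat("Variant", x$variant, ":", x$n_starts, "starts, n =", x$n,
      ", K =", x$K, "\n")
  cat("  min SSE/n =", signif(x$min_sse_n, 3),
      "; median SSE/n (best 100) =", signif(x$median_sse_n, 3),
      "; min AICc =", round(x$min_aicc, 1), "\n\n")
  cat("Parameter uncertainty (log10 scale, best fits):\n")
  u <- x$uncertainty
  u[-1] <- lapply(u[-1], function(col)
    if (is.numeric(col)) round(col, 2) else col)
  print(u, row.names = FALSE)
  if (any(x$uncertainty$non_identifiable))
    cat("non-identifiable (5-95 band spans >= 5 decades):",
        paste(x$uncertainty$parameter[x$uncertainty$non_identifiable],
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ppi_fit <- function(object, rank = 1, fixed = FALSE, ...) {
  p <- .ppi_fit_params(object, rank)
  if (!fixed) p <- p[object$model$free_parameters]
  p
}

#' Predict trajectories from a fitted ensemble
#'
#' Integrates the variant under the fitted rate constants. By default the
#' best fit on the observation grid; `ranks` selects other ensemble members
#' (e.g. `1:10` for the simulation ensemble) and `times` a denser grid.
#'
#' @param object `ppi_fit`.
#' @param times Output grid (defaults to the observation grid).
#' @param ranks Which ensemble fits to simulate, by SSE rank.
#' @param observed If `TRUE`, return only the six observed species (with
#'   bound pools summed); otherwise all state variables.
#' @param ... Unused.
#' @return Long data frame: `time_s`, `species`, `value`, `variant`,
#'   `fit_rank`.
#' @export
predict.ppi_fit <- function(object, times = NULL, ranks = 1,
                            observed = TRUE, ...) {
  if (is.null(times)) times <- object$data$times
  out <- lapply(ranks, function(r) {
    tr <- ppi_integrate(object$model, .ppi_fit_params(object, r),
                        stim = object$stim, times = times,
                        settings = object$settings)
    states <- if (observed) .ppi_observe(tr$states, object$model)
              else tr$states
    data.frame(
      time_s = rep(tr$times, times = ncol(states)),
      species = rep(colnames(states), each = length(tr$times)),
      value = as.vector(states),
      variant = object$model$variant,
      fit_rank = r,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' @export
residuals.ppi_fit <- function(object, rank = 1, ...) {
  r <- .ppi_residuals(object$model, .ppi_fit_params(object, rank),
                      object$data, object$stim, object$settings)
  matrix(r, nrow = length(object$data$times),
         dimnames = list(NULL, colnames(object$data$means)))
}

#' Simulate datasets from a fitted model
#'
#' Parametric simulation: draws `nsim` replicate datasets from the fitted
#' (best) parameter set under the dataset's noise model.
#'
#' @param object `ppi_fit`.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param cv,n_replicates Noise model; defaults to the generator defaults.
#' @param ... Unused.
#' @return List of [ppi_data()] objects.
#' @export
simulate.ppi_fit <- function(object, nsim = 1, seed = 1, cv = 0.2,
                             n_replicates = 3, ...) {
  lapply(seq_len(nsim), function(i)
    ppi_simulate_dataset(object$model, .ppi_fit_params(object, 1),
                         stim = object$stim,
                         noise = ppi_noise(cv, n_replicates,
                                           seed = seed + i - 1),
                         times = object$data$times,
                         settings = object$settings))
}

#' Plot a fitted ensemble against the data
#'
#' One panel per observed species: replicate measurements (points), the mean
#' view (filled points), the best-10 simulation ensemble (grey) and the best
#' fit (black).
#'
#' @param x `ppi_fit`.
#' @param ranks Ensemble members to draw.
#' @param ... Passed to `plot`.
#' @export
plot.ppi_fit <- function(x, ranks = seq_len(min(10, nrow(x$fits))), ...) {
  dense <- seq(0, max(x$data$times), length.out = 121)
  pred <- predict(x, times = dense, ranks = ranks)
  op <- par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (sp in colnames(x$data$means)) {
    ps <- pred[pred$species == sp, ]
    reps <- x$data$replicates[x$data$replicates$species == sp, ]
    ylim <- range(ps$value, reps$value, 0)
    plot(NA, xlim = range(dense), ylim = ylim, xlab = "time (s)",
         ylab = "molecules/platelet", main = sp, ...)
    for (r in rev(ranks)) {
      pr <- ps[ps$fit_rank == r, ]
      lines(pr$time_s, pr$value,
            col = if (r == 1) "black" else "grey70",
            lwd = if (r == 1) 2 else 1)
    }
    points(reps$time_s, reps$value, col = "red3", pch = 1, cex = 0.7)
    points(x$data$times, x$data$means[, sp], col = "red3", pch = 16)
  }
  invisible(x)
}
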