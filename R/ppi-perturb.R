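# Perturbation studies: local sensitivity scores, inhibitor simulation and
# stimulus-reshaping scenarios on fitted ensembles.

#' Local sensitivity analysis
#'
#' Varies each selected rate constant 50% above and below its base value,
#' re-integrates, and scores the effect on each state's endpoint (600 s on
#' the default grid) as \deqn{(O_a - O_i)/O_a,} where `O_i` is the baseline
#' endpoint and `O_a` the endpoint under the adapted parameter. Scores are
#' undefined (NA) where the perturbed endpoint is zero.
#'
#' @param model `ppi_model` or variant id.
#' @param params Full rate-constant vector of the base fit.
#' @param parameters Which rate constants to vary; defaults to the forward
#'   rates present in the variant (r1, r2, r3, r4, th1..th6 as applicable).
#' @param factor Fractional variation (0.5 = +/-50%).
#' @param ics,stim,times,settings Passed to [ppi_integrate()].
#' @return Object of class `ppi_sensitivity`: matrix of scores with rows
#'   `<parameter>+` / `<parameter>-` and one column per state.
#' @export
ppi_sensitivity <- function(model, params, parameters = NULL, factor = 0.5,
                            ics = NULL, stim = ppi_stimulus_params(),
                            times = ppi_times(),
                            settings = ppi_solver_settings()) {
  model <- .ppi_as_model(model)
  all_rates <- c(model$free_parameters, names(model$fixed_parameters))
  if (is.null(parameters)) {
    forward <- c("r1", "r2", "r3", "r4", "th1", "th2", "th3", "th4",
                 "th5", "th6")
    parameters <- intersect(forward, all_rates)
  }
  bad <- setdiff(parameters, all_rates)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  base <- ppi_integrate(model, params, ics = ics, stim = stim,
                        times = times, settings = settings)
  o_i <- base$states[nrow(base$states), ]
  dirs <- c(`+` = 1 + factor, `-` = 1 - factor)
  rows <- character(0)
  scores <- NULL
  for (p in parameters) {
    for (d in names(dirs)) {
      pp <- params
      pp[[p]] <- pp[[p]] * dirs[[d]]
      tr <- ppi_integrate(model, pp, ics = ics, stim = stim,
                          times = times, settings = settings)
      o_a <- tr$states[nrow(tr$states), ]
      sc <- ifelse(o_a == 0, NA_real_, (o_a - o_i) / o_a)
      scores <- rbind(scores, sc)
      rows <- c(rows, paste0(p, d))
    }
  }
  rownames(scores) <- rows
  structure(scores, class = c("ppi_sensitivity", "matrix"),
            variant = model$variant, factor = factor)
}

#' @export
print.ppi_sensitivity <- function(x, ...) {
  cat("Local sensitivity of 600 s endpoints,", attr(x, "variant"),
      "( +/-", attr(x, "factor") * 100, "% )\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' @export
plot.ppi_sensitivity <- function(x, ...) {
  m <- unclass(x)
  m[is.na(m)] <- 0
  pal <- colorRampPalette(c("blue3", "white", "red3"))(101)
  lim <- max(abs(m), 1e-12)
  op <- par(mar = c(5, 6, 2, 1))
  on.exit(par(op))
  image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m)))],
        zlim = c(-lim, lim), col = pal, axes = FALSE, xlab = "", ylab = "",
        main = paste("Sensitivity,", attr(x, "variant")), ...)
  axis(1, seq_len(ncol(m)), colnames(m), las = 2)
  axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 1)
  invisible(x)
}

#' Perturbation scenarios
#'
#' A scenario is a stimulus shape plus an optional rate-constant scaling.
#' `ppi_scenarios()` returns the built-in set: the GSK-A1 inhibitor
#' (`r1` scaled to 10% of its fitted value, modelling PI4KA inhibition) and
#' the three stimulus reshapings — (i) `reduced-plateau`: plateau halved
#' (a1 = 0.001, a2 = 2e-4, a3 = 0.5, a4 = 0.02); (ii) `early-peak`:
#' transient overshoot added (a1 = 0.03, a2 = 2e-3, a3 = 1, a4 = 0.02);
#' (iii) `combined`: early peak and halved plateau (a1 = 0.03, a2 = 2e-4,
#' a3 = 0.5, a4 = 0.02).
#'
#' @param label Scenario name.
#' @param stim Stimulus parameters for the scenario.
#' @param scale Named multipliers applied to rate constants (e.g.
#'   `c(r1 = 0.1)`).
#' @return A `ppi_scenario` (or, for `ppi_scenarios()`, a named list of
#'   them).
#' @export
ppi_scenario <- function(label, stim = ppi_stimulus_params(),
                         scale = NULL) {
  structure(list(label = label, stim = .ppi_check_stim(stim),
                 scale = scale), class = "ppi_scenario")
}

#' @rdname ppi_scenario
#' @export
ppi_scenarios <- function() {
  list(
    baseline = ppi_scenario("baseline"),
    gsk_a1 = ppi_scenario("gsk_a1", scale = c(r1 = 0.1)),
    reduced_plateau = ppi_scenario(
      "reduced_plateau", ppi_stimulus_params(0.001, 2e-4, 0.5, 0.02)),
    early_peak = ppi_scenario(
      "early_peak", ppi_stimulus_params(0.03, 2e-3, 1, 0.02)),
    combined = ppi_scenario(
      "combined", ppi_stimulus_params(0.03, 2e-4, 0.5, 0.02))
  )
}

#' Run a scenario over a fitted ensemble
#'
#' Integrates each of the best `ranks` parameter sets of a fitted ensemble
#' under a scenario's stimulus and rate scaling.
#'
#' @param object `ppi_fit` ensemble.
#' @param scenario `ppi_scenario`.
#' @param ranks Ensemble members (default best 10).
#' @param times Output grid.
#' @return List of class `ppi_scenario_run`: `trajectories` (one
#'   `ppi_trajectory` per rank, best fit first; failed integrations are
#'   dropped with a warning), `scenario`, `variant`, `ranks`.
#' @export
ppi_run_scenario <- function(object, scenario,
                             ranks = seq_len(min(10, nrow(object$fits))),
                             times = NULL) {
  stopifnot(inherits(object, "ppi_fit"), inherits(scenario, "ppi_scenario"))
  if (is.null(times)) times <- object$data$times
  trs <- list()
  kept <- integer(0)
  for (r in ranks) {
    p <- .ppi_fit_params(object, r)
    if (!is.null(scenario$scale)) {
      bad <- setdiff(names(scenario$scale), names(p))
      if (length(bad))
        stop("scenario scales unknown parameter(s): ",
             paste(bad, collapse = ", "))
      p[names(scenario$scale)] <- p[names(scenario$scale)] *
        scenario$scale
    }
    tr <- tryCatch(
      ppi_integrate(object$model, p, stim = scenario$stim, times = times,
                    settings = object$settings),
      error = function(e) NULL)
    if (is.null(tr)) next
    trs[[length(trs) + 1]] <- tr
    kept <- c(kept, r)
  }
  if (length(kept) < length(ranks))
    warning("integration failed for fit rank(s) ",
            paste(setdiff(ranks, kept), collapse = ", "))
  structure(list(trajectories = trs, scenario = scenario,
                 variant = object$model$variant, ranks = kept),
            class = "ppi_scenario_run")
}

#' @export
print.ppi_scenario_run <- function(x, ...) {
  cat("Scenario", x$scenario$label, "on", x$variant, ":",
      length(x$trajectories), "ensemble trajectories\n")
  invisible(x)
}

#' Compare scenario trajectories to a baseline
#'
#' Per species and ensemble member: the relative endpoint change
#' `(scenario - baseline)/baseline` and the shift of the within-window peak
#' time. Zero baseline endpoints are flagged with NA.
#'
#' @param baseline,scenario `ppi_scenario_run`s on matching grids and
#'   ensemble ranks.
#' @return Data frame: `species`, `fit_rank`, `baseline_end`,
#'   `scenario_end`, `rel_change`, `peak_shift_s`.
#' @export
ppi_compare_scenarios <- function(baseline, scenario) {
  stopifnot(inherits(baseline, "ppi_scenario_run"),
            inherits(scenario, "ppi_scenario_run"))
  common <- intersect(baseline$ranks, scenario$ranks)
  out <- list()
  for (r in common) {
    b <- baseline$trajectories[[match(r, baseline$ranks)]]
    s <- scenario$trajectories[[match(r, scenario$ranks)]]
    if (!identical(b$times, s$times))
      stop("baseline and scenario grids differ")
    for (sp in colnames(b$states)) {
      be <- b$states[nrow(b$states), sp]
      se <- s$states[nrow(s$states), sp]
      out[[length(out) + 1]] <- data.frame(
        species = sp, fit_rank = r,
        baseline_end = be, scenario_end = se,
        rel_change = if (be == 0) NA_real_ else (se - be) / be,
        peak_shift_s = b$times[which.max(s$states[, sp])] -
          b$times[which.max(b$states[, sp])],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Export scenario trajectories to CSV
#'
#' Shares the trajectory schema (`time_s`, `species`, `value`, `variant`,
#' `fit_rank`) with a `scenario` label column.
#' @param run `ppi_scenario_run`.
#' @param path CSV path.
#' @export
ppi_write_scenario <- function(run, path) {
  stopifnot(inherits(run, "ppi_scenario_run"))
  dfs <- mapply(function(tr, r) {
    df <- as.data.frame(tr)
    df$fit_rank <- r
    df
  }, run$trajectories, run$ranks, SIMPLIFY = FALSE)
  df <- do.call(rbind, dfs)
  df$scenario <- run$scenario$label
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
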