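# Stiff integration of the model family from basal platelet copy numbers.

#' Observation time grid
#'
#' The seven experimental sampling times (seconds) at which platelet
#' phosphoinositides were measured after CRP stimulation.
#' @return Integer vector `c(0, 30, 60, 90, 120, 180, 600)`.
#' @export
ppi_times <- function() c(0L, 30L, 60L, 90L, 120L, 180L, 600L)

#' Basal initial conditions (copy numbers)
#'
#' Resting-platelet abundances, molecules per platelet: PtdIns 2,700,000;
#' PtdIns4P 64,000; PtdIns(4,5)P2 310,000; PtdIns(3,4,5)P3 1,900;
#' PtdIns(3,4)P2 5,200; unmeasured phosphoinositide pool 25,000; IP3 0;
#' unmeasured inositol pool 100,000,000; IP1 0. For `A03` the PtdIns copy
#' number is split evenly between the membrane (`PI`) and intracellular
#' (`PIc`) pools; for `A05` PtdIns(4,5)P2 is split evenly between free
#' (`PIP2`) and bound (`PIP2b`); for `A04` the bound pool `PIP3b` starts
#' at 0.
#'
#' @param model `ppi_model` or variant id.
#' @return Named numeric vector over the variant's states.
#' @examples
#' sum(ppi_initial_conditions("A0"))   # total pathway content, 103,106,100
#' @export
ppi_initial_conditions <- function(model = "A0") {
  model <- .ppi_as_model(model)
  ic <- c(PI = 2.7e6, PI4P = 6.4e4, PIP2 = 3.1e5, PIP3 = 1900,
          PI34P2 = 5200, Pp = 25000, IP3 = 0, IP1 = 0, Ip = 1e8)
  ic <- ic[.ppi_core_states]
  switch(model$variant,
    A03 = { ic[["PI"]] <- 1.35e6; c(ic, PIc = 1.35e6) },
    A04 = c(ic, PIP3b = 0),
    A05 = { ic[["PIP2"]] <- 1.55e5; c(ic, PIP2b = 1.55e5) },
    ic
  )
}

#' Solver settings
#'
#' Tolerances for the stiff adaptive integrator. Fitted rate constants span
#' 1e-4 to 1e2 per second while abundances span 0 to 1e8 molecules per
#' platelet, so the default is a tight relative tolerance with a small
#' absolute floor.
#'
#' @param rtol Relative tolerance (> 0).
#' @param atol Absolute tolerance (> 0, molecules per platelet).
#' @param method deSolve method; `"lsoda"` switches automatically between
#'   stiff and non-stiff steppers.
#' @return List of class `ppi_solver_settings`.
#' @export
ppi_solver_settings <- function(rtol = 1e-8, atol = 1e-6, method = "lsoda") {
  stopifnot(rtol > 0, atol > 0)
  structure(list(rtol = rtol, atol = atol, method = method),
            class = "ppi_solver_settings")
}

#' Integrate a model variant
#'
#' Solves the variant's mass-action ODE system on an output grid, recording a
#' conservation diagnostic (the pathway is closed, so total abundance must be
#' constant). Small negative undershoots within solver tolerance are clamped
#' to zero in the returned states only.
#'
#' @param model `ppi_model` or variant id.
#' @param params Full rate-constant vector ([ppi_parameters()]).
#' @param ics Initial conditions; defaults to [ppi_initial_conditions()].
#' @param stim Stimulus parameters.
#' @param times Output grid (seconds), sorted, starting at 0.
#' @param settings [ppi_solver_settings()].
#' @return Object of class `ppi_trajectory`: list with `times`,
#'   `states` (time x state matrix), `variant`, `params`,
#'   `conservation_error` (max relative drift of the total) and `stim`.
#' @examples
#' tr <- ppi_integrate("A0", ppi_parameters("A0", c(r1 = 0.1, rm1 = 0.05)))
#' tr$conservation_error
#' @export
ppi_integrate <- function(model, params, ics = NULL,
                          stim = ppi_stimulus_params(),
                          times = ppi_times(),
                          settings = ppi_solver_settings()) {
  model <- .ppi_as_model(model)
  if (is.null(ics)) ics <- ppi_initial_conditions(model)
  if (length(ics) != model$n_states)
    stop("initial conditions have length ", length(ics),
         ", expected ", model$n_states, " for ", model$variant)
  if (!is.null(names(ics))) ics <- ics[model$state_names]
  if (any(ics < 0)) stop("initial conditions must be non-negative")
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0)
    stop("output times must be strictly increasing and non-negative")
  pv <- .ppi_pack_parms(model, params, stim)
  t0 <- if (times[1] > 0) c(0, times) else times

  out <- deSolve::ode(
    y = setNames(as.numeric(ics), model$state_names),
    times = t0, func = "ppi_derivs", parms = pv,
    dllname = "ppikin", initfunc = "ppi_initmod",
    rtol = settings$rtol, atol = settings$atol, method = settings$method
  )
  flag <- attr(out, "istate")[1]
  if (is.null(flag) || flag < 0 || nrow(out) < length(t0) ||
      any(!is.finite(out)))
    stop("integration failed for variant ", model$variant,
         " (solver state ", flag, "); parameters: ",
         paste(names(params), signif(unname(params), 3),
               sep = "=", collapse = ", "))
  states <- out[match(times, out[, 1]), model$state_names, drop = FALSE]
  rownames(states) <- NULL
  total0 <- sum(ics)
  cons <- if (total0 > 0)
    max(abs(rowSums(states) - total0)) / total0 else 0
  # clamp sub-tolerance undershoot for reporting only
  states[states < 0 & states > -10 * settings$atol] <- 0
  structure(list(times = times, states = states, variant = model$variant,
                 params = params, stim = stim,
                 conservation_error = cons, settings = settings),
            class = "ppi_trajectory")
}

#' @export
print.ppi_trajectory <- function(x, ...) {
  cat("ppi_trajectory:", x$variant, "over", min(x$times), "-",
      max(x$times), "s at", length(x$times), "output times\n")
  cat("  conservation drift (relative):",
      format(x$conservation_error, digits = 3), "\n")
  cat("  endpoints (molecules/platelet):\n")
  print(signif(x$states[nrow(x$states), ], 4))
  invisible(x)
}

#' Tidy view of a trajectory
#'
#' @param x `ppi_trajectory`.
#' @param row.names,optional Unused, for the generic.
#' @param ... Unused.
#' @return Long data frame with columns `time_s`, `species`, `value`
#'   (molecules per platelet) and `variant`.
#' @export
as.data.frame.ppi_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    time_s = rep(x$times, times = ncol(x$states)),
    species = rep(colnames(x$states), each = length(x$times)),
    value = as.vector(x$states),
    variant = x$variant,
    stringsAsFactors = FALSE
  )
}

#' Endpoint abundance of a trajectory
#'
#' Value of one species at the final output time (600 s on the default
#' grid), used as the steady-state surrogate in sensitivity and scenario
#' analyses.
#'
#' @param traj `ppi_trajectory`.
#' @param species State name present in the trajectory.
#' @return Abundance, molecules per platelet.
#' @export
ppi_endpoint <- function(traj, species) {
  stopifnot(inherits(traj, "ppi_trajectory"))
  if (!species %in% colnames(traj$states))
    stop("unknown species: ", species)
  unname(traj$states[nrow(traj$states), species])
}

#' @export
plot.ppi_trajectory <- function(x, species = NULL, log = "", ...) {
  if (is.null(species)) species <- colnames(x$states)
  op <- par(mfrow = grDevices::n2mfrow(length(species)),
            mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (sp in species) {
    plot(x$times, x$states[, sp], type = "l", xlab = "time (s)",
         ylab = "molecules/platelet", main = sp, log = log, ...)
  }
  invisible(x)
}
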