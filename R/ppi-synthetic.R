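# Synthetic time-course generator emulating the CRP-stimulation dataset:
# 7 timepoints x 6 species, means of 3 replicates, magnitudes anchored to the
# measured copy numbers.

#' Anchor curves of the CRP-stimulation time courses
#'
#' Per-species anchor points (time in seconds, mean abundance in molecules
#' per platelet) and a shape tag describing the measured behaviour:
#' PtdIns rises from 2.3e6 to 2.9e6 over 60 s then declines to 1.5e6 by
#' 600 s (`peak-then-decline`); PtdIns4P stays near its basal 6.4e4
#' (`flat`); PtdIns(4,5)P2 rises 2.9e5 to 4.8e5 over 120 s and stays
#' elevated; PtdIns(3,4,5)P3 rises 2.2e3 to 5.8e3 over 180 s;
#' PtdIns(3,4)P2 rises 0.5e4 to 3.0e4 over 180 s (all
#' `monotone-saturating`, held after the last anchor); IP1 accumulates
#' linearly to 2.1e3 at 600 s (`linear`).
#'
#' @return Named list (one element per observed species) with fields
#'   `anchors` (two-column matrix: `time_s`, `value`) and `shape`.
#' @export
ppi_anchors <- function() {
  a <- function(shape, ...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("time_s", "value")))
    list(anchors = m, shape = shape)
  }
  list(
    PI     = a("peak-then-decline", 0, 2.3e6, 60, 2.9e6, 600, 1.5e6),
    PI4P   = a("flat",              0, 6.4e4),
    PIP2   = a("monotone-saturating", 0, 2.9e5, 120, 4.8e5),
    PIP3   = a("monotone-saturating", 0, 2.2e3, 180, 5.8e3),
    PI34P2 = a("monotone-saturating", 0, 0.5e4, 180, 3.0e4),
    IP1    = a("linear",            0, 0, 600, 2.1e3)
  )
}

# Segment interpolator: exponential approach between consecutive anchors,
# normalised so the curve passes through both ends exactly; shape constant
# 3 puts ~95% of each segment's change before its right anchor. Held
# constant after the last anchor; linear shapes use straight segments.
.ppi_interp <- function(anchor, times) {
  m <- anchor$anchors
  if (is.unsorted(m[, 1], strictly = TRUE) && nrow(m) > 1)
    stop("anchors must be sorted in time")
  if (nrow(m) == 1 || anchor$shape == "flat")
    return(rep(m[1, 2], length(times)))
  if (anchor$shape == "linear") {
    out <- approx(m[, 1], m[, 2], xout = pmin(times, max(m[, 1])),
                  rule = 2)$y
    return(out)
  }
  cshape <- 3
  vapply(times, function(t) {
    t <- min(t, m[nrow(m), 1])            # hold after last anchor
    i <- findInterval(t, m[, 1], rightmost.closed = TRUE)
    i <- min(max(i, 1), nrow(m) - 1)
    t0 <- m[i, 1]; t1 <- m[i + 1, 1]
    v0 <- m[i, 2]; v1 <- m[i + 1, 2]
    u <- (t - t0) / (t1 - t0)
    v0 + (v1 - v0) * (1 - exp(-cshape * u)) / (1 - exp(-cshape))
  }, numeric(1))
}

#' Noiseless mean curves
#'
#' Smooth interpolation through the anchor points at the requested times:
#' piecewise exponential approach for the saturating/peaked lipid curves,
#' linear accumulation for IP1, constant for the flat PtdIns4P curve. Passes
#' through every anchor exactly.
#'
#' @param anchors [ppi_anchors()]-style list.
#' @param times Times in seconds within `[0, 600]`.
#' @return Matrix (time x species) of mean abundances.
#' @examples
#' mc <- ppi_mean_curves()
#' mc[, "PI34P2"][c(1, 6)]   # 5,000 -> 30,000: the 6-fold rise
#' @export
ppi_mean_curves <- function(anchors = ppi_anchors(), times = ppi_times()) {
  if (any(times < 0) || any(times > 600))
    stop("times must lie in [0, 600] seconds")
  out <- vapply(anchors, .ppi_interp, numeric(length(times)), times = times)
  if (length(times) == 1) out <- matrix(out, nrow = 1,
                                        dimnames = list(NULL, names(anchors)))
  rownames(out) <- NULL
  out
}

#' Replicate noise model
#'
#' Multiplicative lognormal measurement noise: each replicate value is the
#' mean times a unit-mean lognormal factor with the stated coefficient of
#' variation. The default cv of 0.20 matches the scatter of the measured
#' copy numbers (basal PtdIns 2.3 +/- 0.5 e6 gives cv ~ 0.22).
#'
#' @param cv Coefficient of variation per replicate, >= 0.
#' @param n_replicates Replicates per (time, species) cell, >= 1.
#' @param seed Integer RNG seed.
#' @return List of class `ppi_noise`.
#' @export
ppi_noise <- function(cv = 0.20, n_replicates = 3, seed = 1) {
  stopifnot(cv >= 0, n_replicates >= 1)
  structure(list(cv = cv, n_replicates = n_replicates, seed = seed),
            class = "ppi_noise")
}

.ppi_apply_noise <- function(mean_mat, times, noise) {
  species <- colnames(mean_mat)
  grid <- expand.grid(replicate = seq_len(noise$n_replicates),
                      time_s = times, species = species,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- mean_mat[cbind(match(grid$time_s, times),
                       match(grid$species, species))]
  set.seed(noise$seed)
  if (noise$cv > 0) {
    sdlog <- sqrt(log(1 + noise$cv^2))
    fac <- rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    fac <- rep(1, nrow(grid))
  }
  data.frame(time_s = grid$time_s, species = grid$species,
             replicate = grid$replicate, value = pmax(mu * fac, 0),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic dataset from the anchor curves
#'
#' Emulates the structure of the CRP-stimulation measurements: the noiseless
#' anchor-interpolated means on the 7 x 6 observation grid, with replicate
#' lognormal noise. With a fixed seed the dataset is bitwise reproducible.
#'
#' @param anchors [ppi_anchors()]-style list.
#' @param noise [ppi_noise()] model.
#' @param times Observation grid.
#' @return [ppi_data()] object; `truth` records the noiseless means.
#' @examples
#' d <- ppi_generate(noise = ppi_noise(cv = 0.2, seed = 7))
#' dim(d$means)    # 7 x 6
#' @export
ppi_generate <- function(anchors = ppi_anchors(), noise = ppi_noise(),
                         times = ppi_times()) {
  mm <- ppi_mean_curves(anchors, times)
  reps <- .ppi_apply_noise(mm, times, noise)
  ppi_data(reps, truth = list(kind = "anchors", variant = NA_character_,
                              means = mm, times = times, noise = noise))
}

#' Generate a synthetic dataset from a model variant
#'
#' Integrates a variant from its basal initial conditions, samples the six
#' observed species on the observation grid (summing free and bound pools
#' where a variant splits one: `PIP3 + PIP3b` in `A04`, `PIP2 + PIP2b` in
#' `A05`), and applies the replicate noise model. The generating variant and
#' parameters are recorded for parameter-recovery scoring.
#'
#' @param model `ppi_model` or variant id.
#' @param params Full rate-constant vector.
#' @param stim Stimulus parameters.
#' @param noise [ppi_noise()] model.
#' @param times Observation grid.
#' @param settings Solver settings.
#' @return [ppi_data()] object with `truth` holding variant, parameters and
#'   the noiseless grid values.
#' @export
ppi_simulate_dataset <- function(model, params,
                                 stim = ppi_stimulus_params(),
                                 noise = ppi_noise(),
                                 times = ppi_times(),
                                 settings = ppi_solver_settings()) {
  model <- .ppi_as_model(model)
  tr <- ppi_integrate(model, params, stim = stim, times = times,
                      settings = settings)
  mm <- .ppi_observe(tr$states, model)
  reps <- .ppi_apply_noise(mm, times, noise)
  ppi_data(reps, truth = list(kind = "model", variant = model$variant,
                              params = params, stim = stim,
                              means = mm, times = times, noise = noise,
                              trajectory = tr))
}

# map full state matrix to the 6 observed species (pool sums for A04/A05)
.ppi_observe <- function(states, model) {
  out <- states[, .ppi_observed_species, drop = FALSE]
  if (model$variant == "A04")
    out[, "PIP3"] <- out[, "PIP3"] + states[, "PIP3b"]
  if (model$variant == "A05")
    out[, "PIP2"] <- out[, "PIP2"] + states[, "PIP2b"]
  out
}
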