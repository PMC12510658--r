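# Model family: state spaces, rate constants and mass-action right-hand sides
# for the platelet phosphoinositide pathway downstream of GPVI.

# canonical order of the rate constants in the packed parameter vector used by
# the compiled right-hand side; "m" in a name stands for the minus subscript
# of a reverse rate (rm1 is the reverse of r1, thm3 the reverse of th3, ...)
.ppi_rate_order <- c(
  "r1", "rm1", "r2", "rm2", "r3", "r4",
  "th1", "th2", "th3", "thm3", "th4", "thm4", "th5", "thm5",
  "s1", "s2", "sm2",
  "th6", "thm6", "s4", "sm4", "s5", "sm5", "r6", "thm2"
)

.ppi_core_states <- c("PI", "PI4P", "PIP2", "PIP3", "PI34P2",
                      "Pp", "IP3", "IP1", "Ip")

.ppi_core_rates <- c("r1", "rm1", "r2", "rm2", "r3", "r4",
                     "th1", "th2", "th3", "thm3", "th4", "thm4",
                     "th5", "thm5", "s1", "s2", "sm2")

# rates fixed from literature, never free in calibration (s^-1)
.ppi_fixed <- c(th1 = 0.04, r3 = 2e-4)

.ppi_variant_table <- list(
  A0  = list(extra_state = NULL,     extra_rates = NULL,
             note = "baseline mass-action pathway"),
  A01 = list(extra_state = NULL,     extra_rates = NULL,
             note = "stimulus promotes PIP3 -> PI34P2 (SHIP1/2 recruitment)"),
  A02 = list(extra_state = NULL,     extra_rates = NULL,
             note = "IP3 (Ca surrogate) promotes PI4P -> PIP2 (PKC/Rac1/PIP5K)"),
  A03 = list(extra_state = "PIc",    extra_rates = c("th6", "thm6"),
             note = "secondary intracellular PtdIns pool (DTS), slow exchange"),
  A04 = list(extra_state = "PIP3b",  extra_rates = c("s4", "sm4"),
             note = "stimulated sequestration of PIP3 by PH-domain proteins"),
  A05 = list(extra_state = "PIP2b",  extra_rates = c("s5", "sm5"),
             note = "MARCKS-bound PIP2 pool released by IP3 (Ca surrogate)"),
  A06 = list(extra_state = NULL,     extra_rates = NULL,
             note = "IP3 (Ca surrogate) promotes PI -> PI4P (membrane contact sites)"),
  A07 = list(extra_state = NULL,     extra_rates = NULL,
             note = "PI4P promotes its own dephosphorylation (Osh/Sac1)"),
  A08 = list(extra_state = NULL,     extra_rates = NULL,
             note = "PIP2 promotes Pp -> PI34P2 (PtdIns 4-kinase)"),
  A09 = list(extra_state = NULL,     extra_rates = "r6",
             note = "direct synthesis of PI34P2 from PI4P (PIK3C2A)"),
  A10 = list(extra_state = NULL,     extra_rates = "thm2",
             note = "IP3-promoted PI -> Ip shunt (cPLA2 / LPI recycling)")
)

#' Variant identifiers of the phosphoinositide model family
#'
#' @return Character vector of the eleven variant ids, `"A0"` and
#'   `"A01"`--`"A10"`.
#' @export
ppi_variants <- function() names(.ppi_variant_table)

#' GPVI stimulus function
#'
#' Time course of the upstream signalling drive (Syk/LAT/Btk/PLCgamma2
#' phosphorylation) summarised as the dimensionless function
#' \deqn{s(t) = a_1 t e^{-a_2 t^2} + a_3 \tanh(a_4 t),}
#' a transient early component plus a saturating plateau. With the default
#' calibration parameters the stimulus rises from 0 to a plateau of
#' `a3 = 1` with a mild early overshoot.
#'
#' @param t Time in seconds, non-negative (vectorised).
#' @param params Stimulus parameters, see [ppi_stimulus_params()].
#' @return Dimensionless stimulus level, same length as `t`.
#' @examples
#' ppi_stimulus(c(0, 50, 600))
#' @export
ppi_stimulus <- function(t, params = ppi_stimulus_params()) {
  if (any(t < 0)) stop("stimulus is defined for t >= 0 only")
  params <- .ppi_check_stim(params)
  params[["a1"]] * t * exp(-params[["a2"]] * t^2) +
    params[["a3"]] * tanh(params[["a4"]] * t)
}

#' Stimulus parameter set
#'
#' @param a1 Transient amplitude coefficient (s^-1).
#' @param a2 Transient decay rate (s^-2), non-negative.
#' @param a3 Plateau level (dimensionless).
#' @param a4 Plateau rise rate (s^-1), non-negative.
#' @return Named numeric vector with the calibration defaults.
#' @export
ppi_stimulus_params <- function(a1 = 0.001, a2 = 2e-4, a3 = 1, a4 = 0.02) {
  .ppi_check_stim(c(a1 = a1, a2 = a2, a3 = a3, a4 = a4))
}

.ppi_check_stim <- function(params) {
  need <- c("a1", "a2", "a3", "a4")
  if (!all(need %in% names(params)))
    stop("stimulus parameters must contain a1, a2, a3, a4")
  params <- params[need]
  if (params[["a2"]] < 0 || params[["a4"]] < 0)
    stop("stimulus parameters a2 and a4 must be non-negative")
  params
}

#' Build a model variant specification
#'
#' Constructs the full specification of one pathway variant: its ordered state
#' variables (abundances in molecules per platelet), its free and fixed rate
#' constants, and the mapping onto the compiled mass-action right-hand side.
#' The baseline model `A0` tracks nine pools: PtdIns (`PI`), PtdIns4P
#' (`PI4P`), PtdIns(4,5)P2 (`PIP2`), PtdIns(3,4,5)P3 (`PIP3`), PtdIns(3,4)P2
#' (`PI34P2`), a pool of the unmeasured phosphoinositides (`Pp`), IP3, IP1 and
#' a pool of unmeasured inositol (`Ip`). Variants `A01`--`A10` each add one
#' regulatory mechanism; `A03`/`A04`/`A05` add a tenth state (`PIc`, `PIP3b`,
#' `PIP2b`).
#'
#' Reverse rate constants are named with an `m` for the minus subscript
#' (`rm1` is the reverse of `r1`). `th1` (IP3 -> IP1, 0.04 s^-1) and `r3`
#' (IP1 -> Ip, 2e-4 s^-1) are fixed from literature and never free.
#'
#' @param variant One of [ppi_variants()].
#' @return An object of class `ppi_model` with elements `variant`,
#'   `state_names`, `free_parameters`, `fixed_parameters`, `n_states`, `K`
#'   (free-parameter count) and `note`.
#' @examples
#' m <- ppi_model("A03")
#' m$K          # 17 free rate constants
#' m$state_names
#' @export
ppi_model <- function(variant = "A0") {
  variant <- match.arg(variant, ppi_variants())
  info <- .ppi_variant_table[[variant]]
  free <- c(setdiff(.ppi_core_rates, names(.ppi_fixed)), info$extra_rates)
  structure(list(
    variant = variant,
    state_names = c(.ppi_core_states, info$extra_state),
    free_parameters = free,
    fixed_parameters = .ppi_fixed,
    n_states = length(.ppi_core_states) + length(info$extra_state),
    K = length(free),
    note = info$note
  ), class = "ppi_model")
}

#' @export
print.ppi_model <- function(x, ...) {
  cat("Phosphoinositide pathway model", x$variant, "\n")
  cat("  ", x$note, "\n", sep = "")
  cat("  states (", x$n_states, "): ",
      paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  free rate constants (K = ", x$K, "): ",
      paste(x$free_parameters, collapse = ", "), "\n", sep = "")
  cat("  fixed: ", paste(names(x$fixed_parameters),
                         signif(x$fixed_parameters, 3),
                         sep = " = ", collapse = ", "), " (s^-1)\n", sep = "")
  invisible(x)
}

#' Complete parameter set for a variant
#'
#' Assembles a full named rate-constant vector for a variant from the free
#' parameters supplied, filling the fixed rates (`th1`, `r3`) and defaulting
#' unspecified free rates to 0. First-order rate constants are in s^-1;
#' modifier-promoted bilinear rates are per (molecules per platelet) per
#' second.
#'
#' @param model A `ppi_model` or variant id.
#' @param values Named numeric vector/list of rate constants (free rates;
#'   fixed rates may be included and are checked, not overridden unless
#'   `allow_fixed`).
#' @param allow_fixed If `TRUE`, values for `th1`/`r3` override the defaults
#'   (used for structural experiments, never by the fitter).
#' @return Named numeric vector over the variant's full rate set.
#' @export
ppi_parameters <- function(model, values = NULL, allow_fixed = FALSE) {
  model <- .ppi_as_model(model)
  full_names <- c(model$free_parameters, names(model$fixed_parameters))
  p <- setNames(numeric(length(full_names)), full_names)
  p[names(model$fixed_parameters)] <- model$fixed_parameters
  if (!is.null(values)) {
    values <- unlist(values)
    bad <- setdiff(names(values), full_names)
    if (length(bad))
      stop("unknown parameter(s) for ", model$variant, ": ",
           paste(bad, collapse = ", "))
    if (any(values < 0)) stop("rate constants must be non-negative")
    fixed_given <- intersect(names(values), names(model$fixed_parameters))
    if (length(fixed_given) && !allow_fixed)
      values <- values[setdiff(names(values), fixed_given)]
    p[names(values)] <- values
  }
  p
}

.ppi_as_model <- function(model) {
  if (inherits(model, "ppi_model")) model else ppi_model(model)
}

# pack stimulus + rates into the 30-slot vector the compiled code expects
.ppi_pack_parms <- function(model, params, stim = ppi_stimulus_params()) {
  model <- .ppi_as_model(model)
  stim <- .ppi_check_stim(stim)
  need <- c(model$free_parameters, names(model$fixed_parameters))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("missing parameter(s) for ", model$variant, ": ",
         paste(missing, collapse = ", "))
  rates <- setNames(numeric(length(.ppi_rate_order)), .ppi_rate_order)
  rates[need] <- params[need]
  c(match(model$variant, ppi_variants()) - 1, unname(stim), unname(rates))
}

#' Evaluate a variant's right-hand side
#'
#' Instantaneous rates of change (molecules per platelet per second) of every
#' state pool, under mass-action kinetics. This is a literal R transcription
#' of the model equations, exported both as the reference definition of each
#' variant and for diagnostics; integration uses an equivalent compiled
#' version (the two are cross-checked in the test suite).
#'
#' @param model `ppi_model` or variant id.
#' @param t Time (seconds).
#' @param state Named or ordered numeric vector matching the variant's states.
#' @param params Full rate-constant vector (see [ppi_parameters()]).
#' @param stim Stimulus parameters.
#' @return Named derivative vector; its components sum to zero (the pathway
#'   is a closed system).
#' @export
ppi_rhs <- function(model, t, state, params, stim = ppi_stimulus_params()) {
  model <- .ppi_as_model(model)
  if (length(state) != model$n_states)
    stop("state has length ", length(state), ", expected ", model$n_states)
  if (!is.null(names(state))) state <- state[model$state_names]
  v <- model$variant
  s <- ppi_stimulus(t, stim)
  p <- ppi_parameters(model, params[names(params) %in%
                                     c(model$free_parameters,
                                       names(model$fixed_parameters))],
                      allow_fixed = TRUE)
  g <- function(nm) if (nm %in% names(p)) p[[nm]] else 0
  PI <- state[[1]]; PI4P <- state[[2]]; PIP2 <- state[[3]]
  PIP3 <- state[[4]]; PI34P2 <- state[[5]]; Pp <- state[[6]]
  IP3 <- state[[7]]; IP1 <- state[[8]]; Ip <- state[[9]]
  extra <- if (model$n_states > 9) state[[10]] else 0

  f_r1 <- if (v == "A06") g("r1") * IP3 * PI else g("r1") * PI
  f_rm1 <- if (v == "A07") g("rm1") * PI4P^2 else g("rm1") * PI4P
  f_r2 <- if (v == "A02") g("r2") * IP3 * PI4P else g("r2") * PI4P
  f_rm2 <- g("rm2") * PIP2
  f_s2 <- g("s2") * s * PIP2
  f_sm2 <- g("sm2") * PIP3
  f_s1 <- g("s1") * s * PIP2
  f_r4 <- if (v == "A01") g("r4") * s * PIP3 else g("r4") * PIP3
  f_th3 <- g("th3") * PI; f_thm3 <- g("thm3") * Pp
  f_th5 <- g("th5") * Pp; f_thm5 <- g("thm5") * PIP2
  f_th4 <- if (v == "A08") g("th4") * PIP2 * Pp else g("th4") * Pp
  f_thm4 <- g("thm4") * PI34P2
  f_th1 <- g("th1") * IP3; f_r3 <- g("r3") * IP1
  f_th2 <- if (v == "A03") g("th2") * extra else g("th2") * Ip

  d <- c(
    PI = f_th2 - f_r1 + f_rm1 - f_th3 + f_thm3,
    PI4P = f_r1 - f_rm1 - f_r2 + f_rm2,
    PIP2 = f_r2 - f_rm2 - f_s2 + f_sm2 - f_s1 + f_th5 - f_thm5,
    PIP3 = f_s2 - f_sm2 - f_r4,
    PI34P2 = f_r4 + f_th4 - f_thm4,
    Pp = f_th3 - f_thm3 - f_th5 + f_thm5 - f_th4 + f_thm4,
    IP3 = f_s1 - f_th1,
    IP1 = f_th1 - f_r3,
    Ip = f_r3 - f_th2
  )
  if (v == "A03") {
    f_th6 <- g("th6") * Ip; f_thm6 <- g("thm6") * extra
    d[["Ip"]] <- f_r3 - f_th6 + f_thm6
    d <- c(d, PIc = f_th6 - f_thm6 - f_th2)
  } else if (v == "A04") {
    f_s4 <- g("s4") * s * PIP3; f_sm4 <- g("sm4") * extra
    d[["PIP3"]] <- d[["PIP3"]] - f_s4 + f_sm4
    d <- c(d, PIP3b = f_s4 - f_sm4)
  } else if (v == "A05") {
    f_s5 <- g("s5") * PIP2; f_sm5 <- g("sm5") * IP3 * extra
    d[["PIP2"]] <- d[["PIP2"]] - f_s5 + f_sm5
    d <- c(d, PIP2b = f_s5 - f_sm5)
  } else if (v == "A09") {
    f_r6 <- g("r6") * PI4P
    d[["PI4P"]] <- d[["PI4P"]] - f_r6
    d[["PI34P2"]] <- d[["PI34P2"]] + f_r6
  } else if (v == "A10") {
    f_thm2 <- g("thm2") * IP3 * PI
    d[["PI"]] <- d[["PI"]] - f_thm2
    d[["Ip"]] <- d[["Ip"]] + f_thm2
  }
  d
}

# compiled counterpart of ppi_rhs, used internally and in parity tests
.ppi_rhs_c <- function(model, t, state, params, stim = ppi_stimulus_params()) {
  model <- .ppi_as_model(model)
  pv <- .ppi_pack_parms(model, params, stim)
  if (!is.null(names(state))) state <- state[model$state_names]
  setNames(.Call(C_ppi_rhs, as.numeric(t), as.numeric(state), pv),
           model$state_names)
}

#' Serialise a parameter set to JSON
#'
#' Writes a flat name-to-value mapping with the variant id and units recorded,
#' readable back with [ppi_read_parameters()].
#'
#' @param model `ppi_model` or variant id.
#' @param params Named rate-constant vector.
#' @param path File path (`.json`).
#' @export
ppi_write_parameters <- function(model, params, path) {
  model <- .ppi_as_model(model)
  obj <- list(
    variant = model$variant,
    units = "first-order rates s^-1; modifier-promoted rates (molecules platelet^-1)^-1 s^-1",
    parameters = as.list(params)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ppi_write_parameters
#' @param path File path to read.
#' @return For `ppi_read_parameters`, a list with `variant` and the named
#'   `parameters` vector.
#' @export
ppi_read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(variant = obj$variant, parameters = unlist(obj$parameters))
}
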