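# Shared test helpers: random draws in the prior box and tiny datasets.

# random full parameter set for a variant, log-uniform in the prior box
random_params <- function(model, lower = -4, upper = 2) {
  model <- ppi_model(model$variant %||% model)
  free <- stats::setNames(10^stats::runif(model$K, lower, upper),
                          model$free_parameters)
  ppi_parameters(model, free)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# noiseless dataset from the frozen A0 reference parameters
noiseless_a0_data <- function() {
  ppi_simulate_dataset("A0", ppi_example_params("A0"),
                       noise = ppi_noise(cv = 0, n_replicates = 3,
                                         seed = 1))
}

# literal transcription of the baseline (A0) equations, written term by term
# as an independent oracle for the packaged right-hand side
a0_rhs_literal <- function(t, y, p, stim = ppi_stimulus_params()) {
  s <- stim[["a1"]] * t * exp(-stim[["a2"]] * t^2) +
    stim[["a3"]] * tanh(stim[["a4"]] * t)
  with(as.list(c(y, p)), c(
    PI = th2 * Ip - r1 * PI + rm1 * PI4P - th3 * PI + thm3 * Pp,
    PI4P = r1 * PI - rm1 * PI4P - r2 * PI4P + rm2 * PIP2,
    PIP2 = r2 * PI4P - rm2 * PIP2 - s2 * s * PIP2 + sm2 * PIP3 -
      s1 * s * PIP2 + th5 * Pp - thm5 * PIP2,
    PIP3 = s2 * s * PIP2 - sm2 * PIP3 - r4 * PIP3,
    PI34P2 = r4 * PIP3 + th4 * Pp - thm4 * PI34P2,
    Pp = th3 * PI - thm3 * Pp - th5 * Pp + thm5 * PIP2 -
      th4 * Pp + thm4 * PI34P2,
    IP3 = s1 * s * PIP2 - th1 * IP3,
    IP1 = th1 * IP3 - r3 * IP1,
    Ip = r3 * IP1 - th2 * Ip
  ))
}
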