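# Reference parameter sets for synthetic-data experiments.

#' Reference rate constants for synthetic experiments
#'
#' Frozen rate-constant sets used as ground truth when generating synthetic
#' datasets for parameter-recovery and model-selection experiments. They
#' were obtained once by calibrating the variant to the package's
#' anchor-derived mean curves (200-start Latin-hypercube multistart, seed 1)
#' and rounding to two significant digits, so the simulated time courses
#' have the magnitudes and shapes of the measured CRP response. The `A03`
#' set has a slow exchange with the secondary PtdIns pool
#' (`th6`, `thm6` of order 1e-4 to 1e-3 per second), which keeps the
#' inositol pool stable over the 600 s window.
#'
#' @param variant `"A0"` or `"A03"`.
#' @return Full named rate-constant vector (see [ppi_parameters()]).
#' @export
ppi_example_params <- function(variant = c("A0", "A03")) {
  variant <- match.arg(variant)
  values <- switch(variant,
    A0 = c(
      r1 = 0.12, rm1 = 16, r2 = 0.0057, rm2 = 12, r4 = 11,
      th2 = 0.072, th3 = 1.4, thm3 = 0.025, th4 = 1e-4, thm4 = 2.6,
      th5 = 0.0082, thm5 = 0.24, s1 = 1e-4, s2 = 1, sm2 = 0.002
    ),
    A03 = c(
      r1 = 1.3, rm1 = 34, r2 = 0.7, rm2 = 8.2e-4, r4 = 0.79,
      th2 = 1e-4, th3 = 2.9e-4, thm3 = 1, th4 = 1.2, thm4 = 2.3,
      th5 = 0.31, thm5 = 0.72, s1 = 1e-4, s2 = 0.058, sm2 = 0.0018,
      th6 = 0.0023, thm6 = 0.073
    )
  )
  ppi_parameters(variant, values)
}
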