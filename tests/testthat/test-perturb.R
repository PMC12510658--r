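# Perturbation analyses: sensitivity scores, scenarios, inhibitor response.

test_that("sensitivity scores follow the normalised endpoint formula", {
  p <- ppi_example_params("A0")
  # zero variation leaves every endpoint unchanged: all scores 0
  s0 <- ppi_sensitivity("A0", p, parameters = c("r1", "r2"), factor = 0)
  expect_equal(max(abs(s0), na.rm = TRUE), 0)
  # direct check of (O_a - O_i)/O_a for one perturbation
  s <- ppi_sensitivity("A0", p, parameters = "r1", factor = 0.5)
  o_i <- ppi_endpoint(ppi_integrate("A0", p), "PI4P")
  p_up <- p; p_up[["r1"]] <- p[["r1"]] * 1.5
  o_a <- ppi_endpoint(ppi_integrate("A0", p_up), "PI4P")
  expect_equal(s["r1+", "PI4P"], unname((o_a - o_i) / o_a), tolerance = 1e-8)
  expect_identical(rownames(s), c("r1+", "r1-"))
})

test_that("structurally disconnected parameters score zero", {
  # with no PLC flux (s1 = 0) the inositol arm never fills, so perturbing
  # the IP1 degradation rate r3 cannot move any endpoint
  p <- ppi_example_params("A0")
  p[["s1"]] <- 0
  s <- ppi_sensitivity("A0", p, parameters = "r3")
  expect_equal(max(abs(s), na.rm = TRUE), 0, tolerance = 1e-10)
})

test_that("built-in scenarios encode the study perturbations", {
  sc <- ppi_scenarios()
  expect_equal(unname(sc$reduced_plateau$stim),
               c(0.001, 2e-4, 0.5, 0.02))
  expect_equal(unname(sc$early_peak$stim), c(0.03, 2e-3, 1, 0.02))
  expect_equal(unname(sc$combined$stim), c(0.03, 2e-4, 0.5, 0.02))
  expect_equal(sc$gsk_a1$scale, c(r1 = 0.1))
  expect_null(sc$baseline$scale)
})

test_that("identity scenario reproduces the fitted baseline", {
  d <- noiseless_a0_data()
  f <- ppi_fit("A0", d, n_starts = 4, seed = 5)
  base <- ppi_run_scenario(f, ppi_scenarios()$baseline, ranks = 1:2)
  for (i in 1:2) {
    tr_fit <- ppi_integrate(f$model, ppikin:::.ppi_fit_params(f, i),
                            stim = f$stim, times = d$times)
    expect_equal(base$trajectories[[i]]$states, tr_fit$states,
                 tolerance = 1e-10)
  }
  # comparison of a run against itself is all-zero
  cmp <- ppi_compare_scenarios(base, base)
  expect_equal(max(abs(cmp$rel_change), na.rm = TRUE), 0)
  expect_equal(max(abs(cmp$peak_shift_s)), 0)
})

test_that("relative endpoint changes track a uniform rescaling", {
  d <- noiseless_a0_data()
  f <- ppi_fit("A0", d, n_starts = 2, seed = 5)
  base <- ppi_run_scenario(f, ppi_scenarios()$baseline, ranks = 1)
  half <- base
  half$trajectories <- lapply(base$trajectories, function(tr) {
    tr$states <- tr$states * 0.5
    tr
  })
  cmp <- ppi_compare_scenarios(base, half)
  expect_equal(unique(cmp$rel_change[!is.na(cmp$rel_change)]), -0.5)
})

test_that("scenarios preserve the closed-system total", {
  d <- noiseless_a0_data()
  f <- ppi_fit("A0", d, n_starts = 3, seed = 6)
  for (sc in ppi_scenarios()) {
    run <- ppi_run_scenario(f, sc, ranks = 1)
    expect_lt(run$trajectories[[1]]$conservation_error, 1e-6)
  }
})

test_that("reducing the PtdIns 4-kinase rate lowers PtdIns4P monotonically", {
  p <- ppi_example_params("A03")
  ends <- vapply(c(1, 0.5, 0.1, 0), function(sc) {
    q <- p; q[["r1"]] <- p[["r1"]] * sc
    ppi_endpoint(ppi_integrate("A03", q), "PI4P")
  }, numeric(1))
  expect_true(all(diff(ends) < 0))
})
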