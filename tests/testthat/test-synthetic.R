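# Synthetic time-course generator: anchor fidelity, noise contract,
# model-generated datasets.

test_that("noiseless mean curves pass through every anchor exactly", {
  anchors <- ppi_anchors()
  for (sp in names(anchors)) {
    a <- anchors[[sp]]$anchors
    got <- ppi_mean_curves(times = a[, "time_s"])[, sp]
    expect_equal(unname(got), unname(a[, "value"]), label = sp)
  }
  # linear IP1: value at 300 s is the midpoint
  expect_equal(unname(ppi_mean_curves(times = 300)[, "IP1"]), 1050)
})

test_that("fold changes of the noiseless curves match the measured ones", {
  mc <- ppi_mean_curves()
  t <- ppi_times()
  expect_equal(unname(mc[t == 180, "PI34P2"] / mc[t == 0, "PI34P2"]), 6)
  expect_equal(unname(round(mc[t == 120, "PIP2"] / mc[t == 0, "PIP2"], 1)), 1.7)
  expect_equal(unname(round(mc[t == 180, "PIP3"] / mc[t == 0, "PIP3"], 1)), 2.6)
  # PtdIns peaks at 60 s then declines below basal
  expect_equal(unname(mc[t == 60, "PI"]), 2.9e6)
  expect_lt(mc[t == 600, "PI"], mc[t == 0, "PI"])
})

test_that("generation is deterministic and respects the noise contract", {
  d1 <- ppi_generate(noise = ppi_noise(cv = 0.2, seed = 42))
  d2 <- ppi_generate(noise = ppi_noise(cv = 0.2, seed = 42))
  expect_identical(d1$replicates, d2$replicates)
  d3 <- ppi_generate(noise = ppi_noise(cv = 0.2, seed = 43))
  expect_false(identical(d1$replicates, d3$replicates))
  # cv = 0 reproduces the means exactly
  d0 <- ppi_generate(noise = ppi_noise(cv = 0, seed = 1))
  mc <- ppi_mean_curves()
  for (sp in colnames(mc))
    expect_equal(unname(d0$means[, sp]), unname(mc[, sp]))
  expect_true(all(d1$replicates$value >= 0))
  # flat species stays within cv-consistent bounds of its basal level
  pi4p <- d1$replicates$value[d1$replicates$species == "PI4P"]
  expect_true(all(pi4p > 6.4e4 * 0.4 & pi4p < 6.4e4 * 2.5))
})

test_that("replicate noise realises the stated coefficient of variation", {
  d <- ppi_generate(noise = ppi_noise(cv = 0.2, n_replicates = 1000,
                                      seed = 99))
  one <- d$replicates$value[d$replicates$species == "PIP2" &
                              d$replicates$time_s == 120]
  expect_length(one, 1000)
  cv_hat <- stats::sd(one) / mean(one)
  expect_gt(cv_hat, 0.18)
  expect_lt(cv_hat, 0.22)
})

test_that("model-generated datasets sample the trajectory on the grid", {
  p <- ppi_example_params("A0")
  d <- ppi_simulate_dataset("A0", p, noise = ppi_noise(cv = 0, seed = 1))
  expect_equal(length(d$means), 42)
  tr <- ppi_integrate("A0", p)
  for (sp in ppi_species())
    expect_equal(unname(d$means[, sp]), unname(tr$states[, sp]),
                 tolerance = 1e-10)
  expect_identical(d$truth$variant, "A0")
  expect_lt(tr$conservation_error, 1e-6)
  # bound pools are summed into the observable in A04
  p4 <- ppi_parameters("A04", c(ppi_example_params("A0")[
    ppi_model("A0")$free_parameters], s4 = 0.05, sm4 = 0.001))
  d4 <- ppi_simulate_dataset("A04", p4, noise = ppi_noise(cv = 0, seed = 1))
  tr4 <- ppi_integrate("A04", p4)
  expect_equal(unname(d4$means[, "PIP3"]),
               unname(tr4$states[, "PIP3"] + tr4$states[, "PIP3b"]),
               tolerance = 1e-10)
})
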