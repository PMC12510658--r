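# Model family: stimulus function, variant registry, right-hand sides.

test_that("stimulus has the transient-plus-plateau form", {
  expect_equal(ppi_stimulus(0), 0)
  # transient decays, tanh saturates at the plateau a3
  expect_equal(ppi_stimulus(1e6), 1.0, tolerance = 1e-12)
  # frozen scalar evaluation at t = 50 s with calibration defaults:
  # 0.001*50*exp(-2e-4*2500) + tanh(1)
  expect_equal(ppi_stimulus(50), 0.7919207, tolerance = 1e-6)
  expect_error(ppi_stimulus(-1), "t >= 0")
  # continuity: fine grid has no jumps
  s <- ppi_stimulus(seq(0, 600, by = 0.25))
  expect_lt(max(abs(diff(s))), 0.01)
  # halved plateau halves the long-time level
  expect_equal(ppi_stimulus(1e6, ppi_stimulus_params(a3 = 0.5)), 0.5)
})

test_that("variant registry matches the model family structure", {
  expect_length(ppi_variants(), 11)
  m0 <- ppi_model("A0")
  expect_length(m0$state_names, 9)
  for (v in c("A03", "A04", "A05"))
    expect_length(ppi_model(v)$state_names, 10)
  expect_identical(ppi_model("A03")$state_names[10], "PIc")
  expect_identical(ppi_model("A04")$state_names[10], "PIP3b")
  expect_identical(ppi_model("A05")$state_names[10], "PIP2b")
  expect_error(ppi_model("A99"))
  # fixed rates are excluded from the free set
  expect_false(any(c("th1", "r3") %in% m0$free_parameters))
  expect_equal(unname(m0$fixed_parameters), c(0.04, 2e-4))
})

test_that("baseline rhs matches a literal term-by-term transcription", {
  m <- ppi_model("A0")
  set.seed(11)
  for (i in 1:20) {
    p <- random_params(m)
    y <- setNames(runif(9, 0, 1e6), m$state_names)
    t <- runif(1, 0, 600)
    expect_equal(ppi_rhs(m, t, y, p), a0_rhs_literal(t, y, p),
                 tolerance = 1e-12)
  }
})

test_that("rhs of a single active reaction is the hand-computed flux", {
  m <- ppi_model("A0")
  p <- ppi_parameters(m, c(r1 = 0.1), allow_fixed = TRUE)
  p[c("th1", "r3")] <- 0
  y <- setNames(c(100, rep(0, 8)), m$state_names)
  d <- ppi_rhs(m, 0, y, p)
  expect_equal(unname(d),
               c(-10, 10, 0, 0, 0, 0, 0, 0, 0))
  # all rates zero gives the zero vector
  expect_equal(unname(ppi_rhs(m, 5, y, ppi_parameters(m) * 0)),
               rep(0, 9))
})

test_that("every variant is a closed system with non-negative sources", {
  set.seed(23)
  for (v in ppi_variants()) {
    m <- ppi_model(v)
    for (i in 1:10) {
      p <- random_params(m)
      y <- setNames(runif(m$n_states, 0, 1e7), m$state_names)
      d <- ppi_rhs(m, runif(1, 0, 600), y, p)
      expect_lt(abs(sum(d)), 1e-7 * max(abs(d), 1))
      # a depleted pool can only gain
      j <- sample(m$n_states, 1)
      y2 <- y; y2[j] <- 0
      expect_gte(ppi_rhs(m, 10, y2, p)[[j]], 0)
    }
  }
})

test_that("compiled rhs agrees with the R transcription for all variants", {
  set.seed(31)
  for (v in ppi_variants()) {
    m <- ppi_model(v)
    for (i in 1:10) {
      p <- random_params(m)
      y <- setNames(runif(m$n_states, 0, 1e7), m$state_names)
      t <- runif(1, 0, 600)
      a <- ppi_rhs(m, t, y, p)
      b <- ppikin:::.ppi_rhs_c(m, t, y, p)
      expect_equal(a, b, tolerance = 1e-12)
    }
  }
})

test_that("variants reduce to the baseline when their mechanism is off", {
  set.seed(47)
  m0 <- ppi_model("A0")
  p0 <- random_params(m0)
  y9 <- setNames(runif(9, 0, 1e6), m0$state_names)
  d0 <- ppi_rhs(m0, 100, y9, p0)
  # extra-parameter variants: new rates 0, new state 0 -> baseline rhs
  for (v in c("A04", "A05", "A09", "A10")) {
    m <- ppi_model(v)
    p <- ppi_parameters(m, p0[m0$free_parameters], allow_fixed = FALSE)
    p[c("th1", "r3")] <- p0[c("th1", "r3")]
    y <- if (m$n_states == 10) c(y9, setNames(0, m$state_names[10])) else y9
    expect_equal(unname(ppi_rhs(m, 100, y, p)[1:9]), unname(d0),
                 tolerance = 1e-12, label = v)
  }
  # A03 reassigns th2 to the secondary pool, so th2 must be off too
  p0z <- p0; p0z[["th2"]] <- 0
  d0z <- ppi_rhs(m0, 100, y9, p0z)
  m3 <- ppi_model("A03")
  p3 <- ppi_parameters(m3, p0z[m0$free_parameters])
  p3[c("th1", "r3")] <- p0[c("th1", "r3")]
  expect_equal(unname(ppi_rhs(m3, 100, c(y9, PIc = 0), p3)[1:9]),
               unname(d0z), tolerance = 1e-12)
  # promoted-flux variants: the modified flux vanishes with its modifier
  yz <- y9; yz[["IP3"]] <- 0
  for (v in c("A02", "A06")) {
    d <- ppi_rhs(ppi_model(v), 100, yz, p0)
    # with IP3 = 0 the promoted flux is off: compare to baseline with the
    # corresponding rate zeroed
    pz <- p0; pz[[if (v == "A02") "r2" else "r1"]] <- 0
    expect_equal(unname(d), unname(ppi_rhs(m0, 100, yz, pz)),
                 tolerance = 1e-12, label = v)
  }
  # A01 at t = 0: s(0) = 0 switches the promoted r4 flux off
  expect_equal(unname(ppi_rhs(ppi_model("A01"), 0, y9, p0)),
               unname(ppi_rhs(m0, 0, y9, `[[<-`(p0, "r4", 0))),
               tolerance = 1e-12)
})

test_that("rhs rejects malformed input", {
  m <- ppi_model("A0")
  expect_error(ppi_rhs(m, 0, rep(0, 8), ppi_parameters(m)), "length")
  expect_error(ppi_parameters(m, c(nope = 1)), "unknown parameter")
  expect_error(ppi_parameters(m, c(r1 = -1)), "non-negative")
  expect_error(ppikin:::.ppi_pack_parms(m, c(r1 = 0.1)), "missing parameter")
})

test_that("parameter sets round-trip through JSON", {
  p <- ppi_example_params("A03")
  path <- tempfile(fileext = ".json")
  ppi_write_parameters("A03", p, path)
  back <- ppi_read_parameters(path)
  expect_identical(back$variant, "A03")
  expect_equal(back$parameters[names(p)], p)
})
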