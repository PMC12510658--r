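# Calibration machinery: Latin hypercube, cost function, AICc, multistart.

test_that("latin hypercube stratifies every marginal", {
  b <- ppi_bounds("A0")
  # single point lies in the box
  p1 <- ppi_lhs(b, 1, seed = 3)
  expect_true(all(p1 >= -4 & p1 <= 2))
  # n = 10: each of the 10 equal log-bins of every marginal holds one point
  p10 <- ppi_lhs(b, 10, seed = 3)
  for (j in seq_len(ncol(p10))) {
    bins <- findInterval(p10[, j], seq(-4, 2, length.out = 11),
                         rightmost.closed = TRUE)
    expect_equal(sort(bins), 1:10)
  }
  expect_identical(ppi_lhs(b, 10, seed = 3), p10)
  expect_named(as.data.frame(p10), ppi_model("A0")$free_parameters)
})

test_that("cost is zero at the generating parameters and scale-free", {
  d <- noiseless_a0_data()
  truth <- ppi_example_params("A0")
  expect_lt(ppi_sse("A0", truth, d), 1e-12)
  # brute-force double loop over the 42 cells reproduces the cost
  set.seed(17)
  m <- ppi_model("A0")
  for (i in 1:10) {
    p <- random_params(m)
    got <- ppi_sse(m, p, d)
    tr <- suppressWarnings(tryCatch(ppi_integrate(m, p, times = d$times),
                                    error = function(e) NULL))
    if (is.null(tr)) next
    acc <- 0
    for (sp in colnames(d$means)) {
      mx <- max(d$means[, sp])
      for (k in seq_along(d$times))
        acc <- acc + ((tr$states[k, sp] - d$means[k, sp]) / mx)^2
    }
    expect_equal(got, unname(acc), tolerance = 1e-12)
  }
})

test_that("AICc follows the small-sample-corrected formula", {
  expect_equal(ppi_aicc(42, 42, 0), 0)
  expect_equal(ppi_aicc(42, 42, 15), 30 + 480 / 26)
  expect_equal(ppi_aicc(42 * 0.054, 42, 15),
               42 * log(0.054) + 30 + 480 / 26)
  expect_error(ppi_aicc(10, 16, 15), "undefined")
  expect_error(ppi_aicc(0, 42, 15), "positive")
  # complexity penalty is strictly increasing in K at fixed SSE
  a <- vapply(1:20, function(K) ppi_aicc(5, 42, K), numeric(1))
  expect_true(all(diff(a) > 0))
})

test_that("a fit started at the optimum stays there", {
  d <- noiseless_a0_data()
  m <- ppi_model("A0")
  truth <- ppi_example_params("A0")
  r <- ppi_fit_once(m, log10(truth[m$free_parameters]), d)
  expect_lt(r$sse, 1e-12)
  expect_equal(unname(log10(r$par)),
               unname(log10(truth[m$free_parameters])), tolerance = 1e-4)
  expect_error(ppi_fit_once(m, setNames(rep(5, m$K), m$free_parameters), d), "outside")
})

test_that("multistart refines random starts and respects nesting", {
  d <- noiseless_a0_data()
  b <- ppi_bounds("A0")
  starts <- ppi_lhs(b, 6, seed = 8)
  f3 <- ppi_fit("A0", d, starts = starts[1:3, , drop = FALSE])
  f6 <- ppi_fit("A0", d, starts = starts)
  # superset of starts can only improve the best cost
  expect_lte(min(f6$fits$sse), min(f3$fits$sse))
  # n_starts = 1 reduces to a single local fit
  f1 <- ppi_fit("A0", d, starts = starts[1, , drop = FALSE])
  r1 <- ppi_fit_once("A0", starts[1, ], d)
  expect_equal(min(f1$fits$sse), r1$sse)
  # every refined cost is no worse than its start's cost
  for (i in 1:3) {
    p0 <- ppi_parameters("A0", setNames(10^starts[i, ], colnames(starts)))
    expect_lte(f6$fits$sse[f6$fits$start == i], ppi_sse("A0", p0, d) + 1e-9)
  }
  # fixed literature rates are never touched by the optimiser
  pc <- coef(f6, fixed = TRUE)
  expect_equal(pc[["th1"]], 0.04)
  expect_equal(pc[["r3"]], 2e-4)
})

test_that("multistart separates good basins from bad ones", {
  d <- noiseless_a0_data()
  f <- ppi_fit("A0", d, n_starts = 50, seed = 1)
  # best-of-50 is orders of magnitude below the worst start's refined cost
  expect_lt(min(f$fits$sse), 1e-4 * max(f$fits$sse))
  expect_true(all(diff(f$fits$sse) >= 0))
})

test_that("uncertainty bands are nested and flag unconstrained rates", {
  d <- noiseless_a0_data()
  f <- ppi_fit("A0", d, n_starts = 12, seed = 2)
  u <- suppressWarnings(ppi_uncertainty(f, top_k = 12))
  expect_true(all(u$q05 <= u$q25 & u$q25 <= u$q45 & u$q45 <= u$median &
                    u$median <= u$q55 & u$q55 <= u$q75 & u$q75 <= u$q95))
  # identical top fits give zero-width bands
  f2 <- f
  f2$fits <- f$fits[rep(1, 10), ]
  u2 <- suppressWarnings(ppi_uncertainty(f2, top_k = 10))
  expect_equal(u2$q95 - u2$q05, rep(0, nrow(u2)))
  expect_false(any(u2$non_identifiable))
  # a band spanning five of the six prior decades is flagged
  f3 <- f2
  f3$fits[["r1"]] <- seq(-4, 2, length.out = 10)
  u3 <- suppressWarnings(ppi_uncertainty(f3, top_k = 10))
  expect_true(u3$non_identifiable[u3$parameter == "r1"])
})

test_that("model ranking is AICc-ascending with complexity tie-breaks", {
  d <- noiseless_a0_data()
  fake <- function(variant, sse) {
    m <- ppi_model(variant)
    fits <- data.frame(start = 1, sse = sse,
                       aicc = ppi_aicc(sse, 42, m$K), converged = TRUE,
                       failed = FALSE)
    structure(list(fits = fits, model = m, data = d, n = 42, K = m$K),
              class = "ppi_fit")
  }
  # equal SSE: the leaner model must rank first
  r <- ppi_rank(fake("A09", 1), fake("A0", 1))
  expect_identical(r$variant, c("A0", "A09"))
  # submission order does not matter
  r2 <- ppi_rank(fake("A0", 1), fake("A09", 1))
  expect_identical(r$variant, r2$variant)
  # ensembles fitted to different data are rejected
  d2 <- ppi_generate(noise = ppi_noise(cv = 0.3, seed = 9))
  f_other <- fake("A0", 1)
  f_other$data <- d2
  expect_error(ppi_rank(fake("A09", 1), f_other), "same dataset")
  expect_error(ppi_rank(fake("A0", 1)), "at least two")
})
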