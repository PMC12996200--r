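test_that("logistic-map Lyapunov exponent matches the derivative-average
           oracle", {
  s <- generate_benchmark_signal("logistic_map", list(r = 4, x0 = 0.2), 3000, 0)
  est <- max_lyapunov(s$values, dim = 2, tau = 1, theiler = 5,
                      fit_range = 0:4, max_points = Inf)
  oracle <- logistic_lyap_oracle(4, 0.2, 3000)
  expect_equal(as.numeric(est), oracle, tolerance = 0.05 / oracle)
})

test_that("a periodic orbit has an exponent indistinguishable from zero", {
  s <- generate_benchmark_signal("sine", list(freq = 1, rate = 40), 2000, 0)
  est <- max_lyapunov(s$values, dim = 2, tau = 10, theiler = 20,
                      max_points = Inf)
  expect_lt(abs(as.numeric(est)), 0.02)
})

test_that("correlation dimension recovers known set dimensions", {
  t <- seq(0, 1, length.out = 1500)
  line <- cbind(t, t, t) / sqrt(3)
  expect_equal(as.numeric(correlation_dimension(line, theiler = 0)), 1,
               tolerance = 0.1)
  sq <- withr::with_seed(2, cbind(runif(2000), runif(2000)))
  expect_equal(as.numeric(correlation_dimension(sq, theiler = 0)), 2,
               tolerance = 0.15 / 2)
})

test_that("correlation dimension cannot exceed the embedding dimension by
           more than estimator slack", {
  w <- generate_benchmark_signal("white_noise", list(), 4000, 3)
  for (m in 2:3) {
    pts <- delay_embedding(w$values, m, 1)
    expect_lte(as.numeric(correlation_dimension(pts, theiler = 1)), m + 0.2)
  }
})

test_that("sample entropy matches brute-force template counting and known
           regimes", {
  expect_equal(sample_entropy(rep(3.2, 300)), 0)
  x <- withr::with_seed(8, rnorm(400))
  r <- 0.2 * sd(x)
  expect_equal(sample_entropy(x, m = 2, r_frac = 0.2),
               brute_sampen(x, 2, r), tolerance = 1e-12)
  slow <- sin(2 * pi * (0:1999) / 200)
  expect_lt(sample_entropy(slow), 0.3)
})

test_that("sample entropy decreases as a sine increasingly dominates noise", {
  vals <- sapply(c(1.5, 0.8, 0.3, 0.1), function(noise_sd) {
    mean(sapply(1:5, function(s) {
      x <- sin(2 * pi * (0:1499) / 50) +
        withr::with_seed(s, rnorm(1500, sd = noise_sd))
      sample_entropy(x)
    }))
  })
  expect_true(all(diff(vals) < 0))
})

test_that("Renyi entropy matches analytic values and the Shannon limit", {
  expect_equal(renyi_entropy(rep(1 / 8, 8), q = 2, pmf = TRUE), log(8))
  expect_equal(renyi_entropy(rep(1 / 8, 8), q = 0.5, pmf = TRUE), log(8))
  expect_equal(renyi_entropy(c(0.5, 0.5), q = 2, pmf = TRUE), log(2))
  p <- withr::with_seed(1, {v <- runif(6); v / sum(v)})
  expect_equal(renyi_entropy(p, q = 1 + 1e-6, pmf = TRUE), shannon(p),
               tolerance = 1e-4)
  expect_error(renyi_entropy(numeric(0)), "empty")
})

test_that("Hurst estimation recovers known long-range dependence", {
  w <- generate_benchmark_signal("white_noise", list(), 8192, 1)
  expect_equal(hurst_exponent(w$values), 0.5, tolerance = 0.07 / 0.5)
  g <- generate_benchmark_signal("fgn", list(H = 0.8), 8192, 2)
  expect_equal(hurst_exponent(g$values), 0.8, tolerance = 0.1 / 0.8)
  expect_gte(hurst_exponent(seq(0, 1, length.out = 8192)), 0.95)
  expect_error(hurst_exponent(rep(1, 600)), "constant")
  # DFA flavour agrees on fractional Gaussian noise
  expect_equal(hurst_exponent(g$values, method = "dfa"), 0.8,
               tolerance = 0.15 / 0.8)
})

test_that("Hurst estimate agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  g <- generate_benchmark_signal("fgn", list(H = 0.7), 4096, 9)
  ours <- hurst_exponent(g$values)
  theirs <- pracma::hurstexp(g$values, display = FALSE)$Hs
  expect_equal(ours, theirs, tolerance = 0.1)
})

test_that("fractal dimensions separate smooth lines from noise", {
  line <- seq(0, 1, length.out = 2000)
  expect_equal(fractal_dimension(line, "higuchi"), 1, tolerance = 0.05)
  w <- generate_benchmark_signal("white_noise", list(), 4096, 4)
  expect_equal(fractal_dimension(w$values, "higuchi"), 2, tolerance = 0.1 / 2)
  expect_warning(fd <- fractal_dimension(rep(1, 200)), "constant")
  expect_equal(fd, 1)
})

test_that("Katz dimension matches its closed formula by hand", {
  # x = (0, 1, 0.5): L = 1.5, d = 1, n = 2 steps
  hand <- log10(2) / (log10(1 / 1.5) + log10(2))
  expect_equal(fractal_dimension(c(0, 1, 0.5), "katz"), hand)
  # two-point series: d equals L, degenerate denominator -> 1 by convention
  expect_warning(k2 <- fractal_dimension(c(0, 1), "katz"), "degenerate")
  expect_equal(k2, 1)
})

test_that("estimators are invariant under affine rescaling where theory
           says so", {
  s <- generate_benchmark_signal("henon", list(), 3000, 0)
  x <- s$values
  y <- 3 + 2 * x
  m1 <- max_lyapunov(x, dim = 2, tau = 1, theiler = 5, fit_range = 0:4,
                     max_points = Inf)
  m2 <- max_lyapunov(y, dim = 2, tau = 1, theiler = 5, fit_range = 0:4,
                     max_points = Inf)
  expect_equal(as.numeric(m1), as.numeric(m2), tolerance = 1e-9)
  d1 <- correlation_dimension(x, dim = 2, tau = 1, theiler = 5)
  d2 <- correlation_dimension(y, dim = 2, tau = 1, theiler = 5)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-6)
  expect_equal(sample_entropy(x), sample_entropy(y), tolerance = 1e-12)
  expect_equal(fractal_dimension(x, "higuchi"),
               fractal_dimension(y, "higuchi"), tolerance = 1e-9)
})

test_that("chaos screen applies the positivity and dimension criteria", {
  expect_true(chaos_screen(list(mle = 0.5, dcorr = 2.1))$pass)
  s1 <- chaos_screen(list(mle = -0.1, dcorr = 2.1))
  expect_false(s1$pass)
  expect_match(s1$reasons, "MLE")
  s2 <- chaos_screen(list(mle = 0.5, dcorr = 3.2))
  expect_false(s2$pass)
  expect_match(s2$reasons, "DCorr")
  expect_error(chaos_screen(list(mle = NA, dcorr = 1)), "finite")
})
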