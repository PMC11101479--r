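test_that("minkowski_combine reproduces canonical norms and enhancement", {
  expect_equal(minkowski_combine(1, 1, m = 1), 2)
  expect_equal(minkowski_combine(4, 3, m = 2), 5)
  expect_equal(minkowski_combine(1, 1, m = 2), sqrt(2))
  # symmetric in its two channels; weak channel may be zero
  expect_equal(minkowski_combine(3, 7, 1.7), minkowski_combine(7, 3, 1.7))
  expect_equal(minkowski_combine(5, 0, 2.3), 5)
})

test_that("minkowski_combine limits: additive at m=1, MAX as m grows,
           monotone non-increasing in m", {
  set.seed(101)
  for (i in 1:25) {
    s <- runif(1, 1, 200)
    w <- runif(1, 0, s)
    expect_equal(minkowski_combine(s, w, 1), s + w)
    grid <- c(0.2, 0.5, 1, 2, 5, 10, 25, 50)
    vals <- minkowski_combine(s, w, grid)
    expect_true(all(diff(vals) <= 1e-12))
    expect_true(all(vals >= s - 1e-12))
  }
  # inputs differing at least two-fold: m = 50 is within 0.1% of MAX
  expect_lt(abs(minkowski_combine(10, 5, 50) / 10 - 1), 1e-3)
  expect_lt(abs(minkowski_combine(200, 60, 50) / 200 - 1), 1e-3)
})

test_that("minkowski_combine rejects invalid domains", {
  expect_error(minkowski_combine(1, 1, 0), "positive")
  expect_error(minkowski_combine(1, 1, -2), "positive")
  expect_error(minkowski_combine(-1, 1, 2), "non-negative")
  expect_error(minkowski_combine(1, NA, 2), "non-negative")
})

test_that("enhancement_factor matches 2^(1/m) anchors and is decreasing", {
  expect_equal(enhancement_factor(1), 2)
  expect_equal(enhancement_factor(2), 2^(1 / 2))
  expect_equal(round(enhancement_factor(1.85), 2), 1.45)
  m <- seq(0.5, 30, length.out = 50)
  expect_true(all(diff(enhancement_factor(m)) < 0))
  expect_lt(enhancement_factor(1e3), 1.001)
  expect_error(enhancement_factor(0), "positive")
})

test_that("power_law_amplify evaluates a * mono^n and shows inverse
           effectiveness for compressive exponents", {
  expect_equal(power_law_amplify(1, a = 2.2, n = 0.84), 2.2)
  expect_equal(power_law_amplify(100, a = 1, n = 1), 100)
  expect_equal(power_law_amplify(50, a = 2.14, n = 0.89),
               2.14 * exp(0.89 * log(50)))
  x <- seq(1, 500, length.out = 200)
  ratio <- power_law_amplify(x, a = 2.04, n = 0.90) / x
  expect_true(all(diff(ratio) < 0))
  expect_error(power_law_amplify(0, 2, 0.9), "positive")
  expect_error(power_law_amplify(10, -1, 0.9), "positive")
})

test_that("schrodinger_combine: weighted-sum and ratio forms agree, weights
           are magnitude-proportional and normalized", {
  out <- schrodinger_combine(2, 1)
  expect_equal(out$predicted, 5 / 3)
  expect_equal(out$weight_strong, 2 / 3)
  expect_equal(schrodinger_combine(7, 7)$predicted, 7)
  expect_equal(schrodinger_combine(2, 0)$predicted, 2)
  set.seed(202)
  L <- runif(500, 0.01, 300)
  R <- runif(500, 0.01, 300)
  out <- schrodinger_combine(L, R)
  via_weights <- L * (L / (L + R)) + R * (R / (L + R))
  expect_true(all(abs(out$predicted - via_weights) < 1e-12))
  expect_true(all(abs(out$weight_strong + out$weight_weak - 1) < 1e-12))
  # betweenness: strictly inside (weak, strong) when the inputs differ
  s <- pmax(L, R); w <- pmin(L, R)
  d <- s > w
  expect_true(all(out$predicted[d] > w[d] & out$predicted[d] < s[d]))
  expect_error(schrodinger_combine(0, 0), "undefined")
})

test_that("mle_combine applies inverse-variance weights", {
  expect_equal(mle_combine(10, 6, 1, 1)$predicted, 8)
  out <- mle_combine(10, 5, 10, 5)
  expect_equal(out$weight_strong, 1 / 3)
  expect_equal(out$predicted, 20 / 3)
  # an unreliable channel is ignored in the limit
  expect_lt(abs(mle_combine(10, 6, 1, 1e12)$predicted - 10), 1e-9)
  set.seed(303)
  s <- runif(200, 1, 300); w <- s * runif(200, 0.05, 0.99)
  out <- mle_combine(s, w, s, w)
  expect_true(all(abs(out$weight_strong + out$weight_weak - 1) < 1e-12))
  expect_true(all(out$predicted > w & out$predicted < s))
  expect_error(mle_combine(10, 5, 0, 1), "positive")
  expect_error(mle_combine(10, 5, 1, -1), "positive")
})
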