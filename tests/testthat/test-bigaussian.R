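eq7 <- se_mixture_reference()

test_that("bigaussian evaluation follows the half-free exponent form", {
  p <- bigauss_params(0.5, 1, 1, 0, 0, 2)
  expect_equal(eval_bigaussian(p, 1), 0.5)            # peak of one component
  expect_equal(eval_bigaussian(p, 1e4), 0)            # tail limit
  # direct evaluation of the reference parameters at the narrow centre
  v <- eval_bigaussian(eq7, 0.372)
  expect_equal(v, 0.423 + 0.0668 * exp(-((0.372 - 0.226) / 2.369)^2),
               tolerance = 1e-12)
})

test_that("component weights normalise a*sigma and are scale invariant", {
  w <- component_weights(eq7)
  expect_equal(unname(round(100 * w, 1)), c(71.4, 28.6))
  expect_equal(sum(w), 1)
  # symmetric parameters split evenly
  expect_equal(unname(component_weights(bigauss_params(1, 0, 1, 1, 2, 1))),
               c(0.5, 0.5))
  # a vanished component carries no weight
  expect_equal(unname(component_weights(bigauss_params(1, 0, 1, 0, 0, 2))),
               c(1, 0))
  # simultaneous amplitude rescaling leaves weights unchanged
  p2 <- bigauss_params(10 * eq7$a1, eq7$mu1, eq7$sigma1,
                       10 * eq7$a2, eq7$mu2, eq7$sigma2)
  expect_equal(component_weights(p2), w)
  expect_error(component_weights(bigauss_params(0, 0, 1, 0, 0, 2)),
               "weights")
})

test_that("mixture moments use the sigma/sqrt(2) component SD", {
  # single Gaussian: no skew, no excess kurtosis, SD = sigma/sqrt(2)
  m1 <- mixture_moments(bigauss_params(1, 0.5, 2, 0, 0, 3))
  expect_equal(m1$mean, 0.5)
  expect_equal(m1$sd, 2 / sqrt(2))
  expect_equal(m1$skewness, 0)
  expect_equal(m1$ex_kurtosis, 0)
  # symmetric scale mixture: zero skew, positive excess kurtosis
  m2 <- mixture_moments(bigauss_params(1, 0, 1, 0.3, 0, 3))
  expect_equal(m2$skewness, 0)
  expect_gt(m2$ex_kurtosis, 0)
  # reference mixture is leptokurtic; closed form matches Monte Carlo
  m3 <- mixture_moments(eq7)
  expect_gt(m3$ex_kurtosis, 0)
  se <- sample_se_mixture(2e5, eq7, seed = 31)$SE
  x <- se - mean(se)
  mc_kurt <- length(x) * sum(x^4) / sum(x^2)^2 - 3
  expect_equal(m3$ex_kurtosis, mc_kurt, tolerance = 0.15)
  expect_equal(m3$mean, mean(se), tolerance = 0.02)
  expect_equal(m3$sd, sd(se), tolerance = 0.02)
})

test_that("histogram bins are integer-centred with half-integer left-closed edges", {
  h <- se_histogram(c(0.49, 0.50, -0.50, -0.51, 10.0, 10.6), limit = 10)
  expect_equal(h$n[h$center == 0], 2)    # 0.49 and -0.50
  expect_equal(h$n[h$center == 1], 1)    # 0.50 rounds up
  expect_equal(h$n[h$center == -1], 1)   # -0.51 rounds down
  expect_equal(h$n[h$center == 10], 1)   # 10.0 in range, 10.6 dropped
  expect_equal(attr(h, "n_total"), 5)
  expect_lte(sum(h$proportion), 1)
  expect_equal(diff(h$center), rep(1, 20))
})

test_that("a pure Gaussian sample is recognised as (near) single-component", {
  se <- withr::with_seed(21, rnorm(5000, 0.25, 1))
  f <- fit_bigaussian_1d(se, seed = 2)
  expect_gt(f$r2, 0.99)
  # whatever split the overparametrised fit chooses, the implied mixture
  # must reproduce a plain Gaussian: matching first two moments and no
  # material skew or excess kurtosis
  m <- mixture_moments(f$params)
  expect_lt(abs(m$mean - 0.25), 0.1)
  expect_lt(abs(m$sd - 1), 0.1)
  expect_lt(abs(m$skewness), 0.15)
  expect_lt(abs(m$ex_kurtosis), 0.3)
})

test_that("fitting recovers the planted mixture at cohort scale", {
  se <- sample_se_mixture(2000, eq7, seed = 101)$SE
  f <- fit_bigaussian_1d(se, seed = 1)
  expect_gt(f$r2, 0.99)
  expect_lt(abs(f$weights[1] - 0.714), 0.12)   # single-seed MC band
  expect_lt(abs(f$params$mu1 - 0.372), 0.15)
  expect_s3_class(tidy(f), "tbl_df")
  expect_equal(nrow(tidy(f)), 2)
  expect_equal(glance(f)$n, length(se[abs(se) <= 10]))
})

test_that("mean recovered weight over 20 seeds is close to the target", {
  w1 <- vapply(1:20, function(s) {
    se <- sample_se_mixture(2000, eq7, seed = 100 + s)$SE
    unname(fit_bigaussian_1d(se, seed = s)$weights[1])
  }, numeric(1))
  expect_lt(abs(mean(w1) - 0.714), 0.03)
})

test_that("the fit is equivariant under integer shifts of the refraction", {
  se <- sample_se_mixture(2000, eq7, seed = 103)$SE
  f0 <- fit_bigaussian_1d(se, seed = 4)
  f2 <- fit_bigaussian_1d(se + 2, seed = 4)
  expect_equal(f2$params$mu1, f0$params$mu1 + 2, tolerance = 0.02)
  expect_equal(f2$params$mu2, f0$params$mu2 + 2, tolerance = 0.1)
  expect_equal(unname(f2$weights[1]), unname(f0$weights[1]),
               tolerance = 0.02)
})

test_that("too few in-range refractions is an error", {
  expect_error(fit_bigaussian_1d(rnorm(30)), "at least 50")
})
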