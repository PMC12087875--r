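dims <- c("SE", "P_c", "P_lb", "ACD_tot", "AL")

iso_fit <- function(sigma = 1) {
  toy_mv_fit(list(rep(0, 5), rep(10, 5)),
             list(diag(sigma^2, 5), diag(4, 5)))
}

test_that("one-dimensional coverage follows the normal CDF", {
  expect_equal(coverage_1d(2.26), 0.9762, tolerance = 5e-5)
  expect_equal(coverage_1d(1.96), 0.95, tolerance = 5e-4)
  expect_lt(coverage_1d(1e-8), 1e-7)
})

test_that("pair ellipses come from eigen-decomposed 2x2 submatrices", {
  f <- iso_fit(sigma = 3)
  ell <- pair_ellipses(f, epsilon = 2)
  expect_equal(nrow(ell), 10)     # C(5,2)
  # isotropic: circles of radius epsilon * sigma
  expect_equal(ell$len1, rep(6, 10))
  expect_equal(ell$len2, rep(6, 10))
  # anisotropic diagonal: semi-axes sqrt(eigenvalues) on coordinate axes
  S <- diag(c(4, 1, 1, 1, 1))
  f2 <- toy_mv_fit(list(rep(0, 5), rep(10, 5)), list(S, diag(4, 5)))
  e2 <- pair_ellipses(f2, epsilon = 1)
  first <- e2[e2$var_x == "SE" & e2$var_y == "P_c", ]
  expect_equal(first$len1, 2)
  expect_equal(first$len2, 1)
  expect_equal(abs(first$vec1_x), 1)
  expect_equal(abs(first$vec1_y), 0)
  # a non-PD submatrix is an error
  S3 <- diag(c(0, 1, 1, 1, 1))
  f3 <- toy_mv_fit(list(rep(0, 5), rep(10, 5)), list(S3, diag(4, 5)))
  expect_error(pair_ellipses(f3, 1), "positive definite")
})

test_that("classification is the all-pairs Mahalanobis rule", {
  f <- iso_fit()
  centre <- tibble::as_tibble(setNames(as.list(rep(0, 5)), dims))
  cl <- classify_cohort(centre, f, epsilon = 1e-6)
  expect_equal(as.character(cl$subgroup), "Regulated")
  expect_equal(cl$failing_pairs, "")
  # displacement along one dimension breaks exactly the pairs involving it
  off <- centre
  off$AL <- 10   # 10 sigma along AL
  cl2 <- classify_cohort(off, f, epsilon = 2)
  expect_equal(as.character(cl2$subgroup), "Dysregulated")
  expect_equal(cl2$n_failing_pairs, 4L)
  expect_true(all(grepl("AL", strsplit(cl2$failing_pairs, ";")[[1]])))
})

test_that("Regulated regions are nested in epsilon", {
  pl <- sample_planted_mixture(
    400, rep(0, 5), rep(3, 5), diag(5), diag(2, 5), 0.6, seed = 61)
  f <- iso_fit()
  X <- tibble::as_tibble(pl$X)
  lab <- lapply(c(0.5, 1, 2, 3), function(eps) {
    classify_cohort(X, f, eps)$subgroup == "Regulated"
  })
  for (i in 1:3) expect_true(all(lab[[i]] <= lab[[i + 1]]))
  # fraction regulated is non-decreasing in epsilon
  fr <- vapply(lab, mean, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("labels are invariant under unit rescaling of one dimension", {
  pl <- sample_planted_mixture(
    300, rep(0, 5), rep(3, 5), diag(5), diag(2, 5), 0.6, seed = 62)
  f <- iso_fit()
  X <- tibble::as_tibble(pl$X)
  cl <- classify_cohort(X, f, 2)
  # express AL in metres: rescale data, centre and covariance consistently
  X2 <- X
  X2$AL <- X2$AL / 1000
  S1 <- diag(5)
  S1[5, 5] <- S1[5, 5] / 1000^2
  S2 <- diag(4, 5)
  S2[5, 5] <- S2[5, 5] / 1000^2
  mu1 <- rep(0, 5)
  mu2 <- rep(10, 5)
  mu2[5] <- 10 / 1000
  f2 <- toy_mv_fit(list(mu1, mu2), list(S1, S2))
  cl2 <- classify_cohort(X2, f2, 2)
  expect_equal(cl$subgroup, cl2$subgroup)
  # while the ellipse axes rescale
  e1 <- pair_ellipses(f, 1)
  e2 <- pair_ellipses(f2, 1)
  expect_lt(e2$len2[e2$var_x == "ACD_tot" & e2$var_y == "AL"],
            e1$len2[e1$var_x == "ACD_tot" & e1$var_y == "AL"])
})

test_that("a single pair ellipse has chi-square(2) coverage", {
  withr::with_seed(63, {
    n <- 20000
    X <- matrix(rnorm(2 * n), n, 2)
  })
  eps <- 2.26
  inside <- sqrt(rowSums(X^2)) <= eps
  expect_equal(mean(inside), 1 - exp(-eps^2 / 2), tolerance = 0.01)
  # ... which is deliberately not the 1-D reading of the same epsilon
  expect_gt(coverage_1d(eps), 1 - exp(-eps^2 / 2))
})

test_that("epsilon calibration reaches the target fraction", {
  # degenerate cohort at the centre: any epsilon works, lower bracket returned
  f <- iso_fit()
  centre <- tibble::as_tibble(
    setNames(as.list(rep(0, 5)), dims))[rep(1, 60), ]
  cal0 <- calibrate_epsilon(centre, f, target = 0.9)
  expect_equal(cal0$epsilon, 0.5)
  expect_equal(cal0$fraction, 1)
  # planted two-component cohort with overlapping components, fitted then
  # calibrated to 0.714
  pl <- sample_planted_mixture(
    2000, c(0.3, 42, 26, 3.2, 23.1), c(-1.5, 43, 26.8, 3.4, 24.3),
    diag(c(0.4, 1.2, 1.5, 0.08, 0.5)^2),
    diag(c(1.5, 1.4, 1.8, 0.1, 0.9)^2), 0.714, seed = 64)
  X <- tibble::as_tibble(pl$X)
  fit <- fit_multivariate_bigaussian(X, restarts = 5, seed = 9)
  cal <- calibrate_epsilon(X, fit, target = 0.714)
  expect_lt(abs(cal$fraction - 0.714), 0.02)
  # achieved fraction at the returned epsilon dominates half that scale
  cl_half <- classify_cohort(X, fit, cal$epsilon / 2)
  expect_gte(cal$fraction, mean(cl_half$subgroup == "Regulated"))
  # unattainable targets report the boundary fractions
  expect_error(calibrate_epsilon(X, fit, target = 0.9999,
                                 bracket = c(0.5, 1)),
               "unattainable")
})
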