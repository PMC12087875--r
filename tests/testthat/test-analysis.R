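# One mid-size derived synthetic cohort shared across the analysis tests
shared_cohort <- local({
  co <- generate_cohort(cohort_spec(n = 2000, seed = 81))
  suppressMessages(derive_biometry(co))
})

test_that("the emmetropia criterion is inclusive at both bounds", {
  d <- tibble::tibble(SE = c(-0.5, 0, 0.5, 0.6))
  tab <- suppressWarnings(descriptive_table(d))
  expect_equal(tab$n_emm[tab$parameter == "SE"], 3)
  expect_equal(tab$n_all[tab$parameter == "SE"], 4)
})

test_that("descriptive statistics handle constant columns", {
  d <- tibble::tibble(SE = c(0, 0.1, 0.2, 0.3), AL = rep(23, 4))
  tab <- descriptive_table(d)
  al <- tab[tab$parameter == "AL", ]
  expect_equal(al$sd_all, 0)
  expect_equal(al$min_all, 23)
  expect_equal(al$max_all, 23)
  expect_true(is.na(al$p_value))
})

test_that("the synthetic emmetropic subgroup resembles the reference cohort", {
  tab <- descriptive_table(shared_cohort)
  al <- tab[tab$parameter == "AL", ]
  # the generator's refraction model centres ~0.3 D hyperopic of the
  # reference cohort mean, which drags the emmetropic AL mean slightly
  # long; agreement is to 0.25 mm, not to sampling error
  expect_lt(abs(al$mean_emm - 23.12), 0.25)
  expect_gt(al$n_emm, 500)
  # CCT is generated independently of refraction, so the overlapping-group
  # comparison cannot distinguish it (the refraction-linked parameters may
  # differ here because the generator's mixture centre sits ~0.3 D
  # hyperopic of zero)
  expect_false(tab$significant[tab$parameter == "CCT"])
})

test_that("the correlation matrix is symmetric with a Bonferroni mask", {
  cm <- correlation_matrix(shared_cohort)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, nrow(cm$r)))
  expect_equal(cm$alpha, 0.05 / 11)
  expect_lt(abs(cm$r["AL", "VCD"] - 0.951), 0.03)
  expect_true(cm$significant["AL", "VCD"])
  # independent columns: weak and non-significant
  d <- withr::with_seed(82, tibble::tibble(SE = rnorm(2000),
                                           AL = rnorm(2000)))
  cm2 <- correlation_matrix(d, params = c("SE", "AL"))
  expect_lt(abs(cm2$r["SE", "AL"]), 0.05)
  expect_false(cm2$significant["SE", "AL"])
  # zero variance is flagged, not propagated
  d3 <- tibble::tibble(SE = rnorm(10), AL = rep(23, 10))
  cm3 <- correlation_matrix(d3, params = c("SE", "AL"))
  expect_equal(cm3$degenerate, "AL")
  expect_true(is.na(cm3$r["SE", "AL"]))
  expect_false(cm3$significant["SE", "AL"])
})

test_that("refraction bins use half-integer left-closed edges", {
  d <- tibble::tibble(SE = c(0.49, 0.50, -1.2), AL = c(23, 24, 25))
  b <- binned_group_summary(d, params = "AL")
  expect_equal(sort(b$bin), c(-1, 0, 1))
  expect_equal(b$n[b$bin == 0], 1)
  expect_equal(b$n[b$bin == 1], 1)
  # single-bin cohort: one populated row, CI suppressed below n = 3
  b2 <- binned_group_summary(tibble::tibble(SE = c(0.1, 0.2), AL = c(23, 24)),
                             params = "AL")
  expect_equal(nrow(b2), 1)
  expect_true(is.na(b2$ci_lo))
})

test_that("binned axial length decreases towards hyperopia", {
  b <- binned_group_summary(shared_cohort, params = "AL")
  al <- b[b$n >= 20, ]
  al <- al[order(al$bin), ]
  # myopic eyes are longer: mean AL strictly decreases with bin index
  expect_true(all(diff(al$mean) < 0))
  # and the binned SE means are monotone in the bin index by construction
  bse <- binned_group_summary(shared_cohort, params = "SE")
  bse <- bse[order(bse$bin), ]
  expect_true(all(diff(bse$mean) > 0))
})

test_that("alignment regressions recover exact and planted slopes", {
  # noise-free line
  d <- tibble::tibble(AL = seq(20.5, 26.5, by = 0.5))
  d$ACD_tot <- 0.2 * d$AL - 1.3
  d$ASL <- 0.11 * d$AL + 4.9
  d$SE <- rep(0, nrow(d))
  d$P_c <- 42 - (d$AL - 23)
  d$P_lb <- 26 - (d$AL - 23)
  r <- suppressWarnings(fit_alignment_regressions(d, min_group_n = 5))
  acd <- r$fits[r$fits$response == "ACD_tot", ]
  expect_equal(acd$slope, 0.2, tolerance = 1e-12)
  expect_equal(acd$r2, 1, tolerance = 1e-12)
  # the AL window excludes long eyes
  d2 <- dplyr::bind_rows(d, tibble::tibble(AL = 27.5, ACD_tot = 10, ASL = 12,
                                           SE = 0, P_c = 40, P_lb = 20))
  r2 <- suppressWarnings(fit_alignment_regressions(d2, min_group_n = 5))
  expect_equal(r2$fits$n, rep(nrow(d), 2))
  # synthetic cohort: slope close to the generator-implied cov/var ratio
  r3 <- fit_alignment_regressions(shared_cohort)
  implied <- (0.491 * 0.90 * 0.32) / 0.90^2   # cov(AL, AD) / var(AL)
  acd3 <- r3$fits[r3$fits$response == "ACD_tot", ]
  expect_gt(acd3$slope, 0)
  expect_lt(abs(acd3$slope - implied), 0.05)
  expect_gt(nrow(r3$group_slopes), 0)
  expect_true(all(r3$group_slopes$n >= 20))
})

test_that("uniqueness pairs follow the limits-of-agreement rule", {
  base <- shared_cohort[1, c("SE", "P_c", "P_lb", "ACD_tot", "LT", "AL")]
  # two identical eyes form one pair
  two <- dplyr::bind_rows(base, base)
  expect_equal(uniqueness_pairs(two)$n_pairs, 1L)
  # 1 mm of AL alone breaks the match
  far <- base
  far$AL <- far$AL + 1
  expect_equal(uniqueness_pairs(dplyr::bind_rows(base, far))$n_pairs, 0L)
  # three mutually identical eyes yield all three unordered pairs
  three <- dplyr::bind_rows(base, base, base)
  expect_equal(uniqueness_pairs(three)$n_pairs, 3L)
})

test_that("the neighbour scan equals the brute-force oracle", {
  spec <- uniqueness_spec()
  tol <- spec$limit_factor * spec$repeatability
  # 25 base eyes plus sub-tolerance copies: every copy pair must match,
  # and chance near-matches among base eyes are counted identically by
  # both algorithms
  base <- shared_cohort[1:25, spec$parameters]
  copies <- base
  withr::with_seed(83, {
    for (p in spec$parameters) {
      copies[[p]] <- copies[[p]] + runif(25, -0.3, 0.3) * tol[[p]]
    }
  })
  sq <- dplyr::bind_rows(base, copies)
  M <- as.matrix(sq)
  brute <- 0L
  for (i in 1:49) for (j in (i + 1):50) {
    if (all(abs(M[i, ] - M[j, ]) <= tol)) brute <- brute + 1L
  }
  expect_equal(uniqueness_pairs(sq)$n_pairs, brute)
  expect_gte(brute, 25)  # at least the planted duplicates
})

test_that("the relative profile scales positions and power fractions", {
  d <- tibble::tibble(CCT = 0.5, ACD_tot = 3.45, ASL = 7.5, AL = 23,
                      P_c = 42.02, P_lb = 26, P_eye = 63.43)
  pr <- relative_scaling_profile(d)
  expect_equal(pr$pos_lens_ant_pct, 15.0)
  expect_equal(pr$P_cr, 42.02 / 63.43)
  # isotropic scaling of all distances leaves positions unchanged
  d2 <- dplyr::mutate(d, CCT = CCT * 1.1, ACD_tot = ACD_tot * 1.1,
                      ASL = ASL * 1.1, AL = AL * 1.1)
  pr2 <- relative_scaling_profile(d2)
  expect_equal(pr2$pos_lens_ant_pct, pr$pos_lens_ant_pct)
  expect_equal(pr2$pos_lens_post_pct, pr$pos_lens_post_pct)
  # the effectivity variant needs the principal points and stays optional
  pr3 <- relative_scaling_profile(shared_cohort, effectivity = TRUE)
  expect_true(all(c("P_cr_eff", "lens_fraction_eff") %in% names(pr3)))
  expect_true(all(abs(pr3$P_cr_eff + pr3$lens_fraction_eff - 1) < 1e-9))
})

test_that("emmetropic eyes are a subset of the comparison cohort", {
  tab <- descriptive_table(shared_cohort)
  expect_true(all(tab$n_emm <= tab$n_all))
  expect_equal(unique(tab$n_all), nrow(shared_cohort))
})
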