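idx <- refractive_indices()

test_that("distance bookkeeping matches the cohort-mean arithmetic", {
  d <- derive_distances(tibble::tibble(CCT = 0.53, AD = 2.64,
                                       LT = 4.25, AL = 23.14))
  expect_equal(d$ACD_tot, 3.17)
  expect_equal(d$ASL, 7.42)
  expect_equal(d$VCD, 15.72)
  # zero corneal thickness reduces ACD_tot to the aqueous depth
  d0 <- derive_distances(tibble::tibble(CCT = 0, AD = 2.64,
                                        LT = 4.25, AL = 23.14))
  expect_equal(d0$ACD_tot, 2.64)
  # a collapsed vitreous is rejected with the eye named
  expect_error(
    derive_distances(tibble::tibble(eye_id = "bad1", CCT = 0.53, AD = 2.64,
                                    LT = 4.25, AL = 7.42)),
    "bad1")
})

test_that("corneal thick-lens power matches hand evaluation", {
  d <- corneal_power(tibble::tibble(r_ca = 7.8, r_cp = 6.5, CCT = 0.536), idx)
  expect_equal(d$P_ca, 48.205, tolerance = 1e-4)
  expect_equal(d$P_cp, -6.564, tolerance = 1e-4)
  expect_equal(d$P_c, 41.764, tolerance = 1e-4)
  # zero thickness removes the thick-lens cross term
  d0 <- corneal_power(tibble::tibble(r_ca = 7.8, r_cp = 6.5, CCT = 0), idx)
  expect_equal(d0$P_c, d0$P_ca + d0$P_cp)
  # a flat posterior surface contributes no power
  df <- corneal_power(tibble::tibble(r_ca = 7.8, r_cp = Inf, CCT = 0.536), idx)
  expect_equal(df$P_cp, 0)
  expect_equal(df$P_c, df$P_ca)
  expect_error(corneal_power(tibble::tibble(r_ca = 0, r_cp = 6.5,
                                            CCT = 0.5), idx),
               "radius")
})

test_that("a power-free lens leaves the cornea as the whole system", {
  e <- derive_distances(mean_eye()) |> corneal_power(idx)
  e$P_lb <- 0
  d <- eye_cardinal_points(e, idx)
  expect_equal(d$P_eye, d$P_c)
  # the lens model keeps its principal-plane pair even at zero power, so
  # the ocular pp2 sits the fixed H1-H2 separation (0.051 LT) behind the
  # corneal pp2; the corneal value itself is recovered only when the pair
  # collapses
  expect_equal(d$pp_eye2, d$pp_c2 + 0.051 * d$LT, tolerance = 1e-12)
})

test_that("cohort-mean inputs give a whole-eye power near the reported mean", {
  # nonlinearity makes the function of means differ from the mean of the
  # function, so only 0.2 D agreement is expected
  e <- derive_distances(mean_eye()) |> corneal_power(idx)
  e$P_lb <- 26.00
  d <- eye_cardinal_points(e, idx)
  expect_lt(abs(d$P_eye - 63.43), 0.2)
})

test_that("axial power follows the dioptric-distance formula and its limits", {
  d <- axial_power(tibble::tibble(AL = 23, pp_eye2 = 0, P_eye = 60), idx)
  expect_equal(d$P_ax, 1000 * (4 / 3) / 23, tolerance = 1e-9)
  expect_equal(d$SE_model, d$P_ax - 60)
  # SE_model = 0 iff P_ax equals P_eye
  d2 <- axial_power(tibble::tibble(AL = 23, pp_eye2 = 0,
                                   P_eye = 1000 * (4 / 3) / 23), idx)
  expect_equal(d2$SE_model, 0)
  expect_error(axial_power(tibble::tibble(AL = 1, pp_eye2 = 2,
                                          P_eye = 60), idx),
               "pp_eye2")
})

test_that("axial power and model refraction strictly decrease with AL", {
  base <- derive_distances(mean_eye()) |> corneal_power(idx)
  base <- bennett_lens_power(base, idx)
  als <- seq(21, 27, by = 0.25)
  rows <- base[rep(1, length(als)), ]
  rows$AL <- als
  d <- rows |> eye_cardinal_points(idx) |> axial_power(idx)
  expect_true(all(diff(d$P_ax) < 0))
  expect_true(all(diff(d$SE_model) < 0))
})

test_that("Bennett inversion round-trips the measured refraction", {
  eyes <- random_eyes(500, seed = 11)
  d <- eyes |> derive_distances() |> corneal_power(idx) |>
    bennett_lens_power(idx) |>
    eye_cardinal_points(idx) |> axial_power(idx)
  expect_lt(max(abs(d$SE - d$SE_model)), 1e-9)
  # and recovers the generating lens power
  expect_lt(max(abs(d$P_lb - eyes$P_lb_true)), 1e-6)
})

test_that("vergence and forward-model Bennett agree on physiological eyes", {
  # the two methods reference the refraction at slightly different planes,
  # a second-order difference that grows with |SE|; compare within the
  # clinically common range
  eyes <- random_eyes(300, seed = 12)
  eyes <- eyes[abs(eyes$SE) <= 8, ]
  base <- eyes |> derive_distances() |> corneal_power(idx)
  a <- bennett_lens_power(base, idx, method = "eq1-solve")
  b <- bennett_lens_power(base, idx, method = "vergence")
  expect_lt(max(abs(a$P_lb - b$P_lb)), 0.25)
})

test_that("cohort-mean inputs give a Bennett power near the reported mean", {
  d <- derive_distances(mean_eye()) |> corneal_power(idx) |>
    bennett_lens_power(idx)
  expect_lt(abs(d$P_lb - 26.00), 0.5)
})

test_that("an unreachable refraction has no lens-power solution", {
  e <- mean_eye()
  e$SE <- -40  # no physical lens power can produce this
  expect_error(
    derive_distances(e) |> corneal_power(idx) |> bennett_lens_power(idx),
    "Bennett")
})

test_that("axial-length scaling multiplies powers and divides distances", {
  d <- tibble::tibble(P_c = 42, AL = 23, CCT = 0.55)
  s <- scale_to_AL(d)
  expect_equal(s$P_c, 42 * 23 / 1000)
  expect_equal(s$AL, 1)
  expect_equal(s$CCT, 0.55 / 23)
})

test_that("the scaled thick-lens combination reproduces scaled total power", {
  eyes <- random_eyes(1000, seed = 13)
  d <- eyes |> derive_distances() |> corneal_power(idx)
  s <- scale_to_AL(d)
  recombined <- s$P_ca + s$P_cp - s$P_ca * s$P_cp * s$CCT / idx$n_c
  expect_lt(max(abs(recombined - s$P_c)), 1e-12)
  expect_lt(max(abs(s$P_c - d$P_c * d$AL / 1000)), 1e-12)
})

test_that("derive_biometry applies row-wise with logged exclusions", {
  eyes <- random_eyes(3, seed = 14)
  d <- suppressMessages(derive_biometry(eyes))
  expect_equal(nrow(d), 3)
  expect_equal(d$P_cr, d$P_c / d$P_eye)
  expect_equal(d$AL_CR, d$AL / d$r_ca)
  # plant one invalid row
  bad <- eyes
  bad$AL[2] <- bad$CCT[2] + bad$AD[2] + bad$LT[2] - 0.1
  d2 <- suppressMessages(derive_biometry(bad))
  expect_equal(nrow(d2), 2)
  excl <- attr(d2, "exclusions")
  expect_equal(nrow(excl), 1)
  expect_match(excl$reason, "vitreous")
  # empty input warns and returns empty
  expect_warning(derive_biometry(eyes[0, ]), "empty")
})
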