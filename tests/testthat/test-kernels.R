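test_that("effective diffusion is the D*theta*f product", {
  expect_equal(effective_diffusion(7.92e-6, 0.22, 0.3), 5.2272e-7)
  expect_equal(effective_diffusion(6.00e-6, 0.18, 0.3), 3.24e-7)
  expect_equal(effective_diffusion(3e-6, 1, 1), 3e-6)  # identity case
  expect_error(effective_diffusion(-1e-6, 0.2, 0.3))
})

test_that("diurnal water flux is non-negative, peaks at noon and averages to the daily mean", {
  Jd <- 5.38e-7
  expect_equal(water_flux_at(0, Jd), 0)
  expect_equal(water_flux_at(12, Jd), 2 * Jd)   # peak = twice the mean
  expect_equal(water_flux_at(12, Jd), 1.076e-6)
  expect_equal(water_flux_at(27, Jd), water_flux_at(3, Jd))  # 24 h periodic
  tt <- seq(0, 24, length.out = 100001)[-100001]
  expect_true(all(water_flux_at(tt, Jd) >= 0))
  expect_equal(mean(water_flux_at(tt, Jd)), Jd, tolerance = 1e-6)
})

test_that("Michaelis-Menten flux saturates, is monotone and rejects negative input", {
  Fm <- 1e-12; Km <- 4e-6
  expect_equal(mm_uptake_flux(0, Fm, Km), 0)
  expect_equal(mm_uptake_flux(Km, Fm, Km), Fm / 2)       # half saturation
  expect_equal(mm_uptake_flux(1e3 * Km, Fm, Km), Fm, tolerance = 1e-3)
  cc <- seq(0, 1e-4, length.out = 50)
  fl <- mm_uptake_flux(cc, Fm, Km)
  expect_true(all(diff(fl) > 0) && all(fl <= Fm))
  expect_error(mm_uptake_flux(-1e-9, Fm, Km), "non-negative")
})

test_that("hair spacing matches hand arithmetic in both readings", {
  expect_equal(hair_spacing(0.05, 165, mode = "root-surface"),
               sqrt(2 * pi * 0.05 / 165))
  expect_equal(hair_spacing(0.05, 165, mode = "root-surface"), 0.04363,
               tolerance = 1e-3)
  expect_equal(hair_spacing(0.0095, 165, mode = "root-surface"), 0.01902,
               tolerance = 1e-3)
  expect_equal(hair_spacing(0.05, 165, a_h = 4e-4), sqrt(2 * pi * 4e-4 / 165))
  ## dense hairs shrink the spacing toward zero
  expect_lt(hair_spacing(0.05, 1e6, mode = "root-surface"), 1e-3)
  ## dilute-hair ratio stays small for packaged geometries
  hsc <- hair_sink_coefficient(0.05, 165, mode = "root-surface")
  expect_equal(4e-4 / hsc$l, 0.00917, tolerance = 1e-2)
  expect_lt(hair_sink_coefficient(0.0095, 165)$ratio, 0.15)
  ## strained geometry warns but does not fail
  expect_warning(hair_sink_coefficient(0.05, 165, a_h = 0.01), "0.15")
})

test_that("hair sink matches the published form and its gating", {
  hsc <- hair_sink_coefficient(0.05, 165, mode = "root-surface")
  ## at c = Kmh the Michaelis-Menten factor is Fmh/2; coefficient is
  ## (L/l) * (2 pi a_h / l^2) = 22.92 * 1.320
  expect_equal(hsc$coef, 22.92 * 1.320, tolerance = 1e-3)
  Fmh <- 1e-12; Kmh <- 4e-6
  r <- c(0.05, 0.06, 0.08, 0.2)
  Q <- hair_sink(rep(Kmh, 4), r, t_s = 0, a = 0.05, l_rh = 0.023,
                 lifetime_s = 2 * 86400, has_hairs = TRUE,
                 coef = hsc$coef, Fmh = Fmh, Kmh = Kmh)
  expect_equal(Q[1:2], rep(hsc$coef * Fmh / 2, 2))
  expect_equal(Q[3:4], c(0, 0))              # outside the hair zone
  ## expired hairs and hairless segments contribute nothing
  expect_equal(hair_sink(rep(Kmh, 4), r, t_s = 3 * 86400, a = 0.05,
                         l_rh = 0.023, lifetime_s = 2 * 86400,
                         has_hairs = TRUE, coef = hsc$coef,
                         Fmh = Fmh, Kmh = Kmh), rep(0, 4))
  expect_equal(hair_sink(rep(Kmh, 4), r, 0, 0.05, 0.023, 2 * 86400,
                         has_hairs = FALSE, coef = hsc$coef,
                         Fmh = Fmh, Kmh = Kmh), rep(0, 4))
})

test_that("precipitation driving term needs both ions supersaturated", {
  Ksp <- 2.4e-11  # sqrt = 4.899e-6
  expect_equal(precip_driving(4.0e-6, 6.0e-6, Ksp), 0)   # Ca below threshold
  expect_equal(precip_driving(6.0e-6, 5.0e-6, Ksp), 5.0e-6 - sqrt(Ksp))
  expect_equal(precip_driving(6.0e-6, 5.0e-6, Ksp), 1.01e-7, tolerance = 1e-2)
  expect_equal(precip_driving(sqrt(Ksp), sqrt(Ksp), Ksp), 0)  # boundary
  ## vectorized, never negative
  ca <- runif(100, 0, 1e-5); s <- runif(100, 0, 1e-5)
  M <- precip_driving(ca, s, Ksp)
  expect_true(all(M >= 0))
  expect_true(all((M > 0) == (pmin(ca, s) > sqrt(Ksp))))
})

test_that("radial grid is refined at the root and spans the domain exactly", {
  g <- radial_grid(0.05, r_out = 6, n = 300, first_width = 2.5e-4)
  expect_equal(g$faces[1], 0.05)
  expect_equal(g$faces[length(g$faces)], 6)
  expect_lte(g$w[1], 5e-4)
  expect_true(all(diff(g$faces) > 0))
  expect_true(all(abs(diff(g$w) / g$w[-g$n] - (g$g - 1)) < 1e-10))
  expect_error(radial_grid(0.05, first_width = 1e-3), "5e-4")
})
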