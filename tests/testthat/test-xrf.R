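test_that("distance map is the scaled Euclidean distance transform", {
  m <- matrix(0, 7, 7); m[4, 4] <- 1
  d <- distance_map(m, pixel_size = 20)
  expect_equal(d[4, 4], 0)                    # inside the root
  expect_equal(d[4, 5], 20)                   # 4-neighbor
  expect_equal(d[5, 5], 20 * sqrt(2))         # diagonal
  expect_equal(d[4, 7], 60)
  expect_equal(distance_map(matrix(1, 3, 3)), matrix(0, 3, 3))  # all root
  expect_error(distance_map(matrix(0, 3, 3)), "empty")
})

test_that("radial profile matches brute-force per-pixel aggregation exactly", {
  set.seed(42)
  for (i in 1:5) {
    n <- 41
    root <- matrix(FALSE, n, n); root[19:23, 19:23] <- TRUE
    d <- distance_map(root, 20)
    map <- matrix(rpois(n * n, 30), n, n)
    pore <- matrix(runif(n * n) < 0.15, n, n) & !root
    prof <- radial_profile(map, d, pore, bin_width = 20)
    ref <- oracle_profile(map, d, pore, bin_width = 20)
    got <- prof[prof$n > 0, ]
    expect_equal(got$lo / 20, ref$bin)
    expect_equal(got$n, ref$n)
    expect_equal(got$mean, ref$mean)
    expect_equal(got$sd, ref$sd)
  }
})

test_that("constant maps and fully-pored bins behave as expected", {
  n <- 31
  root <- matrix(FALSE, n, n); root[16, 16] <- TRUE
  d <- distance_map(root, 20)
  prof <- radial_profile(matrix(7, n, n), d)
  nz <- prof$n > 0
  expect_true(all(prof$mean[nz] == 7) && all(prof$sd[nz] == 0))
  ## pore mask swallowing an entire annulus empties that bin
  pore <- d >= 40 & d < 60
  prof2 <- radial_profile(matrix(7, n, n), d, pore)
  expect_equal(prof2$n[prof2$lo == 40], 0)
  expect_true(is.na(prof2$mean[prof2$lo == 40]))
  expect_error(radial_profile(matrix(7, n, n), d, pore_mask = !root), "evaluable")
})

test_that("bulk statistics are weighted moments beyond the inner cut", {
  p <- generate_profile_fixture(53, weights = 1, values = rep(2, 53))
  p$mean[p$lo >= 1000] <- c(1, 2, 3)
  b <- bulk_stats(p)
  expect_equal(b$mean, 2)
  expect_equal(b$n_bins, 3)
  ## zero-weight bins are ignored
  p$n[p$lo >= 1000] <- c(1, 0, 1)
  p$mean[p$lo >= 1000] <- c(1, 99, 3)
  expect_equal(bulk_stats(p)$mean, 2)
  ## random fixture against the direct weighted-moment oracle
  set.seed(7)
  w <- sample(1:50, 80, replace = TRUE)
  v <- rnorm(80, 100, 4)
  pf <- generate_profile_fixture(80, weights = w, values = v)
  bs <- bulk_stats(pf, inner_cut_um = 0)
  o <- oracle_weighted_stats(v, w)
  expect_equal(bs$mean, o$mean, tolerance = 1e-12)
  expect_equal(bs$sd, o$sd, tolerance = 1e-12)
  expect_error(bulk_stats(generate_profile_fixture(10, 1, rep(1, 10))), "beyond")
})

test_that("extent rule: no crossing, single crossing, undulating ambiguity", {
  bulk <- list(mean = 50, sd = 2)  # band edge at 54
  ## profile entirely within the band
  p0 <- generate_profile_fixture(40, weights = 100, values = rep(50, 40))
  e0 <- extent_estimate(p0, bulk, "accumulation")
  expect_equal(e0$extent_um, 0)
  expect_false(e0$ambiguous)
  ## monotone decaying enrichment crossing once near 300 um
  v <- 50 + 30 * exp(-(((1:40) - 0.5) * 20) / 120)
  p1 <- generate_profile_fixture(40, weights = 100, values = v)
  e1 <- extent_estimate(p1, bulk, "accumulation")
  expect_false(e1$ambiguous)
  ## analytic crossing of the band edge: d = 120 * log(30/4)
  expect_equal(e1$extent_um, 120 * log(30 / 4), tolerance = 0.05)
  ## undulating profile: crossings near {180, 340, 520}, persistence only
  ## satisfied after 340
  v2 <- rep(50, 40)
  v2[1:9] <- 60; v2[10] <- 49; v2[11:17] <- 60
  v2[24:26] <- 60; v2[28:40] <- 60
  p2 <- generate_profile_fixture(40, weights = 100, values = v2)
  e2 <- extent_estimate(p2, bulk, "accumulation")
  expect_equal(round(e2$crossings_um), c(181, 342, 522))
  expect_equal(e2$extent_um, 342)
  expect_true(e2$ambiguous)
  ## depletion direction mirrors the rule
  p3 <- generate_profile_fixture(40, weights = 100,
                                 values = c(rep(40, 10), rep(50, 30)))
  e3 <- extent_estimate(p3, bulk, "depletion")
  expect_equal(e3$extent_um, 200, tolerance = 25)
})

test_that("zero-gradient noiseless maps give zero extent through the pipeline", {
  sm <- generate_map(map_recipe("loam", size_px = 151, amplitude = 0,
                                texture_cv = 0, noise = FALSE, seed = 2))
  prof <- radial_profile(sm$map, sm$distance, sm$pore)
  ex <- extent_estimate(prof, bulk_stats(prof), "accumulation")
  expect_equal(ex$extent_um, 0)
  expect_false(ex$ambiguous)
})
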