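test_that("map generation is deterministic under a fixed seed", {
  rec <- map_recipe("sand", size_px = 121, root_radius_um = 300, seed = 9)
  a <- generate_map(rec)
  b <- generate_map(rec)
  expect_identical(a$map, b$map)
  expect_identical(a$pore, b$pore)
  ## a different seed moves the grains
  c <- generate_map(map_recipe("sand", size_px = 121, root_radius_um = 300,
                               seed = 10))
  expect_false(identical(a$pore, c$pore))
  ## the generator does not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(generate_map(rec)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("zero amplitude and no noise give a flat matrix signal", {
  sm <- generate_map(map_recipe("loam", size_px = 101, amplitude = 0,
                                texture_cv = 0, noise = FALSE, seed = 4))
  vals <- sm$map[!sm$root & !sm$pore]
  expect_true(all(vals == 50))
  expect_equal(sum(sm$enrichment), 0)
})

test_that("injected enrichment mass matches the envelope on the support", {
  for (style in c("loam", "sand")) for (envl in c("exponential", "step")) {
    sm <- generate_map(map_recipe(style, size_px = 151, envelope = envl,
                                  extent_um = 300, patchiness = 0.5,
                                  noise = FALSE, seed = 6))
    support <- !sm$root & !sm$pore
    expected <- if (envl == "exponential") {
      sum(30 * exp(-sm$distance[support] / 300))
    } else {
      sum(30 * (sm$distance[support] < 300))
    }
    expect_lt(abs(sum(sm$enrichment) - expected) / expected, 0.005)
    ## patchy redistribution also preserves each distance bin's mass
    bin <- floor(sm$distance / 20)
    got <- rowsum(sm$enrichment[support], bin[support])
    ref <- rowsum(if (envl == "exponential") 30 * exp(-sm$distance[support] / 300)
                  else 30 * (sm$distance[support] < 300), bin[support])
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("step-envelope ground truth is recovered by the profiling pipeline", {
  sm <- generate_map(map_recipe("loam", size_px = 301, envelope = "step",
                                extent_um = 500, texture_cv = 0,
                                noise = FALSE, seed = 8))
  prof <- radial_profile(sm$map, sm$distance, sm$pore, max_distance = 2500)
  ex <- extent_estimate(prof, bulk_stats(prof), "accumulation")
  expect_lt(abs(ex$extent_um - 500), 20 + 1e-9)  # within one bin
})

test_that("Poisson noise gives per-pixel variance equal to the mean", {
  ## fixed geometry (no pores, no texture) so the only seed-to-seed
  ## variation is the counting noise itself
  base <- function(seed) map_recipe("loam", size_px = 41, root_radius_um = 100,
                                    pore_fraction = 1e-9, texture_cv = 0,
                                    patchiness = 0, extent_um = 150,
                                    amplitude = 40, seed = seed)
  lam <- generate_map(modifyList(base(1), list(noise = FALSE)))$map
  pix <- which(!generate_map(base(1))$root)[seq(1, 1500, by = 75)]
  reps <- vapply(1:200, function(s) generate_map(base(s))$map[pix],
                 numeric(length(pix)))
  ratio <- apply(reps, 1, var) / lam[pix]
  expect_equal(mean(ratio), 1, tolerance = 0.1)
  ## counts are non-negative integers
  expect_true(all(reps >= 0) && all(reps == round(reps)))
})

test_that("sand porosity profile undulates with the grain diameter period", {
  sm <- generate_map(map_recipe("sand", size_px = 301, amplitude = 0,
                                noise = FALSE, seed = 11))
  ones <- matrix(1, 301, 301)
  all_px <- radial_profile(ones, sm$distance, NULL, 20)
  np <- radial_profile(ones, sm$distance, sm$pore, 20)
  nb <- 75
  frac <- np$n[1:nb] / pmax(all_px$n[1:nb], 1)
  z <- frac - mean(frac)
  ac <- stats::acf(z, lag.max = 20, plot = FALSE)$acf[-1]
  peak <- which(diff(sign(diff(ac))) == -2)[1] + 1
  ## grain diameter is 200 um = 10 bins; allow +-40%
  expect_true(peak >= 6 && peak <= 14)
  expect_gt(ac[peak], 0.3)
})

test_that("profile fixtures validate their inputs and reproduce seeds", {
  f1 <- generate_profile_fixture(10, weights = 2, values = NULL, seed = 5)
  f2 <- generate_profile_fixture(10, weights = 2, values = NULL, seed = 5)
  expect_identical(f1, f2)
  expect_error(generate_profile_fixture(10, values = 1:3), "length")
  fc <- generate_profile_fixture(5, weights = 1, values = rep(3, 5))
  expect_equal(fc$sd, rep(0, 5))
})
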