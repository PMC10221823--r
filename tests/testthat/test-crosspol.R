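test_that("Malus leakage through imperfect crossing", {
  expect_equal(malus_leakage(0), 0)
  expect_equal(malus_leakage(45), 0.5)
  expect_equal(malus_leakage(5), sin(5 * pi / 180)^2)
  expect_error(malus_leakage(90), "< 90")
  # strictly increasing on [0, 90)
  deltas <- seq(0, 85, by = 5)
  expect_true(all(diff(malus_leakage(deltas)) > 0))
})

test_that("ideal crossed polarisers pass exactly half the diffuse light", {
  set.seed(8)
  D <- matrix(runif(64, 0.2, 0.8), 8, 8)
  S <- matrix(runif(64, 0, 2), 8, 8)
  ideal <- polariser_spec(contrast_ratio = Inf, transmission = 1,
                          misalignment_deg = 0)
  expect_equal(crosspol_acquire(D, S, ideal), D / 2)
  # energy ordering: the polarised acquisition never exceeds the
  # unpolarised scene, pixelwise
  pol <- polariser_spec()
  unpol <- pmin(D + S, 1)
  expect_true(all(crosspol_acquire(D, S, pol) <= unpol + 1e-12))
  expect_error(crosspol_acquire(D - 1, S, pol), "non-negative")
})

test_that("residual hotspot visibility follows the closed-form ratio", {
  pol <- polariser_spec(contrast_ratio = 1500, transmission = 1)
  expect_equal(residual_hotspot_ratio(1, 1, pol), 2 / 1500)
  expect_equal(residual_hotspot_ratio(10, 1, pol), 10 / 1500 / 0.5)
  expect_equal(residual_hotspot_ratio(200, 1, pol), 200 / 1500 / 0.5)
  # a glint 200x the diffuse level is visible at the 0.1 Weber
  # threshold even through CR 1500; 10x is not
  expect_gt(residual_hotspot_ratio(200, 1, pol), 0.1)
  expect_lt(residual_hotspot_ratio(10, 1, pol), 0.1)
  # strictly increasing in misalignment
  ratios <- vapply(seq(0, 80, by = 10), function(d)
    residual_hotspot_ratio(10, 1, polariser_spec(misalignment_deg = d)), 0)
  expect_true(all(diff(ratios) > 0))
  expect_error(residual_hotspot_ratio(1, 0, pol), "positive")
})

test_that("scalar hotspot predictor matches the per-pixel acquisition on uniform scenes", {
  pol <- polariser_spec(contrast_ratio = 1500, transmission = 0.9,
                        misalignment_deg = 2)
  for (s_over_d in c(1, 10, 200)) {
    D <- matrix(0.4, 6, 6)
    S <- s_over_d * D
    img <- pol$transmission^2 * (D / 2 +
      S * (1 / pol$contrast_ratio + malus_leakage(2)))  # unclipped model
    measured <- (img - pol$transmission^2 * D / 2) /
      (pol$transmission^2 * D / 2)
    expect_lt(max(abs(measured -
                        residual_hotspot_ratio(S, D, pol))), 1e-12)
    # and the package's clipped acquisition agrees wherever unclipped
    acq <- crosspol_acquire(D, S, pol)
    unclipped <- img <= 1
    expect_lt(max(abs(acq[unclipped] - img[unclipped])), 1e-12)
  }
})

test_that("misalignment adds the sin^2 term per pixel via the angle map", {
  D <- matrix(0.5, 4, 4)
  S <- matrix(1, 4, 4)
  amap <- matrix(2, 4, 4)
  p0 <- polariser_spec(contrast_ratio = 1500, transmission = 1)
  p2 <- polariser_spec(contrast_ratio = 1500, transmission = 1,
                       angle_map = amap)
  gain <- crosspol_acquire(D, S, p2) - crosspol_acquire(D, S, p0)
  expect_equal(gain, S * sin(2 * pi / 180)^2, tolerance = 1e-12)
})

test_that("method comparison ranks raw, multi-flash and cross-pol as expected", {
  sc <- scene_spec(grid_size = 96, rng_seed = 12L)
  cmp <- compare_methods(sc)
  m <- cmp$metrics
  expect_gt(m$saturated_fraction[m$method == "single_flash"], 0)
  expect_equal(m$saturated_fraction[m$method == "multiflash"], 0)
  expect_equal(m$saturated_fraction[m$method == "crosspol"], 0)
  # with nothing to remove, all three methods sit near the truth
  sc0 <- quiet_scene(grid = 96, specular_strength = 0)
  m0 <- compare_methods(sc0)$metrics
  expect_true(all(m0$saturated_fraction == 0))
  expect_true(all(m0$rmse_vs_truth < 0.05))
  # cross-pol mean is about half the unpolarised diffuse mean at T = 1
  comps <- render_crosspol_components(sc0)
  xp <- crosspol_acquire(comps$diffuse, comps$specular,
                         polariser_spec(transmission = 1))
  expect_equal(mean(xp), mean(comps$diffuse) / 2, tolerance = 1e-12)
})
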