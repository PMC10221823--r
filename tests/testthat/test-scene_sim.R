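test_that("illumination field peaks under the fibre and follows the cos^4/r^2 law", {
  sc <- quiet_scene(grid = 100, fibre_offsets = rbind(c(2.4, 0)))
  fld <- illumination_field(sc, 1)
  # independent oracle: evaluate cos^4(theta) * (h/r)^2 at every pixel
  # centre with the documented coordinate convention
  pitch <- sc$field_width / sc$grid_size
  u <- (seq_len(sc$grid_size) - 0.5) * pitch - sc$field_width / 2
  h <- sc$probe_height
  expected <- outer(u, u, function(y, x) {
    r2 <- h^2 + (x - 2.4)^2 + y^2
    (h / sqrt(r2))^4 * (h^2 / r2)  # cos^4(theta) * (h/r)^2, cos = h/r
  })
  expected <- expected / max(expected)
  expect_equal(fld, expected, tolerance = 1e-12)
  # maximum at the pixel nearest the fibre foot
  peak <- which(fld == max(fld), arr.ind = TRUE)
  expect_lt(abs(u[peak[1, 2]] - 2.4), pitch)
  expect_lt(abs(u[peak[1, 1]] - 0), pitch)
  # mirror symmetry about the plane containing the fibre axis (y -> -y)
  expect_equal(fld, fld[rev(seq_len(nrow(fld))), ])
  expect_error(illumination_field(sc, 2), "out of range")
})

test_that("glints sit at the camera-fibre midpoint and form a 1.2 mm half-diagonal square", {
  sc <- quiet_scene()
  expect_equal(specular_center(quiet_scene(fibre_offsets = rbind(c(0, 0))), 1),
               c(0, 0))
  expect_equal(specular_center(sc, 1), c(1.2, 0))
  centers <- t(vapply(1:4, function(i) specular_center(sc, i), numeric(2)))
  expect_equal(sqrt(rowSums(centers^2)), rep(1.2, 4))
  # consecutive glints are a quarter turn apart
  expect_equal(centers[2, ], c(0, 1.2))
  # glint shift equals half the fibre offset difference, for every pair
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(centers[i, ] - centers[j, ],
                 (sc$fibre_offsets[i, ] - sc$fibre_offsets[j, ]) / 2)
})

test_that("diffuse render imprints depth-attenuated, blurred feature contrast", {
  # zero depth, zero blur: contrast is exactly base_contrast
  sc0 <- quiet_scene(layer_thickness_mm = 0)
  d0 <- render_diffuse(sc0)
  ann <- feature_annulus_mask(sc0)
  expect_equal(weber_contrast(d0$image, d0$feature_mask, ann), 1.4)
  # mu_eff = 1 /mm at 1 mm depth: multiplier exp(-2), checked unblurred
  sc1 <- quiet_scene(layer_thickness_mm = 1, mu_eff_per_mm = 1,
                     blur_sigma_per_mm = 0)
  d1 <- render_diffuse(sc1)
  expect_equal(weber_contrast(d1$image, d1$feature_mask, ann),
               1.4 * exp(-2), tolerance = 1e-12)
  # strictly decreasing contrast with depth at fixed mu_eff > 0
  ctr <- vapply(c(0, 0.5, 1, 2), function(d) {
    sc <- quiet_scene(layer_thickness_mm = d)
    di <- render_diffuse(sc)
    weber_contrast(di$image, di$feature_mask, feature_annulus_mask(sc))
  }, 0)
  expect_true(all(diff(ctr) < 0))
  # feature outside the field is rejected
  expect_error(quiet_scene(features = list(list(center = c(7, 0),
                                                diameter = 1,
                                                base_contrast = 1))),
               "outside")
})

test_that("flash stacks are deterministic and reduce to diffuse x illumination without glints", {
  sc <- scene_spec(grid_size = 64, noise_sigma = 0.01, rng_seed = 7L)
  s1 <- render_flash_stack(sc)
  s2 <- render_flash_stack(sc)
  expect_identical(s1$images, s2$images)
  # no glint, no noise: image i is exactly diffuse * illumination_i
  sc0 <- quiet_scene(grid = 64, specular_strength = 0)
  st <- render_flash_stack(sc0)
  dif <- render_diffuse(sc0)
  for (i in 1:4)
    expect_equal(st$images[[i]],
                 pmin(dif$image * illumination_field(sc0, i), 1),
                 tolerance = 1e-14)
})

test_that("the four glints saturate pairwise disjoint pixel sets", {
  st <- render_flash_stack(scene_spec(grid_size = 128))
  masks <- lapply(st$images, function(im) saturation_mask(im, 0.98, 1)$mask)
  for (m in masks) expect_gt(sum(m), 0)
  for (i in 1:3) for (j in (i + 1):4)
    expect_identical(sum(masks[[i]] & masks[[j]]), 0L)
})

test_that("cross-pol components separate diffuse shading from the four glint lobes", {
  sc <- quiet_scene(grid = 128)
  comps <- render_crosspol_components(sc)
  expect_equal(count_local_maxima(comps$specular), 4)
  expect_true(all(comps$diffuse <= 1))
  sc0 <- quiet_scene(grid = 64, specular_strength = 0)
  expect_true(all(render_crosspol_components(sc0)$specular == 0))
})

test_that("quantisation maps renders onto the stated bit-depth grid", {
  sc <- scene_spec(grid_size = 32, bit_depth = 8, noise_sigma = 0.01)
  st <- render_flash_stack(sc)
  for (im in st$images)
    expect_equal(im, round(im * 255) / 255, tolerance = 1e-15)
})
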