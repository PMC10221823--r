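test_that("forward gradients follow the stated difference convention", {
  const <- matrix(0.3, 6, 7)
  g <- forward_gradients(const)
  expect_true(all(g$gx == 0) && all(g$gy == 0))
  ramp <- matrix(rep(seq_len(7), each = 6), 6, 7)  # I[r, c] = c
  gr <- forward_gradients(ramp)
  expect_equal(gr$gx[, 1:6], matrix(1, 6, 6))
  expect_true(all(gr$gx[, 7] == 0) && all(gr$gy == 0))
  expect_error(forward_gradients(array(0, c(2, 2, 2))), "2-D")
  expect_error(forward_gradients(matrix(c(1, NA, 1, 1), 2)), "finite")
})

test_that("divergence(gradient) reproduces the 5-point Laplacian in the interior", {
  for (seed in 0:2) {
    set.seed(seed)
    n <- sample(5:16, 1)
    I <- matrix(runif(n * n), n, n)
    div <- divergence(forward_gradients(I))
    L <- laplacian_stencil(I)
    expect_equal(div[2:(n - 1), 2:(n - 1)], L[2:(n - 1), 2:(n - 1)],
                 tolerance = 1e-14)
  }
})

test_that("total divergence of a forward-gradient field telescopes to zero", {
  set.seed(4)
  I <- matrix(runif(16), 4, 4)
  expect_lt(abs(sum(divergence(forward_gradients(I)))), 1e-12)
})

test_that("saturation mask thresholds then dilates with a square element", {
  expect_false(any(saturation_mask(matrix(0.5, 8, 8), 0.98, 1)$mask))
  img <- matrix(0, 9, 9); img[5, 5] <- 1
  m <- saturation_mask(img, 0.98, 1)$mask
  expect_equal(sum(m), 9)
  expect_true(all(m[4:6, 4:6]))
  # clipped at the border
  img2 <- matrix(0, 9, 9); img2[1, 1] <- 1
  expect_equal(sum(saturation_mask(img2, 0.98, 1)$mask), 4)
  expect_error(saturation_mask(img, threshold = 0), "threshold")
})

test_that("median composite rejects a single outlying flash", {
  mk <- function(v) structure(list(gx = matrix(v, 1, 1),
                                   gy = matrix(v, 1, 1)),
                              class = "gradient_field")
  same <- median_gradient_composite(list(mk(2), mk(2), mk(2), mk(2)))
  expect_equal(same$gx[1, 1], 2)
  outl <- median_gradient_composite(list(mk(0), mk(0), mk(0), mk(10)))
  expect_equal(outl$gx[1, 1], 0)
  four <- median_gradient_composite(list(mk(1), mk(2), mk(3), mk(10)))
  expect_equal(four$gx[1, 1], 2.5)  # even count: mean of middle pair
  expect_error(median_gradient_composite(list(mk(1))), "at least 2")
})

test_that("masked flashes drop out of the composite; fully masked pixels emit zero", {
  set.seed(1)
  fields <- lapply(1:4, function(i) forward_gradients(matrix(runif(36), 6)))
  mask_none <- structure(list(mask = matrix(FALSE, 6, 6)),
                         class = "saturation_mask")
  mask_all <- structure(list(mask = matrix(TRUE, 6, 6)),
                        class = "saturation_mask")
  # masking three of four leaves the remaining field exactly
  comp <- median_gradient_composite(fields,
                                    list(mask_none, mask_all, mask_all,
                                         mask_all))
  expect_identical(comp$gx, fields[[1]]$gx)
  expect_identical(comp$gy, fields[[1]]$gy)
  # all masked -> zero gradient for harmonic infill
  comp0 <- median_gradient_composite(fields, rep(list(mask_all), 4))
  expect_true(all(comp0$gx == 0) && all(comp0$gy == 0))
})

test_that("composite equals the clean gradient wherever at most one flash is perturbed", {
  set.seed(2)
  clean <- matrix(runif(400), 20, 20)
  imgs <- rep(list(clean), 4)
  # disjoint block perturbations, one per flash, separated by > 1 px so
  # the perturbed forward-difference supports never overlap
  blocks <- list(2:4, 7:9, 12:14, 17:19)
  for (i in 1:4)
    imgs[[i]][blocks[[i]], blocks[[i]]] <-
      imgs[[i]][blocks[[i]], blocks[[i]]] + 5
  comp <- median_gradient_composite(lapply(imgs, forward_gradients))
  ref <- forward_gradients(clean)
  expect_identical(comp$gx, ref$gx)
  expect_identical(comp$gy, ref$gy)
})

test_that("min-magnitude composite keeps the smallest-magnitude unmasked value", {
  mk <- function(v) structure(list(gx = matrix(v, 1, 1),
                                   gy = matrix(v, 1, 1)),
                              class = "gradient_field")
  out <- median_gradient_composite(list(mk(3), mk(-1), mk(2), mk(5)),
                                   rule = "min_magnitude")
  expect_equal(out$gx[1, 1], -1)
})
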