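# small scenes used across tests; noise off unless a test needs it
quiet_scene <- function(grid = 96, ...) {
  scene_spec(grid_size = grid, noise_sigma = 0, ...)
}

# 5-point Laplacian by direct stencil, zero-padded outside: the oracle
# for the gradient/divergence adjoint pair
laplacian_stencil <- function(I) {
  m <- nrow(I); n <- ncol(I)
  L <- matrix(0, m, n)
  for (r in 2:(m - 1))
    for (c in 2:(n - 1))
      L[r, c] <- I[r - 1, c] + I[r + 1, c] + I[r, c - 1] + I[r, c + 1] -
        4 * I[r, c]
  L
}

# count local maxima above a floor: pixels not exceeded by any
# 8-neighbour, merged into connected plateau components (symmetric scenes
# put a peak exactly between two pixel centres)
count_local_maxima <- function(img, floor = 0.5 * max(img)) {
  m <- nrow(img); n <- ncol(img)
  peak <- matrix(FALSE, m, n)
  for (r in 2:(m - 1)) for (c in 2:(n - 1)) {
    v <- img[r, c]
    if (v < floor) next
    nb <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (v >= max(nb)) peak[r, c] <- TRUE
  }
  max(EBImage::bwlabel(peak * 1))
}
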