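#' Forward finite-difference gradients of an image
#'
#' Forward differences with replicate edge handling:
#' `gx[r, c] = I[r, c+1] - I[r, c]` (zero in the last column) and
#' `gy[r, c] = I[r+1, c] - I[r, c]` (zero in the last row). This
#' convention is the exact adjoint partner of [divergence()]: composing
#' the two reproduces the 5-point Laplacian in the image interior, which
#' is what the Poisson solver inverts.
#'
#' @param image numeric matrix with finite values.
#' @return an object of class `gradient_field` with components `gx`, `gy`.
#' @export
forward_gradients <- function(image) {
  if (length(dim(image)) != 2) stop("image must be a 2-D matrix")
  if (!all(is.finite(image))) stop("image must contain finite values")
  m <- nrow(image); n <- ncol(image)
  gx <- cbind(image[, -1, drop = FALSE] - image[, -n, drop = FALSE], 0)
  gy <- rbind(image[-1, , drop = FALSE] - image[-m, , drop = FALSE], 0)
  structure(list(gx = gx, gy = gy), class = "gradient_field")
}

#' Backward-difference divergence of a gradient field
#'
#' `div[r, c] = gx[r, c] - gx[r, c-1] + gy[r, c] - gy[r-1, c]`, with
#' out-of-range terms treated as zero — the negative adjoint of
#' [forward_gradients()], so `divergence(forward_gradients(I))` equals
#' the standard 5-point Laplacian of `I` at every interior pixel.
#'
#' @param g a `gradient_field`.
#' @return numeric matrix of the same shape.
#' @export
divergence <- function(g) {
  gx <- g$gx; gy <- g$gy
  if (!identical(dim(gx), dim(gy))) stop("gx and gy shapes differ")
  m <- nrow(gx); n <- ncol(gx)
  dx <- gx - cbind(0, gx[, -n, drop = FALSE])
  dy <- gy - rbind(0, gy[-m, , drop = FALSE])
  dx + dy
}

#' @export
print.gradient_field <- function(x, ...) {
  cat("Gradient field:", nrow(x$gx), "x", ncol(x$gx),
      "(forward differences, replicate edge)\n")
  invisible(x)
}

#' Saturated-pixel mask of one flash image
#'
#' Marks pixels at or above `threshold` as unreliable — on a glossy
#' surface these are the clipped specular glints, where the recorded
#' gradient no longer reflects the scene — and grows the marked region by
#' `dilation` pixels with a square structuring element so that the
#' glint's clipped shoulder is excluded too.
#'
#' @param image unit-range numeric matrix.
#' @param threshold saturation level in `(0, 1]`.
#' @param dilation dilation radius in pixels (0 disables).
#' @return an object of class `saturation_mask` with logical `mask`
#'   (`TRUE` = unreliable) plus the parameters used.
#' @export
saturation_mask <- function(image, threshold = 0.98, dilation = 1) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  mask <- image >= threshold
  if (dilation > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2 * dilation + 1, shape = "box")
    mask <- EBImage::dilate(mask * 1, brush) > 0
    mask <- matrix(as.logical(mask), nrow(image), ncol(image))
  }
  structure(list(mask = mask, threshold = threshold, dilation = dilation),
            class = "saturation_mask")
}

#' Per-pixel robust composite of flash gradients
#'
#' The core of the multi-flash method: because the glints shift with the
#' active fibre, a pixel is corrupted in at most a minority of flashes,
#' so the per-pixel, per-component median across the flashes whose
#' saturation mask is clear recovers the clean diffuse gradient. With an
#' even number of contributing flashes the mean of the two middle values
#' is used; where every flash is masked the composite emits a zero
#' gradient, so the Poisson integration fills the hole harmonically.
#'
#' @param fields list of >= 2 `gradient_field`s of equal shape.
#' @param masks optional list of [saturation_mask()]s, one per field;
#'   `NULL` means no masking.
#' @param rule `"median"` (default) or `"min_magnitude"`, which instead
#'   keeps, per pixel and component, the unmasked value of smallest
#'   absolute magnitude.
#' @return a composite `gradient_field`.
#' @export
median_gradient_composite <- function(fields, masks = NULL,
                                      rule = c("median", "min_magnitude")) {
  rule <- match.arg(rule)
  if (length(fields) < 2) stop("need at least 2 gradient fields")
  dims <- lapply(fields, function(f) dim(f$gx))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("gradient fields have mismatched shapes")
  if (!is.null(masks) && length(masks) != length(fields))
    stop("need one mask per gradient field")
  d <- dims[[1]]
  M <- if (is.null(masks)) {
    matrix(FALSE, prod(d), length(fields))
  } else {
    for (m in masks)
      if (!identical(dim(m$mask), d)) stop("mask shape mismatch")
    matrix(vapply(masks, function(m) as.vector(m$mask),
                  logical(prod(d))),
           nrow = prod(d))
  }
  comp <- function(get) {
    V <- matrix(vapply(fields, function(f) as.vector(get(f)),
                       numeric(prod(d))),
                nrow = prod(d))
    v <- if (rule == "median") masked_row_median(V, M)
         else masked_row_minmag(V, M)
    matrix(v, d[1], d[2])
  }
  structure(list(gx = comp(function(f) f$gx),
                 gy = comp(function(f) f$gy)),
            class = "gradient_field")
}

# row-wise median of V (P x N) over entries where M is FALSE; 0 where all
# entries of a row are masked. Vectorised insertion sort (N is small).
masked_row_median <- function(V, M) {
  V[M] <- Inf
  N <- ncol(V)
  for (i in seq_len(N)[-1]) {
    for (k in seq(i, 2)) {
      a <- pmin(V[, k - 1], V[, k])
      b <- pmax(V[, k - 1], V[, k])
      V[, k - 1] <- a
      V[, k] <- b
    }
  }
  k <- rowSums(!M)
  lo <- pmax((k + 1) %/% 2, 1L)
  hi <- pmax(k %/% 2 + 1L, 1L)
  idx <- seq_len(nrow(V))
  out <- (V[cbind(idx, lo)] + V[cbind(idx, hi)]) / 2
  out[k == 0] <- 0
  out
}

# row-wise min-|value| of V over unmasked entries; 0 where all masked
masked_row_minmag <- function(V, M) {
  A <- abs(V)
  A[M] <- Inf
  j <- max.col(-A, ties.method = "first")
  out <- V[cbind(seq_len(nrow(V)), j)]
  out[rowSums(!M) == 0] <- 0
  out
}
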