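#' Fraction of saturated pixels
#'
#' @param image numeric matrix or array in unit range.
#' @param threshold saturation level; pixels at or above it count.
#' @return fraction in `[0, 1]`.
#' @export
saturated_fraction <- function(image, threshold = 0.98) {
  if (length(image) == 0) stop("empty image")
  mean(image >= threshold)
}

#' Weber contrast of a feature against its background annulus
#'
#' `(mean over feature - mean over annulus) / mean over annulus`, the
#' detectability metric for a sub-surface feature against the local
#' background.
#'
#' @param image numeric matrix.
#' @param feature_mask logical matrix marking feature pixels.
#' @param annulus_mask logical matrix marking the background ring;
#'   must be disjoint from `feature_mask` and non-empty.
#' @return Weber contrast (can be negative for dark features).
#' @export
weber_contrast <- function(image, feature_mask, annulus_mask) {
  if (!any(feature_mask) || !any(annulus_mask))
    stop("feature and annulus masks must be non-empty")
  if (any(feature_mask & annulus_mask))
    stop("feature and annulus masks must be disjoint")
  mf <- mean(image[feature_mask])
  ma <- mean(image[annulus_mask])
  (mf - ma) / ma
}

#' Background annulus around a scene feature
#'
#' Ring between `inner` and `outer` feature radii from the feature
#' centre, with any other feature footprint excluded — the local
#' background [weber_contrast()] is measured against.
#'
#' @param scene a [scene_spec()].
#' @param feature_index which feature.
#' @param inner,outer annulus radii as multiples of the feature radius.
#' @return logical matrix.
#' @export
feature_annulus_mask <- function(scene, feature_index = 1,
                                 inner = 2, outer = 4) {
  validate_scene_spec(scene)
  ax <- pixel_axes(scene)
  n <- scene$grid_size
  f <- scene$features[[feature_index]]
  r <- f$diameter / 2
  dx2 <- outer(rep(1, n), (ax$x - f$center[1])^2)
  dy2 <- outer((ax$y - f$center[2])^2, rep(1, n))
  rho2 <- dx2 + dy2
  ring <- rho2 >= (inner * r)^2 & rho2 <= (outer * r)^2
  for (g in scene$features) {
    gx2 <- outer(rep(1, n), (ax$x - g$center[1])^2)
    gy2 <- outer((ax$y - g$center[2])^2, rep(1, n))
    ring <- ring & (gx2 + gy2) > (g$diameter / 2)^2
  }
  ring
}

#' RMSE against a ground-truth image after photometric matching
#'
#' Root-mean-square error between `image` and `truth` after an optional
#' least-squares affine fit `a * image + b` to the truth. Acquisition
#' methods differ in absolute gain and offset (a cross-polarised image
#' carries `T^2/2`, a normalised reconstruction is unit-max), so
#' comparing them in a common photometric frame is what makes the RMSE
#' meaningful; set `fit = "none"` for the raw difference.
#'
#' @param image,truth numeric matrices of equal shape.
#' @param fit `"affine"` (default) or `"none"`.
#' @return RMSE on the truth's intensity scale.
#' @export
rmse_vs_truth <- function(image, truth, fit = c("affine", "none")) {
  fit <- match.arg(fit)
  if (!identical(dim(image), dim(truth))) stop("shape mismatch")
  x <- as.vector(image); y <- as.vector(truth)
  if (fit == "affine") {
    vx <- stats::var(x)
    a <- if (vx > 0) stats::cov(x, y) / vx else 0
    b <- mean(y) - a * mean(x)
    x <- a * x + b
  }
  sqrt(mean((x - y)^2))
}

#' Feature contrast across burial depths and illumination wavelengths
#'
#' Renders and reconstructs the scene over a grid of top-layer
#' thicknesses and wavelengths, measuring the first feature's Weber
#' contrast for the multi-flash reconstruction and/or the
#' cross-polarised acquisition. Longer wavelengths see smaller effective
#' attenuation, so the table shows contrast falling with depth and
#' rising with wavelength — the resolvability map of the probe. All
#' cells share the scene's noise seed (common random numbers), so
#' differences between cells are systematic rather than sampling noise.
#'
#' @param scene template [scene_spec()]; its depth, wavelength and
#'   attenuation fields are overridden per cell (attenuation from
#'   [default_mu_eff()] unless `mu_eff` is supplied).
#' @param depths top-layer thicknesses in mm.
#' @param wavelengths illumination wavelengths in nm.
#' @param settings a [recon_settings()].
#' @param pol a [polariser_spec()].
#' @param methods subset of `c("multiflash", "crosspol")`.
#' @param mu_eff optional vector of attenuation coefficients (1/mm),
#'   parallel to `wavelengths`.
#' @param out optional path to write the table as CSV.
#' @return data.frame with columns `depth_mm`, `wavelength_nm`,
#'   `mu_eff_per_mm`, `method`, `contrast`.
#' @export
depth_wavelength_table <- function(scene,
                                   depths = c(0, 0.5, 1.0, 2.0),
                                   wavelengths = c(450, 540, 660, 850, 940),
                                   settings = recon_settings(),
                                   pol = polariser_spec(),
                                   methods = c("multiflash", "crosspol"),
                                   mu_eff = NULL,
                                   out = NULL) {
  validate_scene_spec(scene)
  if (length(depths) == 0 || length(wavelengths) == 0)
    stop("depths and wavelengths must be non-empty")
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(mu_eff)) mu_eff <- default_mu_eff(wavelengths)
  rows <- list()
  for (di in seq_along(depths)) {
    for (wi in seq_along(wavelengths)) {
      sc <- scene
      sc$layer_thickness_mm <- depths[di]
      sc$wavelength_nm <- wavelengths[wi]
      sc$mu_eff_per_mm <- mu_eff[wi]
      amask <- feature_annulus_mask(sc)
      for (method in methods) {
        if (method == "multiflash") {
          stack <- render_flash_stack(sc)
          rec <- remove_specular_multiflash(stack, settings)
          ctr <- weber_contrast(rec$image, stack$feature_mask, amask)
        } else {
          comps <- render_crosspol_components(sc)
          xp <- crosspol_acquire(comps$diffuse, comps$specular, pol)
          illum <- comps$diffuse / pmax(comps$ground_truth_diffuse, 1e-6)
          ctr <- weber_contrast(xp / pmax(illum, 1e-3),
                                comps$feature_mask, amask)
        }
        rows[[length(rows) + 1]] <- data.frame(
          depth_mm = depths[di], wavelength_nm = wavelengths[wi],
          mu_eff_per_mm = mu_eff[wi], method = method, contrast = ctr)
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}
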