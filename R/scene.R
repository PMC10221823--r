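#' Effective attenuation defaults per illumination wavelength
#'
#' Lumped effective attenuation coefficients (1/mm) used by the synthetic
#' phantom renderer when a scene does not set `mu_eff_per_mm` explicitly.
#' The table is strictly decreasing in wavelength, so longer wavelengths
#' penetrate deeper — the qualitative behaviour of diffuse light transport
#' in tissue in the visible-to-NIR range. The magnitudes are plausible
#' placeholders, not measured phantom coefficients, and every scene can
#' override them.
#'
#' @param wavelength_nm illumination wavelength in nanometres.
#' @return effective attenuation coefficient in 1/mm; wavelengths between
#'   table entries are linearly interpolated, beyond the table clamped.
#' @export
#' @examples
#' default_mu_eff(660)
#' default_mu_eff(c(450, 940))
default_mu_eff <- function(wavelength_nm) {
  tab_wl <- c(450, 540, 660, 850, 940)
  tab_mu <- c(2.0, 1.5, 1.0, 0.55, 0.45)
  stats::approx(tab_wl, tab_mu, xout = wavelength_nm, rule = 2)$y
}

#' Synthetic probe-and-phantom scene description
#'
#' Describes one synthetic acquisition scene: a downward-looking camera on
#' the central axis at `probe_height` mm above a flat glossy surface,
#' illumination fibres at lateral offsets `fibre_offsets` (default: four
#' fibres concentric around the camera at 2.4 mm radius), a layered
#' tissue-mimicking phantom with circular sub-surface features buried under
#' `layer_thickness_mm` of overlying material, and a Phong-type specular
#' glint model. The rendered field spans `field_width` mm on a square
#' `grid_size` pixel grid; the physical origin is the field centre, x
#' increases rightward (columns), y downward (rows), pixel centres at
#' half-integer offsets.
#'
#' Feature visibility decays with burial depth as
#' `base_contrast * exp(-2 * mu_eff_per_mm * layer_thickness_mm)`
#' (round-trip attenuation), and feature edges blur with depth with
#' Gaussian sigma `blur_sigma_per_mm * layer_thickness_mm` (mm).
#'
#' @param grid_size pixels per side (>= 16).
#' @param field_width imaged field width in mm.
#' @param probe_height camera height above the surface in mm.
#' @param fibre_offsets n x 2 matrix of lateral fibre positions in mm.
#' @param wavelength_nm illumination wavelength (nm).
#' @param layer_thickness_mm thickness of the top layer covering the
#'   features (mm).
#' @param features list of features, each a list with `center` (mm, length
#'   2), `diameter` (mm) and `base_contrast` (Weber contrast at zero depth).
#' @param background_albedo diffuse background level of the bare phantom
#'   surface, in unit range.
#' @param mu_eff_per_mm effective attenuation coefficient (1/mm); default
#'   looked up from [default_mu_eff()] at `wavelength_nm`.
#' @param blur_sigma_per_mm growth of the feature edge blur with depth
#'   (mm of Gaussian sigma per mm of depth).
#' @param specular_strength peak specular amplitude relative to full
#'   scale; values >= 1 saturate the sensor at the glint.
#' @param specular_exponent Phong-type lobe sharpness; the rendered lobe is
#'   `exp(-(rho/sigma_s)^2)` with
#'   `sigma_s = probe_height * sqrt(2 / specular_exponent)`.
#' @param noise_sigma additive Gaussian sensor noise sigma (unit range),
#'   applied before clipping.
#' @param rng_seed integer seed; identical scenes render bit-identically.
#' @param bit_depth `"none"` for float output, or 8 or 16 to quantise
#'   rendered images to that bit depth (then mapped back to unit range).
#' @return an object of class `scene_spec`.
#' @seealso [render_flash_stack()], [render_diffuse()],
#'   [render_crosspol_components()]
#' @export
#' @examples
#' sc <- scene_spec(grid_size = 64, layer_thickness_mm = 0.5,
#'                  wavelength_nm = 850)
#' sc
scene_spec <- function(grid_size = 256,
                       field_width = 10.0,
                       probe_height = 8.0,
                       fibre_offsets = default_fibre_offsets(),
                       wavelength_nm = 660,
                       layer_thickness_mm = 0,
                       features = list(list(center = c(0, 0),
                                            diameter = 1.0,
                                            base_contrast = 1.4)),
                       background_albedo = 0.375,
                       mu_eff_per_mm = NULL,
                       blur_sigma_per_mm = 0.1,
                       specular_strength = 2.0,
                       specular_exponent = 800,
                       noise_sigma = 0.005,
                       rng_seed = 1L,
                       bit_depth = "none") {
  fibre_offsets <- as.matrix(fibre_offsets)
  if (is.null(mu_eff_per_mm)) mu_eff_per_mm <- default_mu_eff(wavelength_nm)
  sc <- structure(list(
    grid_size = as.integer(grid_size),
    field_width = field_width,
    probe_height = probe_height,
    fibre_offsets = fibre_offsets,
    wavelength_nm = wavelength_nm,
    layer_thickness_mm = layer_thickness_mm,
    features = features,
    background_albedo = background_albedo,
    mu_eff_per_mm = mu_eff_per_mm,
    blur_sigma_per_mm = blur_sigma_per_mm,
    specular_strength = specular_strength,
    specular_exponent = specular_exponent,
    noise_sigma = noise_sigma,
    rng_seed = as.integer(rng_seed),
    bit_depth = bit_depth
  ), class = "scene_spec")
  validate_scene_spec(sc)
  sc
}

#' @rdname scene_spec
#' @export
default_fibre_offsets <- function() {
  rbind(c(2.4, 0), c(0, 2.4), c(-2.4, 0), c(0, -2.4))
}

validate_scene_spec <- function(sc) {
  stopifnot(inherits(sc, "scene_spec"))
  if (sc$grid_size < 16) stop("grid_size must be >= 16")
  if (sc$field_width <= 0) stop("field_width must be positive")
  if (sc$probe_height <= 0) stop("probe_height must be positive")
  if (sc$layer_thickness_mm < 0) stop("layer_thickness_mm must be >= 0")
  if (sc$mu_eff_per_mm < 0) stop("mu_eff_per_mm must be >= 0")
  if (sc$specular_strength < 0) stop("specular_strength must be >= 0")
  if (ncol(sc$fibre_offsets) != 2) stop("fibre_offsets must be n x 2 (mm)")
  if (!(identical(sc$bit_depth, "none") || sc$bit_depth %in% c(8, 16)))
    stop("bit_depth must be \"none\", 8 or 16")
  half <- sc$field_width / 2
  for (f in sc$features) {
    if (f$diameter <= 0) stop("feature diameter must be positive")
    if (any(abs(f$center) > half))
      stop("feature center lies outside the imaged field")
  }
  invisible(sc)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("Synthetic probe scene:", x$grid_size, "x", x$grid_size, "px,",
      x$field_width, "mm field\n")
  cat("  camera height", x$probe_height, "mm,", nrow(x$fibre_offsets),
      "fibres at radius", signif(max(sqrt(rowSums(x$fibre_offsets^2))), 3),
      "mm\n")
  cat("  wavelength", x$wavelength_nm, "nm (mu_eff",
      signif(x$mu_eff_per_mm, 3), "/mm), layer",
      x$layer_thickness_mm, "mm,", length(x$features), "feature(s)\n")
  cat("  specular strength", x$specular_strength, ", noise sigma",
      x$noise_sigma, ", seed", x$rng_seed, "\n")
  invisible(x)
}

# pixel-centre coordinates (mm), origin at field centre
pixel_axes <- function(sc) {
  pitch <- sc$field_width / sc$grid_size
  u <- ((seq_len(sc$grid_size)) - 0.5) * pitch - sc$field_width / 2
  list(x = u, y = u, pitch = pitch)
}

#' Illumination footprint of one fibre on the sample surface
#'
#' Irradiance pattern of a bare downward-pointing fibre at lateral offset
#' `fibre_offsets[fibre_index, ]` and height `probe_height`: a
#' `cos^4(theta) * (h/r)^2` falloff (cosine-fourth obliquity times
#' inverse-square distance), normalised so its maximum over the rendered
#' grid is 1.
#'
#' @param scene a [scene_spec()].
#' @param fibre_index which fibre (1-based).
#' @return `grid_size` x `grid_size` matrix in `[0, 1]`.
#' @export
illumination_field <- function(scene, fibre_index) {
  validate_scene_spec(scene)
  if (fibre_index < 1 || fibre_index > nrow(scene$fibre_offsets))
    stop("fibre_index out of range")
  ax <- pixel_axes(scene)
  f <- scene$fibre_offsets[fibre_index, ]
  h <- scene$probe_height
  dx2 <- outer(rep(1, scene$grid_size), (ax$x - f[1])^2)
  dy2 <- outer((ax$y - f[2])^2, rep(1, scene$grid_size))
  r2 <- h^2 + dx2 + dy2
  # cos(theta) = h/r  =>  cos^4 * (h/r)^2 = (h/r)^6 = (h^2/r^2)^3
  fld <- (h^2 / r2)^3
  fld / max(fld)
}

#' Mirror-glint location for one fibre
#'
#' For a flat horizontal surface with the camera on the central axis and a
#' fibre at the same height, the specular reflection of the fibre seen by
#' the camera sits at the lateral midpoint between the camera foot (the
#' origin) and the fibre foot. Activating a different fibre therefore
#' shifts the glint — the effect the multi-flash composite exploits.
#'
#' @inheritParams illumination_field
#' @return length-2 lateral position in mm.
#' @export
specular_center <- function(scene, fibre_index) {
  validate_scene_spec(scene)
  if (fibre_index < 1 || fibre_index > nrow(scene$fibre_offsets))
    stop("fibre_index out of range")
  scene$fibre_offsets[fibre_index, ] / 2
}

# compact specular bump exp(-(rho/sigma_s)^2) of unit peak around a glint
# centre; sigma_s (mm) set from the Phong-type exponent via the lobe's
# angular half-width projected to the surface
specular_lobe <- function(scene, center_mm) {
  ax <- pixel_axes(scene)
  sigma_s <- scene$probe_height * sqrt(2 / scene$specular_exponent)
  dx2 <- outer(rep(1, scene$grid_size), (ax$x - center_mm[1])^2)
  dy2 <- outer((ax$y - center_mm[2])^2, rep(1, scene$grid_size))
  exp(-(dx2 + dy2) / sigma_s^2)
}

#' Render the clean diffuse image of the phantom
#'
#' Background albedo with each circular feature imprinted at Weber
#' contrast `base_contrast * exp(-2 * mu_eff_per_mm * layer_thickness_mm)`
#' and edge-blurred with Gaussian sigma `blur_sigma_per_mm *
#' layer_thickness_mm` (converted from mm to pixels); clipped to unit
#' range. This is the ground truth every reconstruction is judged
#' against; it carries no illumination falloff, glints or noise.
#'
#' @inheritParams illumination_field
#' @return list with `image` (unit-range matrix) and `feature_mask`
#'   (logical matrix marking the unblurred feature footprints).
#' @export
render_diffuse <- function(scene) {
  validate_scene_spec(scene)
  ax <- pixel_axes(scene)
  n <- scene$grid_size
  relief <- matrix(0, n, n)
  fmask <- matrix(FALSE, n, n)
  decay <- exp(-2 * scene$mu_eff_per_mm * scene$layer_thickness_mm)
  for (f in scene$features) {
    dx2 <- outer(rep(1, n), (ax$x - f$center[1])^2)
    dy2 <- outer((ax$y - f$center[2])^2, rep(1, n))
    disc <- (dx2 + dy2) <= (f$diameter / 2)^2
    relief <- relief + f$base_contrast * decay * disc
    fmask <- fmask | disc
  }
  sigma_px <- scene$blur_sigma_per_mm * scene$layer_thickness_mm / ax$pitch
  if (sigma_px > 0)
    relief <- gaussian_blur(relief, sigma_px)
  img <- scene$background_albedo * (1 + relief)
  list(image = clip01(img), feature_mask = fmask)
}

#' Render a multi-flash stack of one scene
#'
#' For each fibre i the sensor records
#' `clip(diffuse * illumination_field_i + specular_strength * lobe_i +
#' noise, 0, 1)`, where `lobe_i` is the compact specular bump centred on
#' that fibre's mirror-glint location. With `specular_strength >= 1` the
#' glint exceeds full scale before clipping, so the detector saturates
#' there, as on a glossy phantom. Rendering is deterministic in the scene
#' seed; the clean diffuse image and feature mask are stored as ground
#' truth.
#'
#' @inheritParams illumination_field
#' @return a [flash_stack()] with one image per fibre.
#' @export
render_flash_stack <- function(scene) {
  validate_scene_spec(scene)
  dif <- render_diffuse(scene)
  nf <- nrow(scene$fibre_offsets)
  set.seed(scene$rng_seed)
  imgs <- vector("list", nf)
  for (i in seq_len(nf)) {
    illum <- illumination_field(scene, i)
    lobe <- specular_lobe(scene, specular_center(scene, i))
    img <- dif$image * illum + scene$specular_strength * lobe
    if (scene$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, scene$noise_sigma),
                          nrow(img))
    img <- clip01(img)
    if (!identical(scene$bit_depth, "none"))
      img <- quantise(img, scene$bit_depth)
    imgs[[i]] <- img
  }
  flash_stack(images = imgs,
              source_positions = scene$fibre_offsets,
              wavelength_nm = scene$wavelength_nm,
              ground_truth_diffuse = dif$image,
              feature_mask = dif$feature_mask,
              scene = scene)
}

#' Render the components seen by the cross-polarised probe
#'
#' Under simultaneous illumination through all fibres the scene presents a
#' diffuse component (clean diffuse image times the peak-normalised sum of
#' the individual fibre footprints) and a specular component (the
#' unclipped sum of all glint lobes scaled by `specular_strength`). They
#' are returned separately so [crosspol_acquire()] can mix them through
#' the polariser model.
#'
#' @inheritParams illumination_field
#' @return list with matrices `diffuse` and `specular`.
#' @export
render_crosspol_components <- function(scene) {
  validate_scene_spec(scene)
  dif <- render_diffuse(scene)
  n <- scene$grid_size
  illum <- matrix(0, n, n)
  spec <- matrix(0, n, n)
  for (i in seq_len(nrow(scene$fibre_offsets))) {
    illum <- illum + illumination_field(scene, i)
    spec <- spec + specular_lobe(scene, specular_center(scene, i))
  }
  list(diffuse = dif$image * (illum / max(illum)),
       specular = scene$specular_strength * spec,
       feature_mask = dif$feature_mask,
       ground_truth_diffuse = dif$image)
}

#' Co-registered multi-flash image stack
#'
#' Container for N co-registered unit-range intensity images of one
#' scene, each tagged with the lateral position of the illumination
#' source active when it was taken. Synthetic stacks from
#' [render_flash_stack()] additionally carry the ground-truth diffuse
#' image and feature mask.
#'
#' @param images list of numeric matrices (or H x W x 3 arrays for RGB),
#'   all the same shape, values in `[0, 1]`.
#' @param source_positions n x 2 matrix of lateral source positions (mm).
#' @param wavelength_nm illumination wavelength, if known.
#' @param ground_truth_diffuse optional clean diffuse image.
#' @param feature_mask optional logical matrix marking feature pixels.
#' @param scene optional originating [scene_spec()].
#' @return an object of class `flash_stack`.
#' @export
flash_stack <- function(images, source_positions,
                        wavelength_nm = NA_real_,
                        ground_truth_diffuse = NULL,
                        feature_mask = NULL,
                        scene = NULL) {
  source_positions <- as.matrix(source_positions)
  if (length(images) != nrow(source_positions))
    stop("need one source position per image")
  dims <- lapply(images, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("all images in a stack must share the same shape")
  rng <- range(unlist(lapply(images, range)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("stack images must be in unit range [0, 1]")
  structure(list(images = images,
                 source_positions = source_positions,
                 wavelength_nm = wavelength_nm,
                 ground_truth_diffuse = ground_truth_diffuse,
                 feature_mask = feature_mask,
                 scene = scene),
            class = "flash_stack")
}

#' @export
print.flash_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat("Multi-flash stack:", length(x$images), "images,",
      paste(d, collapse = " x "), "\n")
  cat("  source positions (mm):\n")
  print(round(x$source_positions, 3))
  if (!is.na(x$wavelength_nm)) cat("  wavelength:", x$wavelength_nm, "nm\n")
  if (!is.null(x$ground_truth_diffuse)) cat("  ground truth available\n")
  invisible(x)
}

#' @export
length.flash_stack <- function(x) length(x$images)

clip01 <- function(x) pmin(pmax(x, 0), 1)

quantise <- function(x, bits) {
  lv <- 2^bits - 1
  round(x * lv) / lv
}

# Gaussian blur in pixels, replicate boundary (EBImage kernel convolution)
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(3, ceiling(3 * sigma_px))
  rad <- min(2 * r + 1, min(dim(img)) - 1 - (min(dim(img)) %% 2))
  out <- EBImage::gblur(img, sigma = sigma_px, radius = rad,
                        boundary = "replicate")
  matrix(as.numeric(out), nrow(img), ncol(img))
}
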