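#' Linear polariser pair specification
#'
#' Parameters of the crossed source/analyser polariser pair of the
#' cross-polarised probe: the extinction (contrast) ratio `CR` (the
#' pass-axis to block-axis transmission ratio; a finite value leaks a
#' fraction `1/CR` of polarisation-maintaining light), the pass-axis
#' transmission `T`, and the deviation `misalignment_deg` of the pair
#' from a perfect 90 degree crossing. An optional per-pixel `angle_map`
#' models the angular spread across a wide-aperture camera, where the
#' surface reflection's polarisation plane meets the analyser at a
#' slightly different angle at each pixel.
#'
#' @param contrast_ratio extinction ratio (> 1); default 1500, typical of
#'   a high-quality wire-grid polariser at 650 nm.
#' @param transmission pass-axis transmission in `(0, 1]`; default 0.90.
#' @param misalignment_deg scalar crossing misalignment in degrees,
#'   `|misalignment_deg| < 90`.
#' @param angle_map optional matrix of per-pixel effective misalignment
#'   (degrees), overriding the scalar.
#' @return an object of class `polariser_spec`.
#' @export
polariser_spec <- function(contrast_ratio = 1500, transmission = 0.90,
                           misalignment_deg = 0, angle_map = NULL) {
  if (contrast_ratio <= 1) stop("contrast_ratio must be > 1")
  if (transmission <= 0 || transmission > 1)
    stop("transmission must be in (0, 1]")
  if (abs(misalignment_deg) >= 90)
    stop("misalignment_deg must satisfy |delta| < 90")
  if (!is.null(angle_map) && any(abs(angle_map) >= 90))
    stop("angle_map entries must satisfy |delta| < 90")
  structure(list(contrast_ratio = contrast_ratio,
                 transmission = transmission,
                 misalignment_deg = misalignment_deg,
                 angle_map = angle_map),
            class = "polariser_spec")
}

#' @export
print.polariser_spec <- function(x, ...) {
  cat("Polariser pair: contrast ratio", x$contrast_ratio,
      ", transmission", x$transmission, "\n")
  cat("  misalignment:",
      if (is.null(x$angle_map)) paste(x$misalignment_deg, "deg")
      else "per-pixel angle map", "\n")
  invisible(x)
}

#' Malus-law leakage through imperfectly crossed polarisers
#'
#' Polarisers crossed at `90 - delta` degrees transmit a fraction
#' `sin^2(delta)` of linearly polarised light (Malus's law with the
#' complement angle): zero at perfect crossing, 1/2 at 45 degrees.
#'
#' @param misalignment_deg misalignment from perfect crossing, degrees
#'   (scalar or array, `|delta| < 90`).
#' @return leaked fraction(s) in `[0, 1)`.
#' @export
malus_leakage <- function(misalignment_deg) {
  if (any(abs(misalignment_deg) >= 90))
    stop("|misalignment_deg| must be < 90")
  sin(misalignment_deg * pi / 180)^2
}

#' Image detected by the cross-polarised probe
#'
#' Mixes the scene's diffuse and specular components through the
#' polariser model:
#' `I = T^2 * (D/2 + S * (1/CR + sin^2(delta)))`, clipped to unit range.
#' Diffuse light is fully depolarised by multiple sub-surface scattering,
#' so exactly half of it passes the analyser; the surface glint is
#' polarisation-maintaining and reaches the sensor only through the
#' finite extinction ratio and any angular misalignment. Both components
#' pass both polarisers' pass-axis transmission, hence the `T^2`.
#'
#' @param diffuse,specular non-negative matrices of equal shape.
#' @param pol a [polariser_spec()].
#' @return detected unit-range image.
#' @export
crosspol_acquire <- function(diffuse, specular, pol = polariser_spec()) {
  if (!identical(dim(diffuse), dim(specular)))
    stop("diffuse and specular shapes differ")
  if (any(diffuse < 0) || any(specular < 0))
    stop("diffuse and specular must be non-negative")
  delta <- if (is.null(pol$angle_map)) pol$misalignment_deg else pol$angle_map
  leak <- 1 / pol$contrast_ratio + malus_leakage(delta)
  clip01(pol$transmission^2 * (diffuse / 2 + specular * leak))
}

#' Visibility of a residual glint under cross-polarisation
#'
#' Weber-type contrast of the leaked specular peak against the
#' cross-polarised diffuse background:
#' `(S_peak * (1/CR + sin^2(delta))) / (D_local / 2)`. When this ratio
#' exceeds the visibility threshold the glint survives as a bright
#' hotspot — which is why very flat, glossy surfaces (specular peak two
#' orders of magnitude above the diffuse level) still show the fibre
#' reflections even through a CR = 1500 polariser pair.
#'
#' @param S_peak specular peak radiance (same units as `D_local`).
#' @param D_local local diffuse level (> 0).
#' @param pol a [polariser_spec()].
#' @return dimensionless visibility ratio.
#' @export
residual_hotspot_ratio <- function(S_peak, D_local, pol = polariser_spec()) {
  if (any(D_local <= 0)) stop("D_local must be positive")
  delta <- if (is.null(pol$angle_map)) pol$misalignment_deg else pol$angle_map
  (S_peak * (1 / pol$contrast_ratio + malus_leakage(delta))) / (D_local / 2)
}

#' Side-by-side comparison of the three acquisition strategies
#'
#' Renders one scene three ways — a single raw flash, the multi-flash
#' reconstruction, and the cross-polarised acquisition — and computes
#' saturated fraction, feature Weber contrast and RMSE against the
#' ground-truth diffuse image for each. The saturated fraction is
#' measured on each method's as-acquired image; for the contrast and
#' RMSE comparison the single flash is illumination-flattened and the
#' cross-polarised image divided by its known illumination footprint, so
#' that all three are judged in a common photometric frame (RMSE after
#' an affine fit to the ground truth; see [rmse_vs_truth()]).
#'
#' @param scene a [scene_spec()].
#' @param settings a [recon_settings()].
#' @param pol a [polariser_spec()].
#' @param flash_index which single flash to report as the uncorrected
#'   baseline.
#' @return list with a metrics data.frame (`metrics`) and the three
#'   images (`images`).
#' @export
compare_methods <- function(scene, settings = recon_settings(),
                            pol = polariser_spec(), flash_index = 1) {
  validate_scene_spec(scene)
  stack <- render_flash_stack(scene)
  truth <- stack$ground_truth_diffuse
  fmask <- stack$feature_mask
  amask <- feature_annulus_mask(scene)

  raw <- stack$images[[flash_index]]
  blur_sigma <- settings$illum_blur_sigma
  if (is.null(blur_sigma)) blur_sigma <- nrow(raw) / 4
  raw_flat <- normalize_illumination(raw, blur_sigma,
                                     floor_eps = settings$log_epsilon)

  recon <- remove_specular_multiflash(stack, settings)

  comps <- render_crosspol_components(scene)
  xp <- crosspol_acquire(comps$diffuse, comps$specular, pol)
  # undo the known simulated illumination so the comparison sees D/2
  illum <- comps$diffuse / pmax(truth, 1e-6)
  xp_flat <- xp / pmax(illum, 1e-3)

  thr <- settings$sat_threshold
  row <- function(method, acquired, flattened) {
    data.frame(method = method,
               saturated_fraction = saturated_fraction(acquired, thr),
               weber_contrast = weber_contrast(flattened, fmask, amask),
               rmse_vs_truth = rmse_vs_truth(flattened, truth))
  }
  metrics <- rbind(row("single_flash", raw, raw_flat),
                   row("multiflash", recon$image, recon$image),
                   row("crosspol", xp, xp_flat))
  list(metrics = metrics,
       images = list(single_flash = raw, multiflash = recon$image,
                     crosspol = xp),
       recon = recon)
}
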