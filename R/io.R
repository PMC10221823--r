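#' Read and write multi-flash stacks on disk
#'
#' A stack directory holds either a multi-page TIFF (`stack.tif`, 8- or
#' 16-bit) or numbered 8-bit PNGs (`flash_001.png`, ...), plus a JSON
#' sidecar `stack.json` recording the source positions, wavelength, bit
#' depth and (for synthetic stacks) the generating scene. Intensities
#' are stored as integers at the chosen bit depth and mapped back to
#' unit range on reading (255 -> 1.0 for 8-bit, 65535 -> 1.0 for
#' 16-bit), so a write/read cycle is lossless once the data are
#' quantised at that depth.
#'
#' @param stack a [flash_stack()].
#' @param path directory to write into (created if missing) / to read.
#' @param format `"tiff"` (multi-page, supports 16-bit) or `"png"`
#'   (numbered files, 8-bit).
#' @param bit_depth 8 or 16 (16 requires `format = "tiff"`).
#' @return `write_stack` returns `path` invisibly; `read_stack` returns
#'   a [flash_stack()].
#' @name stack-io
NULL

#' @rdname stack-io
#' @export
write_stack <- function(stack, path, format = c("tiff", "png"),
                        bit_depth = 16) {
  format <- match.arg(format)
  if (!inherits(stack, "flash_stack")) stop("stack must be a flash_stack")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  if (format == "png" && bit_depth != 8)
    stop("PNG output is 8-bit; use format = \"tiff\" for 16-bit")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  imgs <- lapply(stack$images, quantise, bits = bit_depth)
  if (format == "tiff") {
    tiff::writeTIFF(imgs, file.path(path, "stack.tif"),
                    bits.per.sample = as.integer(bit_depth))
  } else {
    for (i in seq_along(imgs))
      png::writePNG(imgs[[i]],
                    file.path(path, sprintf("flash_%03d.png", i)))
  }
  sidecar <- list(
    n_images = length(imgs),
    format = format,
    bit_depth = bit_depth,
    source_positions_mm = unname(as.matrix(stack$source_positions)),
    wavelength_nm = stack$wavelength_nm,
    package_version = as.character(utils::packageVersion("microflash"))
  )
  if (!is.null(stack$scene)) {
    sc <- unclass(stack$scene)
    sc$fibre_offsets <- unname(as.matrix(sc$fibre_offsets))
    sidecar$scene <- sc
  }
  jsonlite::write_json(sidecar, file.path(path, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname stack-io
#' @export
read_stack <- function(path) {
  if (!dir.exists(path)) stop("stack directory not found: ", path)
  tif <- file.path(path, "stack.tif")
  pngs <- sort(list.files(path, pattern = "^flash_\\d+\\.png$",
                          full.names = TRUE))
  imgs <- if (file.exists(tif)) {
    lapply(tiff::readTIFF(tif, all = TRUE), flatten_gray)
  } else if (length(pngs) > 0) {
    lapply(pngs, function(p) flatten_gray(png::readPNG(p)))
  } else {
    stop("no stack.tif or flash_*.png images in ", path)
  }
  sidecar_path <- file.path(path, "stack.json")
  wavelength <- NA_real_
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    pos <- matrix(as.numeric(sidecar$source_positions_mm), ncol = 2)
    if (!is.null(sidecar$wavelength_nm) &&
        length(sidecar$wavelength_nm) == 1 &&
        !is.na(sidecar$wavelength_nm))
      wavelength <- as.numeric(sidecar$wavelength_nm)
  } else {
    warning("no stack.json sidecar in ", path,
            "; assuming the default 4 fibre positions at 2.4 mm radius")
    pos <- default_fibre_offsets()[seq_len(min(4, length(imgs))), ,
                                   drop = FALSE]
    if (length(imgs) != nrow(pos))
      stop("cannot assign default positions to ", length(imgs), " images")
  }
  flash_stack(images = imgs, source_positions = pos,
              wavelength_nm = wavelength)
}

# readPNG/readTIFF may return H x W x C arrays; collapse gray-encoded
# channels, keep true RGB
flatten_gray <- function(img) {
  if (length(dim(img)) == 2) return(img)
  if (dim(img)[3] >= 3) {
    rgb <- img[, , 1:3, drop = FALSE]
    if (max(abs(rgb[, , 1] - rgb[, , 2])) < 1e-12 &&
        max(abs(rgb[, , 1] - rgb[, , 3])) < 1e-12)
      return(rgb[, , 1])
    return(rgb[, , 1:3])
  }
  img[, , 1]
}
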