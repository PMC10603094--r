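#' Physical-unit 2-D Brillouin frequency-shift map
#'
#' A matrix of Brillouin frequency shifts (GHz) on a regular grid with a
#' physical pixel size, plus the acquisition constants needed to convert
#' shifts to moduli. Pixel `(i, j)` (row, column) has its center at
#' `x = (j - 0.5) * pixel_size_um`, `y = (i - 0.5) * pixel_size_um`; the
#' y axis increases dorsally (row 1 is the most ventral).
#'
#' @param values numeric matrix of frequency shifts, GHz; `NA` marks invalid
#'   pixels.
#' @param pixel_size_um translational step size, micrometers (default 0.5).
#' @param lambda0_nm incident wavelength, nm.
#' @param theta_deg scattering angle, degrees.
#' @return A `brillouin_map` object.
#' @export
brillouin_map <- function(values, pixel_size_um = 0.5,
                          lambda0_nm = 780.24, theta_deg = 180) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (any(values <= 0, na.rm = TRUE))
    stop("Brillouin shifts must be > 0 on valid pixels", call. = FALSE)
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 lambda0_nm = lambda0_nm, theta_deg = theta_deg),
            class = "brillouin_map")
}

#' @export
print.brillouin_map <- function(x, ...) {
  cat(sprintf("Brillouin map: %d x %d px (%.2f x %.2f um), step %.2f um\n",
              nrow(x$values), ncol(x$values),
              nrow(x$values) * x$pixel_size_um, ncol(x$values) * x$pixel_size_um,
              x$pixel_size_um))
  cat(sprintf("  shift range %.3f-%.3f GHz, %d invalid px\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(is.na(x$values))))
  invisible(x)
}

#' Rectangular region of interest in physical units
#'
#' The study convention is a 40 x 20 um rectangle centered on the lesion
#' site, with its ventral edge 5 um dorsal to the notochord.
#' [roi_from_notochord()] builds exactly that anchoring; `roi_spec()` takes
#' explicit edges.
#'
#' @param x_min_um,y_min_um lower-left corner (um); y increases dorsally.
#' @param width_um,height_um rectangle size (um); defaults 40 x 20.
#' @return An `roi_spec` object (closed rectangle; a pixel belongs to the
#'   ROI iff its center lies inside or on the boundary).
#' @export
roi_spec <- function(x_min_um, y_min_um, width_um = 40, height_um = 20) {
  assert_scalar_number(width_um, "width_um", lower = 0, strict_lower = TRUE)
  assert_scalar_number(height_um, "height_um", lower = 0, strict_lower = TRUE)
  structure(list(x_min = x_min_um, x_max = x_min_um + width_um,
                 y_min = y_min_um, y_max = y_min_um + height_um),
            class = "roi_spec")
}

#' @rdname roi_spec
#' @param center_x_um lesion-center x position (um).
#' @param notochord_y_um dorsal edge of the notochord landmark (um).
#' @param offset_um gap between notochord and ventral ROI edge (um, default 5).
#' @export
roi_from_notochord <- function(center_x_um, notochord_y_um,
                               width_um = 40, height_um = 20, offset_um = 5) {
  roi_spec(center_x_um - width_um / 2, notochord_y_um + offset_um,
           width_um, height_um)
}

# logical mask of pixels whose centers fall in the closed ROI rectangle
roi_mask <- function(dim_px, pixel_size_um, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  xc <- (seq_len(dim_px[2]) - 0.5) * pixel_size_um
  yc <- (seq_len(dim_px[1]) - 0.5) * pixel_size_um
  outer(yc >= roi$y_min & yc <= roi$y_max,
        xc >= roi$x_min & xc <= roi$x_max, FUN = `&`)
}

#' ROI summary statistics of a Brillouin map
#'
#' Mean and standard error of the frequency shift over all valid pixels
#' whose centers fall inside the closed ROI rectangle. Invalid (`NA`)
#' pixels are excluded and counted.
#'
#' @param map a [brillouin_map()].
#' @param roi an [roi_spec()].
#' @return list with `mean_GHz`, `sem_GHz`, `sd_GHz`, `n_pixels`,
#'   `n_invalid`.
#' @export
roi_statistics <- function(map, roi) {
  stopifnot(inherits(map, "brillouin_map"))
  mask <- roi_mask(dim(map$values), map$pixel_size_um, roi)
  if (!any(mask))
    stop("ROI contains no pixel centers (outside the map?)", call. = FALSE)
  vals <- map$values[mask]
  n_invalid <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("ROI contains no valid pixels", call. = FALSE)
  s <- if (length(vals) > 1L) stats::sd(vals) else 0
  list(mean_GHz = mean(vals), sem_GHz = s / sqrt(length(vals)), sd_GHz = s,
       n_pixels = length(vals), n_invalid = n_invalid)
}

#' Read and write physical-unit grids
#'
#' Grids travel either as single-channel 32-bit float TIFF or as a plain CSV
#' matrix, in both cases with a JSON sidecar (`<path>.json`) holding the
#' pixel size and acquisition constants.
#'
#' @param map a [brillouin_map()].
#' @param path output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.csv`).
#' @return `write_map` returns `path` invisibly; `read_map` returns a
#'   [brillouin_map()].
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "brillouin_map"))
  ext <- tolower(tools::file_ext(path))
  meta <- list(pixel_size_um = map$pixel_size_um, lambda0_nm = map$lambda0_nm,
               theta_deg = map$theta_deg, unit = "GHz")
  if (ext %in% c("tif", "tiff")) {
    # TIFF samples live in [0, 1]; store affinely rescaled values ([0.1, 1],
    # NA -> 0) and record the transform in the sidecar.
    v <- map$values
    lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
    scale <- if (hi > lo) (hi - lo) / 0.9 else 1
    enc <- 0.1 + (v - lo) / scale
    enc[is.na(enc)] <- 0
    tiff::writeTIFF(enc, path, bits.per.sample = 32L)
    meta$tiff_encoding <- list(offset = lo, scale = scale, na_value = 0)
  } else if (ext == "csv") {
    utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported map format: ", ext, call. = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(pixel_size_um = 0.5, lambda0_nm = 780.24, theta_deg = 180)
  values <- if (ext %in% c("tif", "tiff")) {
    enc <- tiff::readTIFF(path, as.is = FALSE)
    te <- meta$tiff_encoding
    v <- te$offset + (enc - 0.1) * te$scale
    v[enc == te$na_value] <- NA_real_
    v
  } else if (ext == "csv") {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else stop("unsupported map format: ", ext, call. = FALSE)
  dimnames(values) <- NULL
  brillouin_map(values, meta$pixel_size_um, meta$lambda0_nm, meta$theta_deg)
}
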