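#' Co-/cross-polarized OCT amplitude stacks
#'
#' Container for a pair of co-registered, non-negative amplitude image
#' stacks from cross-polarized optical coherence tomography: `co` holds the
#' co-polarized amplitude \eqn{A_{co}} and `cross` the cross-polarized
#' amplitude \eqn{A_{cross}}. Stacks are 3-D arrays (rows x columns x
#' slices); single images are promoted to one-slice stacks.
#'
#' @param co,cross numeric arrays of identical shape, values >= 0.
#' @param pixel_size_um lateral pixel size, micrometers.
#' @return A `polarized_stack` object.
#' @export
polarized_stack <- function(co, cross, pixel_size_um = 1) {
  as_stack <- function(x) {
    if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
    if (!is.array(x) || length(dim(x)) != 3L)
      stop("stacks must be matrices or 3-D arrays", call. = FALSE)
    x
  }
  co <- as_stack(co); cross <- as_stack(cross)
  if (!identical(dim(co), dim(cross)))
    stop("co- and cross-polarized stacks must have the same shape", call. = FALSE)
  if (any(co < 0, na.rm = TRUE) || any(cross < 0, na.rm = TRUE))
    stop("amplitudes must be non-negative", call. = FALSE)
  structure(list(co = co, cross = cross, pixel_size_um = pixel_size_um),
            class = "polarized_stack")
}

#' Average intensity projection of an image stack
#'
#' Per-pixel arithmetic mean along the slice axis.
#'
#' @param stack a 3-D array (rows x columns x slices) or matrix.
#' @return A matrix of per-pixel means.
#' @export
average_intensity_projection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L)
    stop("need a non-empty stack", call. = FALSE)
  rowMeans(stack, dims = 2L)
}

#' Reflectivity and co-polarization ratio
#'
#' Pixelwise sample reflectivity \eqn{R = \sqrt{A_{co}^2 + A_{cross}^2}} and
#' co-polarization ratio \eqn{\delta = A_{co} / (A_{co} + A_{cross})} — the
#' fraction of backscattered amplitude retaining the incident polarization.
#' By default the stacks are first collapsed by
#' [average_intensity_projection()] ("project-first"); `per_slice = TRUE`
#' instead computes the ratio slice-wise and projects the result.
#' Pixels with \eqn{A_{co} + A_{cross} = 0} are masked invalid.
#'
#' @param stack a [polarized_stack()].
#' @param per_slice compute the ratio per slice before projecting?
#' @return A `structure_result`: list with matrices `R`, `delta`, logical
#'   `valid`, and `pixel_size_um`.
#' @export
#' @examples
#' s <- polarized_stack(matrix(3, 2, 2), matrix(4, 2, 2))
#' reflectivity_and_ratio(s)$delta[1, 1]  # 3/7
reflectivity_and_ratio <- function(stack, per_slice = FALSE) {
  stopifnot(inherits(stack, "polarized_stack"))
  ratio <- function(co, cross) {
    tot <- co + cross
    d <- ifelse(tot > 0, co / tot, NA_real_)
    list(R = sqrt(co^2 + cross^2), delta = d, valid = tot > 0)
  }
  if (per_slice) {
    n <- dim(stack$co)[3]
    per <- lapply(seq_len(n), function(k) ratio(stack$co[, , k], stack$cross[, , k]))
    delta <- Reduce(`+`, lapply(per, function(p) ifelse(p$valid, p$delta, 0)))
    nvalid <- Reduce(`+`, lapply(per, function(p) p$valid * 1))
    delta <- ifelse(nvalid > 0, delta / nvalid, NA_real_)
    r <- ratio(average_intensity_projection(stack$co),
               average_intensity_projection(stack$cross))
    res <- list(R = r$R, delta = delta, valid = nvalid > 0)
  } else {
    res <- ratio(average_intensity_projection(stack$co),
                 average_intensity_projection(stack$cross))
  }
  structure(c(res, list(pixel_size_um = stack$pixel_size_um)),
            class = "structure_result")
}

#' Mean co-polarization ratio over an ROI
#'
#' @param result a `structure_result` from [reflectivity_and_ratio()].
#' @param roi an [roi_spec()], or `NULL` for the whole image.
#' @return Mean of `delta` over valid ROI pixels.
#' @export
roi_mean_ratio <- function(result, roi = NULL) {
  stopifnot(inherits(result, "structure_result"))
  mask <- if (is.null(roi)) matrix(TRUE, nrow(result$delta), ncol(result$delta))
          else roi_mask(dim(result$delta), result$pixel_size_um, roi)
  keep <- mask & result$valid
  if (!any(keep)) stop("ROI contains no valid pixels", call. = FALSE)
  mean(result$delta[keep])
}

#' Mean-threshold foreground area
#'
#' Binarizes an intensity image at the mean grey level of the ROI (the
#' automated mean thresholding rule) and counts foreground pixels. A pixel
#' is foreground iff its value is strictly greater than the threshold, so a
#' uniform image deterministically yields zero foreground.
#'
#' @param image numeric matrix.
#' @param roi an [roi_spec()], or `NULL` for the whole image.
#' @param pixel_size_um pixel size used to convert the count to um^2.
#' @return list with `threshold`, `n_foreground`, `area_um2`, `n_roi`.
#' @export
mean_threshold_area <- function(image, roi = NULL, pixel_size_um = 1) {
  image <- as.matrix(image)
  mask <- if (is.null(roi)) matrix(TRUE, nrow(image), ncol(image))
          else roi_mask(dim(image), pixel_size_um, roi)
  vals <- image[mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("empty ROI", call. = FALSE)
  thr <- mean(vals)
  nfg <- sum(vals > thr)
  list(threshold = thr, n_foreground = nfg,
       area_um2 = nfg * pixel_size_um^2, n_roi = length(vals))
}
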