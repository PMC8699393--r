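# Morphometrics: cell-profile area, perimeter, circularity, and masked
# fluorescence from segmentation masks.

#' Cell circularity
#'
#' `4 * pi * area / perimeter^2`: 1 for a circle, approaching 0 for
#' elongated shapes.
#'
#' @param area Cell-profile area, micrometres^2 (positive).
#' @param perimeter Cell peripheral circumference, micrometres (positive).
#' @return Dimensionless circularity.
#' @examples
#' circularity(100 * pi, 20 * pi)  # circle of radius 10 -> 1
#' circularity(100, 40)            # square of side 10 -> pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0))
    stop("parameter error: area and perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' Measure a segmented cell mask
#'
#' Area is the foreground pixel count times `pixel_size^2`.  Perimeter is
#' the length of the sub-pixel iso-contour of the binary mask at level 0.5
#' (marching squares with linear interpolation), which avoids the up-to-
#' sqrt(2) overestimate of boundary-pixel counting that would systematically
#' deflate circularity.  On smooth curved boundaries the contour still
#' tracks the pixel staircase, an upward perimeter bias of up to about 6%
#' (a large digital disk reads circularity near 0.9, not exactly 1); on
#' axis-aligned polygons it is nearly exact.  Discrete circularity
#' estimates slightly above 1 (estimator noise on tiny masks) are clipped
#' to 1 with a warning.
#'
#' @param mask Logical or 0/1 matrix with at least one foreground pixel
#'   forming a single connected component.
#' @param pixel_size Micrometres per pixel.
#' @return List with `area`, `perimeter`, `circularity`.
#' @export
measure_mask <- function(mask, pixel_size = 1) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("parameter error: pixel_size must be a positive scalar")
  m <- (mask > 0) * 1
  n_fg <- sum(m)
  if (n_fg == 0L) stop("parameter error: empty mask")
  n_comp <- max(EBImage::bwlabel(m))
  if (n_comp > 1L)
    stop(sprintf("ambiguity error: mask has %d connected components", n_comp))
  area <- n_fg * pixel_size^2
  perim <- contour_length(m) * pixel_size
  circ <- circularity(area, perim)
  if (circ > 1) {
    warning(sprintf("discrete circularity estimate %.4f > 1 clipped to 1", circ))
    circ <- 1
  }
  list(area = area, perimeter = perim, circularity = circ)
}

# Total length of the level-0.5 iso-contour(s) of a binary matrix.
# grDevices::contourLines performs marching squares with linear
# interpolation; a zero border guarantees closed contours.
contour_length <- function(m) {
  p <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  cl <- grDevices::contourLines(x = seq_len(nrow(p)), y = seq_len(ncol(p)),
                                z = p, levels = 0.5)
  if (length(cl) == 0L) return(0)
  sum(vapply(cl, function(seg) {
    sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2))
  }, numeric(1)))
}

#' Masked fluorescence summation
#'
#' Sums the intensity raster over foreground mask positions — the standard
#' quantification of a labelled cell's fluorescence given its segmented
#' profile.  No background subtraction is applied unless `background` is
#' set, in which case a constant offset is removed per foreground pixel.
#'
#' @param mask Logical or 0/1 matrix.
#' @param image Numeric matrix, same shape as `mask`.
#' @param background Constant per-pixel offset to subtract (default 0).
#' @return Summed intensity (arbitrary units); 0 for an empty intersection.
#' @export
masked_fluorescence <- function(mask, image, background = 0) {
  if (!identical(dim(mask), dim(image)))
    stop(sprintf("geometry error: mask is %dx%d but image is %dx%d",
                 nrow(mask), ncol(mask), nrow(image), ncol(image)))
  fg <- mask > 0
  sum(image[fg]) - background * sum(fg)
}

#' Measure all labelled cells in a mask/image pair
#'
#' Convenience wrapper over [measure_mask()] and [masked_fluorescence()]
#' for the per-label masks returned by [read_mask_and_image()].
#'
#' @param loaded List from [read_mask_and_image()].
#' @return Data frame: `label`, `area_um2`, `perimeter_um`, `circularity`,
#'   `fluor`.
#' @export
measure_labelled <- function(loaded) {
  out <- lapply(names(loaded$masks), function(l) {
    m <- loaded$masks[[l]]
    meas <- measure_mask(m, loaded$pixel_size)
    data.frame(label = l, area_um2 = meas$area, perimeter_um = meas$perimeter,
               circularity = meas$circularity,
               fluor = masked_fluorescence(m, loaded$image),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
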