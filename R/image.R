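#' RGB image container
#'
#' A height x width x 3 numeric array with intensities in `[0, 255]`,
#' channels ordered red, green, blue.
#'
#' @param x Numeric array `h x w x 3` with values in `[0, 255]`.
#' @return An `rgb_image` object.
#' @export
rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3 || dim(x)[3] != 3) {
    stop_gsc("an RGB image must be a height x width x 3 array (grayscale input is not accepted)",
             "gscsoma_format_error")
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    stop_gsc("image intensities must lie in [0, 255]", "gscsoma_format_error")
  }
  structure(x, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat("<rgb_image>", d[1], "x", d[2], "pixels\n")
  invisible(x)
}

#' Simulate an oil-red-O stained micrograph
#'
#' Builds an RGB image in which, inside a rectangular region of interest,
#' the red channel exceeds the green channel by `stain_level` on average
#' (the lipid dye absorbs green light, so stained tissue is red-shifted);
#' outside, the channels are equal on average.
#'
#' @param height,width Image size in pixels.
#' @param roi Region of interest: either a logical `height x width` mask or
#'   a list `list(row = c(r1, r2), col = c(c1, c2))` of inclusive bounds.
#' @param stain_level Mean red-over-green excess inside the ROI, in
#'   `[0, 255]`.
#' @param noise_sd Gaussian pixel noise added independently to the red and
#'   green channels.
#' @param base Background intensity of all channels. Signal recovery is
#'   exact when `base + stain_level <= 255` (no clipping).
#' @param seed Integer seed.
#' @return A list of class `oro_sim`: `image` ([rgb_image()]) and `roi`
#'   (logical mask).
#' @export
#' @examples
#' sim <- simulate_oro_image(20, 30, list(row = c(5, 15), col = c(10, 20)),
#'                           stain_level = 80, noise_sd = 0)
#' mean(oro_signal(sim$image)[sim$roi])
simulate_oro_image <- function(height, width, roi, stain_level, noise_sd = 0,
                               base = 50, seed = 1L) {
  if (!is.numeric(stain_level) || stain_level < 0 || stain_level > 255) {
    stop_gsc("`stain_level` must lie in [0, 255]", "gscsoma_config_error")
  }
  mask <- as_roi_mask(roi, height, width)
  local_seed(seed, {
    clamp <- function(v) pmin(pmax(v, 0), 255)
    red <- base + stain_level * mask
    green <- matrix(base, height, width)
    if (noise_sd > 0) {
      red <- red + matrix(rnorm(height * width, 0, noise_sd), height, width)
      green <- green + matrix(rnorm(height * width, 0, noise_sd), height, width)
    }
    img <- array(0, c(height, width, 3))
    img[, , 1] <- clamp(red)
    img[, , 2] <- clamp(green)
    img[, , 3] <- base
    structure(list(image = rgb_image(img), roi = mask), class = "oro_sim")
  })
}

as_roi_mask <- function(roi, height, width) {
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == c(height, width))) {
      stop_gsc("ROI mask dimensions must match the image", "gscsoma_config_error")
    }
    return(roi)
  }
  if (is.list(roi) && all(c("row", "col") %in% names(roi))) {
    r <- roi$row; cc <- roi$col
    if (r[1] < 1 || r[2] > height || cc[1] < 1 || cc[2] > width ||
        r[1] > r[2] || cc[1] > cc[2]) {
      stop_gsc("ROI bounds fall outside the image", "gscsoma_config_error")
    }
    mask <- matrix(FALSE, height, width)
    mask[r[1]:r[2], cc[1]:cc[2]] <- TRUE
    return(mask)
  }
  stop_gsc("`roi` must be a logical mask or list(row =, col =) bounds",
           "gscsoma_config_error")
}

#' Isolate lipid-stain signal by channel subtraction
#'
#' The stain absorbs green light, so stained pixels are darker in green than
#' in red. The signal is `max(0, R - G)` per pixel; with
#' `direction = "green_minus_red"` the opposite orientation (clamped at
#' zero) is returned instead.
#'
#' @param image An [rgb_image()].
#' @param direction Subtraction orientation; the default yields positive
#'   signal where the red dye attenuates the green channel.
#' @return Numeric matrix of per-pixel signal.
#' @export
oro_signal <- function(image, direction = c("red_minus_green", "green_minus_red")) {
  direction <- match.arg(direction)
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  d <- if (direction == "red_minus_green") image[, , 1] - image[, , 2]
       else image[, , 2] - image[, , 1]
  pmax(d, 0)
}

#' Mean signal intensity over background within a region of interest
#'
#' @param signal Numeric signal matrix (e.g. from [oro_signal()]).
#' @param roi Logical mask with at least one `TRUE` pixel.
#' @param background_level Scalar background; defaults to the median signal
#'   outside the ROI (0 if the ROI covers the whole image).
#' @return Mean over the ROI of `max(0, signal - background_level)`.
#' @export
mean_intensity_over_background <- function(signal, roi, background_level = NULL) {
  if (!is.matrix(signal)) stop_gsc("`signal` must be a matrix", "gscsoma_format_error")
  if (!is.logical(roi) || !all(dim(roi) == dim(signal))) {
    stop_gsc("`roi` must be a logical mask matching the signal", "gscsoma_format_error")
  }
  if (!any(roi)) stop_gsc("ROI is empty", "gscsoma_format_error")
  if (is.null(background_level)) {
    background_level <- if (all(roi)) 0 else median(signal[!roi])
  }
  mean(pmax(0, signal[roi] - background_level))
}

#' Select pixels by color similarity
#'
#' Emulates an image editor's "select by color with fuzziness": a pixel is
#' selected when its largest per-channel absolute difference from the target
#' color (Chebyshev distance) is at most `fuzziness`.
#'
#' @param image An [rgb_image()].
#' @param target_rgb Length-3 target color in `[0, 255]`.
#' @param fuzziness Tolerance in `[0, 255]`; 0 selects exact matches only,
#'   255 selects everything.
#' @return Logical mask (height x width).
#' @export
#' @examples
#' img <- rgb_image(array(c(99, 159, 94), c(1, 1, 3)))
#' isolate_color(img, c(99, 159, 94), fuzziness = 0)
isolate_color <- function(image, target_rgb, fuzziness) {
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  if (length(target_rgb) != 3 || any(target_rgb < 0) || any(target_rgb > 255)) {
    stop_gsc("`target_rgb` must be three values in [0, 255]", "gscsoma_config_error")
  }
  if (fuzziness < 0 || fuzziness > 255) {
    stop_gsc("`fuzziness` must lie in [0, 255]", "gscsoma_config_error")
  }
  d <- pmax(abs(image[, , 1] - target_rgb[1]),
            abs(image[, , 2] - target_rgb[2]),
            abs(image[, , 3] - target_rgb[3]))
  d <= fuzziness
}

#' Read / write an RGB image as PNG
#'
#' @param path PNG file path.
#' @return `read_rgb_png()` returns an [rgb_image()]; `write_rgb_png()`
#'   invisibly returns the path.
#' @export
read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) {
    stop_gsc("grayscale PNG: an RGB image is required", "gscsoma_format_error")
  }
  rgb_image(round(a[, , 1:3, drop = FALSE] * 255))
}

#' @param image An [rgb_image()].
#' @rdname read_rgb_png
#' @export
write_rgb_png <- function(image, path) {
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}
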