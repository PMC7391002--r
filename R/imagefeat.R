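# Low-level visual features of stimulus images: mean HSV colour attributes,
# Sobel-gradient sharpness, and the spectral slope of the rotationally
# averaged Fourier power spectrum.

#' Create a stimulus image
#'
#' Bundles an RGB pixel raster with item metadata and an optional inclusion
#' mask. All feature extractors in the package operate on this container.
#'
#' @param pixels An `H x W x 3` numeric array of RGB values in `[0, 1]`, or an
#'   `H x W` grayscale matrix (replicated across channels).
#' @param item_id Item identifier.
#' @param category Item category, one of `"fractal"`, `"snack"`, `"face"`.
#' @param mask Optional `H x W` logical matrix; `TRUE` marks pixels included
#'   in colour and sharpness statistics. The spectral slope always uses the
#'   full image.
#' @return An object of class `stimulus_image`.
#' @examples
#' img <- stimulus_image(array(runif(48), dim = c(4, 4, 3)), "demo")
#' mean_hsv(img)
#' @export
stimulus_image <- function(pixels, item_id = "item",
                           category = c("fractal", "snack", "face"),
                           mask = NULL) {
  category <- match.arg(category)
  if (is.matrix(pixels)) {
    pixels <- array(rep(as.numeric(pixels), 3L), dim = c(dim(pixels), 3L))
  }
  if (!(is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L)) {
    abort("`pixels` must be an H x W x 3 array (or an H x W grayscale matrix).")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    abort("pixel values must be finite and lie in [0, 1]")
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(pixels)[1:2])) {
      abort("`mask` must be a logical H x W matrix matching the image")
    }
    if (!any(mask)) abort("no included pixels")
  }
  structure(
    list(pixels = pixels, item_id = as.character(item_id),
         category = category, mask = mask),
    class = "stimulus_image"
  )
}

#' @export
print.stimulus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stimulus_image> %s (%s), %d x %d px%s\n",
              x$item_id, x$category, d[1], d[2],
              if (is.null(x$mask)) "" else sprintf(", %d masked-out px",
                                                  sum(!x$mask))))
  invisible(x)
}

#' Read a stimulus image from disk
#'
#' PNG files are decoded with the png package; other formats (JPEG, TIFF)
#' require the EBImage package. Alpha channels are dropped; grayscale rasters
#' are replicated to RGB.
#'
#' @param path Path to an image file.
#' @param item_id Item identifier; defaults to the file name without extension.
#' @inheritParams stimulus_image
#' @return A [stimulus_image()].
#' @export
read_stimulus <- function(path, item_id = NULL,
                          category = c("fractal", "snack", "face")) {
  item_id <- item_id %||% sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort(sprintf("reading .%s files requires the EBImage package", ext))
    }
    img <- EBImage::readImage(path)
    px <- aperm(EBImage::imageData(img), c(2, 1, 3)[seq_along(dim(img))])
  }
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px <- pmin(pmax(px, 0), 1)
  stimulus_image(px, item_id = item_id, category = category)
}

# ITU-R BT.601 luma weights, the default of mainstream image toolboxes.
luma <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Mask out a near-black background
#'
#' Face photographs in this line of work are typically composited on a black
#' background; colour and sharpness statistics are computed without it.
#'
#' @param image A [stimulus_image()].
#' @param threshold Pixels with all three channels below this value are
#'   excluded.
#' @return A logical matrix (`TRUE` = included pixel).
#' @export
black_background_mask <- function(image, threshold = 0.02) {
  px <- image$pixels
  !(px[, , 1] < threshold & px[, , 2] < threshold & px[, , 3] < threshold)
}

resolve_mask <- function(image, mask) {
  d <- dim(image$pixels)[1:2]
  m <- mask %||% image$mask %||% matrix(TRUE, d[1], d[2])
  if (!any(m)) abort("no included pixels")
  m
}

#' Mean HSV colour attributes
#'
#' Converts each pixel from RGB to HSV (hue on the `[0, 1)` fraction-of-the-
#' colour-circle scale; achromatic pixels take hue 0 by the standard
#' convention) and returns the arithmetic mean of each channel over included
#' pixels.
#'
#' @param image A [stimulus_image()].
#' @param mask Optional logical inclusion mask overriding the image's own.
#' @param hue_method `"arithmetic"` (the default) averages hue as a plain
#'   number; `"circular"` uses the circular mean, respecting the wrap-around
#'   of the colour circle.
#' @return A one-row tibble with columns `hue`, `saturation`, `color_value`.
#' @examples
#' red <- stimulus_image(array(rep(c(1, 0, 0), each = 4), c(2, 2, 3)))
#' mean_hsv(red) # hue 0, saturation 1, value 1
#' @export
mean_hsv <- function(image, mask = NULL,
                     hue_method = c("arithmetic", "circular")) {
  hue_method <- match.arg(hue_method)
  keep <- as.vector(resolve_mask(image, mask))
  px <- image$pixels
  m <- rbind(as.vector(px[, , 1])[keep],
             as.vector(px[, , 2])[keep],
             as.vector(px[, , 3])[keep])
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  hue <- if (hue_method == "arithmetic") {
    mean(hsv[1, ])
  } else {
    ang <- 2 * pi * hsv[1, ]
    (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1
  }
  tibble(hue = hue, saturation = mean(hsv[2, ]), color_value = mean(hsv[3, ]))
}

# 3x3 Sobel responses with reflect-edge padding (border pixels included).
sobel_magnitude <- function(g) {
  h <- nrow(g); w <- ncol(g)
  p <- g[c(1, seq_len(h), h), c(1, seq_len(w), w), drop = FALSE]
  ri <- seq_len(h); ci <- seq_len(w)
  tl <- p[ri, ci];     tc <- p[ri, ci + 1];     tr <- p[ri, ci + 2]
  ml <- p[ri + 1, ci];                          mr <- p[ri + 1, ci + 2]
  bl <- p[ri + 2, ci]; bc <- p[ri + 2, ci + 1]; br <- p[ri + 2, ci + 2]
  gx <- (tr + 2 * mr + br) - (tl + 2 * ml + bl)
  gy <- (bl + 2 * bc + br) - (tl + 2 * tc + tr)
  sqrt(gx^2 + gy^2)
}

#' Image sharpness as the mean Sobel gradient
#'
#' Converts the image to grayscale (BT.601 luma) and returns the mean over
#' included pixels of the Sobel--Feldman gradient magnitude
#' `sqrt(Gx^2 + Gy^2)`, computed with reflect-edge padding.
#'
#' @inheritParams mean_hsv
#' @return A nonnegative scalar; 0 for a constant image.
#' @export
sharpness <- function(image, mask = NULL) {
  g <- luma(image$pixels)
  if (length(g) < 2L) abort("image too small for gradient")
  keep <- resolve_mask(image, mask)
  mean(sobel_magnitude(g)[keep])
}

# Circularly shift a square matrix so the DC component (1, 1) lands at the
# centre index n %/% 2 + 1, as conventional for displaying power spectra.
fftshift <- function(m) {
  n <- nrow(m)
  idx <- ((seq_len(n) - 1 - n %/% 2) %% n) + 1
  m[idx, idx]
}

#' Rotational average of a power spectrum
#'
#' Bins a square, DC-centred 2-D power spectrum into integer radial-frequency
#' annuli `f = round(sqrt(u^2 + v^2))` (cycles per image) and averages power
#' within each annulus, excluding the DC component.
#'
#' @param power A square numeric matrix of nonnegative spectral power with the
#'   DC component at the centre (row and column `n %/% 2 + 1`).
#' @return A tibble with columns `freq` (integer cycles per image), `power`
#'   (mean power in the annulus) and `n` (number of spectrum cells averaged).
#' @export
rotational_average <- function(power) {
  if (!is.matrix(power) || nrow(power) != ncol(power)) {
    abort("rotational average requires a square, DC-centred spectrum")
  }
  n <- nrow(power)
  centre <- n %/% 2 + 1
  u <- seq_len(n) - centre
  r <- round(sqrt(outer(u^2, u^2, `+`)))
  keep <- !(row(power) == centre & col(power) == centre)
  f <- factor(r[keep])
  means <- tapply(power[keep], f, mean)
  counts <- tapply(power[keep], f, length)
  tibble(freq = as.integer(names(means)),
         power = as.numeric(means),
         n = as.integer(counts))
}

# Keys bicubic kernel (a = -0.5), the classical "bicubic interpolation"
# kernel of image-processing toolboxes.
cubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  out <- numeric(length(ax))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  out[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  out[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  out
}

interp_matrix <- function(n_in, n_out) {
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale + 0.5
  base <- floor(src)
  W <- matrix(0, n_out, n_in)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 1), n_in)
    w <- cubic_kernel(src - (base + k))
    cells <- cbind(seq_len(n_out), idx)
    W[cells] <- W[cells] + w
  }
  W / rowSums(W)
}

# Separable bicubic resampling (edge-clamped).
resize_bicubic <- function(g, out_h, out_w) {
  interp_matrix(nrow(g), out_h) %*% g %*% t(interp_matrix(ncol(g), out_w))
}

resize_short_side <- function(g, target) {
  h <- nrow(g); w <- ncol(g)
  s <- target / min(h, w)
  out_h <- if (h <= w) target else max(target, round(h * s))
  out_w <- if (w < h) target else max(target, round(w * s))
  if (out_h == h && out_w == w) g else resize_bicubic(g, out_h, out_w)
}

crop_centre <- function(g, size) {
  r0 <- (nrow(g) - size) %/% 2
  c0 <- (ncol(g) - size) %/% 2
  g[r0 + seq_len(size), c0 + seq_len(size), drop = FALSE]
}

#' Spectral slope of an image
#'
#' Natural images have Fourier power spectra that fall off roughly as
#' `1/f^2`; the spectral slope summarises this. The pipeline is: grayscale
#' conversion, bicubic resize so the short dimension equals `crop_size`
#' pixels, central `crop_size x crop_size` crop, 2-D discrete Fourier
#' transform, power = squared magnitude, rotational average over integer
#' frequency annuli, then a least-squares line of `log10(power)` on
#' `log10(frequency)` restricted to `fit_range` cycles per image (the
#' default 10--256 avoids artifacts from extreme low or high frequencies).
#'
#' @param image A [stimulus_image()] or a numeric grayscale matrix. Masks are
#'   ignored: the slope always uses the full crop.
#' @param fit_range Length-2 numeric range of radial frequencies (cycles per
#'   image) entering the fit.
#' @param crop_size Side of the analysis crop in pixels.
#' @return An object of class `spectral_fit`: a list with the binned spectrum
#'   (`radial_freqs`, `radial_power`), `fit_range`, `slope` and `intercept`.
#'   The `slope` element is the feature value.
#' @examples
#' img <- gen_spectral_image(beta = -2, size = 512, seed = 1)
#' fit <- spectral_slope(img)
#' fit$slope # close to -2
#' @export
spectral_slope <- function(image, fit_range = c(10, 256), crop_size = 512L) {
  g <- if (inherits(image, "stimulus_image")) luma(image$pixels) else as.matrix(image)
  if (min(dim(g)) < 2) abort("image too small for spectral analysis")
  g <- resize_short_side(g, crop_size)
  g <- crop_centre(g, crop_size)
  F2 <- Mod(stats::fft(g))^2
  ra <- rotational_average(fftshift(F2))
  # A constant image carries all its power at DC; off-DC bins are zero up to
  # floating-point rounding of the DFT.
  dc <- F2[1, 1]
  nonzero <- ra$power > max(dc, 1) * 1e-26
  sel <- ra$freq >= fit_range[1] & ra$freq <= fit_range[2]
  if (!any(nonzero & sel)) abort("zero power at all nonzero frequencies")
  if (any(sel & !nonzero)) {
    warn(sprintf("%d zero-power annuli dropped from the spectral fit",
                 sum(sel & !nonzero)))
    sel <- sel & nonzero
  }
  fit <- lm(y ~ x, data = data.frame(x = log10(ra$freq[sel]),
                                     y = log10(ra$power[sel])))
  structure(
    list(radial_freqs = ra$freq, radial_power = ra$power,
         fit_range = fit_range,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1])),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> slope = %.4f (fit on %g-%g cycles/image)\n",
              x$slope, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Extract the five low-level visual features for a batch of images
#'
#' Computes mean hue, saturation and colour value, Sobel sharpness, and the
#' spectral slope for each image. For face images a near-black background is
#' masked out of the colour and sharpness statistics by default (the
#' spectral slope always uses the full crop).
#'
#' @param images A list of [stimulus_image()] objects, or the path of a
#'   directory of image files (all assigned `category`).
#' @param category Category assigned when reading from a directory.
#' @param mask_black `NULL` (mask faces only, the default), `TRUE` or `FALSE`.
#' @param black_threshold Per-channel threshold defining "near black".
#' @param hue_method Passed to [mean_hsv()].
#' @return A tibble with columns `item_id`, `category`, `hue`, `saturation`,
#'   `color_value`, `sharpness`, `spectral_slope` (one row per image).
#' @export
extract_features <- function(images, category = c("fractal", "snack", "face"),
                             mask_black = NULL, black_threshold = 0.02,
                             hue_method = "arithmetic") {
  if (is.character(images) && length(images) == 1L) {
    category <- match.arg(category)
    files <- sort(list.files(images, pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) abort(sprintf("no image files found in '%s'", images))
    images <- lapply(files, read_stimulus, category = category)
  }
  purrr::map_dfr(images, function(img) {
    do_mask <- mask_black %||% (img$category == "face")
    msk <- resolve_mask(img, NULL)
    if (do_mask) msk <- msk & black_background_mask(img, black_threshold)
    if (!any(msk)) abort(sprintf("no included pixels for item '%s'", img$item_id))
    hsv <- mean_hsv(img, mask = msk, hue_method = hue_method)
    tibble(
      item_id = img$item_id,
      category = img$category,
      hue = hsv$hue, saturation = hsv$saturation,
      color_value = hsv$color_value,
      sharpness = sharpness(img, mask = msk),
      spectral_slope = spectral_slope(img)$slope
    )
  })
}
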