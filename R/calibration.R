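## Colour-checker calibration.
##
## A 24-chip checker with known sRGB reference values is photographed in
## every scene.  Chip colours measured from the image are regressed onto the
## references, per output channel, over either a linear basis [1, R, G, B]
## or the quadratic cross-band basis
## [1, R, G, B, R^2, G^2, B^2, RG, RB, GB], and the fitted map is applied to
## the whole image.  Fitting happens in encoded (gamma) sRGB space on 0-255
## values; mean CIE76 delta E over the chips after calibration is the
## quality score.  Each light condition gets its own model.

#' Reference sRGB values of the 24-patch colour checker
#'
#' The classic 24-chip checker target (6 x 4 layout: four rows of colour,
#' skin/nature tones, primaries, and a six-step neutral ramp) with its
#' widely published nominal sRGB coordinates.
#'
#' @return A 24 x 3 numeric matrix (columns `R`, `G`, `B`, 0--255) with chip
#'   names as row names, chips numbered row-major from the top-left.
#' @export
colorchecker_srgb <- function() {
  vals <- matrix(c(
    115,  82,  68,   194, 150, 130,    98, 122, 157,    87, 108,  67,
    133, 128, 177,   103, 189, 170,   214, 126,  44,    80,  91, 166,
    193,  90,  99,    94,  60, 108,   157, 188,  64,   224, 163,  46,
     56,  61, 150,    70, 148,  73,   175,  54,  60,   231, 199,  31,
    187,  86, 149,     8, 133, 161,   243, 243, 242,   200, 200, 200,
    160, 160, 160,   122, 122, 121,    85,  85,  85,    52,  52,  52
  ), ncol = 3, byrow = TRUE)
  dimnames(vals) <- list(
    c("dark_skin", "light_skin", "blue_sky", "foliage", "blue_flower",
      "bluish_green", "orange", "purplish_blue", "moderate_red", "purple",
      "yellow_green", "orange_yellow", "blue", "green", "red", "yellow",
      "magenta", "cyan", "white", "neutral_8", "neutral_6_5", "neutral_5",
      "neutral_3_5", "black"),
    c("R", "G", "B"))
  vals
}

#' Rectangular chip layout for a rendered checker
#'
#' Builds the 6 x 4 grid of chip rectangles used both by the synthetic
#' renderer and by [measure_chips()].  Coordinates are 0-based pixels,
#' x rightward, y downward.
#'
#' @param x0,y0 Top-left corner of the checker area.
#' @param chip_size Chip edge length in pixels.
#' @param gap Gap between chips in pixels.
#' @return A list of 24 rectangles, each `list(chip_id, x, y, w, h)`,
#'   numbered row-major.
#' @export
checker_layout <- function(x0 = 0, y0 = 0, chip_size = 16, gap = 4) {
  out <- vector("list", 24L)
  k <- 0L
  for (row in 0:3) {
    for (col in 0:5) {
      k <- k + 1L
      out[[k]] <- list(chip_id = k,
                       x = x0 + col * (chip_size + gap),
                       y = y0 + row * (chip_size + gap),
                       w = chip_size, h = chip_size)
    }
  }
  out
}

.image_array <- function(image) {
  if (inherits(image, "synthetic_image")) image$pixels else image
}

#' Measure checker chips from an image
#'
#' Averages the interior pixels of each chip rectangle after trimming a
#' margin fraction per side (20% by default, so chip borders, overlay
#' strokes and slight misregistration do not contaminate the mean).
#'
#' @param image A `synthetic_image` or an h x w x 3 numeric array (0--255).
#' @param layout Chip rectangles as from [checker_layout()].
#' @param reference 24 x 3 matrix of reference sRGB values
#'   (default [colorchecker_srgb()]).
#' @param margin_fraction Fraction of the chip trimmed per side, in
#'   \[0, 0.5).
#' @param enabled Logical vector marking chips to keep (all by default).
#' @return A data frame with columns `chip_id`, `mR`, `mG`, `mB`
#'   (measured means) and `rR`, `rG`, `rB` (reference values).
#' @export
measure_chips <- function(image, layout, reference = colorchecker_srgb(),
                          margin_fraction = 0.2,
                          enabled = rep(TRUE, length(layout))) {
  px <- .image_array(image)
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("image must be an h x w x 3 array")
  if (margin_fraction < 0 || margin_fraction >= 0.5)
    stop("margin_fraction must lie in [0, 0.5)")
  h <- dim(px)[1]; w <- dim(px)[2]
  rows <- lapply(seq_along(layout), function(i) {
    if (!enabled[i]) return(NULL)
    rc <- layout[[i]]
    kx <- floor(rc$w * margin_fraction)
    ky <- floor(rc$h * margin_fraction)
    xs <- (rc$x + kx):(rc$x + rc$w - 1 - kx)   # 0-based pixel columns
    ys <- (rc$y + ky):(rc$y + rc$h - 1 - ky)
    if (length(xs) < 1L || length(ys) < 1L)
      stop("chip ", rc$chip_id, ": empty interior after margin trim")
    if (min(xs) < 0 || min(ys) < 0 || max(xs) >= w || max(ys) >= h)
      stop("chip ", rc$chip_id, " extends outside the image")
    block <- px[ys + 1L, xs + 1L, , drop = FALSE]
    m <- apply(block, 3, mean)
    data.frame(chip_id = rc$chip_id, mR = m[1], mG = m[2], mB = m[3],
               rR = reference[rc$chip_id, 1], rG = reference[rc$chip_id, 2],
               rB = reference[rc$chip_id, 3])
  })
  do.call(rbind, rows)
}

# Term basis for the calibration regression, on 0-255 encoded values.
.calibration_basis <- function(rgb, method) {
  R <- rgb[, 1]; G <- rgb[, 2]; B <- rgb[, 3]
  switch(method,
    linear = cbind(`1` = 1, R = R, G = G, B = B),
    quadratic_cross_band = cbind(
      `1` = 1, R = R, G = G, B = B,
      `R^2` = R^2, `G^2` = G^2, `B^2` = B^2,
      RG = R * G, RB = R * B, GB = G * B),
    stop("unknown calibration method '", method, "'"))
}

#' Fit a colour-checker calibration model
#'
#' Least-squares regression of reference chip colours on measured chip
#' colours, independently per output channel, in encoded sRGB space.  The
#' quadratic cross-band basis has 10 terms per channel
#' (1, R, G, B, R^2, G^2, B^2, RG, RB, GB); the linear basis has 4.
#'
#' @param measurements Data frame from [measure_chips()].
#' @param method `"quadratic_cross_band"` (default) or `"linear"`.
#' @param illum Illuminant used for the delta E quality score.
#' @param light_condition Optional label recorded on the model; a mismatch
#'   at application time is flagged.
#' @return An object of class `colour_calibration`: list with `method`,
#'   `basis` (term names), `coefficients` (terms x 3 matrix), `mean_delta`
#'   (mean CIE76 delta E over chips after calibration), `n_chips`,
#'   `light_condition`.
#' @export
fit_calibration <- function(measurements,
                            method = c("quadratic_cross_band", "linear"),
                            illum = illuminant(),
                            light_condition = NULL) {
  method <- match.arg(method)
  meas <- as.matrix(measurements[, c("mR", "mG", "mB")])
  ref <- as.matrix(measurements[, c("rR", "rG", "rB")])
  X <- .calibration_basis(meas, method)
  need <- ncol(X)
  if (nrow(X) < need)
    stop("need at least ", need, " chips for the ", method,
         " method, got ", nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient calibration design; dependent terms: ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qx, ref)
  rownames(coef) <- colnames(X)
  colnames(coef) <- c("R", "G", "B")
  fitted <- pmin(pmax(X %*% coef, 0), 255)
  mean_delta <- mean(delta_e76(srgb_to_lab(fitted, illum),
                               srgb_to_lab(ref, illum)))
  structure(list(method = method, basis = colnames(X), coefficients = coef,
                 mean_delta = mean_delta, n_chips = nrow(X),
                 illuminant = if (is.character(illum)) illum else illum$name,
                 light_condition = light_condition),
            class = "colour_calibration")
}

#' @export
print.colour_calibration <- function(x, ...) {
  cat("Colour-checker calibration (", x$method, ")\n", sep = "")
  if (!is.null(x$light_condition))
    cat("  light condition:", x$light_condition, "\n")
  cat("  chips used:     ", x$n_chips, "\n")
  cat("  mean delta E*ab:", format(x$mean_delta, digits = 4), "\n")
  invisible(x)
}

#' Apply a fitted calibration to colours or a whole image
#'
#' Maps 0--255 sRGB values through the fitted polynomial and clips the
#' result back to \[0, 255\].  If both the model and the image carry a light
#' condition label and they differ, a warning-level message is emitted (the
#' operation is legal but usually unintended: calibration is per condition).
#'
#' @param model A `colour_calibration` object.
#' @param x Triple, n x 3 matrix, h x w x 3 array, or `synthetic_image`.
#' @return Calibrated values with the same shape/class as the input.
#' @export
apply_calibration <- function(model, x) {
  stopifnot(inherits(model, "colour_calibration"))
  if (inherits(x, "synthetic_image")) {
    if (!is.null(model$light_condition) && !is.null(x$light_condition) &&
        !identical(model$light_condition, x$light_condition))
      message("note: applying calibration fitted for '",
              model$light_condition, "' to an image from '",
              x$light_condition, "'")
    x$pixels <- apply_calibration(model, x$pixels)
    return(x)
  }
  if (length(dim(x)) == 3L) {
    d <- dim(x)
    flat <- matrix(as.numeric(x), ncol = 3L)
    out <- apply_calibration(model, flat)
    return(array(out, dim = d))
  }
  m <- .as_rgb_matrix(x)
  out <- .calibration_basis(m, model$method) %*% model$coefficients
  out <- pmin(pmax(out, 0), 255)
  if (is.null(dim(x)) && length(x) == 3L) out[1, ] else out
}

#' Serialise / restore a calibration model as JSON
#'
#' @param model A `colour_calibration` object.
#' @param path File to write (`calibration_to_json`) or read
#'   (`calibration_from_json`).
#' @return `calibration_to_json` returns `path` invisibly;
#'   `calibration_from_json` returns the model.
#' @export
calibration_to_json <- function(model, path) {
  stopifnot(inherits(model, "colour_calibration"))
  obj <- list(method = model$method, basis = model$basis,
              coefficients = as.data.frame(model$coefficients),
              mean_delta = model$mean_delta, n_chips = model$n_chips,
              illuminant = model$illuminant,
              light_condition = model$light_condition)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration_to_json
#' @export
calibration_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- as.matrix(obj$coefficients)
  rownames(coef) <- obj$basis
  structure(list(method = obj$method, basis = obj$basis,
                 coefficients = coef, mean_delta = obj$mean_delta,
                 n_chips = obj$n_chips, illuminant = obj$illuminant,
                 light_condition = obj$light_condition),
            class = "colour_calibration")
}
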