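## sRGB <-> CIELab conversion.
##
## The pipeline is the standard one: piecewise sRGB decoding, the sRGB
## (IEC 61966-2-1) primaries to CIE XYZ, then XYZ to Lab against a chosen
## reference white.  No chromatic adaptation transform is applied: images are
## encoded as sRGB and the only free choice is the Lab reference white, which
## defaults to D65 with the 10 degree (1964) observer.

# Reference whites, Y normalised to 100.
.carotlab_illuminants <- list(
  D65_10 = c(X = 94.811, Y = 100, Z = 107.304),
  D65_2  = c(X = 95.047, Y = 100, Z = 108.883),
  D55_10 = c(X = 95.799, Y = 100, Z = 90.926),
  D55_2  = c(X = 95.682, Y = 100, Z = 92.149)
)

# sRGB linear RGB -> XYZ (D65 primaries), rows X, Y, Z.
.srgb_to_xyz_matrix <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

#' Illuminant / observer specification
#'
#' Returns the reference white used on the XYZ -> Lab leg of the conversion.
#' `D65_10` (D65, CIE 1964 10 degree observer) is the default throughout the
#' package.  Note that a D55-balanced acquisition light does not change this
#' choice: the conversion operates on sRGB-encoded values, and the reference
#' white only fixes the Lab origin.
#'
#' @param name One of `"D65_10"`, `"D65_2"`, `"D55_10"`, `"D55_2"`, or a
#'   custom white point given as `white_point`.
#' @param white_point Optional numeric XYZ triple (Y must be 100) overriding
#'   the named white.
#' @return A list with elements `name` and `white_point`.
#' @export
#' @examples
#' illuminant("D65_10")$white_point
illuminant <- function(name = "D65_10", white_point = NULL) {
  if (is.null(white_point)) {
    if (!name %in% names(.carotlab_illuminants))
      stop("unknown illuminant '", name, "'; known: ",
           paste(names(.carotlab_illuminants), collapse = ", "))
    white_point <- .carotlab_illuminants[[name]]
  } else {
    white_point <- as.numeric(white_point)
    names(white_point) <- c("X", "Y", "Z")
    if (abs(white_point["Y"] - 100) > 1e-6)
      stop("white point Y component must be normalised to 100")
  }
  list(name = name, white_point = white_point)
}

# Accept a length-3 vector or an n x 3 matrix; always return n x 3.
.as_rgb_matrix <- function(x, what = "rgb") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop(what, " must have 3 channels")
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != 3L) stop(what, " must have 3 columns")
  storage.mode(x) <- "double"
  x
}

.srgb_decode <- function(v) {
  # v in [0, 1] encoded -> linear
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

.srgb_encode <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert 8-bit sRGB colours to CIELab
#'
#' Decodes sRGB (piecewise gamma), maps through CIE XYZ with the sRGB
#' primaries, and expresses the result as L*, a*, b* relative to the chosen
#' reference white.
#'
#' @param rgb Numeric triple or n x 3 matrix of sRGB values on the 0--255
#'   scale (fractional values allowed; means over pixels are typical input).
#' @param illum An [illuminant()] specification or its name.
#' @return An n x 3 matrix with columns `L`, `a`, `b` (or a named triple if
#'   the input was a triple).
#' @seealso [lab_to_srgb()], [lab_to_lch()]
#' @export
#' @examples
#' srgb_to_lab(c(255, 128, 0))
srgb_to_lab <- function(rgb, illum = illuminant()) {
  if (is.character(illum)) illum <- illuminant(illum)
  x <- .as_rgb_matrix(rgb)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 255))
    stop("rgb channels must lie in [0, 255]")
  lin <- .srgb_decode(x / 255)
  xyz <- lin %*% t(.srgb_to_xyz_matrix) * 100
  wp <- illum$white_point
  fx <- .lab_f(xyz[, 1] / wp["X"])
  fy <- .lab_f(xyz[, 2] / wp["Y"])
  fz <- .lab_f(xyz[, 3] / wp["Z"])
  lab <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (is.null(dim(rgb)) && length(rgb) == 3L) lab[1, ] else lab
}

#' Convert CIELab colours back to 8-bit sRGB
#'
#' Exact inverse of [srgb_to_lab()] for in-gamut colours; out-of-gamut
#' results are clipped to \[0, 255\] unless `clip = FALSE`.
#'
#' @param lab Numeric triple or n x 3 matrix (columns L, a, b).
#' @param illum An [illuminant()] specification or its name.
#' @param clip Clip the result to the 0--255 range (default `TRUE`).
#' @return sRGB values on the 0--255 scale, same shape convention as input.
#' @export
lab_to_srgb <- function(lab, illum = illuminant(), clip = TRUE) {
  if (is.character(illum)) illum <- illuminant(illum)
  x <- .as_rgb_matrix(lab, "lab")
  wp <- illum$white_point
  fy <- (x[, 1] + 16) / 116
  fx <- fy + x[, 2] / 500
  fz <- fy - x[, 3] / 200
  xyz <- cbind(.lab_f_inv(fx) * wp["X"], .lab_f_inv(fy) * wp["Y"],
               .lab_f_inv(fz) * wp["Z"]) / 100
  lin <- xyz %*% t(solve(.srgb_to_xyz_matrix))
  rgb <- .srgb_encode(pmax(lin, 0)) * 255
  # encode() needs non-negative linear values; restore sign convention for
  # tiny negatives produced by round-off, then clip.
  neg <- lin < 0
  if (any(neg)) rgb[neg] <- -.srgb_encode(-lin[neg]) * 255
  if (clip) rgb <- pmin(pmax(rgb, 0), 255)
  if (is.null(dim(lab)) && length(lab) == 3L) {
    out <- rgb[1, ]
    names(out) <- c("R", "G", "B")
    out
  } else {
    colnames(rgb) <- c("R", "G", "B")
    rgb
  }
}

#' Derive chroma and hue angle from CIELab
#'
#' Computes the cylindrical coordinates of the (a*, b*) plane:
#' C* = sqrt(a*^2 + b*^2) and h = atan2(b*, a*) expressed in degrees on
#' \[0, 360).  When a* = b* = 0 the hue is undefined; it is reported as 0 and
#' flagged via the `"hue_undefined"` attribute.
#'
#' @param lab Numeric triple or n x 3 matrix (columns L, a, b).
#' @return Matrix with columns `L`, `C`, `h` (degrees), or a named triple for
#'   triple input, with logical attribute `hue_undefined`.
#' @export
#' @examples
#' lab_to_lch(c(50, 3, 4))   # C = 5, h = 53.130
lab_to_lch <- function(lab) {
  x <- .as_rgb_matrix(lab, "lab")
  C <- sqrt(x[, 2]^2 + x[, 3]^2)
  h <- (atan2(x[, 3], x[, 2]) * 180 / pi) %% 360
  undef <- x[, 2] == 0 & x[, 3] == 0
  h[undef] <- 0
  out <- cbind(L = x[, 1], C = C, h = h)
  if (is.null(dim(lab)) && length(lab) == 3L) {
    out <- out[1, ]
    attr(out, "hue_undefined") <- unname(undef)
  } else {
    attr(out, "hue_undefined") <- unname(undef)
  }
  out
}

#' Convert L, C*, h back to CIELab
#'
#' @param lch Numeric triple or n x 3 matrix (columns L, C, h in degrees).
#' @return Lab values, same shape convention as input.
#' @export
lch_to_lab <- function(lch) {
  x <- .as_rgb_matrix(lch, "lch")
  if (any(x[, 2] < 0)) stop("chroma must be non-negative")
  a <- x[, 2] * cos(x[, 3] * pi / 180)
  b <- x[, 2] * sin(x[, 3] * pi / 180)
  out <- cbind(L = x[, 1], a = a, b = b)
  if (is.null(dim(lch)) && length(lch) == 3L) out[1, ] else out
}

#' CIE76 colour difference
#'
#' Euclidean distance in CIELab, the "delta E" used to score calibration
#' quality.
#'
#' @param lab1,lab2 Lab triples or n x 3 matrices (recycled row-wise if one
#'   side is a single triple).
#' @return Numeric vector of distances.
#' @export
delta_e76 <- function(lab1, lab2) {
  a <- .as_rgb_matrix(lab1, "lab1")
  b <- .as_rgb_matrix(lab2, "lab2")
  if (nrow(a) == 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("lab1 and lab2 must have matching rows")
  sqrt(rowSums((a - b)^2))
}
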