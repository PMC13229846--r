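# Shared fixtures, built in code at test time.

# Identity light conditions: no gain, offset, gamma or glare distortion.
identity_conditions <- function(glare = 0) {
  lapply(light_conditions(exposure_k = 0), function(cc) {
    cc$offset <- c(0, 0, 0)
    cc$gamma <- 1
    cc$glare <- glare
    cc
  })
}

# A small uniform-colour image block.
uniform_image <- function(h, w, rgb) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# Checker "photo": each chip filled with a given 24 x 3 colour matrix.
checker_image <- function(fill, layout = checker_layout(2, 2, 10, 2),
                          h = 60, w = 80, bg = c(0, 0, 0)) {
  img <- uniform_image(h, w, bg)
  for (rc in layout) {
    ys <- (rc$y + 1):(rc$y + rc$h)
    xs <- (rc$x + 1):(rc$x + rc$w)
    for (ch in 1:3) img[ys, xs, ch] <- fill[rc$chip_id, ch]
  }
  list(image = img, layout = layout)
}

# Apply a quadratic cross-band map (10-term basis, 0-255 space) to colours.
quad_map <- function(rgb, coef) {
  R <- rgb[, 1]; G <- rgb[, 2]; B <- rgb[, 3]
  X <- cbind(1, R, G, B, R^2, G^2, B^2, R * G, R * B, G * B)
  X %*% coef
}

# A mild random quadratic cross-band distortion near the identity, gentle
# enough that the 24 checker chips stay strictly inside [0, 255] (clipping
# would break the exact-quadratic relation the recovery tests rely on).
random_quad_coef <- function(seed) {
  set.seed(seed)
  coef <- matrix(0, 10, 3)
  diag_gain <- stats::runif(3, 0.88, 0.97)
  coef[2, 1] <- diag_gain[1]; coef[3, 2] <- diag_gain[2]
  coef[4, 3] <- diag_gain[3]
  coef[1, ] <- stats::runif(3, 1, 5)
  coef[5:10, ] <- matrix(stats::rnorm(18, 0, 4e-5), 6, 3)
  out <- quad_map(colorchecker_srgb(), coef)
  stopifnot(all(out > 0), all(out < 255))
  coef
}

# Independently coded sRGB -> Lab oracle (scalar, loop-based, D65/2deg),
# anchored below to published conversion values for the sRGB primaries.
oracle_srgb_to_lab <- function(rgb) {
  out <- matrix(NA_real_, nrow(rgb), 3)
  M <- rbind(c(0.4124564, 0.3575761, 0.1804375),
             c(0.2126729, 0.7151522, 0.0721750),
             c(0.0193339, 0.1191920, 0.9503041))
  wp <- c(95.047, 100, 108.883)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else
    t / (3 * (6 / 29)^2) + 4 / 29
  for (i in seq_len(nrow(rgb))) {
    lin <- numeric(3)
    for (ch in 1:3) {
      v <- rgb[i, ch] / 255
      lin[ch] <- if (v <= 0.04045) v / 12.92 else ((v + 0.055) / 1.055)^2.4
    }
    xyz <- as.vector(M %*% lin) * 100
    fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
    out[i, ] <- c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  }
  out
}

# The five colour predictors from a truth table.
predictor_cols <- c("L_star", "a_star", "b_star", "C_star", "h_deg")
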