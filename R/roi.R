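## Region-of-interest colour extraction.
##
## Disk perimeters are traced once as polygons (0-based pixel coordinates,
## x rightward, y downward) and the same polygon is reused across all light
## conditions of the same sample.  A pixel belongs to the mask iff its
## centre (i + 0.5, j + 0.5) falls inside the polygon under the even-odd
## fill rule.

#' Rasterise a polygon to a pixel mask
#'
#' Even-odd (crossing-number) fill with pixel centres tested.  Pixel (x, y)
#' (0-based) has its centre at (x + 0.5, y + 0.5).  The same polygon always
#' produces the same mask for images of equal shape, which is what lets one
#' hand-drawn region be applied across all light conditions.
#'
#' @param polygon n x 2 matrix (or list of `c(x, y)` pairs) of vertices in
#'   0-based pixel coordinates; at least 3 vertices; closing edge implicit.
#' @param image_shape `c(height, width)` in pixels.
#' @return Logical height x width matrix; `TRUE` marks interior pixels.
#' @export
#' @examples
#' m <- rasterise_polygon(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
#'                        c(20, 20))
#' sum(m)  # 100 interior pixel centres
rasterise_polygon <- function(polygon, image_shape) {
  if (is.list(polygon)) polygon <- do.call(rbind, polygon)
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  if (ncol(polygon) != 2L) stop("polygon must be n x 2 (x, y)")
  # shoelace area; zero area means a degenerate polygon
  xs <- polygon[, 1]; ys <- polygon[, 2]
  nxt <- c(2:nrow(polygon), 1L)
  area <- abs(sum(xs * ys[nxt] - xs[nxt] * ys)) / 2
  if (area == 0) stop("degenerate polygon (zero area)")
  h <- image_shape[1]; w <- image_shape[2]
  px <- rep(seq_len(w) - 0.5, each = h)   # centre x per matrix cell
  py <- rep(seq_len(h) - 0.5, times = w)  # centre y
  inside <- rep(FALSE, h * w)
  for (k in seq_len(nrow(polygon))) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xs[nxt[k]]; y2 <- ys[nxt[k]]
    if (y1 == y2) next
    crosses <- (y1 > py) != (y2 > py)
    xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
    inside <- xor(inside, crosses & (px < xint))
  }
  matrix(inside, nrow = h, ncol = w)
}

#' Mean and SD colour over a pixel mask
#'
#' Per-channel arithmetic mean and population standard deviation of the
#' masked pixels (population SD: at typical disk pixel counts the n vs n-1
#' distinction is immaterial, and the SD describes the pixel population of
#' the region, not a sample from it).
#'
#' @param image A `synthetic_image` or h x w x 3 array (0--255).
#' @param mask Logical h x w matrix from [rasterise_polygon()].
#' @return List of class `rgb_measurement`: `mean_rgb`, `sd_rgb` (named
#'   length-3 vectors), `n_pixels`.
#' @export
roi_colour <- function(image, mask) {
  px <- .image_array(image)
  if (!all(dim(px)[1:2] == dim(mask)))
    stop("mask shape does not match image shape")
  n <- sum(mask)
  if (n < 1L) stop("empty mask: no pixels selected")
  vals <- vapply(1:3, function(ch) {
    v <- px[, , ch][mask]
    c(mean(v), sqrt(mean((v - mean(v))^2)))
  }, numeric(2))
  structure(list(mean_rgb = stats::setNames(vals[1, ], c("R", "G", "B")),
                 sd_rgb = stats::setNames(vals[2, ], c("R", "G", "B")),
                 n_pixels = n),
            class = "rgb_measurement")
}

#' @export
print.rgb_measurement <- function(x, ...) {
  cat(sprintf("ROI colour: mean RGB (%.2f, %.2f, %.2f), SD (%.2f, %.2f, %.2f), n = %d\n",
              x$mean_rgb[1], x$mean_rgb[2], x$mean_rgb[3],
              x$sd_rgb[1], x$sd_rgb[2], x$sd_rgb[3], x$n_pixels))
  invisible(x)
}

#' Read / write ROI polygon sets as JSON
#'
#' A ROI set is a named list of polygons, each an n x 2 matrix of
#' `[x, y]` 0-based pixel vertices.
#'
#' @param rois Named list of polygons.
#' @param path JSON file path.
#' @return `write_rois` returns `path` invisibly; `read_rois` the list.
#' @export
write_rois <- function(rois, path) {
  obj <- lapply(rois, function(p) {
    p <- if (is.list(p)) do.call(rbind, p) else as.matrix(p)
    unname(lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ])))
  })
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(p) {
    m <- if (is.list(p)) do.call(rbind, lapply(p, as.numeric)) else as.matrix(p)
    colnames(m) <- c("x", "y")
    m
  })
}
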