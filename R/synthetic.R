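## Synthetic study generator.
##
## Emulates the field study the pipeline is built for: 16 carrot cultivars
## (white / yellow / orange / red / purple / purple-yellow), 6 replicate
## disks each, photographed under 6 light conditions (two environments, WF
## without and PF with polarisation, crossed with relative exposure steps).
## Each rendered scene holds the 24-chip colour checker plus the replicate
## disks on a blue background.  Ground truth is a per-disk CIELab colour
## drawn around the cultivar mean, and a pigment panel generated from a
## linear latent link
##    pigment = b0 + b . (L*, a*, b*, C*, h deg) + Gaussian noise
## -- the generative inverse of the PLS model the pipeline fits, so that
## parameter recovery is a meaningful end-to-end check.  Wet-lab absorbance
## tables are produced by algebraically inverting the pigment equations, so
## the chemistry stage reproduces the truth exactly in the noiseless case.

.predictor_names <- c("L_star", "a_star", "b_star", "C_star", "h_deg")

.lab_to_predictors <- function(lab) {
  lab <- .as_rgb_matrix(lab, "lab")
  lch <- lab_to_lch(lab)
  lch <- if (is.null(dim(lch))) matrix(lch, nrow = 1) else lch
  out <- cbind(lab[, 1], lab[, 2], lab[, 3], lch[, 2], lch[, 3])
  colnames(out) <- .predictor_names
  out
}

#' The six imaging light conditions
#'
#' Two environments -- `WF` (no filter; four LED panels, specular glare from
#' moist disk surfaces reaches the sensor) and `PF` (cross-polarised; glare
#' suppressed) -- crossed with relative exposure steps.  Each condition
#' carries a global colour distortion (per-channel gain `2^(step * k)`,
#' additive offset, tone-curve gamma) and a specular-glare amplitude that is
#' zero for the polarised environment.
#'
#' @param exposure_k Exposure-to-gain constant `k` (default 0.06).
#' @return A list of 6 condition specs: `name`, `environment`,
#'   `exposure_step`, `exposure_time_s`, `gain` (length-3), `offset`
#'   (length-3), `gamma`, `glare`.
#' @export
light_conditions <- function(exposure_k = 0.06) {
  spec <- list(
    list(name = "WF-1", environment = "WF", exposure_step = -1L,
         exposure_time_s = 1 / 25, offset = c(3, 1, -2), gamma = 0.96,
         glare = 14),
    list(name = "WF0", environment = "WF", exposure_step = 0L,
         exposure_time_s = 1 / 50, offset = c(0, 0, 0), gamma = 1.00,
         glare = 12),
    list(name = "WF+1", environment = "WF", exposure_step = 1L,
         exposure_time_s = 1 / 100, offset = c(-2, 0, 2), gamma = 1.04,
         glare = 10),
    list(name = "PF0", environment = "PF", exposure_step = 0L,
         exposure_time_s = 1 / 100, offset = c(1, -1, 1), gamma = 1.00,
         glare = 0),
    list(name = "PF+1", environment = "PF", exposure_step = 1L,
         exposure_time_s = 1 / 60, offset = c(2, 1, -1), gamma = 1.03,
         glare = 0),
    list(name = "PF+2", environment = "PF", exposure_step = 2L,
         exposure_time_s = 1 / 30, offset = c(-3, 2, 0), gamma = 1.06,
         glare = 0))
  lapply(spec, function(cc) {
    cc$gain <- rep(2^(cc$exposure_step * exposure_k), 3)
    cc
  })
}

#' Default cultivar panel
#'
#' Sixteen cultivars spanning the four colour clusters seen in diverse
#' carrot germplasm: one white (`W1`), two yellow (`Y1`, `Y2`), nine orange
#' (`O1`--`O9`), one red (`R1`), two fully purple (`P1`, `P2`) and one
#' purple with a yellow core (`PY1`, which sits with the orange/red cluster
#' in colour space).  Mean flesh colours are hand-set so that white has the
#' highest L*, purple the lowest, yellow low a* / high b*, and orange/red
#' high a*; only this qualitative ordering is meaningful.
#'
#' @param lab_sd Per-channel within-cultivar biological SD of the flesh
#'   colour (Lab units).
#' @return List of cultivar specs: `code`, `colour_group`, `mean_lab`,
#'   `lab_sd`.
#' @export
default_cultivars <- function(lab_sd = c(1.5, 1.2, 1.5)) {
  mk <- function(code, group, L, a, b)
    list(code = code, colour_group = group,
         mean_lab = c(L = L, a = a, b = b), lab_sd = lab_sd)
  list(
    mk("W1", "white", 78, 2, 12),
    mk("Y1", "yellow", 68, 2, 55),
    mk("Y2", "yellow", 65, 6, 60),
    mk("O1", "orange", 56, 28, 42),
    mk("O2", "orange", 52, 34, 38),
    mk("O3", "orange", 58, 26, 44),
    mk("O4", "orange", 55, 30, 42),
    mk("O5", "orange", 53, 33, 40),
    mk("O6", "orange", 54, 32, 39),
    mk("O7", "orange", 57, 29, 45),
    mk("O8", "orange", 55, 31, 41),
    mk("O9", "orange", 51, 36, 37),
    mk("R1", "red", 44, 38, 28),
    mk("P1", "purple", 24, 12, -8),
    mk("P2", "purple", 28, 14, -4),
    mk("PY1", "purple_yellow", 42, 30, 30))
}

# Solve for link coefficients that take the colour-cluster means close to
# realistic cluster-mean pigment targets.  A ridge penalty on the slope
# terms (heavier on the hue angle, whose 0/360 wrap makes large hue
# coefficients unphysical) keeps the link gentle, so that the linear model
# with additive noise remains a well-specified description of the study:
# the link stays positive with comfortable margin at every cluster and
# truncation at zero is a rare event rather than a structural feature.
.solve_link <- function(cluster_lab, targets, lambda = 10) {
  X <- cbind(1, .lab_to_predictors(cluster_lab))
  D <- diag(c(0, 1, 1, 1, 1, 5))
  b <- drop(solve(crossprod(X) + lambda * crossprod(D), crossprod(X, targets)))
  names(b) <- c("intercept", .predictor_names)
  b
}

#' Generative colour-to-pigment links
#'
#' Linear links pigment = b0 + b . (L*, a*, b*, C*, h) whose coefficients
#' are solved (ridge-stabilised) so that the six colour-cluster means map
#' close to realistic cluster-level contents (mg/100 g FW): total
#' carotenoids around 8.5--9.5 for orange, 13--15 for red, 5--7 for the
#' purple-yellow cultivar and low (1--2.5) for white/yellow/purple; total
#' anthocyanins around 40 for fully purple, 5--6 for purple-yellow and
#' near zero elsewhere.
#'
#' @param cultivars Cultivar panel, as from [default_cultivars()].
#' @return List with named coefficient vectors `tcc` and `tac`
#'   (`intercept`, `L_star`, `a_star`, `b_star`, `C_star`, `h_deg`).
#' @export
default_links <- function(cultivars = default_cultivars()) {
  groups <- vapply(cultivars, `[[`, "", "colour_group")
  labs <- t(vapply(cultivars, `[[`, numeric(3), "mean_lab"))
  cluster <- function(g) colMeans(labs[groups %in% g, , drop = FALSE])
  centres <- rbind(white = cluster("white"), yellow = cluster("yellow"),
                   orange = cluster("orange"), red = cluster("red"),
                   purple = cluster("purple"),
                   purple_yellow = cluster("purple_yellow"))
  list(
    tcc = .solve_link(centres, c(1.2, 2.0, 8.5, 15, 2.5, 5.2)),
    tac = .solve_link(centres, c(0.3, 0.3, 0.5, 1.0, 40, 6)))
}

#' Synthetic study design
#'
#' Bundles everything that determines a synthetic study: the cultivar
#' panel, replicate count, light conditions, generative links, noise model,
#' wet-lab assay constants and scene geometry.  A design plus its seed
#' fully determines every downstream output.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param cultivars Cultivar panel ([default_cultivars()]).
#' @param n_replicates Disks per cultivar (default 6; with 16 cultivars,
#'   96 roots).
#' @param light_conditions Light conditions ([light_conditions()]).
#' @param link Generative links ([default_links()]).
#' @param pigment_noise_sd Named additive-Gaussian SDs per pigment
#'   (mg/100 g FW); draws are truncated at zero since contents are physical
#'   concentrations.
#' @param pixel_noise_sd Per-pixel sensor noise SD in 8-bit units.
#' @param absorbance_noise_sd Measurement noise on inverted absorbances
#'   (default 0: exact round trip).
#' @param assay Wet-lab constants (masses, volumes, dilution factor,
#'   anthocyanin molar constants, baseline absorbances).
#' @param geometry Scene geometry (image size, chip size/gap, disk radius,
#'   ROI radius).
#' @return Object of class `study_design`.
#' @export
study_design <- function(seed,
                         cultivars = default_cultivars(),
                         n_replicates = 6L,
                         light_conditions = carotlab::light_conditions(),
                         link = default_links(cultivars),
                         pigment_noise_sd = c(tcc = 0.5, tac = 3,
                                              lutein = 0.05, lycopene = 0.45,
                                              alpha_carotene = 0.3,
                                              beta_carotene = 0.5),
                         pixel_noise_sd = 1.5,
                         absorbance_noise_sd = 0,
                         assay = list(tcc_mass_g = 0.5, tcc_volume_mL = 3,
                                      tac_mass_g = 1, tac_volume_mL = 10,
                                      DF = 40, MW = 449.2, EF = 26900,
                                      path_length_cm = 1,
                                      A520_pH45 = 0.15, A700 = 0.02),
                         geometry = list(width = 140L, height = 168L,
                                         checker_x = 8L, checker_y = 6L,
                                         chip_size = 16L, chip_gap = 4L,
                                         disk_radius = 12, roi_radius = 8)) {
  if (missing(seed)) stop("a seed is mandatory for a study design")
  for (cu in cultivars) {
    if (any(cu$lab_sd < 0)) stop("lab_sd must be non-negative")
  }
  if (any(pigment_noise_sd < 0)) stop("pigment noise SDs must be non-negative")
  if (n_replicates < 1L) stop("need at least one replicate")
  # disk centres: rows of 3 below the checker
  g <- geometry
  checker_h <- 4 * (g$chip_size + g$chip_gap) - g$chip_gap
  n_rows <- ceiling(n_replicates / 3)
  step_y <- 2 * g$disk_radius + 10
  need_h <- g$checker_y + checker_h + 14 + n_rows * step_y
  if (need_h > g$height)
    stop("layout error: ", n_replicates,
         " disks do not fit the image height without overlap")
  centres <- list()
  for (i in seq_len(n_replicates)) {
    row <- (i - 1L) %/% 3L
    col <- (i - 1L) %% 3L
    centres[[i]] <- c(x = 30 + col * 40,
                      y = g$checker_y + checker_h + 14 + g$disk_radius +
                        row * step_y)
  }
  g$disk_centres <- centres
  # moisture fraction per cultivar (deterministic, realistic range)
  moisture <- 0.86 + 0.04 * (seq_along(cultivars) - 1) /
    max(1, length(cultivars) - 1)
  names(moisture) <- vapply(cultivars, `[[`, "", "code")
  # per-cultivar mean pigment panel implied by the links
  cultivars <- lapply(cultivars, function(cu) {
    pred <- .lab_to_predictors(cu$mean_lab)[1, ]
    mu_tcc <- max(0, unname(link$tcc[1] + sum(link$tcc[-1] * pred)))
    mu_tac <- if (cu$colour_group %in% c("purple", "purple_yellow", "red"))
      max(0, unname(link$tac[1] + sum(link$tac[-1] * pred))) else 0
    cu$pigment_means <- c(
      tcc = mu_tcc, tac = mu_tac,
      lutein = 0.02 * mu_tcc + 0.08, lycopene = if (cu$colour_group == "red") 1.66 else 0,
      alpha_carotene = 0.20 * mu_tcc, beta_carotene = 0.62 * mu_tcc)
    cu$pigment_sds <- pigment_noise_sd
    cu
  })
  structure(list(seed = as.integer(seed), cultivars = cultivars,
                 n_replicates = as.integer(n_replicates),
                 light_conditions = light_conditions, link = link,
                 pigment_noise_sd = pigment_noise_sd,
                 pixel_noise_sd = pixel_noise_sd,
                 absorbance_noise_sd = absorbance_noise_sd,
                 assay = assay, geometry = g, moisture = moisture),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Synthetic study design:", length(x$cultivars), "cultivars x",
      x$n_replicates, "replicates,", length(x$light_conditions),
      "light conditions, seed", x$seed, "\n")
  invisible(x)
}

#' Invert the pigment equations to wet-lab absorbances
#'
#' Produces the absorbance readings that, fed forward through
#' [lichtenthaler_tcc()] and [ph_differential_tac()], reproduce the given
#' pigment contents.  Carrot extracts are chlorophyll-free, so the
#' total-carotenoid inversion sets A662 = A645 = 0 and
#' A470 = 227 Cx+c path / 1000; anthocyanin absorbances are built over
#' fixed baseline readings in the pH 4.5 buffer.
#'
#' @param panel Data frame with columns `tcc` and optionally `tac`
#'   (mg/100 g FW; `tac = NA` skips the anthocyanin assay for that row) and
#'   `moisture_fraction`.
#' @param assay Assay constants, as in [study_design()].
#' @param noise_sd Gaussian measurement noise added to the absorbances
#'   (truncated at zero; default 0 for an exact round trip).
#' @return Data frame with columns `A662`, `A645`, `A470`, `A520_pH1`,
#'   `A700_pH1`, `A520_pH45`, `A700_pH45` (anthocyanin columns `NA` where
#'   `tac` was `NA`).
#' @export
invert_pigment_equations <- function(panel,
                                     assay = study_design(seed = 1)$assay,
                                     noise_sd = 0) {
  if (any(panel$tcc < 0, na.rm = TRUE) || any(panel$tac < 0, na.rm = TRUE))
    stop("target contents must be non-negative")
  m <- panel$moisture_fraction
  p <- assay$path_length_cm
  # mg/100 g FW -> ug/mL in extract -> A470 (chlorophyll-free)
  cxc <- panel$tcc * 10 * assay$tcc_mass_g /
    (assay$tcc_volume_mL * (1 - m))
  A470 <- 227 * cxc * p / 1000
  out <- data.frame(A662 = 0, A645 = 0, A470 = A470,
                    A520_pH1 = NA_real_, A700_pH1 = NA_real_,
                    A520_pH45 = NA_real_, A700_pH45 = NA_real_)
  has_tac <- !is.na(panel$tac)
  if (any(has_tac)) {
    tac_mg_L <- panel$tac[has_tac] * 10 * assay$tac_mass_g /
      (assay$tac_volume_mL * (1 - m[has_tac]))
    A <- tac_mg_L * assay$EF / (assay$MW * assay$DF * 1000) * p
    out$A520_pH45[has_tac] <- assay$A520_pH45
    out$A700_pH45[has_tac] <- assay$A700
    out$A700_pH1[has_tac] <- assay$A700
    out$A520_pH1[has_tac] <- A + assay$A520_pH45
  }
  if (noise_sd > 0) {
    for (col in c("A470", "A520_pH1", "A520_pH45"))
      out[[col]] <- pmax(0, out[[col]] + stats::rnorm(nrow(out), 0, noise_sd))
  }
  attr(out, "chlorophyll_free") <- TRUE
  out
}

# circular ROI polygon (16-gon), 0-based pixel coordinates
.disk_polygon <- function(centre, radius, n = 16L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = centre["x"] + radius * cos(th),
        y = centre["y"] + radius * sin(th))
}

# Render one scene (checker + disks) and apply the condition's distortion.
.render_scene <- function(design, disk_rgb, condition, pixel_noise_sd) {
  g <- design$geometry
  h <- g$height; w <- g$width
  img <- array(0, dim = c(h, w, 3))
  bg <- c(40, 70, 140)                       # blue background
  for (ch in 1:3) img[, , ch] <- bg[ch]
  layout <- checker_layout(g$checker_x, g$checker_y, g$chip_size, g$chip_gap)
  ref <- colorchecker_srgb()
  for (rc in layout) {
    ys <- (rc$y + 1):(rc$y + rc$h)
    xs <- (rc$x + 1):(rc$x + rc$w)
    for (ch in 1:3) img[ys, xs, ch] <- ref[rc$chip_id, ch]
  }
  # disks with specular glare (WF only): localized Gaussian highlight
  cx_grid <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
  cy_grid <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)
  for (i in seq_len(nrow(disk_rgb))) {
    ctr <- g$disk_centres[[i]]
    d2 <- (cx_grid - ctr["x"])^2 + (cy_grid - ctr["y"])^2
    mask <- d2 <= g$disk_radius^2
    glare_add <- 0
    if (condition$glare > 0) {
      gx <- ctr["x"] + g$disk_radius / 3
      gy <- ctr["y"] - g$disk_radius / 3
      sg <- g$disk_radius / 4
      glare_add <- condition$glare *
        exp(-((cx_grid - gx)^2 + (cy_grid - gy)^2) / (2 * sg^2))
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- disk_rgb[i, ch] + if (is.matrix(glare_add))
        glare_add[mask] else 0
      img[, , ch] <- plane
    }
  }
  # exposure / white-balance distortion, then sensor noise, then 8-bit
  for (ch in 1:3) {
    v <- pmax(img[, , ch], 0) / 255
    img[, , ch] <- condition$gain[ch] * 255 * v^condition$gamma +
      condition$offset[ch]
  }
  if (pixel_noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, pixel_noise_sd), dim(img))
  round(pmin(pmax(img, 0), 255))
}

#' Generate a complete synthetic study
#'
#' Draws per-disk true colours and pigment panels, builds the wet-lab
#' absorbance table by inverting the pigment equations, and (optionally)
#' renders one checker-plus-disks image per cultivar and light condition.
#' The seed in the design fully determines every output; the truth and
#' wet-lab tables do not depend on whether images are rendered.
#'
#' The anthocyanin assay is generated for the cultivars that carry
#' anthocyanins, mirroring realistic sample availability: all replicates of
#' the purple and purple-yellow cultivars except the second purple cultivar
#' (3 replicates) and the red cultivar (1 replicate).
#'
#' @param design A [study_design()].
#' @param render_images Render pixel data (default `TRUE`); `FALSE` returns
#'   truth and wet-lab tables only, which is much faster for statistical
#'   simulations.
#' @return Object of class `carot_study`: list with `images` (named list of
#'   `synthetic_image` objects, or `NULL`), `truth` (data frame: one row per
#'   disk per light condition with true colour and pigment panel), `wetlab`
#'   (absorbance table, one row per assayed disk), `design`.
#' @export
generate_study <- function(design, render_images = TRUE) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  cultivars <- design$cultivars
  nrep <- design$n_replicates
  nsd <- design$pigment_noise_sd

  ## 1. per-disk truth (colour, then pigments through the links)
  disk_rows <- list()
  for (cu in cultivars) {
    for (r in seq_len(nrep)) {
      lab <- cu$mean_lab + stats::rnorm(3) * cu$lab_sd
      lab[1] <- min(max(lab[1], 0), 100)
      pred <- .lab_to_predictors(lab)[1, ]
      mu_tcc <- unname(design$link$tcc[1] + sum(design$link$tcc[-1] * pred))
      tcc <- max(0, mu_tcc + stats::rnorm(1, 0, nsd["tcc"]))
      anth <- cu$colour_group %in% c("purple", "purple_yellow", "red")
      mu_tac <- if (anth)
        unname(design$link$tac[1] + sum(design$link$tac[-1] * pred)) else 0
      tac <- if (anth) max(0, mu_tac + stats::rnorm(1, 0, nsd["tac"])) else 0
      lut <- max(0, 0.02 * mu_tcc + 0.08 + stats::rnorm(1, 0, nsd["lutein"]))
      lyc <- if (cu$colour_group == "red")
        max(0, 1.66 + stats::rnorm(1, 0, nsd["lycopene"])) else 0
      alp <- max(0, 0.20 * mu_tcc + stats::rnorm(1, 0, nsd["alpha_carotene"]))
      bet <- max(0, 0.62 * mu_tcc + stats::rnorm(1, 0, nsd["beta_carotene"]))
      disk_rows[[length(disk_rows) + 1L]] <- data.frame(
        cultivar = cu$code, colour_group = cu$colour_group, replicate = r,
        L_star = pred[1], a_star = pred[2], b_star = pred[3],
        C_star = pred[4], h_deg = pred[5],
        tcc = tcc, tac = tac, lutein = lut, lycopene = lyc,
        alpha_carotene = alp, beta_carotene = bet,
        moisture_fraction = unname(design$moisture[cu$code]))
    }
  }
  disks <- do.call(rbind, disk_rows)
  rownames(disks) <- NULL

  ## 2. wet-lab absorbance table (anthocyanin assay only where available)
  tac_reps <- function(group, code) {
    if (group == "purple" && grepl("2$", code)) 3L
    else if (group %in% c("purple", "purple_yellow")) nrep
    else if (group == "red") 1L
    else 0L
  }
  panel <- disks
  panel$tac_assay <- mapply(function(g, c, r) r <= tac_reps(g, c),
                            panel$colour_group, panel$cultivar,
                            panel$replicate)
  panel$tac[!panel$tac_assay] <- NA
  abs_tab <- invert_pigment_equations(
    data.frame(tcc = panel$tcc, tac = panel$tac,
               moisture_fraction = panel$moisture_fraction),
    assay = design$assay, noise_sd = design$absorbance_noise_sd)
  wetlab <- cbind(panel[, c("cultivar", "replicate", "moisture_fraction")],
                  abs_tab)

  ## 3. truth table: one row per disk per light condition
  cond_names <- vapply(design$light_conditions, `[[`, "", "name")
  truth <- do.call(rbind, lapply(cond_names, function(cn) {
    d <- disks
    d$light_condition <- cn
    d
  }))
  rownames(truth) <- NULL

  ## 4. rendered scenes (one per cultivar x condition)
  images <- NULL
  if (render_images) {
    images <- list()
    for (cu in cultivars) {
      idx <- disks$cultivar == cu$code
      disk_rgb <- lab_to_srgb(as.matrix(disks[idx, c("L_star", "a_star",
                                                     "b_star")]))
      for (cond in design$light_conditions) {
        key <- paste(cu$code, cond$name, sep = "_")
        px <- .render_scene(design, disk_rgb, cond, design$pixel_noise_sd)
        rois <- lapply(seq_len(nrep), function(i)
          .disk_polygon(design$geometry$disk_centres[[i]],
                        design$geometry$roi_radius))
        names(rois) <- paste0(cu$code, "_r", seq_len(nrep))
        images[[key]] <- structure(
          list(pixels = px, roi_polygons = rois,
               checker_layout = checker_layout(design$geometry$checker_x,
                                               design$geometry$checker_y,
                                               design$geometry$chip_size,
                                               design$geometry$chip_gap),
               checker_reference = colorchecker_srgb(),
               cultivar = cu$code, light_condition = cond$name,
               truth = disks[idx, c("cultivar", "replicate", "L_star",
                                    "a_star", "b_star")]),
          class = "synthetic_image")
      }
    }
  }
  structure(list(images = images, truth = truth, wetlab = wetlab,
                 design = design),
            class = "carot_study")
}

#' @export
print.carot_study <- function(x, ...) {
  cat("Synthetic carrot study:", nrow(x$truth), "truth rows (",
      length(unique(x$truth$cultivar)), "cultivars x",
      x$design$n_replicates, "replicates x",
      length(unique(x$truth$light_condition)), "conditions ),",
      if (is.null(x$images)) "no images rendered"
      else paste(length(x$images), "images"), "\n")
  invisible(x)
}

#' @export
print.synthetic_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("Synthetic image ", x$cultivar, " / ", x$light_condition, ": ",
      d[2], " x ", d[1], " px, ", length(x$roi_polygons), " disk ROIs\n",
      sep = "")
  invisible(x)
}

#' Persist a synthetic study to disk
#'
#' Writes PNG images, ROI polygons (JSON), truth and wet-lab tables (CSV)
#' and the key design parameters (YAML) under a directory, in the layout
#' the `real` pipeline mode consumes.
#'
#' @param study A `carot_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "carot_study"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "rois"), showWarnings = FALSE)
  if (!is.null(study$images)) {
    for (key in names(study$images)) {
      img <- study$images[[key]]
      png::writePNG(img$pixels / 255,
                    file.path(dir, "images", paste0(key, ".png")))
    }
    # one ROI file per cultivar (the same polygons serve all 6 conditions)
    done <- character(0)
    for (img in study$images) {
      if (img$cultivar %in% done) next
      write_rois(img$roi_polygons,
                 file.path(dir, "rois", paste0(img$cultivar, ".json")))
      done <- c(done, img$cultivar)
    }
  }
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(study$wetlab, file.path(dir, "wetlab.csv"),
                   row.names = FALSE)
  d <- study$design
  yaml::write_yaml(list(seed = d$seed,
                        n_replicates = d$n_replicates,
                        cultivars = vapply(d$cultivars, `[[`, "", "code"),
                        light_conditions = vapply(d$light_conditions, `[[`,
                                                  "", "name"),
                        pixel_noise_sd = d$pixel_noise_sd,
                        pigment_noise_sd = as.list(d$pigment_noise_sd)),
                   file.path(dir, "design.yaml"))
  invisible(dir)
}
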