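## Spectrophotometric pigment chemistry.
##
## Total carotenoid content (TCC) from absorbances at 662/645/470 nm via the
## Lichtenthaler equations:
##   Ca    = 11.75 A662 - 2.35 A645                     [ug/mL]
##   Cb    = 18.61 A645 - 3.96 A662                     [ug/mL]
##   Cx+c  = (1000 A470 - 2.27 Ca - 81.4 Cb) / 227      [ug/mL]
## Total monomeric anthocyanin content (TAC) via the pH-differential method:
##   A   = (A520 - A700)_{pH 1.0} - (A520 - A700)_{pH 4.5}
##   TAC = A * MW * DF * 1000 / EF                      [mg/L]
## with cyanidin-3-glucoside constants MW = 449.2 g/mol,
## EF = 26900 L mol^-1 cm^-1 by default (the standard constants for the
## assay; both are explicit parameters).
##
## Contents are reported per 100 g fresh weight:
##   mg/100 g FW = C [ug/mL or mg/L] * V [mL] / (10 * m [g]) * (1 - moisture)
## where m is the assayed (dry) sample mass and moisture the fresh-tissue
## water fraction.  The bench bookkeeping is not standardised across labs,
## so every factor is an explicit argument.

# concentration (per mL or per L of extract) -> mg per 100 g fresh weight
.to_fw <- function(conc, extract_volume_mL, sample_mass_g, moisture_fraction) {
  conc * extract_volume_mL / (10 * sample_mass_g) * (1 - moisture_fraction)
}

.check_assay_params <- function(extract_volume_mL, sample_mass_g,
                                moisture_fraction, path_length_cm) {
  if (any(extract_volume_mL <= 0)) stop("extract_volume_mL must be positive")
  if (any(sample_mass_g <= 0)) stop("sample_mass_g must be positive")
  if (any(moisture_fraction < 0 | moisture_fraction >= 1))
    stop("moisture_fraction must lie in [0, 1)")
  if (any(path_length_cm <= 0)) stop("path_length_cm must be positive")
}

#' Total carotenoids from 662/645/470 nm absorbances (Lichtenthaler)
#'
#' Computes chlorophyll a, chlorophyll b and total carotenoid concentrations
#' from the three absorbance readings, then converts carotenoids to
#' mg/100 g fresh weight.  Absorbances are normalised to a 1 cm optical path
#' before the equations are applied.
#'
#' @param A662,A645,A470 Absorbance readings (vectors recycle).
#' @param extract_volume_mL Total extract volume per sample.
#' @param sample_mass_g Assayed (freeze-dried) sample mass.
#' @param moisture_fraction Fresh-tissue moisture fraction in \[0, 1).
#' @param path_length_cm Optical path length (default 1 cm).
#' @return Data frame with columns `Ca`, `Cb`, `Cxc` (ug/mL) and
#'   `tcc_mg_per_100g_fw`.
#' @export
#' @examples
#' lichtenthaler_tcc(0, 0, 1, extract_volume_mL = 3, sample_mass_g = 0.5,
#'                   moisture_fraction = 0.88)$Cxc  # 1000/227 = 4.4053
lichtenthaler_tcc <- function(A662, A645, A470,
                              extract_volume_mL, sample_mass_g,
                              moisture_fraction, path_length_cm = 1) {
  if (any(c(A662, A645, A470) < 0)) stop("absorbances must be non-negative")
  .check_assay_params(extract_volume_mL, sample_mass_g, moisture_fraction,
                      path_length_cm)
  a662 <- A662 / path_length_cm
  a645 <- A645 / path_length_cm
  a470 <- A470 / path_length_cm
  Ca <- 11.75 * a662 - 2.35 * a645
  Cb <- 18.61 * a645 - 3.96 * a662
  Cxc <- (1000 * a470 - 2.27 * Ca - 81.4 * Cb) / 227
  if (any(Cxc < -1e-9))
    stop("negative total-carotenoid concentration: inconsistent readings")
  Cxc <- pmax(Cxc, 0)
  data.frame(Ca = Ca, Cb = Cb, Cxc = Cxc,
             tcc_mg_per_100g_fw = .to_fw(Cxc, extract_volume_mL,
                                         sample_mass_g, moisture_fraction))
}

#' Total monomeric anthocyanins by the pH-differential method
#'
#' Applies the two-buffer absorbance difference and the molar conversion to
#' mg/L of cyanidin-3-glucoside equivalents, then converts to mg/100 g
#' fresh weight.  Duplicate extractions may be supplied as multi-column
#' matrices; they are averaged at the absorbance level before the
#' difference is formed.
#'
#' @param A520_pH1,A700_pH1,A520_pH45,A700_pH45 Absorbances in the pH 1.0
#'   and pH 4.5 buffers; vectors, or matrices whose columns are duplicate
#'   extractions.
#' @param DF Dilution factor (>= 1).
#' @param MW Molar weight of the reference anthocyanin (g/mol; default
#'   cyanidin-3-glucoside, 449.2).
#' @param EF Molar extinction coefficient (L mol^-1 cm^-1; default 26900).
#' @param extract_volume_mL,sample_mass_g,moisture_fraction,path_length_cm
#'   As in [lichtenthaler_tcc()].
#' @return Data frame with columns `A` (corrected absorbance),
#'   `tac_mg_per_L`, `tac_mg_per_100g_fw`.
#' @export
#' @examples
#' ph_differential_tac(1.0, 0, 0.2, 0, DF = 40, extract_volume_mL = 10,
#'                     sample_mass_g = 1, moisture_fraction = 0.88)
ph_differential_tac <- function(A520_pH1, A700_pH1, A520_pH45, A700_pH45,
                                DF, MW = 449.2, EF = 26900,
                                extract_volume_mL, sample_mass_g,
                                moisture_fraction, path_length_cm = 1) {
  avg <- function(x) if (is.matrix(x)) rowMeans(x) else x
  a520_1 <- avg(A520_pH1); a700_1 <- avg(A700_pH1)
  a520_45 <- avg(A520_pH45); a700_45 <- avg(A700_pH45)
  if (any(c(a520_1, a700_1, a520_45, a700_45) < 0))
    stop("absorbances must be non-negative")
  if (any(DF < 1)) stop("dilution factor DF must be >= 1")
  if (any(MW <= 0) || any(EF <= 0)) stop("MW and EF must be positive")
  .check_assay_params(extract_volume_mL, sample_mass_g, moisture_fraction,
                      path_length_cm)
  A <- ((a520_1 - a700_1) - (a520_45 - a700_45)) / path_length_cm
  if (any(A < -1e-9))
    stop("negative pH-differential absorbance: inconsistent readings")
  A <- pmax(A, 0)
  tac_mg_L <- A * MW * DF * 1000 / EF
  data.frame(A = A, tac_mg_per_L = tac_mg_L,
             tac_mg_per_100g_fw = .to_fw(tac_mg_L, extract_volume_mL,
                                         sample_mass_g, moisture_fraction))
}

#' Pigment names recognised by the modelling stages
#' @return Character vector of pigment identifiers.
#' @export
pigment_names <- function() {
  c("tcc", "tac", "lutein", "lycopene", "alpha_carotene", "beta_carotene")
}

.is_purple <- function(cultivar) grepl("^P[0-9]", cultivar)
.is_red <- function(cultivar) grepl("^R[0-9]", cultivar)

#' Filter sample records before pigment modelling
#'
#' Applies the content-based and cultivar-based exclusion rules used before
#' model fitting:
#' \itemize{
#'   \item total contents (`tcc`, `tac`): rows below 0.25 mg/100 g FW are
#'     removed (spectrophotometric totals near zero in strongly coloured
#'     roots are likely false positives);
#'   \item `tac`: the red cultivar is removed (single sample, minimal
#'     content);
#'   \item individual carotenoids (`lutein`, `alpha_carotene`,
#'     `beta_carotene`): fully purple cultivars are removed, but
#'     sub-threshold rows from other cultivars are retained down to the
#'     HPLC detection limit of 0.025 mg/100 g;
#'   \item `lycopene`: not modelled (present in one cultivar only); all
#'     rows are removed with reason `not_modelled`.
#' }
#' Rows removed are returned with a reason code so that sample counts are
#' conserved and auditable.
#'
#' @param records Data frame with at least a `cultivar` column and a content
#'   column named after the pigment (mg/100 g FW).
#' @param pigment One of [pigment_names()].
#' @param threshold Omission threshold for total contents (default 0.25).
#' @param detection_limit HPLC detection limit for individual carotenoids
#'   (default 0.025).
#' @return List with `kept` (data frame) and `removed` (data frame with an
#'   extra `reason` column; one of `below_threshold`,
#'   `below_detection_limit`, `purple_cultivar_excluded`,
#'   `red_cultivar_excluded`, `not_modelled`, `missing_content`).
#' @export
apply_content_filters <- function(records, pigment, threshold = 0.25,
                                  detection_limit = 0.025) {
  if (!pigment %in% pigment_names())
    stop("unknown pigment '", pigment, "'; known: ",
         paste(pigment_names(), collapse = ", "))
  if (!pigment %in% names(records))
    stop("records lack a '", pigment, "' content column")
  if (nrow(records) == 0L)
    return(list(kept = records,
                removed = cbind(records, reason = character(0))))
  content <- records[[pigment]]
  reason <- rep(NA_character_, nrow(records))
  if (pigment == "lycopene") {
    reason[] <- "not_modelled"
  } else {
    reason[is.na(content)] <- "missing_content"
    if (pigment %in% c("tcc", "tac")) {
      reason[is.na(reason) & content < threshold] <- "below_threshold"
      if (pigment == "tac")
        reason[.is_red(records$cultivar)] <- "red_cultivar_excluded"
    } else {
      reason[.is_purple(records$cultivar)] <- "purple_cultivar_excluded"
      reason[is.na(reason) & content < detection_limit] <-
        "below_detection_limit"
    }
  }
  keep <- is.na(reason)
  removed <- records[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], removed = removed)
}
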