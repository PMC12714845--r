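# Derived echocardiographic indices, HFpEF eligibility, H2FPEF score.
# Devereux and Du Bois constants are the standard published forms.

#' Left-ventricular mass, body surface area and LVMI
#'
#' `lv_mass()` is the Devereux formula
#' `0.8 * 1.04 * ((IVS + LVID + PWT)^3 - LVID^3) + 0.6` (cm in, g out);
#' `bsa_dubois()` is `0.007184 * W^0.425 * H^0.725` (kg, cm in, m^2 out);
#' `lv_mass_index()` is their ratio in g/m^2. All are vectorized.
#'
#' @param ivs,lvid,pwt Interventricular septum, LV internal dimension and
#'   posterior wall thickness, cm (end-diastole).
#' @param weight,height Body weight (kg) and height (cm).
#' @return Numeric vector (g, m^2, or g/m^2).
#' @export
#' @examples
#' lv_mass(1.0, 5.0, 1.0)      # ~182 g
#' bsa_dubois(70, 170)         # ~1.81 m^2
lv_mass <- function(ivs, lvid, pwt) {
  if (any(c(ivs, lvid, pwt) <= 0, na.rm = TRUE)) {
    abort("wall dimensions must be positive.")
  }
  0.8 * 1.04 * ((ivs + lvid + pwt)^3 - lvid^3) + 0.6
}

#' @rdname lv_mass
#' @export
bsa_dubois <- function(weight, height) {
  if (any(c(weight, height) <= 0, na.rm = TRUE)) {
    abort("weight and height must be positive.")
  }
  0.007184 * weight^0.425 * height^0.725
}

#' @rdname lv_mass
#' @export
lv_mass_index <- function(ivs, lvid, pwt, weight, height) {
  lv_mass(ivs, lvid, pwt) / bsa_dubois(weight, height)
}

#' Relative wall thickness
#'
#' `2 * PWT / LVID`, dimensionless.
#'
#' @param pwt,lvid Posterior wall thickness and LV internal dimension (same
#'   units).
#' @return Numeric vector.
#' @export
relative_wall_thickness <- function(pwt, lvid) {
  if (any(lvid <= 0, na.rm = TRUE) || any(pwt <= 0, na.rm = TRUE)) {
    abort("pwt and lvid must be positive.")
  }
  2 * pwt / lvid
}

#' E/e' ratio
#'
#' Early mitral inflow velocity divided by the mean of septal and lateral
#' early annular velocities.
#'
#' @param e Mitral E velocity.
#' @param e_septal,e_lateral Septal and lateral e' velocities (same units
#'   as `e`).
#' @return Numeric vector.
#' @export
e_over_eprime_ratio <- function(e, e_septal, e_lateral) {
  m <- (e_septal + e_lateral) / 2
  if (any(m <= 0, na.rm = TRUE) || any(e <= 0, na.rm = TRUE)) {
    abort("velocities must be positive.")
  }
  e / m
}

#' HFpEF eligibility screen
#'
#' A record is eligible when LVEF >= 50% and at least one structural or
#' functional criterion holds: sex-specific LVMI (> 115 g/m^2 male,
#' > 95 g/m^2 female), RWT > 0.42, E/e' > 9, or rhythm-specific NT-proBNP
#' (> 125 pg/mL sinus, > 365 pg/mL atrial fibrillation). Thresholds are
#' strict inequalities except LVEF. Missing criteria count as not met; a
#' missing LVEF is an error.
#'
#' @param data Cohort with `lvef` and any of `sex`, `lvmi`, `rwt`,
#'   `e_over_eprime`, `af`, `ntprobnp`.
#' @return `data` with logical `hfpef_eligible` and character
#'   `hfpef_exclusion` (first failing reason, `NA` when eligible) appended.
#' @export
hfpef_screen <- function(data) {
  check_columns(data, "lvef", "data")
  if (any(is.na(data$lvef))) abort("missing LVEF; cannot screen.")
  n <- nrow(data)
  get <- function(nm, default = NA) {
    if (nm %in% names(data)) data[[nm]] else rep(default, n)
  }
  met <- function(x) !is.na(x) & x
  lvmi_crit <- met(ifelse(get("sex") == "male",
                          get("lvmi") > 115, get("lvmi") > 95))
  rwt_crit <- met(get("rwt") > 0.42)
  ee_crit <- met(get("e_over_eprime") > 9)
  bnp_crit <- met(ifelse(met(get("af") == 1),
                         get("ntprobnp") > 365, get("ntprobnp") > 125))
  ef_ok <- data$lvef >= 50
  structural <- lvmi_crit | rwt_crit | ee_crit | bnp_crit
  dplyr::mutate(
    as_tibble(data),
    hfpef_eligible = ef_ok & structural,
    hfpef_exclusion = dplyr::case_when(
      !ef_ok ~ "lvef_below_50",
      !structural ~ "no_structural_or_functional_criterion",
      TRUE ~ NA_character_))
}

#' H2FPEF score
#'
#' Points: atrial fibrillation 3; BMI > 30 kg/m^2 (obesity) 2; age > 60,
#' >= 2 antihypertensive medications, E/e' > 9, and PASP > 35 mmHg 1 each
#' (0-9 total).
#'
#' @param data Cohort with `af`, `bmi`, `age`, `n_antihtn`,
#'   `e_over_eprime`, `pasp`.
#' @return `data` with an integer `h2fpef` column appended.
#' @export
h2fpef_score <- function(data) {
  need <- c("af", "bmi", "age", "n_antihtn", "e_over_eprime", "pasp")
  check_columns(data, need, "data")
  na_cols <- need[vapply(need, function(nm) any(is.na(data[[nm]])),
                         logical(1))]
  if (length(na_cols) > 0L) {
    abort(paste0("missing values in required field(s): ",
                 paste(na_cols, collapse = ", ")))
  }
  dplyr::mutate(
    as_tibble(data),
    h2fpef = 3L * as.integer(.data$af == 1) +
      2L * as.integer(.data$bmi > 30) +
      as.integer(.data$age > 60) +
      as.integer(.data$n_antihtn >= 2) +
      as.integer(.data$e_over_eprime > 9) +
      as.integer(.data$pasp > 35))
}
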