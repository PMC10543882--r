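#' Watson urea distribution volume
#'
#' Anthropometric estimate of total body water (L), used as the urea
#' distribution volume V in Kt/V:
#' males `2.447 - 0.09516 age + 0.1074 height + 0.3362 weight`,
#' females `-2.097 + 0.1069 height + 0.2466 weight`
#' (age in years, height in cm, weight in kg).
#'
#' @param sex Character vector, `"male"` or `"female"`.
#' @param age_years,height_cm,weight_kg Numeric vectors.
#' @return Numeric vector of volumes (L).
#' @examples
#' watson_volume("male", 60, 170, 70)
#' @export
watson_volume <- function(sex, age_years, height_cm, weight_kg) {
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be \"male\" or \"female\".", call. = FALSE)
  }
  if (any(age_years < 18, na.rm = TRUE) ||
      any(height_cm <= 0 | weight_kg <= 0, na.rm = TRUE)) {
    stop("Adult anthropometrics required: age >= 18, positive height and weight.",
         call. = FALSE)
  }
  v <- ifelse(
    sex == "male",
    2.447 - 0.09516 * age_years + 0.1074 * height_cm + 0.3362 * weight_kg,
    -2.097 + 0.1069 * height_cm + 0.2466 * weight_kg
  )
  if (any(v <= 0, na.rm = TRUE)) {
    stop("Watson volume non-positive: implausible anthropometrics.",
         call. = FALSE)
  }
  v
}

#' Weekly Kt/V urea by route
#'
#' Daily urea clearance for each route is (collection urea concentration x
#' collection volume) / serum urea, i.e. litres of plasma cleared per day;
#' weekly Kt/V multiplies by 7 and normalises to the urea distribution
#' volume V. The total is the exact sum of the renal and peritoneal
#' components.
#'
#' @param effluent_volume_L,effluent_urea_mmol_L 24-h pooled effluent.
#' @param urine_volume_L,urine_urea_mmol_L 24-h urine (0 volume = anuria).
#' @param serum_urea_mmol_L Serum urea; must be positive.
#' @param v_L Urea distribution volume, e.g. from [watson_volume()].
#' @return Tibble with `ktv_renal_weekly`, `ktv_peritoneal_weekly`,
#'   `ktv_total_weekly`.
#' @examples
#' ktv_components(10, 18, 1.2, 110, 20, 38.53)
#' @export
ktv_components <- function(effluent_volume_L, effluent_urea_mmol_L,
                           urine_volume_L, urine_urea_mmol_L,
                           serum_urea_mmol_L, v_L) {
  if (any(serum_urea_mmol_L <= 0, na.rm = TRUE)) {
    stop("Serum urea must be positive: clearance undefined otherwise.",
         call. = FALSE)
  }
  if (any(v_L <= 0, na.rm = TRUE)) {
    stop("Urea distribution volume must be positive.", call. = FALSE)
  }
  renal_daily <- urine_volume_L * urine_urea_mmol_L / serum_urea_mmol_L
  perit_daily <- effluent_volume_L * effluent_urea_mmol_L / serum_urea_mmol_L
  tibble::tibble(
    ktv_renal_weekly = 7 * renal_daily / v_L,
    ktv_peritoneal_weekly = 7 * perit_daily / v_L,
    ktv_total_weekly = .data$ktv_renal_weekly + .data$ktv_peritoneal_weekly
  )
}

#' Protein nitrogen appearance
#'
#' Bergstrom formula for PD: PNA (g protein/day) = 20.1 + 7.50 x UNA, where
#' UNA is total urea nitrogen appearance in g N/day (urinary plus peritoneal
#' urea output, 0.028 g N per mmol urea). The intercept is the non-urea
#' nitrogen floor. nPNA normalises by body weight.
#'
#' @param una_gN_day Urea nitrogen appearance, g N/day (non-negative).
#' @return Numeric vector, PNA in g/day.
#' @examples
#' pna(6) # 20.1 + 45
#' @export
pna <- function(una_gN_day) {
  if (any(una_gN_day < 0, na.rm = TRUE)) {
    stop("Urea nitrogen appearance cannot be negative.", call. = FALSE)
  }
  20.1 + 7.50 * una_gN_day
}

#' @rdname pna
#' @param pna_g_day PNA in g/day.
#' @param weight_kg Body weight, kg.
#' @export
npna <- function(pna_g_day, weight_kg) {
  if (any(weight_kg <= 0, na.rm = TRUE)) {
    stop("Weight must be positive.", call. = FALSE)
  }
  pna_g_day / weight_kg
}

#' Peritoneal membrane transporter category
#'
#' Classifies the 4-h peritoneal equilibration test dialysate-to-plasma
#' creatinine ratio into the four Twardowski bands. With the default band
#' edges a ratio below 0.50 is `low`, from 0.50 up to (excluding) 0.65
#' `low_average`, up to and including 0.81 `high_average`, and above that
#' `high`.
#'
#' @param dp_creatinine_4h Numeric vector of D/P creatinine ratios in
#'   \[0, 1.2\].
#' @param config A [pd_config()]; band edges come from `config$pet_bands`.
#' @return Factor with levels low, low_average, high_average, high.
#' @examples
#' pet_category(c(0.49, 0.5, 0.65, 0.72, 0.82))
#' @export
pet_category <- function(dp_creatinine_4h, config = pd_config()) {
  ok <- is.na(dp_creatinine_4h) |
    (dp_creatinine_4h >= 0 & dp_creatinine_4h <= 1.2)
  if (!all(ok)) {
    stop("D/P creatinine ratio outside [0, 1.2].", call. = FALSE)
  }
  cut(
    dp_creatinine_4h,
    breaks = c(-Inf, config$pet_bands, Inf),
    labels = c("low", "low_average", "high_average", "high"),
    right = FALSE
  )
}

#' Adequacy panel for a cohort
#'
#' Convenience wrapper computing the Watson volume, weekly Kt/V urea by
#' route, PNA/nPNA and the PET transporter category for every patient.
#'
#' @param patients Data frame with the demographic, collection and serum
#'   columns used by [watson_volume()], [ktv_components()], [pna()] and
#'   [pet_category()] (see [read_cohort()] for the schema).
#' @param config A [pd_config()].
#' @return Tibble, one row per patient: `patient_id`, `watson_v_L`, the
#'   three weekly Kt/V components, `una_gN_day`, `pna_g_day`,
#'   `npna_g_kg_day`, `dp_creatinine_4h` and `transporter`.
#' @export
compute_adequacy <- function(patients, config = pd_config()) {
  patients <- tibble::as_tibble(patients)
  v <- watson_volume(patients$sex, patients$age_years,
                     patients$height_cm, patients$weight_kg)
  ktv <- ktv_components(
    patients$effluent_volume_L, patients$effluent_urea_mmol_L,
    patients$urine_volume_L, patients$urine_urea_mmol_L,
    patients$serum_urea_mmol_L, v
  )
  una <- (patients$urine_volume_L * patients$urine_urea_mmol_L +
            patients$effluent_volume_L * patients$effluent_urea_mmol_L) *
    config$urea_gN_per_mmol
  p <- pna(una)
  tibble::tibble(
    patient_id = patients$patient_id,
    watson_v_L = v,
    ktv,
    una_gN_day = una,
    pna_g_day = p,
    npna_g_kg_day = npna(p, patients$weight_kg),
    dp_creatinine_4h = patients$dp_creatinine_4h,
    transporter = pet_category(patients$dp_creatinine_4h, config)
  )
}
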