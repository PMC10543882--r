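#' Configuration for the synthetic PD cohort generator
#'
#' Defaults emulate a contemporary incident peritoneal dialysis cohort of
#' 183 patients: modality mix APD/CAPD/CCPD of 29/26.8/44.2%, 56.3% male,
#' 30.1% diabetic, age 59.4 +/- 16.4 years, 49.2% prescribed a
#' calcium-containing phosphate binder, and icodextrin used by essentially
#' all CAPD/CCPD long dwells but no APD patient. Dialysate equilibration is
#' modelled as a single-pool exponential approach of the drained calcium
#' concentration towards serum ionized calcium with time constant `tau_h`.
#'
#' @param n Cohort size.
#' @param seed Root seed; each patient gets an independent substream drawn
#'   from it, so editing one patient's draw does not reshuffle the others.
#' @param modality_probs Named probabilities for APD, CAPD, CCPD (sum 1).
#' @param male_prob,diabetic_prob Bernoulli probabilities.
#' @param age_mean,age_sd Age distribution (years), truncated at 18.
#' @param weight_mean,weight_sd Weight distribution (kg), truncated at 40.
#' @param binder_prob Probability of a calcium-containing binder
#'   prescription.
#' @param icodextrin_prob Named per-modality probability that the long dwell
#'   uses icodextrin.
#' @param tau_h Calcium equilibration time constant of a dwell (hours).
#'   Calcium equilibrates far more slowly than urea; the default 12 h leaves
#'   short cycler dwells close to the fresh-bag concentration while long
#'   icodextrin dwells approach serum levels.
#' @param serum_ica_mean,serum_ica_sd Serum ionized calcium (mmol/L). The
#'   default mean 1.22 sits below the 1.25 mmol/L glucose dialysate and well
#'   below the 1.75 mmol/L icodextrin, so glucose exchanges have a near-zero
#'   diffusive gradient while icodextrin dwells load calcium.
#' @param uf_glucose_short,uf_glucose_day,uf_glucose_long,uf_icodextrin
#'   Length-2 vectors (mean, sd) of per-exchange ultrafiltration (L) for
#'   short cycler glucose dwells, daytime manual glucose dwells, overnight
#'   glucose dwells (negative mean: fluid absorption) and icodextrin long
#'   dwells.
#' @param anuric_prob Probability of anuria (urine volume 0).
#' @param urine_vol_meanlog,urine_vol_sdlog Log-normal 24-h urine volume (L).
#' @param urine_ca_meanlog,urine_ca_sdlog Log-normal 24-h urinary calcium
#'   (mmol/day).
#' @param conc_noise_sd Measurement noise (mmol/L) added to each drained
#'   exchange's calcium concentration.
#' @return A list of class `pd_cohort_config`.
#' @export
cohort_config <- function(n = 183,
                          seed = 1L,
                          modality_probs = c(APD = 0.290, CAPD = 0.268, CCPD = 0.442),
                          male_prob = 0.563,
                          diabetic_prob = 0.301,
                          age_mean = 59.4, age_sd = 16.4,
                          weight_mean = 70.8, weight_sd = 14.5,
                          binder_prob = 0.492,
                          icodextrin_prob = c(APD = 0, CAPD = 0.938, CCPD = 0.951),
                          tau_h = 12,
                          serum_ica_mean = 1.22, serum_ica_sd = 0.07,
                          uf_glucose_short = c(0.08, 0.10),
                          uf_glucose_day = c(0.08, 0.12),
                          uf_glucose_long = c(-0.05, 0.15),
                          uf_icodextrin = c(0.30, 0.18),
                          anuric_prob = 0.08,
                          urine_vol_meanlog = log(1.05), urine_vol_sdlog = 0.75,
                          urine_ca_meanlog = log(0.45), urine_ca_sdlog = 0.9,
                          conc_noise_sd = 0.015) {
  if (n <= 0) stop("`n` must be positive.", call. = FALSE)
  if (abs(sum(modality_probs) - 1) > 1e-9 ||
      any(modality_probs < 0) || any(modality_probs > 1)) {
    stop("`modality_probs` must be probabilities summing to 1.", call. = FALSE)
  }
  probs <- c(male_prob, diabetic_prob, binder_prob, anuric_prob, icodextrin_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("All probabilities must lie in [0, 1].", call. = FALSE)
  }
  if (tau_h <= 0) stop("`tau_h` must be positive.", call. = FALSE)
  structure(
    as.list(environment()),
    class = "pd_cohort_config"
  )
}

#' Simulate the drain of one dialysate dwell
#'
#' Single-pool, instantly mixed dwell: the drained calcium concentration
#' relaxes exponentially from the fresh dialysate concentration towards
#' serum ionized calcium with equilibration fraction
#' `k = 1 - exp(-dwell_h / tau_h)`. The drained volume is the instilled fill
#' plus ultrafiltration; a drain that would be negative (fluid absorption
#' exceeding the fill) is clipped at zero with a warning.
#'
#' @param conc_dialysate_mmol_L Fresh dialysate calcium (mmol/L).
#' @param serum_ica_mmol_L Serum ionized calcium (mmol/L).
#' @param dwell_h Dwell duration (hours, >= 0).
#' @param uf_L Ultrafiltration over the dwell (L, may be negative).
#' @param fill_L Volume instilled into the patient (L).
#' @param tau_h Equilibration time constant (hours, > 0).
#' @return Tibble: `equilibration_k`, `drain_volume_L`,
#'   `drain_calcium_mmol_L`, `drained_calcium_mmol` (the mass).
#' @examples
#' simulate_exchange(1.75, 1.22, dwell_h = 14, uf_L = 0.3, fill_L = 2)
#' @export
simulate_exchange <- function(conc_dialysate_mmol_L, serum_ica_mmol_L,
                              dwell_h, uf_L, fill_L, tau_h = 12) {
  if (any(dwell_h < 0)) stop("`dwell_h` must be non-negative.", call. = FALSE)
  if (any(tau_h <= 0)) stop("`tau_h` must be positive.", call. = FALSE)
  k <- 1 - exp(-dwell_h / tau_h)
  vol <- fill_L + uf_L
  if (any(vol < 0)) {
    warning("Negative drain volume clipped at 0 (fluid absorption exceeded fill).",
            call. = FALSE)
    vol <- pmax(vol, 0)
  }
  conc <- conc_dialysate_mmol_L +
    (serum_ica_mmol_L - conc_dialysate_mmol_L) * k
  tibble::tibble(
    equilibration_k = k,
    drain_volume_L = vol,
    drain_calcium_mmol_L = conc,
    drained_calcium_mmol = vol * conc
  )
}

# truncated normal by resampling; n small so rejection is fine
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

# exchange plan for one patient; returns prescription + latent dwell columns
plan_exchanges <- function(modality, uses_ico, uses_strong_glucose, cfg) {
  glucose_day <- if (uses_strong_glucose) "glucose_2_27" else "glucose_1_36"
  if (modality == "APD") {
    n_cyc <- sample(4:5, 1)
    tibble::tibble(
      dialysate = c(rep("glucose_1_36", n_cyc - 1), glucose_day),
      delivery = "cycler",
      nominal_fill_L = 2.0,
      dwell_h = stats::runif(n_cyc, 1.6, 2.4),
      dwell_kind = "glucose_short"
    )
  } else if (modality == "CAPD") {
    long_type <- if (uses_ico) "icodextrin" else "glucose_1_36"
    tibble::tibble(
      dialysate = c(glucose_day, "glucose_1_36", "glucose_1_36", long_type),
      delivery = "manual_capd",
      nominal_fill_L = 2.0,
      dwell_h = c(stats::runif(3, 4, 5.5), stats::runif(1, 8, 10)),
      dwell_kind = c(rep("glucose_day", 3),
                     if (uses_ico) "icodextrin" else "glucose_long")
    )
  } else { # CCPD: overnight cycler plus a long day dwell
    n_cyc <- sample(4:5, 1)
    day_type <- if (uses_ico) "icodextrin" else "glucose_1_36"
    tibble::tibble(
      dialysate = c(rep("glucose_1_36", n_cyc - 1), glucose_day, day_type),
      delivery = "cycler",
      nominal_fill_L = 2.0,
      dwell_h = c(stats::runif(n_cyc, 1.8, 2.6), stats::runif(1, 13, 15)),
      dwell_kind = c(rep("glucose_short", n_cyc),
                     if (uses_ico) "icodextrin" else "glucose_long")
    )
  }
}

uf_params <- function(kind, cfg) {
  switch(kind,
         glucose_short = cfg$uf_glucose_short,
         glucose_day = cfg$uf_glucose_day,
         glucose_long = cfg$uf_glucose_long,
         icodextrin = cfg$uf_icodextrin)
}

# one patient's full record; called inside that patient's RNG substream
simulate_patient <- function(id, cfg, config) {
  sex <- if (stats::runif(1) < cfg$male_prob) "male" else "female"
  age <- rnorm_trunc(1, cfg$age_mean, cfg$age_sd, lower = 18, upper = 95)
  height <- if (sex == "male") rnorm_trunc(1, 172, 8, 150, 200) else
    rnorm_trunc(1, 159, 7, 140, 185)
  weight <- rnorm_trunc(1, cfg$weight_mean, cfg$weight_sd, lower = 40)
  diabetic <- stats::runif(1) < cfg$diabetic_prob
  modality <- sample(names(cfg$modality_probs), 1, prob = cfg$modality_probs)
  uses_ico <- stats::runif(1) < cfg$icodextrin_prob[[modality]]
  uses_strong <- stats::runif(1) < 0.279

  serum_ca <- rnorm_trunc(1, 2.30, 0.18, 1.6, 3.1)
  serum_ica <- rnorm_trunc(1, cfg$serum_ica_mean + 0.30 * (serum_ca - 2.30),
                           0.035, 0.9, 1.6)
  serum_urea <- rnorm_trunc(1, 16, 4, 6, 40)
  serum_creat <- stats::rlnorm(1, log(580), 0.35)
  phosphate <- rnorm_trunc(1, 1.52, 0.41, 0.4, 3.5)
  albumin <- rnorm_trunc(1, 37.3, 4.3, 20, 55)
  dp_urea <- rnorm_trunc(1, 0.62, 0.10, 0.30, 0.95)
  dp_creat <- rnorm_trunc(1, 0.72, 0.14, 0.30, 1.10)

  ex <- plan_exchanges(modality, uses_ico, uses_strong, cfg)
  uf_ms <- t(vapply(ex$dwell_kind, uf_params, numeric(2), cfg = cfg))
  ex$uf_L <- stats::rnorm(nrow(ex), uf_ms[, 1], uf_ms[, 2])
  ex$measured_fill_L <- ifelse(
    ex$delivery == "cycler",
    ex$nominal_fill_L * stats::runif(nrow(ex), 0.98, 1.02),
    NA_real_
  )
  # manual bags are overfilled; the flush goes straight to the drain bag
  bag_L <- ifelse(ex$delivery == "manual_capd",
                  ex$nominal_fill_L * config$capd_overfill_factor,
                  ex$measured_fill_L)
  flush_L <- ifelse(ex$delivery == "manual_capd", config$flush_volume_L, 0)
  fill_patient_L <- bag_L - flush_L
  conc_fresh <- unname(config$dialysate_calcium[ex$dialysate])
  drain <- simulate_exchange(conc_fresh, serum_ica, ex$dwell_h, ex$uf_L,
                             fill_patient_L, cfg$tau_h)
  drain_conc_meas <- pmax(
    drain$drain_calcium_mmol_L + stats::rnorm(nrow(ex), 0, cfg$conc_noise_sd), 0
  )
  ex$sim_fill_patient_L <- fill_patient_L
  ex$sim_flush_L <- flush_L
  ex$sim_drain_volume_L <- drain$drain_volume_L
  ex$sim_drain_calcium_mmol_L <- drain_conc_meas
  ex$sim_drain_calcium_true_mmol_L <- drain$drain_calcium_mmol_L

  effl_vol <- sum(drain$drain_volume_L + flush_L)
  effl_mass <- sum(drain$drain_volume_L * drain_conc_meas + flush_L * conc_fresh)
  effl_ca <- if (effl_vol > 0) effl_mass / effl_vol else 0
  effl_urea <- serum_urea * dp_urea
  effl_creat <- serum_creat * dp_creat * 0.9

  anuric <- stats::runif(1) < cfg$anuric_prob
  urine_vol <- if (anuric) 0 else
    min(stats::rlnorm(1, cfg$urine_vol_meanlog, cfg$urine_vol_sdlog), 4.5)
  urine_ca_day <- if (anuric) 0 else
    min(stats::rlnorm(1, cfg$urine_ca_meanlog, cfg$urine_ca_sdlog), 4)
  urine_urea <- if (anuric) 0 else rnorm_trunc(1, 95, 35, 10, 250)

  binder <- stats::runif(1) < cfg$binder_prob
  product <- if (binder) {
    sample(c("calcium_carbonate", "calcium_acetate", "calcium_magnesium_carbonate"),
           1, prob = c(0.55, 0.30, 0.15))
  } else "none"
  tablets <- if (binder) sample(2:6, 1, prob = c(0.20, 0.30, 0.25, 0.15, 0.10)) else 0

  t_ls <- stats::rnorm(1, -0.7, 1.5)
  z_ls <- t_ls + 0.9 + stats::rnorm(1, 0, 0.7)
  t_fn <- stats::rnorm(1, -1.4, 1.0)
  z_fn <- t_fn + 0.9 + stats::rnorm(1, 0, 0.6)

  patient <- tibble::tibble(
    patient_id = id,
    sex = sex, age_years = age, height_cm = height, weight_kg = weight,
    diabetic = diabetic, modality = modality,
    icodextrin_user = uses_ico,
    effluent_volume_L = effl_vol,
    effluent_calcium_mmol_L = effl_ca,
    effluent_urea_mmol_L = effl_urea,
    effluent_creatinine_umol_L = effl_creat,
    urine_volume_L = urine_vol,
    urine_calcium_mmol_L = if (urine_vol > 0) urine_ca_day / urine_vol else 0,
    urine_urea_mmol_L = urine_urea,
    serum_calcium_mmol_L = serum_ca,
    serum_urea_mmol_L = serum_urea,
    serum_creatinine_umol_L = serum_creat,
    serum_phosphate_mmol_L = phosphate,
    serum_albumin_g_L = albumin,
    binder_product = product,
    binder_tablets_per_day = tablets,
    dp_creatinine_4h = dp_creat,
    t_lumbar = t_ls, z_lumbar = z_ls,
    t_femoral_neck = t_fn, z_femoral_neck = z_fn,
    bmd_ls_g_cm2 = max(1.03 + 0.13 * (t_ls + 0.7) + stats::rnorm(1, 0, 0.04), 0.3),
    bmd_fn_g_cm2 = max(0.74 + 0.10 * (t_fn + 1.4) + stats::rnorm(1, 0, 0.03), 0.2),
    appendicular_lean_mass_kg = rnorm_trunc(1, 19.3, 4.9, 8, 40),
    body_fat_kg = stats::rlnorm(1, log(20), 0.4),
    davies_comorbidity = sample(0:3, 1, prob = c(0.30, 0.35, 0.25, 0.10)),
    frailty_score = sample(1:7, 1, prob = c(0.05, 0.2, 0.3, 0.25, 0.12, 0.06, 0.02)),
    sim_serum_ica_mmol_L = serum_ica,
    sim_dp_urea = dp_urea
  )
  ex$patient_id <- id
  ex$exchange_id <- seq_len(nrow(ex))
  list(patient = patient, exchanges = ex)
}

#' Generate a synthetic peritoneal dialysis cohort
#'
#' Draws a full cohort from [cohort_config()]: per-patient demographics,
#' modality-specific exchange prescriptions, mechanistically simulated 24-h
#' effluent (see [simulate_exchange()]), urine and serum chemistry, binder
#' prescriptions and DXA scores. Columns prefixed `sim_` carry the latent
#' truth (serum ionized calcium, per-exchange ultrafiltration and drain
#' concentrations) for parameter-recovery checks; they are not part of the
#' observed record schema.
#'
#' @param cfg A [cohort_config()].
#' @param config A [pd_config()]; supplies dialysate calcium levels and the
#'   CAPD overfill/flush convention the effluent simulation honours.
#' @return A list of class `pd_cohort` with tibbles `patients` and
#'   `exchanges`, plus the `cfg` used.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 5, seed = 42))
#' coh$patients$modality
#' @export
generate_cohort <- function(cfg = cohort_config(), config = pd_config()) {
  if (!inherits(cfg, "pd_cohort_config")) {
    stop("`cfg` must come from cohort_config().", call. = FALSE)
  }
  set.seed(cfg$seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n)
  sims <- purrr::map(seq_len(cfg$n), function(i) {
    set.seed(patient_seeds[i])
    simulate_patient(i, cfg, config)
  })
  patients <- dplyr::bind_rows(purrr::map(sims, "patient"))
  exchanges <- dplyr::bind_rows(purrr::map(sims, "exchanges"))
  exchanges <- dplyr::select(
    exchanges, "patient_id", "exchange_id", "dialysate", "delivery",
    "nominal_fill_L", "measured_fill_L", "dwell_h", dplyr::starts_with("sim_")
  )
  structure(
    list(patients = patients, exchanges = exchanges, cfg = cfg),
    class = "pd_cohort"
  )
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat("<pd_cohort> n =", nrow(x$patients),
      "patients,", nrow(x$exchanges), "exchanges\n")
  print(table(x$patients$modality))
  invisible(x)
}
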