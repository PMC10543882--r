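#' Convert between milligrams and millimoles of elemental calcium
#'
#' Uses the molar mass of calcium from the active configuration
#' (40.08 mg/mmol by default), so that e.g. 0.649 mmol/day pairs with
#' 26.0 mg/day.
#'
#' @param mass_mg,amount_mmol Numeric vectors.
#' @param config A [pd_config()].
#' @return Numeric vector of the converted quantity.
#' @examples
#' mg_to_mmol(2000) # the 2 g/day guideline ceiling, about 49.9 mmol
#' mmol_to_mg(mg_to_mmol(26))
#' @export
mg_to_mmol <- function(mass_mg, config = pd_config()) {
  mass_mg / config$ca_mg_per_mmol
}

#' @rdname mg_to_mmol
#' @export
mmol_to_mg <- function(amount_mmol, config = pd_config()) {
  amount_mmol * config$ca_mg_per_mmol
}

#' Actual bag volume of a dialysate exchange
#'
#' Manual (CAPD) bags are overfilled to allow the flush-before-fill
#' technique: a nominal 2.0 L bag contains 2.15 L, and other nominal manual
#' volumes scale by the same factor. Cycler exchanges use the cycler's
#' volumetric record when available, otherwise the nominal fill.
#'
#' @param exchanges Data frame with one row per exchange: columns
#'   `delivery` (`"manual_capd"` or `"cycler"`), `nominal_fill_L`, and
#'   optionally `measured_fill_L` (NA where no volumetric record exists).
#' @param config A [pd_config()].
#' @return The input as a tibble with an `actual_fill_L` column added.
#' @examples
#' ex <- tibble::tibble(
#'   delivery = c("manual_capd", "cycler"),
#'   nominal_fill_L = c(2, 2),
#'   measured_fill_L = c(NA, 2.1)
#' )
#' bag_volumes(ex)
#' @export
bag_volumes <- function(exchanges, config = pd_config()) {
  exchanges <- tibble::as_tibble(exchanges)
  if (!all(c("delivery", "nominal_fill_L") %in% names(exchanges))) {
    stop("`exchanges` needs columns `delivery` and `nominal_fill_L`.",
         call. = FALSE)
  }
  if (!"measured_fill_L" %in% names(exchanges)) {
    exchanges$measured_fill_L <- NA_real_
  }
  bad_delivery <- !exchanges$delivery %in% pd_delivery_types
  if (any(bad_delivery)) {
    stop("Unknown delivery type: ",
         paste(unique(exchanges$delivery[bad_delivery]), collapse = ", "),
         call. = FALSE)
  }
  if (any(exchanges$nominal_fill_L <= 0, na.rm = TRUE) ||
      any(is.na(exchanges$nominal_fill_L))) {
    stop("Nominal fill volumes must be present and positive.", call. = FALSE)
  }
  if (any(exchanges$measured_fill_L <= 0, na.rm = TRUE)) {
    stop("Measured cycler fill volumes must be positive where present.",
         call. = FALSE)
  }
  dplyr::mutate(
    exchanges,
    actual_fill_L = dplyr::case_when(
      .data$delivery == "manual_capd" ~
        .data$nominal_fill_L * config$capd_overfill_factor,
      !is.na(.data$measured_fill_L) ~ .data$measured_fill_L,
      TRUE ~ .data$nominal_fill_L
    )
  )
}

#' Daily instilled dialysate calcium per patient
#'
#' Sums actual bag volume times dialysate calcium concentration over each
#' patient's exchanges. Under `flush_handling = "flush_excluded"` the flush
#' volume is removed from the instilled side of every manual exchange
#' instead of being recovered in the effluent.
#'
#' @param exchanges Data frame of exchanges with columns `patient_id`,
#'   `dialysate`, `delivery`, `nominal_fill_L` and optionally
#'   `measured_fill_L`.
#' @param config A [pd_config()].
#' @return Tibble with one row per patient: `patient_id`, `n_exchanges`,
#'   `instilled_volume_L` (sum of actual fills, the volume against which
#'   ultrafiltration is measured) and `instilled_calcium_mmol_day`.
#' @examples
#' ex <- tibble::tibble(
#'   patient_id = 1, dialysate = "icodextrin",
#'   delivery = "manual_capd", nominal_fill_L = 2
#' )
#' instilled_calcium(ex) # 2.15 L x 1.75 mmol/L
#' @export
instilled_calcium <- function(exchanges, config = pd_config()) {
  if (nrow(exchanges) == 0) {
    warning("No exchanges supplied: dry regimen, instilled calcium is 0.",
            call. = FALSE)
    return(tibble::tibble(
      patient_id = integer(0), n_exchanges = integer(0),
      instilled_volume_L = numeric(0), instilled_calcium_mmol_day = numeric(0)
    ))
  }
  bad_type <- !exchanges$dialysate %in% names(config$dialysate_calcium)
  if (any(bad_type)) {
    stop("Unknown dialysate type: ",
         paste(unique(exchanges$dialysate[bad_type]), collapse = ", "),
         call. = FALSE)
  }
  ex <- bag_volumes(exchanges, config)
  ex <- dplyr::mutate(
    ex,
    ca_conc = unname(config$dialysate_calcium[.data$dialysate]),
    instilled_L = dplyr::if_else(
      config$flush_handling == "flush_excluded" &
        .data$delivery == "manual_capd",
      pmax(.data$actual_fill_L - config$flush_volume_L, 0),
      .data$actual_fill_L
    )
  )
  dplyr::summarise(
    dplyr::group_by(ex, .data$patient_id),
    n_exchanges = dplyr::n(),
    instilled_volume_L = sum(.data$instilled_L),
    instilled_calcium_mmol_day = sum(.data$instilled_L * .data$ca_conc),
    .groups = "drop"
  )
}

#' Absorbed elemental calcium from phosphate binders
#'
#' Prescribed elemental calcium per day is tablets/day times elemental
#' content per tablet; the absorbed amount applies the configured gut
#' absorption fraction (default 20%) and converts mg to mmol.
#'
#' @param product Character vector of binder products
#'   (`"calcium_carbonate"`, `"calcium_acetate"`,
#'   `"calcium_magnesium_carbonate"` or `"none"`).
#' @param tablets_per_day Numeric vector of daily tablet counts (0 for none).
#' @param elemental_mg_per_tablet Optional numeric vector overriding the
#'   configured per-product elemental content.
#' @param config A [pd_config()].
#' @param absorption_fraction Fraction absorbed; defaults to the configured
#'   value.
#' @return Numeric vector, absorbed calcium in mmol/day.
#' @examples
#' absorbed_binder_calcium("calcium_carbonate", 2) # 200 mg -> ~4.99 mmol
#' @export
absorbed_binder_calcium <- function(product, tablets_per_day,
                                    elemental_mg_per_tablet = NULL,
                                    config = pd_config(),
                                    absorption_fraction = config$absorption_fraction) {
  if (absorption_fraction < 0 || absorption_fraction > 1) {
    stop("`absorption_fraction` must lie in [0, 1].", call. = FALSE)
  }
  if (any(tablets_per_day < 0, na.rm = TRUE)) {
    stop("Negative binder dose.", call. = FALSE)
  }
  bad <- !product %in% pd_binder_products
  if (any(bad)) {
    stop("Unknown binder product: ",
         paste(unique(product[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(product == "none" & tablets_per_day > 0, na.rm = TRUE) ||
      any(product != "none" & tablets_per_day == 0, na.rm = TRUE)) {
    stop("`product = \"none\"` must pair with 0 tablets/day and vice versa.",
         call. = FALSE)
  }
  mg_tab <- if (is.null(elemental_mg_per_tablet)) {
    unname(c(config$binder_content, none = 0)[product])
  } else {
    rng <- config$binder_content_range
    out_of_range <- product != "none" &
      (elemental_mg_per_tablet < rng[1] | elemental_mg_per_tablet > rng[2])
    if (any(out_of_range, na.rm = TRUE)) {
      stop("Elemental content outside plausible range [",
           rng[1], ", ", rng[2], "] mg/tablet.", call. = FALSE)
    }
    elemental_mg_per_tablet
  }
  mg_to_mmol(tablets_per_day * mg_tab * absorption_fraction, config)
}

#' Full nested calcium balance for a cohort
#'
#' Computes, per patient and per 24 h, the three nested balance levels:
#'
#' * net peritoneal balance = instilled dialysate calcium minus the calcium
#'   mass measured in the pooled 24-h effluent (positive = patient gains
#'   calcium);
#' * combined balance = peritoneal balance minus urinary calcium losses;
#' * overall balance = combined balance plus elemental calcium absorbed from
#'   calcium-containing phosphate binders.
#'
#' Also reports 24-h ultrafiltration as drained effluent volume minus the
#' summed actual fill volumes.
#'
#' @param patients Data frame, one row per patient, with columns
#'   `patient_id`, `effluent_volume_L`, `effluent_calcium_mmol_L`,
#'   `urine_volume_L`, `urine_calcium_mmol_L`, `binder_product`,
#'   `binder_tablets_per_day`. A zero urine volume encodes anuria.
#' @param exchanges Exchange-level data frame as for [instilled_calcium()].
#' @param config A [pd_config()].
#' @return Tibble, one row per patient: the instilled/effluent masses, all
#'   three balances (mmol/day), `ultrafiltration_L`, the absorbed binder
#'   calcium and three logical `*_positive` sign columns (a balance of
#'   exactly 0 counts as non-positive).
#' @examples
#' pts <- tibble::tibble(
#'   patient_id = 1, effluent_volume_L = 11.1, effluent_calcium_mmol_L = 1.2,
#'   urine_volume_L = 1, urine_calcium_mmol_L = 0.5,
#'   binder_product = "none", binder_tablets_per_day = 0
#' )
#' ex <- tibble::tibble(
#'   patient_id = 1, dialysate = rep("glucose_1_36", 4),
#'   delivery = "manual_capd", nominal_fill_L = 2
#' )
#' compute_balance(pts, ex)
#' @export
compute_balance <- function(patients, exchanges, config = pd_config()) {
  patients <- tibble::as_tibble(patients)
  needed <- c("patient_id", "effluent_volume_L", "effluent_calcium_mmol_L",
              "urine_volume_L", "urine_calcium_mmol_L")
  missing_cols <- setdiff(needed, names(patients))
  if (length(missing_cols)) {
    stop("`patients` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(patients$effluent_volume_L) || anyNA(patients$effluent_calcium_mmol_L)) {
    stop("Effluent collection missing for some patients: balance undefined.",
         call. = FALSE)
  }
  if (any(patients$effluent_volume_L < 0) ||
      any(patients$effluent_calcium_mmol_L < 0) ||
      any(patients$urine_volume_L < 0, na.rm = TRUE) ||
      any(patients$urine_calcium_mmol_L < 0, na.rm = TRUE)) {
    stop("Collection volumes and concentrations must be non-negative.",
         call. = FALSE)
  }
  if (!"binder_product" %in% names(patients)) patients$binder_product <- "none"
  if (!"binder_tablets_per_day" %in% names(patients)) {
    patients$binder_tablets_per_day <- 0
  }

  inst <- instilled_calcium(exchanges, config)
  out <- dplyr::left_join(patients, inst, by = "patient_id")
  no_rx <- is.na(out$instilled_calcium_mmol_day)
  if (any(no_rx)) {
    warning(sum(no_rx), " patient(s) without exchanges: instilled calcium 0.",
            call. = FALSE)
    out$instilled_calcium_mmol_day[no_rx] <- 0
    out$instilled_volume_L[no_rx] <- 0
    out$n_exchanges[no_rx] <- 0L
  }

  out <- dplyr::mutate(
    out,
    effluent_calcium_mmol_day =
      .data$effluent_volume_L * .data$effluent_calcium_mmol_L,
    peritoneal_balance_mmol_day =
      .data$instilled_calcium_mmol_day - .data$effluent_calcium_mmol_day,
    ultrafiltration_L = .data$effluent_volume_L - .data$instilled_volume_L,
    urinary_calcium_mmol_day =
      dplyr::coalesce(.data$urine_volume_L * .data$urine_calcium_mmol_L, 0),
    combined_balance_mmol_day =
      .data$peritoneal_balance_mmol_day - .data$urinary_calcium_mmol_day,
    absorbed_binder_mmol_day = absorbed_binder_calcium(
      .data$binder_product, .data$binder_tablets_per_day, config = config
    ),
    overall_balance_mmol_day =
      .data$combined_balance_mmol_day + .data$absorbed_binder_mmol_day,
    peritoneal_positive = .data$peritoneal_balance_mmol_day > 0,
    combined_positive = .data$combined_balance_mmol_day > 0,
    overall_positive = .data$overall_balance_mmol_day > 0
  )
  dplyr::select(
    out, "patient_id", "n_exchanges", "instilled_volume_L",
    "instilled_calcium_mmol_day", "effluent_calcium_mmol_day",
    "peritoneal_balance_mmol_day", "ultrafiltration_L",
    "urinary_calcium_mmol_day", "combined_balance_mmol_day",
    "absorbed_binder_mmol_day", "overall_balance_mmol_day",
    "peritoneal_positive", "combined_positive", "overall_positive"
  )
}
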