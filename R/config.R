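#' Pipeline configuration
#'
#' Collects every tunable constant of the balance pipeline in one validated
#' list, so that no clinical constant is hard-coded at a call site.
#'
#' @param flush_handling How the CAPD flush-before-fill overfill enters the
#'   mass balance. `"overfill_recovered"` (default): the full overfilled bag
#'   volume counts as instilled calcium, because the flush drains into the
#'   collection bag and its calcium is recovered in the measured 24-h
#'   effluent, keeping the balance closed. `"flush_excluded"`: the flush
#'   volume is subtracted from the instilled side (appropriate only if the
#'   flush is discarded before the effluent collection).
#' @param absorption_fraction Fraction of prescribed elemental binder calcium
#'   assumed absorbed from the gut. Default 0.20.
#' @param flush_volume_L Median measured flush-before-fill volume (L),
#'   used only under `flush_handling = "flush_excluded"`. Default 0.09.
#' @param capd_overfill_factor Ratio of true manual-bag content to nominal
#'   fill volume. Default 2.15/2.0, i.e. a nominal 2.0 L CAPD bag contains
#'   2.15 L.
#' @param ca_mg_per_mmol Molar mass of calcium, mg per mmol. Default 40.08.
#' @param dialysate_calcium Named numeric vector, calcium concentration
#'   (mmol/L) per dialysate type. Glucose dialysates carry 1.25 mmol/L,
#'   icodextrin 1.75 mmol/L.
#' @param binder_content Named numeric vector, elemental calcium (mg) per
#'   tablet for each binder product. Defaults: calcium carbonate 1.25 g
#'   tablet = 500 mg elemental, calcium acetate 1 g tablet = 253 mg,
#'   calcium/magnesium carbonate combination = 110 mg.
#' @param binder_content_range Plausible range (mg/tablet) used in input
#'   validation. Default c(110, 500).
#' @param pet_bands Upper edges of the low, low-average and high-average
#'   D/P creatinine transporter bands. Default c(0.50, 0.65, 0.815): a ratio
#'   below 0.50 is low, up to but excluding 0.65 low-average, up to and
#'   including 0.81 high-average, above that high.
#' @param pna_formula Identifier of the protein nitrogen appearance equation;
#'   only `"bergstrom"` (PNA = 20.1 + 7.50 * UNA g N/day) is currently
#'   implemented, the field exists so alternatives can be registered.
#' @param urea_gN_per_mmol Grams of urea nitrogen per mmol urea. Default 0.028.
#'
#' @return A list of class `pd_config`.
#' @examples
#' cfg <- pd_config()
#' cfg$dialysate_calcium[["icodextrin"]]
#' @export
pd_config <- function(flush_handling = c("overfill_recovered", "flush_excluded"),
                      absorption_fraction = 0.20,
                      flush_volume_L = 0.09,
                      capd_overfill_factor = 2.15 / 2.0,
                      ca_mg_per_mmol = 40.08,
                      dialysate_calcium = c(
                        glucose_1_36 = 1.25,
                        glucose_2_27 = 1.25,
                        glucose_3_86 = 1.25,
                        icodextrin = 1.75
                      ),
                      binder_content = c(
                        calcium_carbonate = 500,
                        calcium_acetate = 253,
                        calcium_magnesium_carbonate = 110
                      ),
                      binder_content_range = c(110, 500),
                      pet_bands = c(0.50, 0.65, 0.815),
                      pna_formula = "bergstrom",
                      urea_gN_per_mmol = 0.028) {
  flush_handling <- match.arg(flush_handling)
  if (!is.numeric(absorption_fraction) || length(absorption_fraction) != 1 ||
      is.na(absorption_fraction) ||
      absorption_fraction < 0 || absorption_fraction > 1) {
    stop("`absorption_fraction` must be a single number in [0, 1].", call. = FALSE)
  }
  if (any(dialysate_calcium <= 0)) {
    stop("Dialysate calcium concentrations must be positive.", call. = FALSE)
  }
  if (capd_overfill_factor <= 0 || flush_volume_L < 0) {
    stop("Overfill factor must be positive and flush volume non-negative.",
         call. = FALSE)
  }
  if (length(pet_bands) != 3 || is.unsorted(pet_bands, strictly = TRUE)) {
    stop("`pet_bands` must be three strictly increasing band edges.", call. = FALSE)
  }
  pna_formula <- match.arg(pna_formula, "bergstrom")
  structure(
    list(
      flush_handling = flush_handling,
      absorption_fraction = absorption_fraction,
      flush_volume_L = flush_volume_L,
      capd_overfill_factor = capd_overfill_factor,
      ca_mg_per_mmol = ca_mg_per_mmol,
      dialysate_calcium = dialysate_calcium,
      binder_content = binder_content,
      binder_content_range = binder_content_range,
      pet_bands = pet_bands,
      pna_formula = pna_formula,
      urea_gN_per_mmol = urea_gN_per_mmol
    ),
    class = "pd_config"
  )
}

#' @export
print.pd_config <- function(x, ...) {
  cat("<pd_config>\n")
  cat("  flush handling      :", x$flush_handling, "\n")
  cat("  absorption fraction :", x$absorption_fraction, "\n")
  cat("  dialysate Ca mmol/L :",
      paste(names(x$dialysate_calcium), x$dialysate_calcium,
            sep = "=", collapse = ", "), "\n")
  cat("  binder mg/tablet    :",
      paste(names(x$binder_content), x$binder_content,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# valid factor levels used across the package
pd_modalities <- c("APD", "CAPD", "CCPD")
pd_dialysate_types <- c("glucose_1_36", "glucose_2_27", "glucose_3_86", "icodextrin")
pd_delivery_types <- c("manual_capd", "cycler")
pd_binder_products <- c("calcium_carbonate", "calcium_acetate",
                        "calcium_magnesium_carbonate", "none")
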