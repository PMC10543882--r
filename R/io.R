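#' Read and validate a cohort from CSV
#'
#' Reads the patient-level and exchange-level tables, checks the schema and
#' every row-level invariant (non-negative volumes and concentrations,
#' known factor levels, binder product/dose consistency, anuria encoded as
#' zero urine volume with zero solute outputs), and reports offending rows
#' by line number instead of silently dropping them.
#'
#' @param patients_csv Path to the patient table. Mandatory columns:
#'   `patient_id`, `sex`, `age_years`, `height_cm`, `weight_kg`,
#'   `modality`, `effluent_volume_L`, `effluent_calcium_mmol_L`,
#'   `effluent_urea_mmol_L`, `urine_volume_L`, `urine_calcium_mmol_L`,
#'   `urine_urea_mmol_L`, `serum_calcium_mmol_L`, `serum_urea_mmol_L`,
#'   `binder_product`, `binder_tablets_per_day`. Calcium columns are in
#'   mmol; a companion `<col>_unit` column, when present, must say so (`mg`
#'   values are converted on read, anything else is a unit error).
#' @param exchanges_csv Path to the exchange table with columns
#'   `patient_id`, `dialysate`, `delivery`, `nominal_fill_L` and optionally
#'   `measured_fill_L`, `dwell_h`.
#' @param config A [pd_config()].
#' @return List with tibbles `patients` and `exchanges`. Invalid rows abort
#'   with a message listing each problem as `file:line`.
#' @export
read_cohort <- function(patients_csv, exchanges_csv, config = pd_config()) {
  patients <- readr::read_csv(patients_csv, show_col_types = FALSE)
  exchanges <- readr::read_csv(exchanges_csv, show_col_types = FALSE)

  mandatory <- c("patient_id", "sex", "age_years", "height_cm", "weight_kg",
                 "modality", "effluent_volume_L", "effluent_calcium_mmol_L",
                 "effluent_urea_mmol_L", "urine_volume_L",
                 "urine_calcium_mmol_L", "urine_urea_mmol_L",
                 "serum_calcium_mmol_L", "serum_urea_mmol_L",
                 "binder_product", "binder_tablets_per_day")
  missing_cols <- setdiff(mandatory, names(patients))
  if (length(missing_cols)) {
    stop("Schema error in ", patients_csv, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mandatory_ex <- c("patient_id", "dialysate", "delivery", "nominal_fill_L")
  missing_ex <- setdiff(mandatory_ex, names(exchanges))
  if (length(missing_ex)) {
    stop("Schema error in ", exchanges_csv, ": missing column(s) ",
         paste(missing_ex, collapse = ", "), call. = FALSE)
  }

  # unit columns: calcium must be mmol-based; mg converted, others rejected
  for (col in grep("calcium", names(patients), value = TRUE)) {
    unit_col <- paste0(col, "_unit")
    if (unit_col %in% names(patients)) {
      units <- unique(stats::na.omit(patients[[unit_col]]))
      bad <- setdiff(units, c("mmol", "mmol_L", "mmol/L", "mg", "mg_L", "mg/L"))
      if (length(bad)) {
        stop("Unit error in column `", col, "`: unrecognised unit ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      is_mg <- patients[[unit_col]] %in% c("mg", "mg_L", "mg/L")
      patients[[col]][is_mg] <- mg_to_mmol(patients[[col]][is_mg], config)
      patients[[unit_col]] <- NULL
    }
  }

  problems <- character()
  flag <- function(bad, msg, file) {
    # +1 for the header line so numbers match the raw file
    idx <- which(bad)
    if (length(idx)) {
      problems <<- c(problems,
                     paste0(file, ":", idx + 1, " ", msg))
    }
  }
  p <- patients
  flag(!p$sex %in% c("male", "female"), "invalid sex", patients_csv)
  flag(!p$modality %in% pd_modalities, "invalid modality", patients_csv)
  flag(is.na(p$effluent_volume_L) | p$effluent_volume_L < 0,
       "effluent volume missing or negative", patients_csv)
  flag(!is.na(p$urine_volume_L) & p$urine_volume_L < 0,
       "negative urine volume", patients_csv)
  num_cols <- c("effluent_calcium_mmol_L", "effluent_urea_mmol_L",
                "urine_calcium_mmol_L", "urine_urea_mmol_L",
                "serum_calcium_mmol_L")
  for (col in num_cols) {
    flag(!is.na(p[[col]]) & p[[col]] < 0,
         paste("negative", col), patients_csv)
  }
  flag(!is.na(p$serum_urea_mmol_L) & p$serum_urea_mmol_L <= 0,
       "serum urea must be positive", patients_csv)
  flag(!p$binder_product %in% pd_binder_products,
       "unknown binder product", patients_csv)
  flag(!is.na(p$binder_tablets_per_day) & p$binder_tablets_per_day < 0,
       "negative binder dose", patients_csv)
  flag((p$binder_product == "none") != (p$binder_tablets_per_day == 0),
       "binder product/dose mismatch", patients_csv)
  flag(p$urine_volume_L == 0 &
         (p$urine_calcium_mmol_L > 0 | p$urine_urea_mmol_L > 0),
       "anuric patient with non-zero urine solutes", patients_csv)

  e <- exchanges
  flag(!e$dialysate %in% pd_dialysate_types, "unknown dialysate type",
       exchanges_csv)
  flag(!e$delivery %in% pd_delivery_types, "unknown delivery type",
       exchanges_csv)
  flag(is.na(e$nominal_fill_L) | e$nominal_fill_L <= 0,
       "nominal fill must be positive", exchanges_csv)
  if ("measured_fill_L" %in% names(e)) {
    flag(!is.na(e$measured_fill_L) & e$measured_fill_L <= 0,
         "measured fill must be positive", exchanges_csv)
  }
  flag(!e$patient_id %in% p$patient_id, "exchange for unknown patient",
       exchanges_csv)

  if (length(problems)) {
    stop("Cohort validation failed (", length(problems), " problem(s)):\n",
         paste(problems, collapse = "\n"), call. = FALSE)
  }
  list(patients = patients, exchanges = exchanges)
}

#' Write the per-patient balance table
#'
#' @param balance Output of [compute_balance()].
#' @param path Destination CSV. Units are embedded in the column names
#'   (mmol/day, L).
#' @return `path`, invisibly.
#' @export
write_balance <- function(balance, path) {
  readr::write_csv(balance, path)
  invisible(path)
}

#' Full analysis report bundle
#'
#' Runs the whole downstream pipeline on a cohort — balance, adequacy, DXA
#' classification, the three balance-level tabulations, the Spearman screen
#' and the backward logistic model for combined and overall positivity —
#' and writes a deterministic CSV/markdown bundle with run metadata
#' (content hash of config and inputs).
#'
#' @param patients,exchanges Cohort tibbles (see [read_cohort()]).
#' @param out_dir Output directory, created if needed.
#' @param config A [pd_config()].
#' @param candidates Candidate predictors for the screen/model; defaults to
#'   a standard clinical set present in the patient table.
#' @return Invisibly, a list with every computed table and the bundle hash.
#' @export
report_cohort <- function(patients, exchanges, out_dir,
                          config = pd_config(),
                          candidates = NULL) {
  if (nrow(patients) == 0) stop("Empty cohort: nothing to report.", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  balance <- compute_balance(patients, exchanges, config)
  full <- dplyr::left_join(patients, balance, by = "patient_id")
  adequacy <- tryCatch(compute_adequacy(patients, config),
                       error = function(e) NULL)
  dxa <- tryCatch(classify_dxa(patients), error = function(e) NULL)

  tabs <- purrr::map(
    rlang::set_names(c("peritoneal", "combined", "overall")),
    ~ tabulate_balance_groups(full, level = .x, by = "modality")
  )

  if (is.null(candidates)) {
    default_cands <- c("peritoneal_balance_mmol_day", "urinary_calcium_mmol_day",
                       "ultrafiltration_L", "serum_calcium_mmol_L",
                       "urine_volume_L", "age_years", "weight_kg",
                       "icodextrin_user", "binder_tablets_per_day")
    candidates <- intersect(default_cands, names(full))
  }
  screen <- spearman_screen(full, "combined_positive", candidates)
  model <- tryCatch(
    backward_logistic(full, "overall_positive",
                      setdiff(candidates, "binder_tablets_per_day"),
                      nonparametric = c("urine_volume_L")),
    error = function(e) NULL
  )

  readr::write_csv(balance, file.path(out_dir, "balance.csv"))
  if (!is.null(adequacy)) {
    readr::write_csv(adequacy, file.path(out_dir, "adequacy.csv"))
  }
  if (!is.null(dxa)) readr::write_csv(dxa, file.path(out_dir, "dxa.csv"))
  purrr::iwalk(tabs, ~ readr::write_csv(
    .x, file.path(out_dir, paste0("tabulation_", .y, ".csv"))
  ))
  readr::write_csv(screen, file.path(out_dir, "spearman_screen.csv"))
  if (!is.null(model)) {
    readr::write_csv(tidy(model), file.path(out_dir, "logistic_model.csv"))
  }

  results <- list(balance = balance, adequacy = adequacy, dxa = dxa,
                  tabulations = tabs, screen = screen, model = model)
  bundle_hash <- rlang::hash(list(patients, exchanges,
                                  config[setdiff(names(config), NULL)]))
  md <- c(
    "# PD calcium balance report", "",
    paste0("- patients: ", nrow(patients)),
    paste0("- exchanges: ", nrow(exchanges)),
    paste0("- config/input hash: ", bundle_hash),
    paste0("- flush handling: ", config$flush_handling),
    paste0("- absorption fraction: ", config$absorption_fraction),
    "",
    "## Positive balance by level (all / per modality)",
    purrr::imap_chr(tabs, function(t, lvl) {
      paste0("- ", lvl, ": ",
             paste0(t$stratum, " ", t$n_positive, "/", t$n,
                    " (", t$pct_positive, "%)", collapse = "; "))
    }),
    "",
    "## Risk factors (Spearman screen, combined positivity)",
    paste0("- ", screen$variable, ": rho=", round(screen$rho, 2),
           " p=", signif(screen$p_value, 2))
  )
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(c(results, list(hash = bundle_hash)))
}
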