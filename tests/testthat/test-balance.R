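test_that("manual bags carry the flush-before-fill overfill, cyclers their record", {
  ex <- tibble::tibble(
    delivery = c("manual_capd", "manual_capd", "cycler", "cycler"),
    nominal_fill_L = c(2, 2.5, 2, 2.2),
    measured_fill_L = c(NA, NA, 2.0, NA)
  )
  out <- bag_volumes(ex)
  expect_equal(out$actual_fill_L, c(2.15, 2.6875, 2.0, 2.2))

  expect_error(bag_volumes(tibble::tibble(delivery = "manual_capd",
                                          nominal_fill_L = 0)),
               "positive")
  expect_error(bag_volumes(tibble::tibble(delivery = "cycler",
                                          nominal_fill_L = 2,
                                          measured_fill_L = -1)),
               "positive")
  expect_error(bag_volumes(tibble::tibble(delivery = "gravity",
                                          nominal_fill_L = 2)),
               "delivery")
})

test_that("instilled calcium sums actual volume times dialysate concentration", {
  glucose <- tibble::tibble(patient_id = 1, dialysate = "glucose_1_36",
                            delivery = "manual_capd", nominal_fill_L = 2)
  expect_equal(instilled_calcium(glucose)$instilled_calcium_mmol_day,
               2.15 * 1.25)
  ico <- dplyr::mutate(glucose, dialysate = "icodextrin")
  expect_equal(instilled_calcium(ico)$instilled_calcium_mmol_day, 2.15 * 1.75)
  expect_warning(out <- instilled_calcium(glucose[0, ]), "dry regimen")
  expect_equal(nrow(out), 0)
  expect_error(instilled_calcium(dplyr::mutate(glucose, dialysate = "saline")),
               "dialysate")
})

test_that("peritoneal balance is instilled minus measured effluent mass", {
  pts <- tibble::tibble(
    patient_id = 1, effluent_volume_L = 11.1, effluent_calcium_mmol_L = 1.20,
    urine_volume_L = 0, urine_calcium_mmol_L = 0,
    binder_product = "none", binder_tablets_per_day = 0
  )
  ex <- tibble::tibble(patient_id = 1, dialysate = rep("glucose_1_36", 4),
                       delivery = "manual_capd", nominal_fill_L = 2)
  b <- compute_balance(pts, ex)
  expect_equal(b$instilled_calcium_mmol_day, 10.75)
  expect_equal(b$peritoneal_balance_mmol_day, 10.75 - 13.32)
  expect_equal(b$ultrafiltration_L, 11.1 - 4 * 2.15)
  # effluent mass equal to instilled -> exactly zero balance
  pts0 <- dplyr::mutate(pts, effluent_calcium_mmol_L = 10.75 / 11.1)
  b0 <- compute_balance(pts0, ex)
  expect_equal(b0$peritoneal_balance_mmol_day, 0)
  expect_false(b0$peritoneal_positive) # ties classified non-positive
})

test_that("binder absorption converts mg to mmol at the configured fraction", {
  expect_equal(absorbed_binder_calcium("none", 0), 0)
  expect_equal(absorbed_binder_calcium("calcium_carbonate", 2), 200 / 40.08)
  expect_equal(absorbed_binder_calcium("calcium_magnesium_carbonate", 1),
               22 / 40.08)
  expect_equal(
    absorbed_binder_calcium("calcium_acetate", 3, absorption_fraction = 0),
    0
  )
  expect_error(absorbed_binder_calcium("calcium_carbonate", -1), "dose")
  expect_error(absorbed_binder_calcium("calcium_carbonate", 0), "pair")
  expect_error(
    absorbed_binder_calcium("calcium_carbonate", 1,
                            elemental_mg_per_tablet = 900),
    "range"
  )
})

test_that("mg/mmol conversion round-trips and matches the printed pairing", {
  expect_equal(mg_to_mmol(0), 0)
  expect_equal(mmol_to_mg(0.649), 26.0, tolerance = 0.002)
  expect_equal(mg_to_mmol(2000), 49.9, tolerance = 0.001)
  x <- c(0.01, 1, 26, 514.3, 2000)
  expect_equal(mg_to_mmol(mmol_to_mg(x)), x, tolerance = 1e-12)
  expect_equal(mmol_to_mg(mg_to_mmol(x)), x, tolerance = 1e-12)
})

test_that("the three balance levels nest arithmetically with sign rules", {
  pts <- tibble::tibble(
    patient_id = 1:2,
    effluent_volume_L = c(9, 9),
    effluent_calcium_mmol_L = c(11.25 / 9, 10.75 / 9), # perit -0.5 and 0
    urine_volume_L = c(1, 0),
    urine_calcium_mmol_L = c(0.3, 0),
    binder_product = c("calcium_carbonate", "none"),
    binder_tablets_per_day = c(2, 0)
  )
  ex <- tidyr::crossing(patient_id = 1:2, k = 1:4)
  ex <- dplyr::mutate(ex, dialysate = "glucose_1_36", delivery = "manual_capd",
                      nominal_fill_L = 2)
  b <- compute_balance(pts, ex)
  expect_equal(b$peritoneal_balance_mmol_day[1], -0.5)
  expect_equal(b$combined_balance_mmol_day[1], -0.8)
  expect_equal(b$overall_balance_mmol_day[1], -0.8 + 200 / 40.08)
  expect_equal(unlist(b[1, c("peritoneal_positive", "combined_positive",
                             "overall_positive")], use.names = FALSE),
               c(FALSE, FALSE, TRUE))
  # anuric, no binders: all three levels coincide
  expect_equal(b$combined_balance_mmol_day[2], b$peritoneal_balance_mmol_day[2])
  expect_equal(b$overall_balance_mmol_day[2], b$peritoneal_balance_mmol_day[2])
  expect_error(compute_balance(dplyr::mutate(pts, effluent_volume_L = NA), ex),
               "undefined")
})

test_that("mass-balance identity and monotonicity hold on random records", {
  fx <- random_records(500, seed = 11)
  b <- compute_balance(fx$patients, fx$exchanges)
  # instilled = effluent mass + peritoneal balance, exactly
  expect_true(all(abs(
    b$instilled_calcium_mmol_day -
      (b$effluent_calcium_mmol_day + b$peritoneal_balance_mmol_day)
  ) < 1e-9))
  expect_equal(b$combined_balance_mmol_day,
               b$peritoneal_balance_mmol_day - b$urinary_calcium_mmol_day)
  expect_equal(b$overall_balance_mmol_day,
               b$combined_balance_mmol_day + b$absorbed_binder_mmol_day)

  # more effluent volume at fixed concentration strictly lowers the balance
  fx2 <- fx
  fx2$patients$effluent_volume_L <- fx$patients$effluent_volume_L + 0.5
  b2 <- compute_balance(fx2$patients, fx2$exchanges)
  expect_true(all(b2$peritoneal_balance_mmol_day < b$peritoneal_balance_mmol_day))

  # overall balance nondecreasing in tablet count
  fx3 <- fx
  fx3$patients$binder_tablets_per_day <-
    fx$patients$binder_tablets_per_day +
    (fx$patients$binder_product != "none")
  b3 <- compute_balance(fx3$patients, fx3$exchanges)
  expect_true(all(b3$overall_balance_mmol_day >= b$overall_balance_mmol_day))

  # zero absorption collapses overall onto combined
  cfg0 <- pd_config(absorption_fraction = 0)
  b4 <- compute_balance(fx$patients, fx$exchanges, cfg0)
  expect_equal(b4$overall_balance_mmol_day, b4$combined_balance_mmol_day)
})

test_that("flush_excluded removes the flush from the instilled side only", {
  ex <- tibble::tibble(patient_id = 1,
                       dialysate = c("glucose_1_36", "icodextrin"),
                       delivery = c("manual_capd", "cycler"),
                       nominal_fill_L = 2, measured_fill_L = c(NA, 2))
  inst_default <- instilled_calcium(ex)
  inst_flush <- instilled_calcium(ex, pd_config(flush_handling = "flush_excluded"))
  expect_equal(
    inst_default$instilled_calcium_mmol_day -
      inst_flush$instilled_calcium_mmol_day,
    0.09 * 1.25 # one manual exchange loses its flush; the cycler is untouched
  )
})
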