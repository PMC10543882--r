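# Brute-force Spearman oracle: average ranks computed by explicit sorting,
# Pearson correlation by explicit sums. Independent of stats::cor.
oracle_rank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}
oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  n <- length(x)
  mx <- sum(rx) / n; my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# Cohort realising a fixed table of positive-balance counts through real
# collections, so the tabulation runs on compute_balance() output:
# peritoneal positives 19/53 APD, 20/48 CAPD, 39/82 CCPD; 39 combined
# positives (32 icodextrin users); 90 binder prescriptions of which 88 are
# overall-positive; 105 overall positives in total.
make_count_fixture <- function(config = pd_config()) {
  modality <- rep(c("APD", "CAPD", "CCPD"), c(53, 48, 82))
  perit_pos <- c(rep(c(TRUE, FALSE), c(19, 34)),
                 rep(c(TRUE, FALSE), c(20, 28)),
                 rep(c(TRUE, FALSE), c(39, 43)))
  n <- length(modality)
  ord <- order(!perit_pos) # positives first
  modality <- modality[ord]; perit_pos <- perit_pos[ord]

  # first 39 of the 78 peritoneal positives stay positive after urine
  combined_pos <- rep(FALSE, n)
  combined_pos[which(perit_pos)[1:39]] <- TRUE

  perit_target <- ifelse(perit_pos, 0.5, -0.5)
  urine_ca_day <- ifelse(combined_pos, 0.1, ifelse(perit_pos, 1.0, 0.2))

  # binders: 22 combined-positive users + 68 combined-negative users;
  # 2 of the negatives have losses exceeding the absorbed binder calcium
  binder <- rep(FALSE, n)
  binder[which(combined_pos)[1:22]] <- TRUE
  neg_idx <- which(!combined_pos)
  binder[neg_idx[1:68]] <- TRUE
  deep_negative <- neg_idx[1:2] # binder users with a net loss regardless
  urine_ca_day[deep_negative] <- 6.0

  ico <- rep(FALSE, n)
  ico[which(combined_pos)[1:32]] <- TRUE
  ico[which(!combined_pos)[1:87]] <- TRUE

  # one manual 2 L glucose bag x4: instilled 10.75 mmol into 9 L effluent
  patients <- tibble::tibble(
    patient_id = seq_len(n),
    modality = modality,
    icodextrin_user = ico,
    effluent_volume_L = 9,
    effluent_calcium_mmol_L = (10.75 - perit_target) / 9,
    urine_volume_L = 1,
    urine_calcium_mmol_L = urine_ca_day,
    binder_product = ifelse(binder, "calcium_carbonate", "none"),
    binder_tablets_per_day = ifelse(binder, 2, 0)
  )
  exchanges <- tidyr::crossing(
    patient_id = seq_len(n), exchange_id = 1:4
  )
  exchanges$dialysate <- "glucose_1_36"
  exchanges$delivery <- "manual_capd"
  exchanges$nominal_fill_L <- 2
  list(patients = patients, exchanges = exchanges)
}

# random single-exchange records for property tests
random_records <- function(n, seed = 1) {
  set.seed(seed)
  patients <- tibble::tibble(
    patient_id = seq_len(n),
    effluent_volume_L = runif(n, 5, 15),
    effluent_calcium_mmol_L = runif(n, 0.8, 1.8),
    urine_volume_L = runif(n, 0, 3),
    urine_calcium_mmol_L = runif(n, 0, 1.5),
    binder_product = sample(c("calcium_carbonate", "calcium_acetate",
                              "calcium_magnesium_carbonate", "none"),
                            n, replace = TRUE),
    binder_tablets_per_day = 0
  )
  patients$binder_tablets_per_day <-
    ifelse(patients$binder_product == "none", 0, sample(1:6, n, replace = TRUE))
  exchanges <- tibble::tibble(
    patient_id = rep(seq_len(n), each = 2),
    dialysate = sample(c("glucose_1_36", "icodextrin"), 2 * n, replace = TRUE),
    delivery = sample(c("manual_capd", "cycler"), 2 * n, replace = TRUE),
    nominal_fill_L = runif(2 * n, 1.5, 3),
    measured_fill_L = NA_real_
  )
  list(patients = patients, exchanges = exchanges)
}
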