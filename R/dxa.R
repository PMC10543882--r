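#' WHO bone-density classification from DXA scores
#'
#' Applies the WHO criteria: osteoporosis if the T-score is below -2.5 or
#' the Z-score is below -2.0; otherwise normal if the T-score is at least
#' -1.0, and osteopenia in between. The boundaries are assigned so that
#' exactly -1.0 is normal ("no less than -1.0"), exactly -2.5 is osteopenia
#' (osteoporosis requires strictly less), and exactly -2.0 on the Z-score is
#' not osteoporosis (the Z criterion is strict).
#'
#' @param t_score,z_score Numeric vectors of DXA T and Z scores. A missing
#'   score yields the explicit `unclassified` level, never a silent default.
#' @return Factor with ordered levels
#'   `normal < osteopenia < osteoporosis` plus `unclassified`.
#' @examples
#' who_classify(c(-1.0, -1.5, -2.6, -1.5), c(0, 0, 0, -2.5))
#' @export
who_classify <- function(t_score, z_score) {
  n <- max(length(t_score), length(z_score))
  t_score <- rep_len(t_score, n)
  z_score <- rep_len(z_score, n)
  out <- dplyr::case_when(
    is.na(t_score) | is.na(z_score) ~ "unclassified",
    t_score < -2.5 | z_score < -2.0 ~ "osteoporosis",
    t_score >= -1.0 ~ "normal",
    TRUE ~ "osteopenia"
  )
  factor(out, levels = c("normal", "osteopenia", "osteoporosis", "unclassified"))
}

#' Site-wise and worst-site DXA classification for a cohort
#'
#' Classifies the lumbar spine and femoral neck separately with
#' [who_classify()] and reports the most severe of the two as the
#' worst-site category. Sites with missing scores are `unclassified` and do
#' not worsen the worst-site call; a patient with no scored site at all is
#' `unclassified` overall.
#'
#' @param patients Data frame with columns `patient_id`, `t_lumbar`,
#'   `z_lumbar`, `t_femoral_neck`, `z_femoral_neck`.
#' @return Tibble: `patient_id`, `dxa_lumbar`, `dxa_femoral_neck`,
#'   `dxa_worst`.
#' @export
classify_dxa <- function(patients) {
  patients <- tibble::as_tibble(patients)
  ls <- who_classify(patients$t_lumbar, patients$z_lumbar)
  fn <- who_classify(patients$t_femoral_neck, patients$z_femoral_neck)
  severity <- function(f) {
    s <- as.integer(factor(f, levels = c("normal", "osteopenia", "osteoporosis")))
    s # NA for unclassified
  }
  worst_idx <- pmax(severity(ls), severity(fn), na.rm = TRUE)
  worst <- c("normal", "osteopenia", "osteoporosis")[worst_idx]
  worst[is.na(worst_idx)] <- "unclassified"
  tibble::tibble(
    patient_id = patients$patient_id,
    dxa_lumbar = ls,
    dxa_femoral_neck = fn,
    dxa_worst = factor(worst, levels = levels(ls))
  )
}
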