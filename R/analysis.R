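#' Round half away from zero
#'
#' Printed cohort percentages use conventional half-up rounding (42.65 ->
#' 42.7), not banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tabulate positive-balance counts by stratum
#'
#' Counts and percentages of patients with a positive balance at one of the
#' three nested levels, overall and within each stratum (by default PD
#' modality). Percentages are 100 k/n rounded half-up to one decimal.
#'
#' @param data Data frame containing the logical sign column for the chosen
#'   level (as produced by [compute_balance()], e.g. joined back onto the
#'   patient table) and the stratifying column.
#' @param level `"peritoneal"`, `"combined"` (peritoneal + urinary) or
#'   `"overall"` (+ absorbed binder calcium).
#' @param by Name of the stratifying column; `NULL` for the overall row
#'   only.
#' @return Tibble with `stratum`, `n`, `n_positive`, `pct_positive`.
#' @examples
#' d <- tibble::tibble(modality = rep(c("APD", "CAPD"), c(4, 4)),
#'                     peritoneal_positive = rep(c(TRUE, FALSE), 4))
#' tabulate_balance_groups(d)
#' @export
tabulate_balance_groups <- function(data,
                                    level = c("peritoneal", "combined", "overall"),
                                    by = "modality") {
  level <- match.arg(level)
  if (nrow(data) == 0) stop("Empty cohort.", call. = FALSE)
  col <- paste0(level, "_positive")
  if (!col %in% names(data)) {
    stop("Column `", col, "` not found; run compute_balance() first.",
         call. = FALSE)
  }
  one <- function(d, label) {
    tibble::tibble(
      stratum = label,
      n = nrow(d),
      n_positive = sum(d[[col]]),
      pct_positive = round_half_up(100 * sum(d[[col]]) / nrow(d), 1)
    )
  }
  out <- one(data, "all")
  if (!is.null(by)) {
    strata <- dplyr::group_split(dplyr::group_by(data, .data[[by]]))
    out <- dplyr::bind_rows(
      out,
      purrr::map(strata, ~ one(.x, as.character(.x[[by]][1])))
    )
  }
  out
}

#' Univariate Spearman screen
#'
#' Spearman rank correlation (average ranks on ties) of each candidate
#' variable against the outcome, with a two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom. Constant columns yield an undefined rho, reported as missing.
#'
#' @param data Data frame.
#' @param outcome Name of the outcome column (numeric or binary-coded).
#' @param candidates Character vector of candidate column names.
#' @return Tibble with `variable`, `n`, `rho`, `p_value`, ordered by
#'   p-value.
#' @examples
#' spearman_screen(mtcars, "mpg", c("wt", "hp", "qsec"))
#' @export
spearman_screen <- function(data, outcome, candidates) {
  y_all <- data[[outcome]]
  if (is.logical(y_all) || is.factor(y_all)) y_all <- as.numeric(y_all)
  rows <- purrr::map(candidates, function(v) {
    x <- data[[v]]
    if (is.logical(x) || is.factor(x)) x <- as.numeric(x)
    ok <- stats::complete.cases(x, y_all)
    x <- x[ok]; y <- y_all[ok]
    n <- length(x)
    if (n < 4 || length(unique(x)) < 2 || length(unique(y)) < 2) {
      return(tibble::tibble(variable = v, n = n,
                            rho = NA_real_, p_value = NA_real_))
    }
    rho <- stats::cor(x, y, method = "spearman")
    p <- if (abs(rho) >= 1) {
      0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
    tibble::tibble(variable = v, n = n, rho = rho, p_value = p)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$p_value)
}

# moment skewness; used to decide log transformation
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Games-Howell pairwise comparisons (Welch t with studentized-range
# reference); no installed package provides this post-hoc.
games_howell <- function(x, g) {
  g <- factor(g)
  lev <- levels(g)
  k <- length(lev)
  stats_g <- purrr::map(lev, function(l) {
    xi <- x[g == l & !is.na(x)]
    list(n = length(xi), m = mean(xi), v = stats::var(xi))
  })
  names(stats_g) <- lev
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  dplyr::bind_rows(purrr::map(pairs, function(pr) {
    a <- stats_g[[pr[1]]]; b <- stats_g[[pr[2]]]
    se2 <- a$v / a$n + b$v / b$n
    tstat <- (a$m - b$m) / sqrt(se2)
    df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
    p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    tibble::tibble(comparison = paste(pr[1], "-", pr[2]),
                   diff = a$m - b$m, t = tstat, df = df, p_adj = p)
  }))
}

#' Group comparison with the test matched to the declared variable type
#'
#' Two balance-sign (or modality) groups are compared by Welch t-test for
#' variables declared parametric, Mann-Whitney U for nonparametric and
#' chi-square for categorical; with more than two groups ANOVA or
#' Kruskal-Wallis is used, with a Tukey HSD post-hoc when group variances
#' are compatible (Bartlett p >= 0.05) and Games-Howell otherwise.
#'
#' @param data Data frame.
#' @param variable Column to compare.
#' @param grouping Grouping column (>= 2 non-empty groups).
#' @param type `"parametric"`, `"nonparametric"` or `"categorical"`.
#' @return One-row tibble with `variable`, `test`, `statistic`, `p_value`;
#'   when a post-hoc was run its pairwise table is attached as attribute
#'   `"posthoc"`.
#' @export
group_tests <- function(data, variable, grouping,
                        type = c("parametric", "nonparametric", "categorical")) {
  type <- match.arg(type)
  x <- data[[variable]]
  g <- factor(data[[grouping]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2 || any(table(g) == 0)) {
    stop("Need at least two non-empty groups.", call. = FALSE)
  }
  posthoc <- NULL
  if (type == "categorical") {
    tab <- table(x, g)
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out <- tibble::tibble(variable = variable, test = "chi-square",
                          statistic = unname(res$statistic),
                          p_value = res$p.value)
  } else if (type == "parametric") {
    if (is.numeric(x) && all(tapply(x, g, function(v) stats::var(v)) == 0) &&
        length(unique(x)) == 1) {
      return(tibble::tibble(variable = variable, test = "t-test",
                            statistic = NA_real_, p_value = NA_real_))
    }
    if (nlevels(g) == 2) {
      res <- stats::t.test(x ~ g)
      out <- tibble::tibble(variable = variable, test = "t-test (Welch)",
                            statistic = unname(res$statistic),
                            p_value = res$p.value)
    } else {
      fit <- stats::aov(x ~ g)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      fstat <- summary(fit)[[1]][["F value"]][1]
      hom <- tryCatch(stats::bartlett.test(x ~ g)$p.value >= 0.05,
                      error = function(e) TRUE)
      posthoc <- if (hom) {
        th <- stats::TukeyHSD(fit)$g
        tibble::tibble(comparison = rownames(th), diff = th[, "diff"],
                       p_adj = th[, "p adj"])
      } else {
        games_howell(x, g)
      }
      out <- tibble::tibble(
        variable = variable,
        test = paste0("ANOVA + ", if (hom) "Tukey" else "Games-Howell"),
        statistic = fstat, p_value = p
      )
    }
  } else {
    if (stats::var(x) == 0) {
      return(tibble::tibble(variable = variable, test = "Mann-Whitney U",
                            statistic = NA_real_, p_value = NA_real_))
    }
    if (nlevels(g) == 2) {
      res <- suppressWarnings(stats::wilcox.test(x ~ g))
      out <- tibble::tibble(variable = variable, test = "Mann-Whitney U",
                            statistic = unname(res$statistic),
                            p_value = res$p.value)
    } else {
      res <- stats::kruskal.test(x ~ g)
      out <- tibble::tibble(variable = variable, test = "Kruskal-Wallis",
                            statistic = unname(res$statistic),
                            p_value = res$p.value)
    }
  }
  if (!is.null(posthoc)) attr(out, "posthoc") <- posthoc
  out
}

#' Backward stepwise logistic regression
#'
#' Fits a binomial GLM of a binary outcome on candidates pre-screened by
#' [spearman_screen()] at `entry_p`, then removes the least significant
#' variable in turn until all remaining Wald p-values are below `stay_p` or
#' no removal improves the fit: a non-significant variable is kept when
#' dropping it would increase the AIC. Variables declared nonparametric are
#' log-transformed before entry when strictly positive and right-skewed
#' (moment skewness > 1). Quasi-separated variables (Wald SE > 50) are
#' dropped with a warning.
#'
#' @param data Data frame.
#' @param outcome Name of a binary (logical or 0/1) outcome column.
#' @param candidates Character vector of candidate predictors.
#' @param entry_p Univariate screen threshold (default 0.1).
#' @param stay_p Retention threshold on the Wald p-value (default 0.05).
#' @param nonparametric Candidates eligible for log transformation.
#' @param screen If `FALSE`, skip the univariate screen and enter all
#'   candidates.
#' @param max_iter Safety cap on elimination passes.
#' @return Object of class `pd_logistic`; see [tidy.pd_logistic()] and
#'   [glance.pd_logistic()].
#' @export
backward_logistic <- function(data, outcome, candidates,
                              entry_p = 0.1, stay_p = 0.05,
                              nonparametric = character(),
                              screen = TRUE, max_iter = 100) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("Outcome must be binary.", call. = FALSE)

  screen_tbl <- spearman_screen(data, outcome, candidates)
  entered <- if (screen) {
    screen_tbl$variable[!is.na(screen_tbl$p_value) &
                          screen_tbl$p_value < entry_p]
  } else {
    candidates
  }

  df <- data[, intersect(c(entered), names(data)), drop = FALSE]
  df <- tibble::as_tibble(lapply(df, function(col) {
    if (is.logical(col) || is.factor(col)) as.numeric(as.factor(col)) - 1 else col
  }))
  transformed <- character()
  for (v in intersect(entered, nonparametric)) {
    if (all(df[[v]] > 0, na.rm = TRUE) && sample_skewness(df[[v]]) > 1) {
      df[[paste0("log_", v)]] <- log(df[[v]])
      df[[v]] <- NULL
      transformed <- c(transformed, v)
    }
  }
  vars <- names(df)
  df$.y <- y

  fit_model <- function(vv) {
    f <- if (length(vv)) {
      stats::reformulate(vv, response = ".y")
    } else {
      .y ~ 1
    }
    suppressWarnings(stats::glm(f, family = stats::binomial(), data = df))
  }

  dropped <- character()
  fit <- fit_model(vars)
  for (iter in seq_len(max_iter)) {
    if (!length(vars)) break
    sm <- summary(fit)$coefficients
    sm <- sm[setdiff(rownames(sm), "(Intercept)"), , drop = FALSE]
    se <- stats::setNames(sm[, "Std. Error"], rownames(sm))
    sep <- names(se)[se > 50]
    if (length(sep)) {
      warning("Dropping quasi-separated variable(s): ",
              paste(sep, collapse = ", "), call. = FALSE)
      vars <- setdiff(vars, sep)
      dropped <- c(dropped, sep)
      fit <- fit_model(vars)
      next
    }
    ps <- stats::setNames(sm[, "Pr(>|z|)"], rownames(sm))
    weak <- names(sort(ps[ps >= stay_p], decreasing = TRUE))
    if (!length(weak)) break
    removed <- FALSE
    for (v in weak) {
      cand_fit <- fit_model(setdiff(vars, v))
      if (stats::AIC(cand_fit) <= stats::AIC(fit)) {
        vars <- setdiff(vars, v)
        dropped <- c(dropped, v)
        fit <- cand_fit
        removed <- TRUE
        break
      }
    }
    if (!removed) break # every weak variable improves fit; keep them
  }
  if (!fit$converged) stop("Logistic fit did not converge.", call. = FALSE)

  n <- nrow(df)
  dev <- fit$deviance
  null_dev <- fit$null.deviance
  r2_cs <- 1 - exp((dev - null_dev) / n)
  r2_nagelkerke <- r2_cs / (1 - exp(-null_dev / n))

  structure(
    list(fit = fit, retained = vars, dropped = dropped,
         transformed = transformed, screen = screen_tbl,
         entered = entered, n = n,
         pseudo_r2 = r2_nagelkerke,
         entry_p = entry_p, stay_p = stay_p),
    class = "pd_logistic"
  )
}

#' @export
print.pd_logistic <- function(x, ...) {
  cat("<pd_logistic> n =", x$n,
      "| retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  cat("Nagelkerke r2 =", round(x$pseudo_r2, 3), "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a backward logistic fit
#'
#' One row per retained term with the coefficient, its standard error, the
#' Wald statistic `(beta/SE)^2`, the odds ratio `exp(beta)` and its 95%
#' Wald interval `exp(beta +/- 1.96 SE)`.
#'
#' @param x A [backward_logistic()] fit.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std_error`, `wald`,
#'   `odds_ratio`, `conf_low`, `conf_high`, `p_value`.
#' @export
tidy.pd_logistic <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  if (!length(terms)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std_error = numeric(), wald = numeric(),
                          odds_ratio = numeric(), conf_low = numeric(),
                          conf_high = numeric(), p_value = numeric()))
  }
  beta <- sm[terms, "Estimate"]
  se <- sm[terms, "Std. Error"]
  tibble::tibble(
    term = terms,
    estimate = unname(beta),
    std_error = unname(se),
    wald = unname((beta / se)^2),
    odds_ratio = unname(exp(beta)),
    conf_low = unname(exp(beta - 1.96 * se)),
    conf_high = unname(exp(beta + 1.96 * se)),
    p_value = unname(sm[terms, "Pr(>|z|)"])
  )
}

#' @rdname tidy.pd_logistic
#' @export
glance.pd_logistic <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_entered = length(x$entered),
    n_retained = length(x$retained),
    aic = stats::AIC(x$fit),
    deviance = x$fit$deviance,
    null_deviance = x$fit$null.deviance,
    pseudo_r2_nagelkerke = x$pseudo_r2
  )
}

#' Grouped cohort summary table
#'
#' One row per declared variable, summarised within each level of the
#' grouping column as mean +/- SD (parametric), median (IQR)
#' (nonparametric) or n (%) (categorical), with the matching group test
#' p-value from [group_tests()] and conventional significance stars.
#'
#' @param data Data frame.
#' @param grouping Grouping column (e.g. a balance-sign flag).
#' @param variables Named character vector: names are columns, values their
#'   declared type (`"parametric"`, `"nonparametric"`, `"categorical"`).
#' @return Tibble with `variable`, one summary column per group, `p_value`
#'   and `stars`.
#' @export
grouped_summary <- function(data, grouping, variables) {
  g <- factor(data[[grouping]])
  fmt <- function(x, type) {
    x <- x[!is.na(x)]
    if (type == "parametric") {
      sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
    } else if (type == "nonparametric") {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.2f (%.2f–%.2f)", q[2], q[1], q[3])
    } else {
      x <- as.logical(x)
      sprintf("%d (%.1f)", sum(x), round_half_up(100 * mean(x), 1))
    }
  }
  rows <- purrr::imap(variables, function(type, v) {
    cells <- purrr::map_chr(levels(g),
                            ~ fmt(data[[v]][g == .x & !is.na(g)], type))
    names(cells) <- levels(g)
    p <- tryCatch(group_tests(data, v, grouping, type = type)$p_value,
                  error = function(e) NA_real_)
    stars <- dplyr::case_when(
      is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
      p < 0.05 ~ "*", TRUE ~ ""
    )
    tibble::as_tibble(c(list(variable = v), as.list(cells),
                        list(p_value = p, stars = stars)))
  })
  dplyr::bind_rows(rows)
}
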