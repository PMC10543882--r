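test_that("percentages are rounded half away from zero to one decimal", {
  expect_equal(round_half_up(42.65), 42.7)
  expect_equal(round_half_up(42.64), 42.6)
  expect_equal(round_half_up(-0.15, 1), -0.2)
  expect_equal(round_half_up(100 * 78 / 183), 42.6)
})

test_that("balance tabulation reproduces counts overall and per stratum", {
  fx <- make_count_fixture()
  b <- compute_balance(fx$patients, fx$exchanges)
  full <- dplyr::left_join(fx$patients, b, by = "patient_id")

  tab <- tabulate_balance_groups(full, "peritoneal", by = "modality")
  expect_equal(tab$n_positive[tab$stratum == "all"], 78)
  expect_equal(tab$pct_positive[tab$stratum == "all"], 42.6)
  expect_equal(tab$pct_positive[match(c("APD", "CAPD", "CCPD"), tab$stratum)],
               c(35.8, 41.7, 47.6))
  expect_equal(sum(tab$n[tab$stratum != "all"]), tab$n[tab$stratum == "all"])

  # permutation invariance of the counts
  perm <- full[sample.int(nrow(full)), ]
  tab2 <- tabulate_balance_groups(perm, "peritoneal", by = "modality")
  expect_equal(dplyr::arrange(tab2, stratum), dplyr::arrange(tab, stratum))

  allneg <- dplyr::mutate(full, peritoneal_positive = FALSE)
  expect_equal(
    tabulate_balance_groups(allneg, "peritoneal", by = NULL)$pct_positive, 0
  )
  expect_error(tabulate_balance_groups(full[0, ], "peritoneal"), "Empty")
})

test_that("spearman screen matches rank arithmetic and the brute-force oracle", {
  d <- tibble::tibble(x = 1:5, y = c(2, 1, 4, 3, 5))
  out <- spearman_screen(d, "y", "x")
  expect_equal(out$rho, 1 - 6 * 4 / (5 * 24)) # 0.8 by the d^2 formula
  expect_equal(spearman_screen(tibble::tibble(x = 1:6, y = (1:6)^3),
                               "y", "x")$rho, 1)

  # exhaustive small cases: all permutations at n = 5, plus tied data
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v),
                  function(i) lapply(perms(v[-i]), function(p) c(v[i], p))),
           recursive = FALSE)
  }
  x <- 1:5
  for (p in perms(1:5)) {
    got <- spearman_screen(tibble::tibble(x = x, y = p), "y", "x")
    expect_equal(got$rho, oracle_spearman(x, p), tolerance = 1e-12)
  }
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    xt <- sample(1:4, n, replace = TRUE)
    yt <- sample(1:4, n, replace = TRUE)
    want <- oracle_spearman(xt, yt)
    got <- spearman_screen(tibble::tibble(x = xt, y = yt), "y", "x")
    if (is.na(want)) expect_true(is.na(got$rho)) else
      expect_equal(got$rho, want, tolerance = 1e-12)
  }

  # constant column is reported missing, not an error
  cc <- spearman_screen(tibble::tibble(x = rep(1, 10), y = 1:10), "y", "x")
  expect_true(is.na(cc$rho) && is.na(cc$p_value))
})

test_that("group tests pick the declared test and significance class", {
  # equal proportions: chi-square near 1
  d <- tibble::tibble(x = rep(c(TRUE, FALSE), 50), g = rep(c("a", "b"), each = 50))
  expect_gt(group_tests(d, "x", "g", "categorical")$p_value, 0.9)

  # 2x2 counts (32,7 / 58,86): strongly significant
  d2 <- tibble::tibble(
    x = rep(c(TRUE, FALSE, TRUE, FALSE), c(32, 7, 58, 86)),
    g = rep(c("pos", "neg"), c(39, 144))
  )
  res2 <- group_tests(d2, "x", "g", "categorical")
  expect_lt(res2$p_value, 0.01)
  expect_equal(res2$statistic, 183 * (32 * 86 - 7 * 58)^2 /
                 (39 * 144 * 90 * 93), tolerance = 1e-9)

  # two normals two sd apart at n = 50/50: decisive t-test
  set.seed(8)
  d3 <- tibble::tibble(x = c(rnorm(50), rnorm(50, 2)),
                       g = rep(c("a", "b"), each = 50))
  expect_lt(group_tests(d3, "x", "g", "parametric")$p_value, 0.001)
  expect_equal(group_tests(d3, "x", "g", "nonparametric")$test, "Mann-Whitney U")

  # three groups: ANOVA with a post-hoc attached
  d4 <- tibble::tibble(x = c(rnorm(40), rnorm(40, 1), rnorm(40, 2)),
                       g = rep(c("a", "b", "c"), each = 40))
  res4 <- group_tests(d4, "x", "g", "parametric")
  expect_match(res4$test, "ANOVA")
  ph <- attr(res4, "posthoc")
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adj >= 0 & ph$p_adj <= 1))
  expect_equal(group_tests(d4, "x", "g", "nonparametric")$test, "Kruskal-Wallis")

  # unequal variances route to Games-Howell
  d5 <- tibble::tibble(x = c(rnorm(40, 0, 0.2), rnorm(40, 1, 3), rnorm(40, 2, 0.2)),
                       g = rep(c("a", "b", "c"), each = 40))
  expect_match(group_tests(d5, "x", "g", "parametric")$test, "Games-Howell")

  expect_error(group_tests(d3[d3$g == "a", ], "x", "g", "parametric"),
               "two non-empty")
})

test_that("logistic backward elimination matches the 2x2 closed form", {
  # single binary covariate: beta must equal the table log odds ratio
  d <- tibble::tibble(
    x = rep(c(1, 1, 0, 0), c(30, 10, 15, 45)),
    y = rep(c(1, 0, 1, 0), c(30, 10, 15, 45))
  )
  fit <- backward_logistic(d, "y", "x", screen = FALSE, stay_p = 1)
  td <- tidy(fit)
  expect_equal(td$estimate, log(30 * 45 / (10 * 15)), tolerance = 1e-6)
  # defining identities of the reported fields
  expect_equal(td$odds_ratio, exp(td$estimate))
  expect_equal(td$wald, (td$estimate / td$std_error)^2)
  expect_equal(td$conf_low, exp(td$estimate - 1.96 * td$std_error))
  expect_equal(td$conf_high, exp(td$estimate + 1.96 * td$std_error))
  g <- glance(fit)
  expect_true(g$pseudo_r2_nagelkerke > 0 && g$pseudo_r2_nagelkerke < 1)
})

test_that("backward elimination drops noise and keeps planted effects", {
  set.seed(42)
  n <- 600
  d <- tibble::tibble(
    binder = rbinom(n, 1, 0.5),
    noise1 = rnorm(n),
    noise2 = rnorm(n),
    uf = rnorm(n)
  )
  eta <- -1 + 2.5 * d$binder - 0.8 * d$uf
  d$y <- rbinom(n, 1, plogis(eta))
  fit <- backward_logistic(d, "y", c("binder", "noise1", "noise2", "uf"))
  expect_true(all(c("binder", "uf") %in% fit$retained))
  td <- tidy(fit)
  expect_gt(td$odds_ratio[td$term == "binder"], 1)
  expect_lt(td$odds_ratio[td$term == "uf"], 1)

  # outcome exactly orthogonal to every candidate: empty retained list
  d0 <- tibble::tibble(
    y = rep(0:1, each = 100),
    a = rep(rep(c(-1, 1), 50), 2), # identical pattern in both outcome arms
    b = rep(rep(c(-1, -1, 1, 1), 25), 2)
  )
  fit0 <- backward_logistic(d0, "y", c("a", "b"), screen = FALSE)
  expect_length(fit0$retained, 0)
  expect_equal(nrow(tidy(fit0)), 0)

  expect_error(backward_logistic(tibble::tibble(y = c(0, 1, 2), x = 1:3),
                                 "y", "x"), "binary")
})

test_that("right-skewed nonparametric variables are log transformed on entry", {
  set.seed(15)
  n <- 400
  d <- tibble::tibble(vol = rlnorm(n, 0, 1.2))
  d$y <- rbinom(n, 1, plogis(-1.5 * log(d$vol)))
  fit <- backward_logistic(d, "y", "vol", nonparametric = "vol")
  expect_equal(fit$transformed, "vol")
  expect_true("log_vol" %in% fit$retained)
})

test_that("grouped summaries format by declared type with matching stars", {
  set.seed(6)
  d <- tibble::tibble(
    g = rep(c("neg", "pos"), each = 40),
    wt = c(rnorm(40, 70, 5), rnorm(40, 71, 5)),
    urine = rlnorm(80, 0, 0.5),
    male = rbinom(80, 1, 0.5) == 1,
    ca = c(rnorm(40, 2.33, 0.1), rnorm(40, 2.17, 0.1))
  )
  tab <- grouped_summary(d, "g", c(wt = "parametric", urine = "nonparametric",
                                   male = "categorical", ca = "parametric"))
  expect_equal(tab$variable, c("wt", "urine", "male", "ca"))
  expect_match(tab$neg[1], "±")
  expect_match(tab$pos[2], "\\(")
  expect_equal(tab$stars[4], "***") # 1.6 sd separation at n = 40/40
})
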