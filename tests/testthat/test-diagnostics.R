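# Contingency tables, diagnostic metrics, association tests and ROC.

test_that("dichotomize counts a hand-enumerable toy set correctly", {
  pts <- data.frame(t_half_s = c(5, 9, 12, 40),
                    sto2_pct = c(70, 65, 62, 40))
  tab <- dichotomize(pts, "t_half_s", cutoff = 10, direction = "le")
  expect_equal(tab$tp, 2); expect_equal(tab$fp, 0)
  expect_equal(tab$fn, 1); expect_equal(tab$tn, 1)

  all_good <- data.frame(t_half_s = c(3, 4, 5), sto2_pct = c(80, 85, 90))
  tab2 <- dichotomize(all_good, "t_half_s", cutoff = 10, direction = "le")
  expect_equal(c(tab2$fp, tab2$fn, tab2$tn), c(0, 0, 0))

  expect_error(dichotomize(pts[0, ], "t_half_s", cutoff = 10,
                           direction = "le"), "empty")
})

test_that("ties at the cutoff follow the printed inequality", {
  pts <- data.frame(f_max_au = c(25, 25, 30), t_half_s = c(10, 10, 10),
                    sto2_pct = c(70, 50, 70))
  # strict > for F_MAX: the two ties fall outside the safe range
  t1 <- dichotomize(pts, "f_max_au")
  expect_equal(c(t1$tp, t1$fp, t1$fn, t1$tn), c(1, 0, 1, 1))
  # inclusive <= for T_1/2MAX: ties fall inside
  t2 <- dichotomize(pts, "t_half_s")
  expect_equal(c(t2$tp, t2$fp, t2$fn, t2$tn), c(2, 1, 0, 0))
})

test_that("dichotomization of a seeded cohort equals the brute-force loop", {
  pts <- generate_cohort(cohort_config(), seed = 3)
  tab <- dichotomize(pts, "t_max_s", cutoff = 30, direction = "le")
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(pts))) {
    within <- pts$t_max_s[i] <= 30
    good <- pts$sto2_pct[i] >= 60
    if (within && good) tp <- tp + 1
    else if (within) fp <- fp + 1
    else if (good) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(tp, fp, fn, tn))
})

test_that("diagnostic metrics reproduce the published T_MAX row", {
  met <- diagnostic_metrics(contingency_2x2(tp = 322, fp = 1, fn = 7, tn = 10))
  est <- round(met$estimate_pct, 1)
  names(est) <- met$metric
  expect_equal(unname(est), c(97.9, 90.9, 99.7, 58.8, 97.6))
})

test_that("a perfect table yields 100% everywhere and zero denominators flag NA", {
  met <- diagnostic_metrics(contingency_2x2(tp = 50, fp = 0, fn = 0, tn = 5))
  expect_true(all(met$estimate_pct == 100))

  met2 <- diagnostic_metrics(contingency_2x2(tp = 10, fp = 5, fn = 0, tn = 0))
  npv <- met2[met2$metric == "npv", ]
  expect_true(is.na(npv$estimate_pct) && is.na(npv$ci_low_pct))
  spec <- met2[met2$metric == "specificity", ]
  expect_equal(spec$estimate_pct, 0)
})

test_that("Clopper-Pearson intervals match the beta-quantile oracle", {
  ci <- diagnostic_metrics(contingency_2x2(tp = 319, fp = 5, fn = 10, tn = 6))
  sens <- ci[ci$metric == "sensitivity", ]
  oracle <- 100 * oracle_clopper(319, 329)
  expect_equal(sens$ci_low_pct, oracle[1], tolerance = 1e-9)
  expect_equal(sens$ci_high_pct, oracle[2], tolerance = 1e-9)
  # published interval for the same count, printed to 1 decimal
  expect_equal(round(c(sens$ci_low_pct, sens$ci_high_pct), 1), c(94.5, 98.5))
  # degenerate bounds: x = n and x = 0
  expect_equal(oracle_clopper(10, 10)[2], 1)
  w <- diagnostic_metrics(contingency_2x2(tp = 10, fp = 0, fn = 0, tn = 1),
                          ci_method = "wilson")
  expect_true(all(w$ci_low_pct >= 0 & w$ci_high_pct <= 100))
})

test_that("accuracy satisfies its prevalence-weighted identity exactly", {
  set.seed(37)
  for (i in 1:20) {
    cts <- rmultinom(1, 200, runif(4, 0.05, 1))[, 1]
    tab <- contingency_2x2(cts[1], cts[2], cts[3], cts[4])
    met <- diagnostic_metrics(tab)
    est <- met$estimate_pct; names(est) <- met$metric
    P <- cts[1] + cts[3]; N <- cts[2] + cts[4]
    if (P == 0 || N == 0) next
    expect_equal(est[["accuracy"]],
                 (est[["sensitivity"]] * P + est[["specificity"]] * N) / (P + N),
                 tolerance = 1e-9)
  }
})

test_that("association tests pick the right method and match enumeration", {
  even <- association_test(contingency_2x2(10, 10, 10, 10))
  expect_equal(even$method, "chi-square")
  expect_equal(even$p_value, 1)

  sep <- association_test(contingency_2x2(5, 0, 0, 5))
  expect_equal(sep$method, "fisher")
  expect_equal(sep$p_value, oracle_fisher_enum(5, 0, 0, 5), tolerance = 1e-9)
  expect_equal(sep$p_value, 0.0079365, tolerance = 1e-4)

  # published slope table: strongly associated
  slope_tab <- association_test(contingency_2x2(234, 0, 95, 11))
  expect_lt(slope_tab$p_value, 0.001)
})

test_that("Fisher p-values equal hypergeometric enumeration on small tables", {
  set.seed(41)
  for (i in 1:25) {
    cts <- as.vector(rmultinom(1, sample(8:30, 1), runif(4, 0.1, 1)))
    tab <- contingency_2x2(cts[1], cts[2], cts[3], cts[4])
    res <- association_test(tab)
    if (res$method != "fisher") next
    expect_equal(res$p_value,
                 oracle_fisher_enum(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-9)
  }
})

test_that("ROC handles separation, the null case, and matches pair counting", {
  sep <- data.frame(t_max_s = c(rep(5, 20), rep(60, 5)),
                    sto2_pct = c(rep(80, 20), rep(40, 5)))
  expect_equal(roc_analysis(sep, "t_max_s")$auc, 1)

  set.seed(43)
  null_pts <- data.frame(slope_au_per_s = rnorm(200),
                         sto2_pct = sample(c(40, 80), 200, replace = TRUE))
  rn <- roc_analysis(null_pts, "slope_au_per_s")
  expect_true(rn$ci_low <= 0.5 && 0.5 <= rn$ci_high)
  expect_gt(rn$p_value, 0.05)

  pts <- data.frame(t_half_s = round(rexp(100, 0.2), 1),
                    sto2_pct = runif(100, 40, 95))
  r <- roc_analysis(pts, "t_half_s")
  expect_equal(r$auc,
               oracle_auc_pairs(-pts$t_half_s, as.integer(pts$sto2_pct >= 60)),
               tolerance = 1e-12)

  expect_error(roc_analysis(data.frame(t_max_s = 1:10,
                                       sto2_pct = rep(80, 10)), "t_max_s"),
               "undefined ROC")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(47)
  pts <- data.frame(slope_au_per_s = rlnorm(150, 2, 0.5),
                    sto2_pct = runif(150, 40, 95))
  a1 <- roc_analysis(pts, "slope_au_per_s")$auc
  pts2 <- pts; pts2$slope_au_per_s <- log(pts$slope_au_per_s)
  pts3 <- pts; pts3$slope_au_per_s <- pts$slope_au_per_s^3
  expect_equal(roc_analysis(pts2, "slope_au_per_s")$auc, a1, tolerance = 1e-12)
  expect_equal(roc_analysis(pts3, "slope_au_per_s")$auc, a1, tolerance = 1e-12)
})

test_that("orientation is fixed by the registry, not auto-flipped", {
  # a parameter whose safe direction is "low" but which in this sample is
  # paradoxically low in the poor-oxygenation class must give AUC < 0.5
  pts <- data.frame(perfusion_tr = c(rep(0.9, 30), rep(0.2, 10)),
                    sto2_pct = c(rep(80, 30), rep(40, 10)))
  expect_lt(roc_analysis(pts, "perfusion_tr")$auc, 0.5)
})

test_that("diagnostic_summary binds metrics, association and AUC per parameter", {
  pts <- generate_cohort(cohort_config(), seed = 5)
  ds <- diagnostic_summary(pts, parameters = c("t_half_s", "t_max_s"))
  expect_equal(nrow(ds), 10)
  expect_true(all(c("p_value", "auc") %in% names(ds)))
  expect_true(all(ds$auc >= 0 & ds$auc <= 1))
})
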