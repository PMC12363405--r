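# first-principles survival layer against hand computations and the
# independent reference implementation

test_that("Fisher exact matches hand-enumerated hypergeometric sums", {
  expect_equal(signif(fisher_exact_2x2(matrix(c(8, 1, 0, 7), 2))$p_value, 2),
               0.0014)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  withr::with_seed(7, {
    for (i in 1:25) {
      m <- matrix(rpois(4, 5), 2)
      expect_equal(fisher_exact_2x2(m)$p_value,
                   stats::fisher.test(m)$p.value, tolerance = 1e-12)
    }
  })
})

test_that("product-limit estimates match hand computation and conventions", {
  d <- tibble::tibble(t = c(1, 2, 3), e = c(TRUE, TRUE, FALSE))
  f <- km_fit(d, t, e)
  expect_equal(f$steps$surv, c(2 / 3, 1 / 3))
  expect_equal(surv_at(f, 0.5), 1)           # flat before the first event
  expect_equal(surv_at(f, c(1, 2)), c(2 / 3, 1 / 3))
  expect_equal(f$median, 2)

  all_cens <- tibble::tibble(t = c(5, 7, 9), e = FALSE)
  f2 <- km_fit(all_cens, t, e)
  expect_identical(nrow(f2$steps), 0L)
  expect_true(is.na(f2$median))
  expect_equal(surv_at(f2, 8), 1)
  expect_error(km_fit(all_cens[0, ], t, e), "Empty")

  # ties: events precede censorings at the same time
  tie <- tibble::tibble(t = c(2, 2, 2, 4), e = c(TRUE, TRUE, FALSE, TRUE))
  ft <- km_fit(tie, t, e)
  expect_equal(ft$steps$n_risk, c(4, 1))
  expect_equal(ft$steps$surv[1], 0.5)
})

test_that("log-rank statistic matches the frozen hand-worked example", {
  d <- tibble::tibble(t = c(1, 2, 3, 4), e = TRUE,
                      g = c("A", "A", "B", "B"))
  lr <- logrank_test(d, t, e, g)
  # O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9 -> chi2 = (7/6)^2 / (17/36)
  expect_equal(lr$o_a, 2)
  expect_equal(lr$e_a, 5 / 6)
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))

  same <- tibble::tibble(t = rep(c(1, 2, 3), 2), e = TRUE,
                         g = rep(c("A", "B"), each = 3))
  lrs <- logrank_test(same, t, e, g)
  expect_equal(lrs$statistic, 0)
  expect_equal(lrs$p_value, 1)

  none <- tibble::tibble(t = c(1, 2), e = FALSE, g = c("A", "B"))
  expect_warning(lr0 <- logrank_test(none, t, e, g), "No events")
  expect_equal(lr0$p_value, 1)
})

test_that("hazard ratio is symmetric and identity under equal groups", {
  d <- tibble::tibble(t = c(1, 3, 5, 7, 2, 4, 6, 8),
                      e = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
                      g = rep(c("A", "B"), each = 4))
  hr <- mh_hazard_ratio(d, t, e, g)
  d_sw <- d |> dplyr::mutate(g = factor(g, levels = c("B", "A")))
  hr_sw <- mh_hazard_ratio(d_sw, t, e, g)
  expect_equal(hr$hr, 1 / hr_sw$hr, tolerance = 1e-12)

  same <- tibble::tibble(t = rep(c(1, 2, 3), 2), e = TRUE,
                         g = rep(c("A", "B"), each = 3))
  expect_equal(mh_hazard_ratio(same, t, e, g)$hr, 1)

  onegrp <- tibble::tibble(t = c(1, 2, 3, 4), e = c(TRUE, TRUE, FALSE, FALSE),
                           g = c("A", "A", "B", "B"))
  expect_warning(hr0 <- mh_hazard_ratio(onegrp, t, e, g), "Zero events")
  expect_true(is.infinite(hr0$conf_high) || hr0$conf_low == 0)
})

test_that("reverse-censor follow-up is the KM median of flipped indicators", {
  allc <- tibble::tibble(t = rep(50, 6), e = FALSE)
  expect_equal(reverse_km_followup(allc, t, e)$median_followup, 50)
  alle <- tibble::tibble(t = c(1, 2, 3), e = TRUE)
  expect_true(is.na(reverse_km_followup(alle, t, e)$median_followup))
  mix <- tibble::tibble(t = c(10, 20, 30, 40, 50),
                        e = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  flip <- mix |> dplyr::mutate(e = !e)
  expect_equal(reverse_km_followup(mix, t, e)$median_followup,
               km_fit(flip, t, e)$median)
})

test_that("Pearson correlation matches hand values and rejects degeneracy", {
  d <- tibble::tibble(x = 1:4, y = 2 * (1:4) + 1)
  expect_equal(pearson_r(d, x, y), 1)
  expect_equal(pearson_r(d |> dplyr::mutate(y = -x), x, y), -1)
  expect_equal(pearson_r(tibble::tibble(x = 1:4, y = c(2, 1, 4, 3)), x, y),
               0.6)
  expect_error(pearson_r(tibble::tibble(x = 1:4, y = 1), x, y),
               "zero variance")
  expect_error(pearson_r(tibble::tibble(x = 1:2, y = 2:3), x, y), "n >= 3")
})

test_that("survival computations are invariant to row order", {
  withr::with_seed(42, {
    d <- tibble::tibble(t = round(rexp(60, 0.1), 3),
                        e = runif(60) < 0.7,
                        g = sample(c("A", "B"), 60, TRUE))
    sh <- d[sample.int(60), ]
    expect_equal(tidy(km_fit(d, t, e)), tidy(km_fit(sh, t, e)))
    expect_equal(logrank_test(d, t, e, g)$statistic,
                 logrank_test(sh, t, e, g)$statistic)
    expect_equal(mh_hazard_ratio(d, t, e, g)$hr,
                 mh_hazard_ratio(sh, t, e, g)$hr)
  })
})

test_that("stratified reporting reproduces the designed cohort contrasts", {
  co <- plasmamrd:::fixture_cohort()
  rep <- stratify_and_report(co, "emr")
  expect_equal(unname(rep$contingency["EMR", "CMR"]), 8)
  expect_equal(unname(rep$contingency["no EMR", ]), c(1, 7))
  expect_equal(rep$cmr_rates$cmr_rate, c(1, 0.125))
  expect_equal(signif(rep$fisher$p_value, 2), 0.0014)
  expect_lt(rep$logrank$p_value, 0.05)
  expect_lt(rep$hazard_ratio$hr, 1)
  # self-consistency with the direct hazard-ratio computation
  direct <- mh_hazard_ratio(
    co |> dplyr::mutate(grp = factor(ifelse(emr, "EMR", "no EMR"),
                                     levels = c("EMR", "no EMR"))),
    "pfs_months", "pfs_event", "grp")
  expect_equal(rep$hazard_ratio$hr, direct$hr)
  # EMR stratum: no progression events by 24 months
  expect_equal(rep$surv_at_time$surv[rep$surv_at_time$stratum == "EMR"], 1)
  expect_equal(rep$median_followup, 50)
  td <- tidy(rep)
  expect_identical(nrow(td), 2L)

  single <- co |> dplyr::mutate(emr = TRUE)
  expect_warning(r1 <- stratify_and_report(single, "emr"), "two strata")
  expect_null(r1$fisher)
})
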