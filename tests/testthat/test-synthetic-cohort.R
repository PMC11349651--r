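test_that("generation is reproducible and respects n", {
  params <- default_cohort_params()
  params$positive$n <- 15L
  params$negative$n <- 10L
  c1 <- generate_cohort(params, seed = 99)
  c2 <- generate_cohort(params, seed = 99)
  expect_identical(c1, c2)
  expect_length(c1, 25L)

  params$positive$n <- 0L
  params$negative$n <- 0L
  expect_length(generate_cohort(params, seed = 1), 0L)

  expect_error(group_params(n = -1, age_mean = 70, age_sd = 10,
                            prop_female = 0.5, duration_mean = 3,
                            duration_sd = 1, mmse_mean = 25, mmse_sd = 2,
                            npiq_mean = 2, npiq_sd = 1,
                            npiq_domain_weights = setNames(rep(1, 12), npiq_domains()),
                            hachinski_mean = 2, hachinski_sd = 1,
                            p_rapid = 0.5, fazekas_probs = rep(0.25, 4),
                            scheltens_probs = rep(0.2, 5)))
})

test_that("generated subjects satisfy all record invariants", {
  cohort <- generate_cohort(seed = 31)  # default 30 + 22
  expect_length(cohort, 52L)
  for (s in cohort) {
    expect_s3_class(s, "caps_subject")
    expect_true(s$age > 40)
    expect_true(s$fazekas %in% 0:3)
    expect_true(s$scheltens_mtla %in% 0:4)
    expect_true(all(s$cognitive_scores$raw >= 0 & s$cognitive_scores$raw <= 30))
    expect_true(!is.unsorted(s$cognitive_scores$date))
    np <- npiq_summary(s$npiq)
    expect_true(np$total_score <= 36L)
  }
  statuses <- vapply(cohort, `[[`, character(1), "amyloid_status_reference")
  expect_equal(sum(statuses == "positive"), 30L)
  expect_equal(sum(statuses == "negative"), 22L)
})

test_that("synthesized visits reproduce the drawn rapid/slow status", {
  params <- default_cohort_params()
  params$positive$n <- 200L
  params$negative$n <- 0L
  cohort <- generate_cohort(params, seed = 8)
  rates <- vapply(cohort, function(s) annualized_decline(s)$rate, numeric(1))
  # drops of 0-2 points over 366 days stay below 2/yr; drops of 3-6 exceed it
  expect_true(all(rates[rates <= 2] < 2))
  expect_true(all(rates > 2 | rates < 2.5))
  frac_rapid <- mean(rates > 2)
  expect_gt(frac_rapid, 0.45)
  expect_lt(frac_rapid, 0.75)
})

test_that("sample means track the configured means (calibration)", {
  params <- default_cohort_params()
  params$positive$n <- 4000L
  params$negative$n <- 4000L
  for (seed in c(2, 3, 4)) {
    tab <- cohort_table(generate_cohort(params, seed = seed))
    for (grp in c("positive", "negative")) {
      sub <- tab[tab$amyloid_status_reference == grp, ]
      p <- params[[grp]]
      for (v in list(c("npiq_total", p$npiq_mean),
                     c("baseline_mmse", p$mmse_mean),
                     c("hachinski", p$hachinski_mean),
                     c("age", p$age_mean))) {
        x <- sub[[v[1]]]
        se <- sd(x) / sqrt(length(x))
        expect_lt(abs(mean(x) - as.numeric(v[2])), 3 * se,
                  label = sprintf("seed %d %s %s deviation", seed, grp, v[1]))
      }
    }
  }
})

test_that("the group contrast is preserved: positives decline more, score higher on NPI-Q", {
  params <- default_cohort_params()
  params$positive$n <- 1000L
  params$negative$n <- 1000L
  for (seed in c(13, 14, 15)) {
    tab <- cohort_table(generate_cohort(params, seed = seed))
    pos <- tab[tab$amyloid_status_reference == "positive", ]
    neg <- tab[tab$amyloid_status_reference == "negative", ]
    expect_lt(mean(pos$baseline_mmse), mean(neg$baseline_mmse))
    expect_gt(mean(pos$npiq_total), mean(neg$npiq_total))
  }
})

test_that("NPI-Q allocation matches the drawn total and favours depression/irritability", {
  params <- default_cohort_params()
  params$positive$n <- 500L
  params$negative$n <- 0L
  cohort <- generate_cohort(params, seed = 21)
  sev <- do.call(rbind, lapply(cohort, function(s) unclass(s$npiq)))
  expect_true(all(sev >= 0 & sev <= 3))
  dom_means <- colMeans(sev)
  others <- dom_means[setdiff(npiq_domains(), c("depression", "irritability"))]
  expect_gt(dom_means[["depression"]], max(others))
  expect_gt(dom_means[["irritability"]], max(others))
})

test_that("the 48-subject fixture is stable and reproduces the published table", {
  fx <- fixture_cohort()
  expect_length(fx, 48L)
  expect_identical(fx, fixture_cohort())  # deterministic, no RNG involved
  statuses <- vapply(fx, `[[`, character(1), "amyloid_status_reference")
  expect_equal(sum(statuses == "positive"), 28L)
  expect_equal(sum(statuses == "negative"), 20L)
  for (s in fx) expect_s3_class(s, "caps_subject")

  ev <- evaluate_score(fx)
  expect_equal(unlist(ev$confusion[c("tp", "fp", "tn", "fn")]),
               c(tp = 25L, fp = 4L, tn = 16L, fn = 3L))

  # the two octogenarian false negatives carry Scheltens 4, so CAPS-MT
  # reclassifies them as positive
  ev_mt <- evaluate_score(fx, score = "caps_mt")
  expect_equal(ev_mt$confusion$fn, 1L)
})
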