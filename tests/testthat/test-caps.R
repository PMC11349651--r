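test_that("component point rules match the scoring table", {
  expect_equal(npiq_points(0), 0L)
  expect_equal(npiq_points(1), 1L)
  expect_equal(npiq_points(7), 2L)
  expect_error(npiq_points(-1), "NPI-Q")

  expect_equal(fazekas_points(0), 1L)
  expect_equal(fazekas_points(1), 1L)
  expect_equal(fazekas_points(2), 0L)
  expect_equal(fazekas_points(3), 0L)
  expect_error(fazekas_points(4), "fazekas")

  expect_equal(mtla_points(2), 0L)
  expect_equal(mtla_points(3), 1L)
  expect_equal(mtla_points(4), 1L)
})

test_that("classification threshold is 'at or above', default 3", {
  expect_equal(classify(3), "positive")
  expect_equal(classify(2), "negative")
  expect_equal(classify(4), "positive")
  expect_equal(classify(2, threshold = 2), "positive")
})

test_that("compute_caps adds the three components", {
  r0 <- compute_caps(make_subject(npiq_total = 0, drop = 1, fazekas = 2))
  expect_equal(r0$caps_total, 0L)
  expect_equal(r0$predicted_status, "negative")

  r4 <- compute_caps(make_subject(npiq_total = 3, drop = 3, fazekas = 0))
  expect_equal(r4$caps_total, 4L)
  expect_equal(r4$predicted_status, "positive")

  r2 <- compute_caps(make_subject(npiq_total = 1, drop = 1, fazekas = 1))
  expect_equal(r2$caps_total, 2L)
  expect_equal(c(r2$npiq_points, r2$decline_points, r2$fazekas_points),
               c(1L, 0L, 1L))
  expect_equal(r2$predicted_status, "negative")
})

test_that("CAPS-MT appends one point for Scheltens above 2", {
  r <- compute_caps_mt(make_subject(npiq_total = 1, drop = 1, fazekas = 1,
                                    scheltens = 3))
  expect_equal(r$caps_total, 2L)
  expect_equal(r$caps_mt_total, 3L)
  expect_equal(r$predicted_status, "positive")

  r4 <- compute_caps_mt(make_subject(npiq_total = 3, drop = 3, fazekas = 0,
                                     scheltens = 0))
  expect_equal(r4$caps_mt_total, 4L)

  r1 <- compute_caps_mt(make_subject(npiq_total = 0, drop = 1, fazekas = 2,
                                     scheltens = 4))
  expect_equal(r1$caps_mt_total, 1L)
})

test_that("missing components raise errors naming the component", {
  no_faz <- make_subject(npiq_total = 2, drop = 3, fazekas = 0)
  no_faz$fazekas <- NULL
  expect_error(compute_caps(no_faz), "Fazekas",
               class = "capscore_incomplete_subject")

  one_visit <- make_subject(npiq_total = 2, drop = 3, fazekas = 0)
  one_visit$cognitive_scores <- one_visit$cognitive_scores[1L, ]
  expect_error(compute_caps(one_visit), "cognitive scores",
               class = "capscore_incomplete_subject")

  no_sch <- make_subject(npiq_total = 2, drop = 3, fazekas = 0)
  expect_error(compute_caps_mt(no_sch), "Scheltens",
               class = "capscore_incomplete_subject")
})

test_that("CAPS is monotone over the full discrete component lattice", {
  # component functions over their entire domains
  np <- vapply(0:36, npiq_points, integer(1))
  expect_true(all(diff(np) >= 0L))
  fz <- vapply(0:3, fazekas_points, integer(1))
  expect_true(all(diff(fz) <= 0L))
  mt <- vapply(0:4, mtla_points, integer(1))
  expect_true(all(diff(mt) >= 0L))

  # end-to-end: totals over the NPI x decline x Fazekas x Scheltens lattice
  lat <- expand.grid(npiq = c(0L, 1L, 2L, 5L), drop = c(1L, 4L),
                     faz = 0:3, sch = 0:4)
  lat$caps <- NA_integer_
  lat$caps_mt <- NA_integer_
  for (i in seq_len(nrow(lat))) {
    r <- compute_caps_mt(make_subject(npiq_total = lat$npiq[i],
                                      drop = lat$drop[i],
                                      fazekas = lat$faz[i],
                                      scheltens = lat$sch[i]))
    lat$caps[i] <- r$caps_total
    lat$caps_mt[i] <- r$caps_mt_total
  }
  expect_true(all(lat$caps %in% 0:4))
  expect_true(all(lat$caps_mt %in% 0:5))
  expect_equal(range(lat$caps), c(0L, 4L))
  expect_equal(range(lat$caps_mt), c(0L, 5L))
  # monotone in NPI-Q and decline, antitone in Fazekas, holding others fixed
  for (i in seq_len(nrow(lat))) {
    up_np <- lat[lat$npiq >= lat$npiq[i] & lat$drop == lat$drop[i] &
                 lat$faz == lat$faz[i] & lat$sch == lat$sch[i], ]
    expect_true(all(up_np$caps >= lat$caps[i]))
    up_fz <- lat[lat$npiq == lat$npiq[i] & lat$drop == lat$drop[i] &
                 lat$faz >= lat$faz[i] & lat$sch == lat$sch[i], ]
    expect_true(all(up_fz$caps <= lat$caps[i]))
  }
})

test_that("the CAPS decision ignores fields outside its three components", {
  s <- make_subject(npiq_total = 2, drop = 3, fazekas = 1, scheltens = 2,
                    status = "positive")
  base <- compute_caps(s)
  s$age <- 85
  s$sex <- "male"
  s$hachinski <- 4L
  s$lawton_brody <- 23L
  s$scheltens_mtla <- 4L
  s$amyloid_status_reference <- "negative"
  mod <- compute_caps(s)
  expect_equal(mod$caps_total, base$caps_total)
  expect_equal(mod$predicted_status, base$predicted_status)
})
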