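mk_dates <- function(days, origin = "2021-03-01") as.character(as.Date(origin) + days)

test_that("eligibility applies the pre-progression count and window rules", {
  prog <- "2021-09-01"
  # 3 samples at progression-200/-90/-10 days: eligible for PFS
  d <- as.character(as.Date(prog) - c(200, 90, 10))
  expect_true(slope_eligibility(d, prog, "PFS"))
  # 3 samples all >120d before progression: window empty
  d2 <- as.character(as.Date(prog) - c(200, 170, 140))
  el2 <- slope_eligibility(d2, prog, "PFS")
  expect_false(el2)
  expect_match(attr(el2, "reason"), "window")
  # only 2 pre-progression samples + 1 after: ineligible for OS
  d3 <- as.character(c(as.Date(prog) - c(150, 60), as.Date(prog) + 30))
  el3 <- slope_eligibility(d3, prog, "OS")
  expect_false(el3)
  expect_match(attr(el3, "reason"), "before progression")
  # the same draws in the OS window but not the PFS one
  d4 <- as.character(c(as.Date(prog) - c(200, 170, 140), as.Date(prog) + 30))
  expect_true(slope_eligibility(d4, prog, "OS"))
  expect_false(slope_eligibility(d4, prog, "PFS"))
  expect_false(slope_eligibility(d, NA, "PFS"))
})

test_that("the slope is the least-squares slope in percentage points per day", {
  t1 <- "2021-03-01"
  prog <- "2021-06-01"
  r <- delfi_tf_slope(mk_dates(c(0, 30, 60)), c(10, 8, 6), t1, prog, "PFS")
  expect_equal(r$slope, -1 / 15)
  expect_equal(r$n_points, 3L)
  r0 <- delfi_tf_slope(mk_dates(c(0, 30, 60)), c(4, 4, 4), t1, prog, "PFS")
  expect_equal(r0$slope, 0)
  # random series match the closed form; shift and scale behave linearly
  withr::local_seed(17)
  for (i in 1:5) {
    days <- sort(sample(0:90, 6))
    y <- runif(6, 0, 30)
    r1 <- delfi_tf_slope(mk_dates(days), y, t1, prog, "PFS")
    beta <- sum((days - mean(days)) * (y - mean(y))) / sum((days - mean(days))^2)
    expect_equal(r1$slope, beta)
    r2 <- delfi_tf_slope(mk_dates(days, origin = "2022-03-01"), y, "2022-03-01",
                         "2022-06-01", "PFS")
    expect_equal(r2$slope, r1$slope)
    r3 <- delfi_tf_slope(mk_dates(days), 2 * y, t1, prog, "PFS")
    expect_equal(r3$slope, 2 * r1$slope)
  }
  # points after the analysis window are excluded: OS admits 60 extra days
  days <- c(0, 40, 80, 110)
  y <- c(10, 6, 4, 9)
  prog2 <- mk_dates(90)
  rpfs <- delfi_tf_slope(mk_dates(days), y, t1, prog2, "PFS")
  ros <- delfi_tf_slope(mk_dates(days), y, t1, prog2, "OS")
  expect_equal(rpfs$n_points, 3L)
  expect_equal(ros$n_points, 4L)
  # fewer than 2 included points: undefined
  rbad <- delfi_tf_slope(mk_dates(c(-10, 0)), c(5, 4), mk_dates(0), prog, "PFS")
  expect_true(is.na(rbad$slope))
})

test_that("cohort slopes dichotomize at the eligible median with ties below", {
  sl <- tibble::tibble(patient_id = paste0("P", 1:3), analysis = "PFS",
                       slope = c(-1, 0, 2), n_points = 3L, eligible = TRUE,
                       above_median = NA)
  d <- dichotomize_slopes(sl)
  expect_equal(d$above_median, c(FALSE, FALSE, TRUE))  # tie at the median goes below
  sl$slope <- c(3, 3, 3)
  expect_equal(dichotomize_slopes(sl)$above_median, c(FALSE, FALSE, FALSE))
  sl2 <- tibble::tibble(patient_id = paste0("P", 1:4), analysis = "PFS",
                        slope = c(-2, -1, 1, 2), n_points = 3L, eligible = TRUE,
                        above_median = NA)
  expect_equal(dichotomize_slopes(sl2)$above_median, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("cohort slope analysis joins scores with clinical metadata", {
  scores <- tibble::tibble(
    patient_id = rep(c("A", "B"), each = 4),
    date = c(mk_dates(c(-5, 20, 50, 80)), mk_dates(c(-5, 20, 200, 250))),
    delfi_tf = c(10, 8, 6, 4, 5, 5, 5, 20))
  clinical <- tibble::tibble(
    patient_id = c("A", "B"),
    treatment_start = mk_dates(0),
    progression_date = c(mk_dates(100), mk_dates(100)))
  res <- delfi_slopes(scores, clinical, "PFS")
  # patient A: T1 at day 20, collinear decline of -2 per 30 days
  expect_true(res$eligible[res$patient_id == "A"])
  expect_equal(res$slope[res$patient_id == "A"], -2 / 30)
  # patient B has only two draws before progression
  expect_false(res$eligible[res$patient_id == "B"])
})
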