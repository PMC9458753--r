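test_that("compute_volume implements the ellipsoid formula", {
  expect_equal(compute_volume(2, 1), pi / 3)
  # l = w = d reduces to the sphere volume
  d <- 3.7
  expect_equal(compute_volume(d, d), pi * d^3 / 6)
  expect_equal(compute_volume(0, 5), 0)
  expect_error(compute_volume(-1, 2), "non-negative")
})

test_that("censoring flags unsustained rapid doubling and nothing else", {
  # the worked example: a 6x spike over 3 days that immediately reverses
  tc <- tumor_timecourse("m", "control", c(0, 3, 6), c(100, 600, 110))
  expect_equal(censor_timecourse(tc)$censored, c(FALSE, TRUE, FALSE))
  # the sustained counterpart is kept
  tc2 <- tumor_timecourse("m", "control", c(0, 3, 6, 9),
                          c(100, 600, 1200, 2400))
  expect_false(any(censor_timecourse(tc2)$censored))
  # a monotone series with all ratios below the fold threshold never triggers
  tc3 <- tumor_timecourse("m", "control", 0:5, 100 * 1.8^(0:5))
  expect_false(any(censor_timecourse(tc3)$censored))
  # slow doubling (gap wider than the window) is biology, not artifact
  tc4 <- tumor_timecourse("m", "control", c(0, 10, 20), c(100, 500, 120))
  expect_false(any(censor_timecourse(tc4)$censored))
  expect_warning(out <- censor_timecourse(
    tumor_timecourse("m", "control", c(0, 3), c(100, 600))), "fewer than 3")
  expect_equal(out$censored, c(FALSE, FALSE))
})

test_that("censoring is idempotent and only touches flags", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    times <- cumsum(c(0, runif(n - 1, 2, 6)))
    vols <- 200 * exp(0.05 * times) * exp(rnorm(n, 0, 0.3))
    j <- sample(2:(n - 1), 1)
    vols[j] <- vols[j] * runif(1, 2.5, 8)
    tc <- tumor_timecourse("m", "treatment", times, vols)
    once <- censor_timecourse(tc)
    twice <- censor_timecourse(once)
    expect_identical(once, twice)
    expect_identical(once$times, tc$times)
    expect_identical(once$volumes, tc$volumes)
    # first and last points are never censored
    expect_false(once$censored[1])
    expect_false(once$censored[n])
  }
})

test_that("trajectory classification compares endpoints within a band", {
  up <- tumor_timecourse("m", "control", c(0, 10, 20), c(200, 400, 800))
  expect_equal(classify_trajectory(up, 0.2), "increasing")
  down <- tumor_timecourse("m", "control", c(0, 10, 20), c(200, 150, 90))
  expect_equal(classify_trajectory(down, 0.2), "decreasing")
  flat <- tumor_timecourse("m", "control", c(0, 10, 20), c(200, 190, 205))
  expect_equal(classify_trajectory(flat, 0.2), "stable")
  # censored endpoint is skipped: last non-censored point decides
  spiky <- tumor_timecourse("m", "control", c(0, 10, 20), c(200, 205, 900),
                            censored = c(FALSE, FALSE, TRUE))
  expect_equal(classify_trajectory(spiky, 0.2), "stable")
  all_cens <- tumor_timecourse("m", "control", c(0, 10), c(200, 210),
                               censored = c(TRUE, TRUE))
  expect_error(classify_trajectory(all_cens), "non-censored")
})

test_that("fisher_exact_response matches the hypergeometric enumeration oracle", {
  # the experimental outcome: 1/25 control vs 7/29 treated mice decreasing
  ctrl <- response_counts(19, 1, 5)
  trt <- response_counts(19, 7, 3)
  p <- fisher_exact_response(ctrl, trt)
  expect_equal(p, fisher_oracle(1, 24, 7, 22), tolerance = 1e-10)
  expect_equal(round(p, 2), 0.06)
  # no association
  expect_equal(fisher_exact_response(response_counts(15, 5, 5),
                                     response_counts(15, 5, 5)), 1)
  # perfectly separated table: only two equally extreme tables exist
  expect_equal(fisher_exact_response(response_counts(10, 0, 0),
                                     response_counts(0, 10, 0)),
               2 / choose(20, 10), tolerance = 1e-10)
  expect_error(fisher_exact_response(response_counts(0, 0, 0), trt),
               "non-empty")
})

test_that("fisher_exact_response is symmetric in groups and response columns", {
  set.seed(21)
  for (rep in 1:25) {
    cnt <- matrix(sample(0:12, 6, replace = TRUE), 2, 3)
    if (any(rowSums(cnt) == 0)) next
    a <- response_counts(cnt[1, 1], cnt[1, 2], cnt[1, 3])
    b <- response_counts(cnt[2, 1], cnt[2, 2], cnt[2, 3])
    p <- fisher_exact_response(a, b)
    # swap group labels
    expect_equal(fisher_exact_response(b, a), p, tolerance = 1e-12)
    # swap decreasing <-> not-decreasing (relabel classes so that the
    # "decreasing" slot holds the complement)
    a2 <- response_counts(0, cnt[1, 1] + cnt[1, 3], cnt[1, 2])
    b2 <- response_counts(0, cnt[2, 1] + cnt[2, 3], cnt[2, 2])
    expect_equal(fisher_exact_response(a2, b2), p, tolerance = 1e-12)
    # and against the enumeration oracle
    n1 <- sum(cnt[1, ]); n2 <- sum(cnt[2, ])
    expect_equal(p, fisher_oracle(cnt[1, 2], n1 - cnt[1, 2],
                                  cnt[2, 2], n2 - cnt[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("cohort CSV round-trips and rejects invalid files", {
  cohort <- list(
    a = tumor_timecourse("a", "control", c(0, 3, 7), c(200, 230, 260),
                         censored = c(FALSE, TRUE, FALSE)),
    b = tumor_timecourse("b", "treatment", c(0, 4), c(180, 150)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_identical(back, cohort)

  df <- utils::read.csv(path)
  bad1 <- df; bad1$volume_mm3[2] <- -1
  p1 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad1, p1, row.names = FALSE)
  expect_error(read_cohort(p1), "non-positive volume")

  bad2 <- df; bad2$time_days[2] <- bad2$time_days[1]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad2, p2, row.names = FALSE)
  expect_error(read_cohort(p2), "strictly increasing")

  bad3 <- df[, setdiff(names(df), "volume_mm3")]
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad3, p3, row.names = FALSE)
  expect_error(read_cohort(p3), "missing column")
})

test_that("count_responses partitions a cohort", {
  cohort <- list(
    tumor_timecourse("a", "control", c(0, 20), c(200, 800)),
    tumor_timecourse("b", "control", c(0, 20), c(200, 90)),
    tumor_timecourse("c", "control", c(0, 20), c(200, 205)))
  rc <- count_responses(cohort)
  expect_equal(rc$increasing + rc$decreasing + rc$stable, 3)
  expect_equal(rc$decreasing, 1)
})
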