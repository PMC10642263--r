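test_that("inverse-CDF sampling reproduces the generating distribution", {
  cv <- surv_curve("weibull", weib_ch_os[["scale"]], weib_ch_os[["shape"]])
  ipd <- simulate_ipd(cv, n = 50000, censor_time = NULL, seed = 17)
  expect_true(all(ipd$event == 1L))
  # closed-form median oracle
  expect_equal(median(ipd$time_months),
               (log(2) / weib_ch_os[["scale"]])^(1 / weib_ch_os[["shape"]]),
               tolerance = 0.3 / 24)
  # Kolmogorov-Smirnov distance against the analytic survival function
  tt <- sort(ipd$time_months)
  emp <- 1 - seq_along(tt) / length(tt)
  expect_lt(max(abs(emp - S_weibull_oracle(tt, weib_ch_os))), 0.01)
})

test_that("administrative censoring with accrual behaves as specified", {
  cv <- surv_curve("weibull", 0.03, 1.6)
  ipd <- simulate_ipd(cv, n = 2000, censor_time = 24, accrual_window = 12,
                      seed = 19)
  expect_true(all(ipd$time_months[ipd$event == 0] <= 24))
  expect_true(all(ipd$time_months[ipd$event == 0] >= 12))
  expect_gt(sum(ipd$event == 0), 0)
  expect_error(simulate_ipd(cv, 10, censor_time = 5, accrual_window = 6))
})

test_that("a fixed seed gives a byte-identical pseudo-IPD file", {
  cv <- surv_curve("weibull", 0.03, 1.6)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_ipd(simulate_ipd(cv, n = 500, seed = 77), f1)
  write_ipd(simulate_ipd(cv, n = 500, seed = 77), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  ipd <- read_ipd(f1)
  expect_named(ipd, c("time_months", "event"))
})

test_that("Kaplan-Meier estimate equals the empirical survival when uncensored", {
  cv <- surv_curve("weibull", 0.05, 1.3)
  ipd <- simulate_ipd(cv, n = 400, censor_time = NULL, seed = 29)
  km <- km_estimator(ipd)
  expect_equal(km$survival[1], 1 - km$n_event[1] / 400)
  ec <- ecdf(ipd$time_months)
  expect_equal(km$survival, 1 - ec(km$time), tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 1e-12))
  # single observation: survival drops to 0 at the event time
  km1 <- km_estimator(data.frame(time_months = 5, event = 1L))
  expect_equal(km1$time, 5)
  expect_equal(km1$survival, 0)
})

test_that("censoring lifts the Kaplan-Meier curve above the naive all-event curve", {
  cv <- surv_curve("weibull", 0.04, 1.4)
  set.seed(37)
  ipd <- simulate_ipd(cv, n = 1500, censor_time = 18, accrual_window = 12)
  km <- km_estimator(ipd)
  naive <- 1 - ecdf(ipd$time_months)(km$time)  # treats censorings as events
  expect_true(all(km$survival - naive >= -1e-12))
  expect_gt(max(km$survival - naive), 0)
})

test_that("digitizer emulation returns exact, monotone coordinates", {
  cv <- surv_curve("weibull", 0.03, 1.5)
  ipd <- simulate_ipd(cv, n = 300, censor_time = 30, seed = 43)
  km <- km_estimator(ipd)
  coords <- digitize_emulate(km, m = 25, jitter_sd = 0)
  step <- stepfun(km$time, c(1, km$survival), right = FALSE)
  expect_equal(coords$survival, step(coords$time_months))
  expect_equal(coords$survival[1], 1)
  jit <- digitize_emulate(km, m = 25, jitter_sd = 0.05, seed = 3)
  expect_true(all(diff(jit$survival) <= 0))
  expect_true(all(jit$survival >= 0 & jit$survival <= 1))
})

test_that("reconstruction reproduces interval event counts and the KM curve", {
  cv <- surv_curve("weibull", 0.02, 1.7)
  ipd <- simulate_ipd(cv, n = 200, censor_time = NULL, seed = 53)
  km <- km_estimator(ipd)
  coords <- digitize_emulate(km, m = 30, jitter_sd = 0)
  rec <- reconstruct_ipd(coords, n_total = 200)
  # counting identity per interval
  alive <- round(200 * coords$survival)
  expect_equal(sum(rec$event), 200 - alive[length(alive)])
  for (j in c(5, 15, 25)) {
    expect_equal(sum(rec$event[rec$time_months <= coords$time_months[j]]),
                 200 - alive[j])
  }
  # flat segments allocate no events
  flat <- which(diff(alive) == 0)
  if (length(flat)) {
    j <- flat[1]
    inside <- rec$event == 1 &
      rec$time_months > coords$time_months[j] &
      rec$time_months <= coords$time_months[j + 1]
    expect_false(any(inside))
  }
  # KM of the reconstructed sample tracks the input coordinates
  km_rec <- km_estimator(rec)
  step_rec <- stepfun(km_rec$time, c(1, km_rec$survival), right = FALSE)
  expect_lt(max(abs(step_rec(coords$time_months) - coords$survival)),
            1 / 200 + 1e-9)
  expect_error(reconstruct_ipd(data.frame(time_months = c(0, 1),
                                          survival = c(0.9, 0.8)), 100),
               "start at 1")
  expect_error(reconstruct_ipd(data.frame(time_months = c(0, 1, 2),
                                          survival = c(1, 0.5, 0.7)), 100),
               "non-increasing")
})

test_that("digitize-reconstruct-refit recovers the generating Weibull", {
  cv <- surv_curve("weibull", weib_ch_pfs[["scale"]], weib_ch_pfs[["shape"]])
  ipd <- simulate_ipd(cv, n = 1000, censor_time = 18, seed = 61)
  km <- km_estimator(ipd)
  coords <- digitize_emulate(km, m = 40, jitter_sd = 0)
  rec <- reconstruct_ipd(coords, n_total = 1000, censor_time = 18)
  f <- fit_censored(rec, "weibull")
  expect_lt(abs(f$curve$scale - cv$scale) / cv$scale, 0.15)
  expect_lt(abs(f$curve$shape - cv$shape) / cv$shape, 0.15)
})
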