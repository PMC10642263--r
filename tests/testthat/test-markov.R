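test_that("cohort trace conserves occupancy and death is absorbing", {
  for (arm_name in c("tc", "chemo")) {
    tr <- bc0$traces[[arm_name]]
    expect_equal(nrow(tr), 80)
    expect_equal(tr$pfs + tr$pd + tr$death, rep(1, nrow(tr)),
                 tolerance = 1e-10)
    expect_true(all(diff(tr$pfs) <= 1e-12))
    expect_true(all(diff(tr$death) >= -1e-12))
    expect_true(all(tr$new_deaths >= -1e-12))
    expect_true(all(tr$pfs >= 0 & tr$pfs <= 1))
    expect_true(all(tr$pd >= 0 & tr$pd <= 1))
  }
})

test_that("progression probability clamps at zero when death dominates", {
  # PFS curve flatter than OS late on: p_pfs_exit < p_death
  arm <- arm_spec("clamp", os_curve = surv_curve("weibull", 0.2, 1),
                  pfs_curve = surv_curve("weibull", 0.01, 1))
  tp <- transition_probs(arm, 1:10, model_settings())
  expect_true(all(tp$p_pd == 0))
  tr <- run_cohort(arm, model_settings(n_cycles = 20))
  expect_true(all(tr$pfs + tr$pd + tr$death - 1 < 1e-12))
  expect_true(all(tr$pd >= 0))
})

test_that("an empty horizon yields an empty trace and zero totals", {
  s <- model_settings(n_cycles = 0)
  arm <- build_arm(cfg0, "chemo")
  tr <- run_cohort(arm, s)
  expect_equal(nrow(tr), 0)
  tot <- accrue_totals(tr, arm, s)
  expect_equal(tot, list(cost = 0, ly = 0, qaly = 0))
})

test_that("with no deaths, full utilities and no discounting QALYs equal the horizon", {
  arm <- arm_spec("immortal",
                  os_curve = surv_curve("weibull", 1e-12, 1),
                  pfs_curve = surv_curve("weibull", 1e-12, 1),
                  utility_pfs = 1, utility_pd = 1)
  s <- model_settings(discount_rate = 0)
  tot <- accrue_totals(run_cohort(arm, s), arm, s)
  expect_equal(tot$qaly, 10, tolerance = 1e-6)
  expect_equal(tot$ly, 10, tolerance = 1e-6)
})

test_that("life expectancy matches the area under the OS curve", {
  # partitioned-survival oracle on the same clock: sum of S_os over the
  # cycle grid times the per-cycle year fraction
  s <- model_settings(discount_rate = 0)
  arm <- build_arm(cfg0, "chemo")
  tot <- accrue_totals(run_cohort(arm, s), arm, s)
  k <- seq_len(s$n_cycles)
  oracle <- sum(S_weibull_oracle((k - 1) * s$survival_step_months,
                                 weib_ch_os)) * s$cycle_length_months / 12
  expect_equal(tot$ly, oracle, tolerance = 1e-10)
  # and within half a cycle of the continuous-time integral on that clock
  integrand <- function(t) S_weibull_oracle(t, weib_ch_os)
  auc <- integrate(integrand, 0, s$n_cycles * s$survival_step_months,
                   rel.tol = 1e-10)$value *
    (s$cycle_length_months / s$survival_step_months) / 12
  expect_lt(abs(tot$ly - auc), s$cycle_length_months / 12 / 2)
})

test_that("QALYs equal LYs when utilities are 1 and disutility 0", {
  arm <- build_arm(cfg0, "tc")
  arm$utility_pfs <- 1; arm$utility_pd <- 1; arm$ae_disutility <- 0
  s <- settings_from_config(cfg0)
  tot <- accrue_totals(run_cohort(arm, s), arm, s)
  expect_identical(tot$qaly, tot$ly)
})

test_that("discounting can only shrink totals", {
  arm <- build_arm(cfg0, "tc")
  s1 <- settings_from_config(cfg0)
  s0 <- model_settings(discount_rate = 0)
  t1 <- accrue_totals(run_cohort(arm, s1), arm, s1)
  t0 <- accrue_totals(run_cohort(arm, s0), arm, s0)
  expect_lt(t1$cost, t0$cost)
  expect_lt(t1$qaly, t0$qaly)
  s_eq <- model_settings(discount_rate = 0)
  expect_equal(accrue_totals(run_cohort(arm, s_eq), arm, s_eq)$ly, t0$ly)
})

test_that("life expectancy decreases as the OS scale grows", {
  s <- model_settings()
  lys <- vapply(c(0.001, 0.003, 0.01, 0.03, 0.1), function(lam) {
    arm <- arm_spec("g", os_curve = surv_curve("weibull", lam, 1.5),
                    pfs_curve = surv_curve("weibull", 0.05, 1.2))
    accrue_totals(run_cohort(arm, s), arm, s)$ly
  }, numeric(1))
  expect_true(all(diff(lys) < 0))
})

test_that("one-time adverse-event burden matches the printed risk/cost rows", {
  expect_equal(ae_onetime_cost(build_arm(cfg0, "tc")), 1304.19,
               tolerance = 1e-5)
  expect_equal(ae_onetime_cost(build_arm(cfg0, "chemo")), 1523.43,
               tolerance = 1e-5)
})

test_that("zero costs give zero total cost whatever the trace", {
  arm <- arm_spec("free", os_curve = surv_curve("weibull", 0.01, 1.5),
                  pfs_curve = surv_curve("weibull", 0.05, 1.2))
  s <- model_settings()
  expect_equal(accrue_totals(run_cohort(arm, s), arm, s)$cost, 0)
})

test_that("limited chemotherapy duration only charges the early cycles", {
  arm <- build_arm(cfg0, "chemo")
  s_all <- settings_from_config(cfg0)                  # until progression
  s_3 <- model_settings(chemo_duration_cycles = 3)
  c_all <- accrue_totals(run_cohort(arm, s_all), arm, s_all)$cost
  c_3 <- accrue_totals(run_cohort(arm, s_3), arm, s_3)$cost
  expect_lt(c_3, c_all)
  # with the drug backbone zeroed the two settings coincide
  arm0 <- arm; arm0$drug_cost_limited <- 0
  expect_equal(accrue_totals(run_cohort(arm0, s_all), arm0, s_all)$cost,
               accrue_totals(run_cohort(arm0, s_3), arm0, s_3)$cost)
})
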