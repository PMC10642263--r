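test_that("parameter sampling honours each distribution and its moments", {
  ptab <- parameter_table(cfg0)
  expect_true(all(ptab$dist[grepl("^costs/", ptab$parameter)] == "gamma"))
  expect_true(all(ptab$dist[grepl("ae_risks|utilities|post_disc",
                                  ptab$parameter)] == "beta"))
  expect_equal(ptab$dist[ptab$parameter == "model/discount_rate"], "uniform")

  draws <- sample_parameters(ptab, n = 10000, seed = 2)
  expect_equal(dim(draws), c(10000L, nrow(ptab)))
  # support constraints
  expect_true(all(draws[, "costs/drugs/tislelizumab"] > 0))
  expect_true(all(draws[, "utilities/pd"] > 0 & draws[, "utilities/pd"] < 1))
  d <- draws[, "model/discount_rate"]
  expect_true(all(d >= 0 & d <= 0.08))
  # method-of-moments: sampled means within 3 standard errors of the specified mean
  for (p in c("utilities/pd", "utilities/pfs", "costs/drugs/tislelizumab",
              "arms/tc/ae_risks/platelet_count_decreased",
              "costs/terminal_care")) {
    x <- draws[, p]
    base <- ptab$base[ptab$parameter == p]
    expect_lt(abs(mean(x) - base), 3 * sd(x) / sqrt(length(x)))
  }
})

test_that("degenerate and infeasible specifications fall back sensibly", {
  spec1 <- data.frame(parameter = "p", base = 5, low = 5, high = 5,
                      dist = "gamma")
  expect_true(all(sample_parameters(spec1, n = 50, seed = 1) == 5))
  # SD too large for the beta support triggers the uniform fallback
  spec2 <- data.frame(parameter = "q", base = 0.5, low = 0, high = 4 * 0.49,
                      dist = "beta")
  expect_warning(x <- sample_parameters(spec2, n = 200, seed = 1),
                 "infeasible")
  expect_true(all(x >= 0 & x <= 4 * 0.49))
})

test_that("PSA is reproducible and collapses to the base case when fixed", {
  p1 <- run_psa(cfg0, n_iter = 150, seed = 9)
  p2 <- run_psa(cfg0, n_iter = 150, seed = 9)
  expect_identical(p1$results, p2$results)
  p3 <- run_psa(cfg0, n_iter = 150, seed = 10)
  expect_false(identical(p1$results$delta_cost, p3$results$delta_cost))

  cfg_fixed <- fix_all_dists(cfg0)
  pf <- run_psa(cfg_fixed, n_iter = 1, seed = 1)
  expect_equal(pf$results$delta_cost, bc0$comparison$delta_cost,
               tolerance = 1e-10)
  expect_equal(pf$results$delta_qaly, bc0$comparison$delta_qaly,
               tolerance = 1e-10)
})

test_that("the fast PSA engine agrees with the public model path", {
  ptab <- parameter_table(cfg0)
  eng <- npccea:::psa_engine(cfg0)
  v <- ptab$base
  out <- eng$eval(v)
  expect_equal(out[["cost_tc"]], bc0$totals$tc$cost, tolerance = 1e-12)
  expect_equal(out[["qaly_tc"]], bc0$totals$tc$qaly, tolerance = 1e-12)
  expect_equal(out[["cost_chemo"]], bc0$totals$chemo$cost, tolerance = 1e-12)
  expect_equal(out[["ly_chemo"]], bc0$totals$chemo$ly, tolerance = 1e-12)
  # and at a perturbed draw, against a config rebuilt with the same values
  v2 <- v; i <- match("utilities/pd", ptab$parameter); v2[i] <- 0.45
  j <- match("costs/drugs/tislelizumab", ptab$parameter); v2[j] <- 900
  cfg2 <- config_set(config_set(cfg0, "utilities/pd", 0.45),
                     "costs/drugs/tislelizumab", 900)
  bc2 <- run_base_case(cfg2)
  out2 <- eng$eval(v2)
  expect_equal(out2[["cost_tc"]] - out2[["cost_chemo"]],
               bc2$comparison$delta_cost, tolerance = 1e-10)
  expect_equal(out2[["qaly_tc"]] - out2[["qaly_chemo"]],
               bc2$comparison$delta_qaly, tolerance = 1e-10)
})

test_that("the acceptability curve is consistent, bounded and monotone", {
  psa <- run_psa(cfg0, n_iter = 400, seed = 4)
  cc <- ceac(psa)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_equal(cc$probability[cc$wtp == psa$wtp], psa$prob_ce)
  expect_equal(ceac(psa, wtp_grid = 0)$probability, 0)  # all delta costs > 0
  if (all(psa$results$delta_qaly > 0))
    expect_true(all(diff(cc$probability) >= 0))
})

test_that("one-way analysis: zero-width ranges reproduce the base ICER", {
  cfg <- cfg0
  cfg$utilities$pd$low <- cfg$utilities$pd$base
  cfg$utilities$pd$high <- cfg$utilities$pd$base
  tor <- owsa(cfg, parameters = "utilities/pd")
  expect_equal(tor$icer_low, attr(tor, "base_icer"))
  expect_equal(tor$icer_high, attr(tor, "base_icer"))
  expect_equal(tor$span, 0)
})

test_that("one-way analysis is ordered by span and flags broken rows", {
  tor <- owsa(cfg0, parameters = c("utilities/pd", "costs/drugs/cisplatin",
                                   "model/discount_rate"))
  expect_named(tor, c("parameter", "low_value", "high_value", "icer_low",
                      "icer_high", "span", "excluded"))
  expect_true(all(diff(tor$span) <= 0))
  expect_equal(tor$parameter[1], "utilities/pd")   # dwarfs a chemo drug cost
  expect_error(owsa(cfg0, parameters = "not/a/parameter"), "unknown")
  # when the QALY gain vanishes the ICER is undefined and the row excluded
  cfg <- cfg0
  cfg$curves$tc <- cfg$curves$chemo   # no survival benefit at all
  cfg$arms$tc$ae_disutility <- cfg$arms$chemo$ae_disutility
  expect_warning(tor2 <- owsa(cfg, parameters = "utilities/pfs"),
                 "excluded")
  expect_true(tor2$excluded[tor2$parameter == "utilities/pfs"])
  expect_true(is.na(tor2$span[1]))
})
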