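# Shared fixtures, built once per test run.

cfg0 <- default_config()
bc0 <- run_base_case(cfg0)

# published Weibull parameters, used directly by oracles
weib_tc_os  <- c(scale = 0.005008, shape = 1.297713)
weib_tc_pfs <- c(scale = 0.075560, shape = 0.950960)
weib_ch_os  <- c(scale = 0.001060, shape = 2.027554)
weib_ch_pfs <- c(scale = 0.034444, shape = 1.615226)

# independent Weibull survival oracle (kept separate from surv_prob)
S_weibull_oracle <- function(t, p) exp(-p[["scale"]] * t^p[["shape"]])

# replace every sampling distribution by "fixed" (degenerate PSA)
fix_all_dists <- function(x) {
  if (is.list(x)) {
    if (!is.null(x$dist)) x$dist <- "fixed"
    return(lapply(x, fix_all_dists))
  }
  x
}
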