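#' Parametric survival curve
#'
#' Construct a parametric survival curve in the scale/shape convention used
#' throughout health-economic decision models:
#' \describe{
#'   \item{exponential}{\eqn{S(t) = \exp(-\lambda t)} (shape fixed at 1).}
#'   \item{weibull}{\eqn{S(t) = \exp(-\lambda t^\gamma)}.}
#'   \item{loglogistic}{\eqn{S(t) = 1 / (1 + (\lambda t)^\gamma)}.}
#'   \item{gompertz}{\eqn{S(t) = \exp((\lambda/\gamma)(1 - e^{\gamma t}))}.}
#'   \item{lognormal}{\eqn{S(t) = 1 - \Phi((\log t - \mu)/\sigma)}; the scale
#'     slot holds the log-time location \eqn{\mu} (any real) and the shape slot
#'     the spread \eqn{\sigma > 0}.}
#' }
#' Time is measured in months.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"gompertz"`, `"lognormal"`.
#' @param scale Scale parameter \eqn{\lambda} (> 0), or location \eqn{\mu}
#'   for the log-normal.
#' @param shape Shape parameter \eqn{\gamma} (> 0), or spread \eqn{\sigma}
#'   for the log-normal. Ignored (fixed at 1) for the exponential.
#' @return An object of class `surv_curve`.
#' @examples
#' cv <- surv_curve("weibull", scale = 0.001060, shape = 2.027554)
#' surv_prob(cv, c(0, 12, 24))
#' median(cv) # (log 2 / lambda)^(1/gamma)
#' @export
surv_curve <- function(family = c("exponential", "weibull", "loglogistic",
                                  "gompertz", "lognormal"),
                       scale, shape = 1) {
  family <- match.arg(family)
  if (family == "exponential") shape <- 1
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (family != "lognormal" && scale <= 0)
    stop("`scale` must be > 0 for family '", family, "'")
  if (shape <= 0)
    stop("`shape` must be > 0")
  structure(list(family = family, scale = scale, shape = shape),
            class = "surv_curve")
}

#' @export
print.surv_curve <- function(x, ...) {
  lab <- if (x$family == "lognormal") c("meanlog", "sdlog") else c("scale", "shape")
  cat(sprintf("<surv_curve> %s (%s = %g, %s = %g), median %.2f months\n",
              x$family, lab[1], x$scale, lab[2], x$shape, median(x)))
  invisible(x)
}

# number of free parameters, used for AIC/BIC
n_params <- function(family) if (family == "exponential") 1L else 2L

#' Survival probability
#'
#' Evaluate \eqn{S(t)} for a parametric curve (or a proportional-hazards
#' adjusted curve from [apply_hr()]). `S(0) = 1` for every family and
#' `S` is non-increasing in `t`.
#'
#' @param curve A `surv_curve` (or `surv_curve_ph`) object.
#' @param t Vector of non-negative times in months.
#' @return Vector of survival probabilities in `[0, 1]`.
#' @export
surv_prob <- function(curve, t) UseMethod("surv_prob")

#' @export
surv_prob.surv_curve <- function(curve, t) {
  if (any(!is.finite(t) | t < 0)) stop("`t` must be finite and >= 0")
  lam <- curve$scale; gam <- curve$shape
  switch(curve$family,
    exponential = exp(-lam * t),
    weibull     = exp(-lam * t^gam),
    loglogistic = 1 / (1 + (lam * t)^gam),
    gompertz    = exp((lam / gam) * (1 - exp(gam * t))),
    lognormal   = stats::plnorm(t, meanlog = lam, sdlog = gam,
                                lower.tail = FALSE))
}

#' Instantaneous hazard
#'
#' Hazard function \eqn{h(t) = f(t)/S(t)} of a parametric curve. Used e.g. to
#' derive the hazard ratio implied by two fitted overall-survival curves.
#'
#' @inheritParams surv_prob
#' @return Vector of hazards (per month).
#' @export
hazard_rate <- function(curve, t) {
  stopifnot(inherits(curve, "surv_curve"))
  if (any(!is.finite(t) | t < 0)) stop("`t` must be finite and >= 0")
  lam <- curve$scale; gam <- curve$shape
  switch(curve$family,
    exponential = rep_len(lam, length(t)),
    weibull     = lam * gam * t^(gam - 1),
    loglogistic = (lam * gam * (lam * t)^(gam - 1)) / (1 + (lam * t)^gam),
    gompertz    = lam * exp(gam * t),
    lognormal   = stats::dlnorm(t, lam, gam) /
                  stats::plnorm(t, lam, gam, lower.tail = FALSE))
}

#' Median survival time
#'
#' Closed-form median of a parametric survival curve, in months.
#'
#' @param x A `surv_curve`.
#' @param na.rm Unused.
#' @param ... Unused.
#' @export
median.surv_curve <- function(x, na.rm = FALSE, ...) {
  lam <- x$scale; gam <- x$shape
  switch(x$family,
    exponential = log(2) / lam,
    weibull     = (log(2) / lam)^(1 / gam),
    loglogistic = 1 / lam,
    gompertz    = log1p(-(gam / lam) * log(0.5)) / gam,
    lognormal   = exp(lam))
}

#' Per-cycle transition probability from a survival curve
#'
#' Probability of leaving the curve's state during model cycle `k`, given
#' occupancy at the start of the cycle:
#' \deqn{p_k = 1 - S(k c) / S((k-1) c)}
#' For the exponential family this is constant in `k` (memoryless); for a
#' Weibull with shape > 1 it is non-decreasing in `k`.
#'
#' @param curve A `surv_curve`.
#' @param k Cycle index (vector allowed), `k >= 1`.
#' @param cycle_length Time step in months advanced per cycle (> 0).
#' @return Probabilities in `[0, 1]`. When `S((k-1)c)` underflows to zero the
#'   cohort is already absorbed; the probability is reported as 1 with a
#'   warning.
#' @export
cycle_transition_prob <- function(curve, k, cycle_length) {
  stopifnot(inherits(curve, c("surv_curve", "surv_curve_ph")))
  if (any(k < 1) || any(k != floor(k))) stop("`k` must be integer >= 1")
  if (!is.numeric(cycle_length) || cycle_length <= 0)
    stop("`cycle_length` must be > 0")
  s1 <- surv_prob(curve, k * cycle_length)
  s0 <- surv_prob(curve, (k - 1) * cycle_length)
  p <- ifelse(s0 > 0, 1 - s1 / s0, 1)
  if (any(s0 == 0))
    warning("survival underflow before cycle ", min(k[s0 == 0]),
            ": cohort effectively absorbed, transition probability set to 1")
  pmin(pmax(p, 0), 1)
}

#' Proportional-hazards adjustment of a survival curve
#'
#' Applies a hazard ratio under proportional hazards,
#' \eqn{S_{adj}(t) = S(t)^{hr}}. For the Weibull, exponential and Gompertz
#' families the cumulative hazard is proportional to the scale parameter, so
#' the result is the same family with `scale * hr` (closed form). For the
#' log-logistic and log-normal families the adjusted curve leaves the family;
#' a `surv_curve_ph` wrapper is returned whose `surv_prob()` method evaluates
#' the power form directly.
#'
#' @param curve A `surv_curve` (or an already adjusted `surv_curve_ph`).
#' @param hr Hazard ratio, > 0. Adjustments compose multiplicatively:
#'   applying `hr1` then `hr2` equals applying `hr1 * hr2`.
#' @return A `surv_curve` or `surv_curve_ph`.
#' @export
apply_hr <- function(curve, hr) {
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0)
    stop("`hr` must be a single positive number")
  if (inherits(curve, "surv_curve_ph"))
    return(apply_hr_wrap(curve$baseline, curve$hr * hr))
  stopifnot(inherits(curve, "surv_curve"))
  apply_hr_wrap(curve, hr)
}

apply_hr_wrap <- function(baseline, hr) {
  if (hr == 1) return(baseline)
  if (baseline$family %in% c("exponential", "weibull", "gompertz"))
    return(surv_curve(baseline$family, scale = baseline$scale * hr,
                      shape = baseline$shape))
  structure(list(baseline = baseline, hr = hr), class = "surv_curve_ph")
}

#' @export
surv_prob.surv_curve_ph <- function(curve, t) {
  surv_prob(curve$baseline, t)^curve$hr
}

#' @export
print.surv_curve_ph <- function(x, ...) {
  cat(sprintf("<surv_curve_ph> %s baseline with hazard ratio %g\n",
              x$baseline$family, x$hr))
  invisible(x)
}

#' Hazard ratio implied by two fitted survival curves
#'
#' Ratio of the intervention to comparator hazards at a reference time,
#' by default the comparator's median survival. Because independently fitted
#' curves are generally not proportional, the ratio depends on the reference
#' time; it is used as a summary when coupling overall-survival modulation to
#' subgroup progression-free-survival hazard ratios.
#'
#' @param intervention,comparator `surv_curve` objects.
#' @param t Reference time in months (default: comparator median).
#' @return A single positive number.
#' @export
implied_hr <- function(intervention, comparator, t = median(comparator)) {
  hazard_rate(intervention, t) / hazard_rate(comparator, t)
}
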