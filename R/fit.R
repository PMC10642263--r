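#' @importFrom stats optim median setNames
NULL

surv_families <- c("exponential", "weibull", "loglogistic", "gompertz",
                   "lognormal")

# log f(t) and log S(t) on the log-parameter scale; par = c(log lambda,
# log gamma), except lognormal where par = c(mu, log sigma).
loglik_censored <- function(par, time, event, family) {
  if (family == "lognormal") {
    mu <- par[1]; sig <- exp(par[2])
    lf <- stats::dlnorm(time, mu, sig, log = TRUE)
    lS <- stats::plnorm(time, mu, sig, lower.tail = FALSE, log.p = TRUE)
  } else {
    lam <- exp(par[1])
    gam <- if (family == "exponential") 1 else exp(par[2])
    lt <- log(time)
    switch(family,
      exponential = {
        lh <- log(lam); lS <- -lam * time
      },
      weibull = {
        lh <- log(lam * gam) + (gam - 1) * lt; lS <- -lam * time^gam
      },
      loglogistic = {
        u <- gam * (log(lam) + lt)          # log((lambda t)^gamma)
        lS <- -ifelse(u > 30, u, log1p(exp(pmin(u, 30))))
        lh <- log(gam) + u - lt + lS        # h = gamma u / (t (1 + u))
      },
      gompertz = {
        lh <- log(lam) + gam * time; lS <- (lam / gam) * (1 - exp(gam * time))
      })
    lf <- lh + lS
  }
  ll <- sum(lf[event == 1]) + sum(lS[event == 0])
  if (!is.finite(ll)) -1e10 else ll
}

# moment-style starting values plus spread, on the optimiser scale
fit_starts <- function(time, event, family) {
  tbar <- mean(time)
  rate0 <- max(sum(event) / sum(time), 1e-8)
  if (family == "lognormal") {
    m <- mean(log(time)); s <- max(stats::sd(log(time)), 0.2)
    return(list(c(m, log(s)), c(m + 0.5, log(s * 2)), c(m - 0.5, log(s / 2))))
  }
  base <- c(log(rate0), 0)
  list(base, base + c(-1, log(1.6)), base + c(0.7, log(0.6)))
}

#' Fit a parametric survival family to right-censored data
#'
#' Maximises the right-censored log-likelihood
#' \deqn{\ell = \sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)}
#' by multi-start Nelder-Mead on log-transformed parameters (three fixed
#' starting points; the best optimum is kept), and reports AIC and BIC.
#'
#' @param data A data frame with columns `time_months` (> 0) and `event`
#'   (1 = death/progression observed, 0 = right-censored), as produced by
#'   [simulate_ipd()] or read from a pseudo individual-patient-data CSV.
#' @param family Survival family, see [surv_curve()].
#' @return An object of class `surv_fit` with elements `curve`
#'   (a [surv_curve()]), `loglik`, `aic`, `bic`, `n_obs`, `n_events`,
#'   `family`, and `convergence` (0 = converged).
#' @examples
#' ipd <- simulate_ipd(surv_curve("weibull", 0.0344, 1.62), n = 200, seed = 1)
#' fit_censored(ipd, "weibull")
#' @export
fit_censored <- function(data, family = surv_families) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data),
            all(c("time_months", "event") %in% names(data)))
  time <- as.numeric(data$time_months)
  event <- as.integer(data$event)
  if (any(!is.finite(time) | time < 0)) stop("times must be finite and >= 0")
  if (!all(event %in% 0:1)) stop("`event` must be 0/1")
  if (length(time) < 10) stop("need at least 10 observations")
  if (sum(event) < 1)
    stop("all observations are censored: the likelihood is unidentifiable")
  if (any(time[event == 1] <= 0)) stop("event times must be > 0")
  time <- pmax(time, .Machine$double.eps)

  best <- NULL
  for (start in fit_starts(time, event, family)) {
    if (family == "exponential") start <- start[1]
    opt <- try(stats::optim(start, loglik_censored, time = time, event = event,
                            family = family,
                            method = if (length(start) == 1) "Brent" else "Nelder-Mead",
                            lower = if (length(start) == 1) -25 else -Inf,
                            upper = if (length(start) == 1) 10 else Inf,
                            control = list(fnscale = -1, maxit = 2000)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value > best$value) best <- opt
  }
  if (is.null(best) || !is.finite(best$value) || best$value <= -1e9)
    stop("fit_censored did not converge for family '", family, "'")

  if (family == "lognormal") {
    scale <- best$par[1]; shape <- exp(best$par[2])
  } else if (family == "exponential") {
    scale <- exp(best$par[1]); shape <- 1
  } else {
    scale <- exp(best$par[1]); shape <- exp(best$par[2])
  }
  k <- n_params(family); n <- length(time)
  structure(list(curve = surv_curve(family, scale = scale, shape = shape),
                 family = family,
                 loglik = best$value,
                 aic = 2 * k - 2 * best$value,
                 bic = k * log(n) - 2 * best$value,
                 n_obs = n, n_events = sum(event),
                 convergence = best$convergence),
            class = "surv_fit")
}

#' @export
print.surv_fit <- function(x, ...) {
  cat(sprintf("<surv_fit> %s: loglik %.2f, AIC %.2f, BIC %.2f (n = %d, events = %d)\n",
              x$family, x$loglik, x$aic, x$bic, x$n_obs, x$n_events))
  print(x$curve)
  invisible(x)
}

#' Fit all five survival families
#'
#' Convenience wrapper fitting every supported family to the same censored
#' sample, e.g. to feed [select_family()].
#'
#' @inheritParams fit_censored
#' @param families Character vector of families to fit.
#' @return A named list of `surv_fit` objects (failed fits are dropped with
#'   a warning).
#' @export
fit_all_families <- function(data, families = surv_families) {
  fits <- list()
  for (fam in families) {
    f <- try(fit_censored(data, fam), silent = TRUE)
    if (inherits(f, "try-error")) {
      warning("family '", fam, "' failed to fit: ", attr(f, "condition")$message)
    } else fits[[fam]] <- f
  }
  fits
}

#' Select the best-fitting survival family
#'
#' Picks the fit with the smallest information criterion. Ties are broken
#' deterministically by family order (exponential, weibull, loglogistic,
#' gompertz, lognormal).
#'
#' @param fits List of `surv_fit` objects (e.g. from [fit_all_families()]).
#' @param criterion `"aic"` or `"bic"`.
#' @return The selected `surv_fit`.
#' @export
select_family <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0) stop("`fits` must be a non-empty list")
  stopifnot(all(vapply(fits, inherits, logical(1), "surv_fit")))
  fam <- vapply(fits, `[[`, character(1), "family")
  val <- vapply(fits, `[[`, numeric(1), criterion)
  ord <- order(val, match(fam, surv_families))
  fits[[ord[1]]]
}

#' Write a multi-family fit report as JSON
#'
#' @param fits Named list of `surv_fit` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  rep <- lapply(fits, function(f) list(
    family = f$family, scale = f$curve$scale, shape = f$curve$shape,
    loglik = f$loglik, aic = f$aic, bic = f$bic,
    n = f$n_obs, events = f$n_events))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
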