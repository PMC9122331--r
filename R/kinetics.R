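# Forward model for in vivo pulse labeling with amino-acid (lysine) reuse.
#
# The free lysine pool does not label instantaneously: degraded pre-existing
# proteins keep releasing light lysine, so the heavy fraction of the precursor
# pool rises with double-exponential kinetics. A protein degraded with rate
# constant k then incorporates label following dh/dt = k (F(t) - h(t)); the
# fitted half-life is thereby intrinsically corrected for lysine reuse.

#' Lysine precursor-pool kinetic parameters
#'
#' Parameters of the double-exponential heavy-fraction curve of the free
#' lysine pool, \eqn{F(t) = 1 - a e^{-b t} - (1 - a) e^{-t/r}}. `a` is the
#' (dimensionless) weight of the fast component, `b` its rate in 1/day, and
#' `r` the time constant in days of the slow, reuse-dominated component.
#' The defaults are the mouse brain values used throughout this package.
#'
#' @param a fraction in \[0, 1\].
#' @param b rate, per day; must be positive.
#' @param r time constant, days; must be positive.
#' @return an object of class `precursor_pool_params`.
#' @examples
#' pp <- precursor_pool_params()
#' precursor_fraction(c(0, 14, 21), pp)
#' @export
precursor_pool_params <- function(a = 0.034277, b = 0.444865, r = 11.836573) {
  stopifnot_scalar_number(a, "a")
  if (a < 0 || a > 1) ta_config_error("field 'a' must lie in [0, 1]")
  stopifnot_scalar_number(b, "b", positive = TRUE)
  stopifnot_scalar_number(r, "r", positive = TRUE)
  structure(list(a = a, b = b, r = r), class = "precursor_pool_params")
}

as_precursor_pool_params <- function(x) {
  if (inherits(x, "precursor_pool_params")) return(x)
  precursor_pool_params(a = x$a, b = x$b, r = x$r)
}

#' Heavy fraction of the free precursor pool at time t
#'
#' @param t time(s) in days since the start of the pulse; non-negative.
#' @param params a [precursor_pool_params()] object.
#' @return numeric vector of fractions in \[0, 1).
#' @export
precursor_fraction <- function(t, params = precursor_pool_params()) {
  params <- as_precursor_pool_params(params)
  if (any(!is.finite(t)) || any(t < 0))
    ta_domain_error("precursor_fraction: t must be finite and >= 0")
  1 - params$a * exp(-params$b * t) - (1 - params$a) * exp(-t / params$r)
}

# one exponential-difference term of the closed-form solution:
#   k/(k - d) * (exp(-d t) - exp(-k t))
# with the removable singularity at k == d handled by a first-order
# expansion when |k - d| < tol (per day)
.exp_diff_term <- function(t, k, d, tol = 1e-6) {
  if (abs(k - d) < tol) {
    # exp(-d t) - exp(-k t) = exp(-k t) (exp((k-d) t) - 1)
    #                      ~= exp(-k t) ((k-d) t + ((k-d) t)^2 / 2)
    k * exp(-k * t) * t * (1 + (k - d) * t / 2)
  } else {
    k / (k - d) * (exp(-d * t) - exp(-k * t))
  }
}

#' Heavy fraction of a protein under reuse-corrected labeling kinetics
#'
#' Closed-form solution of `dh/dt = k (F(t) - h)`, `h(0) = 0`, where `F` is
#' [precursor_fraction()] and `k` the degradation rate constant (per day):
#' \deqn{h(t) = 1 - e^{-kt} - \frac{a k}{k - b}(e^{-bt} - e^{-kt})
#'             - \frac{(1-a) k}{k - 1/r}(e^{-t/r} - e^{-kt})}
#' Continuous limits are used when k is within `1e-6`/day of `b` or `1/r`.
#'
#' @param t time(s) in days; non-negative.
#' @param k degradation rate constant, per day (scalar); `ln(2) / halflife`.
#' @param params a [precursor_pool_params()] object.
#' @return numeric vector of labeled fractions in \[0, 1).
#' @seealso [integrate_labeling_ode()] for the numerical oracle.
#' @export
protein_heavy_fraction <- function(t, k, params = precursor_pool_params()) {
  params <- as_precursor_pool_params(params)
  if (any(!is.finite(t)) || any(t < 0))
    ta_domain_error("protein_heavy_fraction: t must be finite and >= 0")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    ta_domain_error("protein_heavy_fraction: k must be a single positive rate")
  a <- params$a
  h <- 1 - exp(-k * t) -
    a * .exp_diff_term(t, k, params$b) -
    (1 - a) * .exp_diff_term(t, k, 1 / params$r)
  pmin(pmax(h, 0), 1 - 1e-15)
}

#' Numerically integrate the labeling ODE (independent oracle)
#'
#' Integrates `dh/dt = k (F(t) - h)` with an adaptive Dormand-Prince
#' Runge-Kutta 4(5) scheme at tight tolerance. This is deliberately a fully
#' independent route from the closed form in [protein_heavy_fraction()] and
#' is intended for testing, not production fitting.
#'
#' @param t_grid sorted, non-negative times (days) at which to report h.
#' @param k degradation rate constant, per day.
#' @param params a [precursor_pool_params()] object.
#' @param tol local error tolerance (absolute), default `1e-10`.
#' @return numeric vector of h values, one per grid point.
#' @export
integrate_labeling_ode <- function(t_grid, k, params = precursor_pool_params(),
                                   tol = 1e-10) {
  params <- as_precursor_pool_params(params)
  if (any(!is.finite(t_grid)) || any(t_grid < 0))
    ta_domain_error("integrate_labeling_ode: t_grid must be finite and >= 0")
  if (is.unsorted(t_grid))
    ta_domain_error("integrate_labeling_ode: t_grid must be sorted ascending")
  f <- function(t, h) k * (precursor_fraction(t, params) - h)

  # Dormand-Prince 5(4) coefficients
  c2 <- 1 / 5; c3 <- 3 / 10; c4 <- 4 / 5; c5 <- 8 / 9
  a21 <- 1 / 5
  a31 <- 3 / 40; a32 <- 9 / 40
  a41 <- 44 / 45; a42 <- -56 / 15; a43 <- 32 / 9
  a51 <- 19372 / 6561; a52 <- -25360 / 2187; a53 <- 64448 / 6561
  a54 <- -212 / 729
  a61 <- 9017 / 3168; a62 <- -355 / 33; a63 <- 46732 / 5247
  a64 <- 49 / 176; a65 <- -5103 / 18656
  b1 <- 35 / 384; b3 <- 500 / 1113; b4 <- 125 / 192
  b5 <- -2187 / 6784; b6 <- 11 / 84
  # embedded 4th-order weights
  e1 <- 5179 / 57600; e3 <- 7571 / 16695; e4 <- 393 / 640
  e5 <- -92097 / 339200; e6 <- 187 / 2100; e7 <- 1 / 40

  out <- numeric(length(t_grid))
  t <- 0; h <- 0
  dt <- 1e-3
  for (i in seq_along(t_grid)) {
    target <- t_grid[i]
    while (t < target - 1e-14) {
      dt <- min(dt, target - t)
      k1 <- f(t, h)
      k2 <- f(t + c2 * dt, h + dt * a21 * k1)
      k3 <- f(t + c3 * dt, h + dt * (a31 * k1 + a32 * k2))
      k4 <- f(t + c4 * dt, h + dt * (a41 * k1 + a42 * k2 + a43 * k3))
      k5 <- f(t + c5 * dt, h + dt * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4))
      k6 <- f(t + dt, h + dt * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 +
                                  a65 * k5))
      h5 <- h + dt * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6)
      k7 <- f(t + dt, h5)
      h4 <- h + dt * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 +
                        e7 * k7)
      err <- abs(h5 - h4)
      if (err <= tol || dt < 1e-12) {
        t <- t + dt
        h <- h5
        dt <- dt * min(5, max(0.2, 0.9 * (tol / max(err, 1e-300))^0.2))
      } else {
        dt <- dt * max(0.2, 0.9 * (tol / err)^0.2)
      }
    }
    out[i] <- h
  }
  out
}

#' Convert between labeled fraction and heavy/light ratio
#'
#' `fraction_to_ratio(f) = f / (1 - f)`; `ratio_to_fraction(r) = r / (1 + r)`.
#' The two are exact inverses on their domains.
#'
#' @param f labeled fraction(s) in \[0, 1).
#' @param ratio heavy/light ratio(s), non-negative.
#' @return numeric vector.
#' @export
fraction_to_ratio <- function(f) {
  bad <- is.finite(f) & (f < 0 | f >= 1)
  if (any(bad, na.rm = TRUE) || any(!is.finite(f) & !is.na(f)))
    ta_domain_error("fraction_to_ratio: f must lie in [0, 1)")
  f / (1 - f)
}

#' @rdname fraction_to_ratio
#' @export
ratio_to_fraction <- function(ratio) {
  bad <- is.finite(ratio) & ratio < 0
  if (any(bad, na.rm = TRUE))
    ta_domain_error("ratio_to_fraction: ratio must be >= 0")
  ratio / (1 + ratio)
}

#' Half-life / rate-constant conversion
#'
#' @param halflife half-life in days.
#' @param k first-order degradation rate constant, per day.
#' @return the other quantity, `ln(2) / x`.
#' @export
halflife_to_rate <- function(halflife) {
  if (any(halflife <= 0, na.rm = TRUE))
    ta_domain_error("halflife_to_rate: halflife must be > 0")
  log(2) / halflife
}

#' @rdname halflife_to_rate
#' @export
rate_to_halflife <- function(k) {
  if (any(k <= 0, na.rm = TRUE))
    ta_domain_error("rate_to_halflife: k must be > 0")
  log(2) / k
}
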