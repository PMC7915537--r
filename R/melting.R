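#' Hill parameters for the two-transition melting model
#'
#' Bundles and validates the parameter vector of the birefringence melting
#' model: `A` is the birefringence of fully crystallized meibum (1 when
#' normalized), `B` and `C` the contributions of the two liquid-crystal
#' forms (or compositional domains) that melt at transition temperatures
#' `T1 < T2` (Kelvin), and `k`, `m` their unitless Hill cooperativity
#' coefficients (steepness of each transition).
#'
#' @param A,B,C Amplitudes; `A > 0`, `B, C >= 0`.
#' @param T1,T2 Transition temperatures in Kelvin, `0 < T1 < T2`.
#' @param k,m Hill coefficients, `> 0`.
#' @return A named list of class `hill_params`.
#' @examples
#' hill_params(A = 1, B = 0.5, C = 0.5, T1 = 304, T2 = 359, k = 39, m = 29)
#' @export
hill_params <- function(A = 1, B = 0.5, C = 0.5, T1, T2, k, m) {
  stopifnot(A > 0, B >= 0, C >= 0, T1 > 0, k > 0, m > 0)
  if (!(T1 < T2)) stop("T1 must be smaller than T2", call. = FALSE)
  structure(list(A = A, B = B, C = C, T1 = T1, T2 = T2, k = k, m = m),
            class = "hill_params")
}

#' Two-transition Hill melting model
#'
#' Birefringence as a function of absolute temperature:
#' \deqn{I_{br}(T) = A - \frac{B\,T^k}{T_1^k + T^k} - \frac{C\,T^m}{T_2^m + T^m}}
#' Each Hill term is evaluated as `B / (1 + exp(k * log(T1 / T)))`, which is
#' algebraically identical but does not overflow for large cooperativity
#' coefficients (`T^k` with `k ~ 120` at `T ~ 300 K` far exceeds double
#' range, while the exponent `k * log(T1/T)` stays moderate).
#'
#' @param T Temperature(s) in Kelvin, all `> 0`.
#' @param p A [hill_params()] object (or compatible list).
#' @return Birefringence value(s), same length as `T`.
#' @export
hill_model <- function(T, p) {
  if (any(T <= 0)) stop("temperature must be positive (Kelvin)",
                        call. = FALSE)
  p$A - hill_term(T, p$B, p$T1, p$k) - hill_term(T, p$C, p$T2, p$m)
}

# One logistic-in-log-temperature melting step; overflow-safe.
hill_term <- function(T, amp, Tc, coef) {
  z <- coef * (log(Tc) - log(T))
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- amp / (1 + exp(z[pos]))
  # for z << 0, exp(z) underflows gracefully
  out[!pos] <- amp * 1 / (1 + exp(z[!pos]))
  out
}

# Direct textbook form; overflows for large k. Used as a cross-check only.
hill_model_naive <- function(T, p) {
  p$A - (p$B * T^p$k) / (p$T1^p$k + T^p$k) -
    (p$C * T^p$m) / (p$T2^p$m + T^p$m)
}

validate_melting_curve <- function(curve) {
  stopifnot(all(c("temperature_K", "birefringence") %in% names(curve)))
  if (nrow(curve) < 7) {
    stop("melting curve needs at least 7 points", call. = FALSE)
  }
  if (any(curve$temperature_K <= 0)) {
    stop("temperatures must be positive Kelvin", call. = FALSE)
  }
  if (is.unsorted(curve$temperature_K, strictly = TRUE)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  curve
}

#' Detect melting transitions by spline differentiation
#'
#' Mechanism-free transition detection: fits a smoothing spline (penalty by
#' generalized cross-validation) to the birefringence curve and locates
#' local minima of its first derivative (points of steepest birefringence
#' loss) on a dense temperature grid. Shallow wiggles are discarded: a
#' candidate must descend faster than `min_slope_frac` times the mean
#' overall slope of the curve.
#'
#' @param curve Tibble with `temperature_K`, `birefringence` (>= 7 points).
#' @param min_slope_frac Sensitivity threshold as a fraction of the mean
#'   absolute slope `range(I) / range(T)`; default 0.5.
#' @return Numeric vector of transition temperatures (Kelvin), ascending;
#'   empty when the curve has no resolvable transition.
#' @export
spline_transitions <- function(curve, min_slope_frac = 0.5) {
  tr <- transition_minima(curve, min_slope_frac)
  sort(tr$temperature_K)
}

# Local minima of the smoothing-spline first derivative, with their slopes.
transition_minima <- function(curve, min_slope_frac = 0.5) {
  validate_melting_curve(curve)
  empty <- tibble::tibble(temperature_K = numeric(0), slope = numeric(0))
  rng <- diff(range(curve$birefringence))
  if (rng <= 0) {
    return(empty)
  }
  ss <- stats::smooth.spline(curve$temperature_K, curve$birefringence,
                             cv = FALSE) # GCV
  grid <- seq(min(curve$temperature_K), max(curve$temperature_K),
              length.out = 2000)
  d1 <- stats::predict(ss, grid, deriv = 1)$y
  floor_slope <- -min_slope_frac * rng / diff(range(curve$temperature_K))
  n <- length(d1)
  is_min <- c(FALSE, d1[2:(n - 1)] < d1[1:(n - 2)] &
                d1[2:(n - 1)] <= d1[3:n], FALSE) & d1 < floor_slope
  tibble::tibble(temperature_K = grid[is_min], slope = d1[is_min])
}

#' Fit the two-transition Hill model to a melting curve
#'
#' Bounded Levenberg-Marquardt least squares
#' (via \pkg{minpack.lm}) of the [hill_model()] to observed
#' birefringence. Cooperativity coefficients are optimized in log-space
#' (they span roughly 30 to 120 across genotypes) with bounds
#' `k, m in [1, 500]` and `T1, T2 in [200, 500] K`. With `init = "auto"`
#' the start is taken from the data: `A = max(I)`, transition temperatures
#' from [spline_transitions()] (falling back to the 30%/70% quantiles of
#' the temperature range), `B = C = (max(I) - min(I)) / 2`, and two
#' deterministic starts `k = m = 30` and `k = m = 120` of which the better
#' fit is kept. Parameters are reported with `T1 < T2` (component labels
#' swapped post hoc if the optimizer crosses them).
#'
#' @param curve Tibble with `temperature_K`, `birefringence`.
#' @param init `"auto"` or a [hill_params()] starting point.
#' @return A `melt_fit` object: fields `params` ([hill_params()]),
#'   `r_squared`, `residuals`, `fitted`, `converged`, `n_iter`, `curve`.
#' @export
fit_melting <- function(curve, init = "auto") {
  validate_melting_curve(curve)
  temp <- curve$temperature_K
  ibr <- curve$birefringence

  starts <- if (identical(init, "auto")) {
    a0 <- max(ibr)
    amp0 <- (max(ibr) - min(ibr)) / 2
    tr <- transition_minima(curve)
    tt <- if (nrow(tr) >= 2) {
      # the two steepest descents, in temperature order
      sort(tr$temperature_K[order(tr$slope)][1:2])
    } else if (nrow(tr) == 1) {
      # single detected transition: bracket it
      tr$temperature_K[1] + c(-0.1, 0.1) * diff(range(temp))
    } else {
      stats::quantile(range(temp), c(0.3, 0.7), names = FALSE)
    }
    tt <- pmin(pmax(tt, 201), 499)
    lapply(c(30, 120), function(kk) {
      list(A = a0, B = max(amp0, 1e-3), C = max(amp0, 1e-3),
           T1 = tt[1], T2 = tt[2], k = kk, m = kk)
    })
  } else {
    list(init)
  }

  resid_fn <- function(par) {
    ibr - (par[1] - par[2] / (1 + exp(exp(par[6]) * (log(par[4]) - log(temp))))
           - par[3] / (1 + exp(exp(par[7]) * (log(par[5]) - log(temp)))))
  }
  lower <- c(1e-6, 0, 0, 200, 200, 0, 0)
  upper <- c(Inf, Inf, Inf, 500, 500, log(500), log(500))
  best <- NULL
  for (s in starts) {
    p0 <- c(s$A, s$B, s$C, s$T1, s$T2, log(s$k), log(s$m))
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(p0, lower), upper), fn = resid_fn,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-12, ptol = 1e-12, maxfev = 10000)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- fit$deviance
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) {
    stop("melting fit failed from every starting point", call. = FALSE)
  }

  cf <- best$fit$par
  pars <- list(A = cf[1], B = cf[2], C = cf[3], T1 = cf[4], T2 = cf[5],
               k = exp(cf[6]), m = exp(cf[7]))
  if (pars$T1 > pars$T2) { # report components in ascending temperature
    pars <- list(A = pars$A, B = pars$C, C = pars$B,
                 T1 = pars$T2, T2 = pars$T1, k = pars$m, m = pars$k)
  }
  if (pars$T1 == pars$T2) pars$T2 <- pars$T2 + 1e-9
  params <- hill_params(A = pars$A, B = pars$B, C = pars$C,
                        T1 = pars$T1, T2 = pars$T2, k = pars$k, m = pars$m)
  fitted_vals <- hill_model(temp, params)
  res <- ibr - fitted_vals
  ss_tot <- sum((ibr - mean(ibr))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  # nls.lm info codes 1:4 signal convergence; 5+ mean the iteration or
  # evaluation budget ran out
  structure(list(
    params = params,
    r_squared = r2,
    residuals = res,
    fitted = fitted_vals,
    converged = best$fit$info %in% 1:4,
    n_iter = best$fit$niter,
    curve = curve
  ), class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  p <- x$params
  cat("Two-transition Hill melting fit\n")
  cat(sprintf("  T1 = %.2f K (k = %.1f, B = %.3f)\n", p$T1, p$k, p$B))
  cat(sprintf("  T2 = %.2f K (m = %.1f, C = %.3f)\n", p$T2, p$m, p$C))
  cat(sprintf("  A = %.4f, r^2 = %.5f, converged: %s\n",
              p$A, x$r_squared, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a melting fit
#'
#' @param x A `melt_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
#' @exportS3Method generics::tidy
tidy.melt_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' One-row summary of a melting fit
#'
#' @param x A `melt_fit` object.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `sigma`, `converged`, `n.iter`, `nobs`.
#' @export
#' @exportS3Method generics::glance
glance.melt_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = stats::sd(x$residuals),
    converged = x$converged,
    n.iter = x$n_iter,
    nobs = length(x$residuals)
  )
}

#' Temperature at a given melt fraction
#'
#' Solves `(A - I(T)) / (B + C) = fraction` for `T` by bisection on the
#' monotone melting model: the temperature at which the requested fraction
#' of the total meltable birefringence has been lost. For a single-term
#' model (`C = 0`) and `fraction = 0.5` this is exactly `T1`.
#'
#' @param p A [hill_params()] object.
#' @param fraction Melt fraction in (0, 1).
#' @return Temperature in Kelvin.
#' @export
melt_fraction_at <- function(p, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  if (p$B + p$C <= 0) {
    stop("model has no meltable component (B + C = 0)", call. = FALSE)
  }
  f <- function(T) (p$A - hill_model(T, p)) / (p$B + p$C) - fraction
  lo <- p$T1 / 100
  hi <- p$T2 * 100
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
}
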