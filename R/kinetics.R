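#' Degradation kinetic coefficients
#'
#' Container for the five constants of the strain-modulated degradation law
#' \deqn{D(\varepsilon, t) = a\,(b + c\,\varepsilon^{n})\, t^{m}}
#' together with the initial fracture strain \eqn{\varepsilon_0} of the
#' undegraded polymer. The defaults are the coefficients calibrated for
#' pre-stretched PLLA strips degraded in phosphate-buffered saline.
#'
#' @param a,b,c Dimensionless non-negative rate constants (`a > 0`).
#' @param m Time exponent, `> 0` (time is measured in days).
#' @param n Strain exponent, `> 0`.
#' @param epsilon0 Initial fracture strain of the undegraded material,
#'   dimensionless, `> 0`. Default 1.22.
#' @return An object of class `degradation_coefficients`.
#' @examples
#' degradation_coefficients()
#' degradation_coefficients(a = 0.4, epsilon0 = 1.3)
#' @export
degradation_coefficients <- function(a = 0.385, b = 0.152, c = 0.616,
                                     m = 0.342, n = 0.236, epsilon0 = 1.22) {
  for (nm in c("a", "b", "c", "m", "n", "epsilon0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("coefficient '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (a <= 0) stop("coefficient 'a' must be > 0", call. = FALSE)
  if (b < 0)  stop("coefficient 'b' must be >= 0", call. = FALSE)
  if (c < 0)  stop("coefficient 'c' must be >= 0", call. = FALSE)
  if (m <= 0) stop("exponent 'm' must be > 0", call. = FALSE)
  if (n <= 0) stop("exponent 'n' must be > 0", call. = FALSE)
  if (epsilon0 <= 0) stop("'epsilon0' must be > 0", call. = FALSE)
  structure(list(a = a, b = b, c = c, m = m, n = n, epsilon0 = epsilon0),
            class = "degradation_coefficients")
}

#' @export
print.degradation_coefficients <- function(x, ...) {
  cat("PLLA degradation coefficients: D(strain, t) = a (b + c strain^n) t^m\n")
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g, m = %.4g, n = %.4g\n",
              x$a, x$b, x$c, x$m, x$n))
  cat(sprintf("  initial fracture strain epsilon0 = %.4g\n", x$epsilon0))
  invisible(x)
}

as_degradation_coefficients <- function(x) {
  if (inherits(x, "degradation_coefficients")) return(x)
  if (is.list(x)) return(do.call(degradation_coefficients, x))
  stop("cannot interpret object as degradation coefficients", call. = FALSE)
}

# strain-dependent rate factor k(strain) = a (b + c strain^n)
rate_factor <- function(strain, coeffs) {
  coeffs$a * (coeffs$b + coeffs$c * strain^coeffs$n)
}

#' Degradation degree as a function of strain and time
#'
#' Evaluates the power-law damage variable
#' \eqn{D = \min(1,\; a (b + c \varepsilon^n) t^m)}. `D = 0` means pristine
#' material; `D = 1` means complete local degradation. `D` is non-decreasing
#' in both strain and time.
#'
#' @param strain Maximum principal strain(s), dimensionless, `>= 0`.
#'   Negative values are a domain error here; field readers clamp compressive
#'   strains to zero before they reach the kinetics (see
#'   [read_scaffold_field()]).
#' @param time_days Degradation time(s) in days, `>= 0`.
#' @param coeffs A [degradation_coefficients()] object.
#' @return Degradation degree(s) in `[0, 1]`, recycled over the inputs.
#' @examples
#' degradation_degree(0.4, 30)            # about 0.80 after one month
#' degradation_degree(0, c(3, 10, 20, 30))
#' @export
degradation_degree <- function(strain, time_days,
                               coeffs = degradation_coefficients()) {
  coeffs <- as_degradation_coefficients(coeffs)
  check_numeric(strain, "strain")
  check_numeric(time_days, "time_days")
  if (any(strain < 0))
    stop("'strain' must be >= 0 (got ", min(strain), ")", call. = FALSE)
  if (any(time_days < 0))
    stop("'time_days' must be >= 0 (got ", min(time_days), ")", call. = FALSE)
  pmin(1, rate_factor(strain, coeffs) * time_days^coeffs$m)
}

#' Fracture strain at a given degradation degree
#'
#' The material fracture strain decreases linearly with the degradation
#' degree: \eqn{\varepsilon_t = \varepsilon_0 (1 - D)}. It equals
#' \eqn{\varepsilon_0} (default 1.22) for pristine material and 0 for fully
#' degraded material.
#'
#' @param degree Degradation degree(s) in `[0, 1]`.
#' @inheritParams degradation_degree
#' @return Fracture strain(s), dimensionless.
#' @examples
#' fracture_strain(c(0, 0.5, 1))   # 1.22, 0.61, 0
#' @export
fracture_strain <- function(degree, coeffs = degradation_coefficients()) {
  coeffs <- as_degradation_coefficients(coeffs)
  check_numeric(degree, "degree")
  if (any(degree < 0 | degree > 1))
    stop("'degree' must lie in [0, 1]", call. = FALSE)
  coeffs$epsilon0 * (1 - degree)
}

#' Time to local fracture at a given strain
#'
#' Inverts the degradation law for the time at which the fracture strain
#' decays to the applied strain, i.e. solves
#' \eqn{a (b + c \varepsilon^n) t^m = 1 - \varepsilon/\varepsilon_0} for `t`.
#' Material already strained at or beyond `epsilon0` fractures immediately
#' (time 0). The fracture time is strictly decreasing in strain on
#' `(0, epsilon0)`.
#'
#' @inheritParams degradation_degree
#' @return Fracture time(s) in days (`Inf` if the rate factor is zero).
#' @examples
#' fracture_time(0.3)    # about 29.5 days: under a month
#' fracture_time(0.02)   # about 232 days: beyond seven months
#' @export
fracture_time <- function(strain, coeffs = degradation_coefficients()) {
  coeffs <- as_degradation_coefficients(coeffs)
  check_numeric(strain, "strain")
  if (any(strain < 0))
    stop("'strain' must be >= 0", call. = FALSE)
  target <- pmax(0, 1 - strain / coeffs$epsilon0)
  k <- rate_factor(strain, coeffs)
  out <- ifelse(k > 0, (target / k)^(1 / coeffs$m), Inf)
  out[strain >= coeffs$epsilon0] <- 0
  out
}

#' Advance the damage state over one time increment
#'
#' Accumulates degradation under a (possibly time-varying) strain using an
#' equivalent-time scheme: the pseudo-time `t_eq` at which the closed-form
#' law at the *current* strain would produce the current degree is recovered,
#' and the law is re-evaluated at `t_eq + dt`. Under constant strain the
#' composition of any number of steps reproduces
#' [degradation_degree()]`(strain, total_time)` to floating-point accuracy.
#' Damage is irreversible: the result never falls below `current_degree`, and
#' `degree = 1` is absorbing.
#'
#' The alternative `mode = "global_time"` re-evaluates the closed form at the
#' supplied global time `t_now + dt` with the current strain and takes the
#' running maximum; it coincides with the equivalent-time scheme when the
#' strain is constant and is offered for comparison when it is not.
#'
#' @param current_degree Degradation degree(s) in `[0, 1]` at the start of
#'   the increment.
#' @param strain Strain(s) acting during the increment, `>= 0`.
#' @param dt Time increment in days, `> 0`.
#' @inheritParams degradation_degree
#' @param mode Accumulation rule, `"equivalent_time"` (default) or
#'   `"global_time"`.
#' @param t_now Global time in days at the start of the increment; required
#'   for `mode = "global_time"`, ignored otherwise.
#' @return Updated degradation degree(s) in `[0, 1]`.
#' @examples
#' d <- 0
#' for (i in 1:60) d <- advance_damage(d, strain = 0.4, dt = 0.5)
#' all.equal(d, degradation_degree(0.4, 30))
#' @export
advance_damage <- function(current_degree, strain, dt,
                           coeffs = degradation_coefficients(),
                           mode = c("equivalent_time", "global_time"),
                           t_now = NULL) {
  coeffs <- as_degradation_coefficients(coeffs)
  mode <- match.arg(mode)
  check_numeric(current_degree, "current_degree")
  check_numeric(strain, "strain")
  if (any(current_degree < 0 | current_degree > 1))
    stop("'current_degree' must lie in [0, 1]", call. = FALSE)
  if (any(strain < 0)) stop("'strain' must be >= 0", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number of days", call. = FALSE)

  k <- rate_factor(strain, coeffs)
  if (mode == "global_time") {
    if (is.null(t_now))
      stop("'t_now' is required for mode = \"global_time\"", call. = FALSE)
    new <- pmin(1, k * (t_now + dt)^coeffs$m)
  } else {
    t_eq <- ifelse(k > 0, (pmin(current_degree, 1) / k)^(1 / coeffs$m), Inf)
    new <- ifelse(is.finite(t_eq), pmin(1, k * (t_eq + dt)^coeffs$m),
                  current_degree)
  }
  # irreversibility and saturation
  out <- pmax(current_degree, new)
  out[current_degree >= 1] <- 1
  out
}

check_numeric <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)))
    stop("'", name, "' must be finite numeric", call. = FALSE)
  invisible(x)
}
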