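#' Artery hyperelastic coefficients
#'
#' Coefficients of the sixth-order reduced polynomial strain energy density
#' \deqn{U = \sum_{i=1}^{6} C_{i0} (\bar I_1 - 3)^i} used for the arterial
#' wall. Defaults are the calibrated coronary-artery values; units are MPa
#' (assumed by convention for coronary tissue — the calibration source does
#' not state them).
#'
#' @param C10,C20,C30,C40,C50,C60 Coefficients in MPa.
#' @return An object of class `artery_coefficients`.
#' @export
artery_coefficients <- function(C10 = 6.52e-3, C20 = 4.89e-2,
                                C30 = 9.26e-3, C40 = 0.76,
                                C50 = -0.43, C60 = 8.69e-2) {
  vals <- c(C10, C20, C30, C40, C50, C60)
  if (!is.numeric(vals) || length(vals) != 6L || any(!is.finite(vals)))
    stop("all six coefficients must be single finite numbers", call. = FALSE)
  structure(list(C10 = C10, C20 = C20, C30 = C30,
                 C40 = C40, C50 = C50, C60 = C60),
            class = "artery_coefficients")
}

#' @export
print.artery_coefficients <- function(x, ...) {
  cat("Reduced polynomial artery coefficients (MPa):\n")
  cat(sprintf("  C10 = %.4g, C20 = %.4g, C30 = %.4g\n", x$C10, x$C20, x$C30))
  cat(sprintf("  C40 = %.4g, C50 = %.4g, C60 = %.4g\n", x$C40, x$C50, x$C60))
  invisible(x)
}

as_artery_coefficients <- function(x) {
  if (inherits(x, "artery_coefficients")) return(x)
  if (is.list(x)) return(do.call(artery_coefficients, x))
  stop("cannot interpret object as artery coefficients", call. = FALSE)
}

artery_C <- function(coeffs) {
  unname(unlist(coeffs[c("C10", "C20", "C30", "C40", "C50", "C60")]))
}

#' Strain energy density of the artery wall
#'
#' @param I1bar First invariant of the isochoric left Cauchy-Green tensor,
#'   `>= 3` (equal to 3 in the undeformed state).
#' @param coeffs An [artery_coefficients()] object.
#' @return Strain energy density in MPa; 0 at `I1bar = 3`.
#' @examples
#' strain_energy(c(3, 3.1, 4))
#' @export
strain_energy <- function(I1bar, coeffs = artery_coefficients()) {
  coeffs <- as_artery_coefficients(coeffs)
  check_numeric(I1bar, "I1bar")
  if (any(I1bar < 3))
    stop("'I1bar' must be >= 3 (first invariant at zero strain is 3)",
         call. = FALSE)
  C <- artery_C(coeffs)
  x <- I1bar - 3
  out <- 0
  for (i in 1:6) out <- out + C[i] * x^i
  out
}

#' Incompressible uniaxial Cauchy stress of the artery wall
#'
#' Standard incompressible uniaxial reduction of the reduced polynomial
#' model: with stretch `lambda`, `I1bar = lambda^2 + 2/lambda` and
#' \deqn{\sigma = 2(\lambda^2 - 1/\lambda) \sum_i i\, C_{i0}
#'   (\bar I_1 - 3)^{i-1}.}
#' The small-strain uniaxial (Young's) modulus is `6 * C10`.
#'
#' @param stretch Uniaxial stretch(es) `lambda > 0` (1 = undeformed).
#' @inheritParams strain_energy
#' @return Cauchy stress in MPa; 0 at `stretch = 1`.
#' @examples
#' uniaxial_stress(c(1, 1.1, 1.2))
#' 6 * artery_coefficients()$C10    # initial modulus, MPa
#' @export
uniaxial_stress <- function(stretch, coeffs = artery_coefficients()) {
  coeffs <- as_artery_coefficients(coeffs)
  check_numeric(stretch, "stretch")
  if (any(stretch <= 0))
    stop("'stretch' must be > 0", call. = FALSE)
  C <- artery_C(coeffs)
  I1 <- stretch^2 + 2 / stretch
  x <- I1 - 3
  dUdI1 <- 0
  for (i in 1:6) dUdI1 <- dUdI1 + i * C[i] * x^(i - 1)
  2 * (stretch^2 - 1 / stretch) * dUdI1
}

#' Elastic recoil rate of a deployed scaffold
#'
#' Percent diameter reduction after balloon withdrawal, relative to the
#' fully expanded diameter, reported to one decimal as is conventional.
#'
#' @param expanded_d Fully expanded outer diameter, mm.
#' @param recoiled_d Outer diameter after recoil, mm.
#' @return Recoil rate in percent.
#' @examples
#' recoil_rate(3.5, 3.28)   # 6.3
#' @export
recoil_rate <- function(expanded_d, recoiled_d) {
  check_numeric(expanded_d, "expanded_d")
  check_numeric(recoiled_d, "recoiled_d")
  if (any(recoiled_d <= 0))
    stop("'recoiled_d' must be > 0", call. = FALSE)
  if (any(recoiled_d > expanded_d))
    stop("'recoiled_d' cannot exceed 'expanded_d'", call. = FALSE)
  round(100 * (expanded_d - recoiled_d) / expanded_d, 1)
}

#' Lumen-diameter trend during scaffold degradation
#'
#' Reduced-order surrogate for the arterial lumen response as the scaffold
#' loses capacity: a monotone interpolation between the deployed diameter at
#' capacity 1 and the unloaded (stent-free) diameter at capacity 0. This is
#' a bookkeeping surrogate, not a finite element prediction of the
#' stent-artery contact problem.
#'
#' @param capacity Numeric vector of capacity values in `[0, 1]` (e.g. the
#'   `capacity` column of a simulation trajectory), expected non-increasing.
#' @param deployed Deployed lumen diameter at full capacity, mm
#'   (default 3.28).
#' @param unloaded Unloaded diameter at zero capacity, mm (default 3.0).
#' @param mode Interpolation shape: `"linear"` (default) or `"smoothstep"`
#'   (cubic, flat at both ends).
#' @return Diameters in mm, same length as `capacity`.
#' @examples
#' lumen_trend(c(1, 0.5, 0))   # 3.28, 3.14, 3.00
#' @export
lumen_trend <- function(capacity, deployed = 3.28, unloaded = 3.0,
                        mode = c("linear", "smoothstep")) {
  mode <- match.arg(mode)
  check_numeric(capacity, "capacity")
  if (any(capacity < 0 | capacity > 1))
    stop("'capacity' must lie in [0, 1]", call. = FALSE)
  if (deployed < unloaded)
    stop("'deployed' diameter must be >= 'unloaded' diameter", call. = FALSE)
  if (any(diff(capacity) > 1e-12))
    warning("capacity trajectory is not non-increasing", call. = FALSE)
  f <- if (mode == "smoothstep") capacity^2 * (3 - 2 * capacity) else capacity
  unloaded + (deployed - unloaded) * f
}
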