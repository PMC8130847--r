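#' Validate a table of degradation-experiment records
#'
#' A degradation record is one observation from a pre-stretch degradation
#' experiment: the applied tensile strain, the immersion time in days, and
#' the measured degradation degree (fractional loss of fracture strain).
#'
#' @param records A data frame with columns `strain` (>= 0), `time_days`
#'   (>= 0) and `degree` (in `[0, 1]`).
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_degradation_records <- function(records) {
  if (!is.data.frame(records))
    stop("'records' must be a data frame", call. = FALSE)
  need <- c("strain", "time_days", "degree")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in need) check_numeric(records[[nm]], nm)
  if (any(records$strain < 0))
    stop("record strains must be >= 0", call. = FALSE)
  if (any(records$time_days < 0))
    stop("record times must be >= 0", call. = FALSE)
  if (any(records$degree < 0 | records$degree > 1))
    stop("record degrees must lie in [0, 1]", call. = FALSE)
  records
}

#' Fit the degradation coefficients to experimental records
#'
#' Estimates the five constants `a, b, c, m, n` of the degradation law by
#' bounded nonlinear least squares (Levenberg-Marquardt), minimizing the sum
#' of squared differences between predicted and observed degradation
#' degrees. The initial fracture strain `epsilon0` is not estimated; it is
#' carried over from `init`.
#'
#' The design must be informative: at least five records spanning at least
#' two distinct strains and two distinct times, otherwise the five
#' parameters are not identifiable and an error is raised.
#'
#' @param records Data frame of records, see
#'   [validate_degradation_records()].
#' @param init Starting coefficients, a [degradation_coefficients()] object.
#'   Defaults to the package's calibrated PLLA values.
#' @param lower,upper Named numeric vectors of box bounds for
#'   `a, b, c, m, n`. Defaults: `a, b, c` in `[0, 10]` (with a tiny positive
#'   floor on `a`), `m, n` in `[0.01, 3]`.
#' @return An object of class `degradation_fit`: a list with elements
#'   `coefficients` (a [degradation_coefficients()] object), `residuals`
#'   (observed minus fitted, per record), `fitted`, `rss`,
#'   `residual_norm` (= `sqrt(rss)`), `records`, and `convergence` info from
#'   the optimizer.
#' @examples
#' rec <- generate_degradation_dataset(noise_sd = 0)
#' fit <- fit_degradation_coefficients(rec)
#' coef(fit)
#' @export
fit_degradation_coefficients <- function(records,
                                         init = degradation_coefficients(),
                                         lower = c(a = 1e-8, b = 0, c = 0,
                                                   m = 0.01, n = 0.01),
                                         upper = c(a = 10, b = 10, c = 10,
                                                   m = 3, n = 3)) {
  records <- validate_degradation_records(records)
  init <- as_degradation_coefficients(init)
  par_names <- c("a", "b", "c", "m", "n")
  if (nrow(records) < length(par_names))
    stop("need at least ", length(par_names), " records to estimate ",
         length(par_names), " parameters (got ", nrow(records), ")",
         call. = FALSE)
  if (length(unique(records$strain)) < 2L)
    stop("design is degenerate: at least 2 distinct strains are required ",
         "to identify the strain dependence (c, n)", call. = FALSE)
  if (length(unique(records$time_days)) < 2L)
    stop("design is degenerate: at least 2 distinct times are required ",
         "to identify the time exponent m", call. = FALSE)
  lower <- lower[par_names]; upper <- upper[par_names]
  if (anyNA(lower) || anyNA(upper) || any(lower > upper))
    stop("invalid bounds for ", paste(par_names, collapse = ", "),
         call. = FALSE)

  start <- unlist(init[par_names])
  start <- pmin(pmax(start, lower), upper)
  resid_fun <- function(p) {
    cf <- degradation_coefficients(a = max(p[["a"]], 1e-12), b = p[["b"]],
                                   c = p[["c"]], m = p[["m"]], n = p[["n"]],
                                   epsilon0 = init$epsilon0)
    records$degree - degradation_degree(records$strain, records$time_days, cf)
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  p <- fit$par
  coeffs <- degradation_coefficients(a = p[["a"]], b = p[["b"]], c = p[["c"]],
                                     m = p[["m"]], n = p[["n"]],
                                     epsilon0 = init$epsilon0)
  res <- resid_fun(p)
  structure(list(coefficients = coeffs,
                 residuals = res,
                 fitted = records$degree - res,
                 rss = sum(res^2),
                 residual_norm = sqrt(sum(res^2)),
                 records = records,
                 convergence = list(info = fit$info,
                                    message = fit$message,
                                    niter = fit$niter)),
            class = "degradation_fit")
}

#' @export
coef.degradation_fit <- function(object, ...) {
  unlist(object$coefficients[c("a", "b", "c", "m", "n")])
}

#' @export
residuals.degradation_fit <- function(object, ...) object$residuals

#' @export
print.degradation_fit <- function(x, ...) {
  cat("Degradation-law least-squares fit (", nrow(x$records),
      " records)\n", sep = "")
  print(x$coefficients)
  cat(sprintf("  residual norm = %.4g (RSS = %.4g)\n",
              x$residual_norm, x$rss))
  cat("  ", x$convergence$message, "\n", sep = "")
  invisible(x)
}

#' Read degradation records from CSV
#'
#' Expects a header `strain,time_days,degree`.
#'
#' @param path Path to the CSV file.
#' @return A validated records data frame.
#' @export
read_degradation_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_degradation_records(
    utils::read.csv(path, stringsAsFactors = FALSE))
}
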