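# Synthetic survival inputs: Weibull stand-ins for the trial Kaplan-Meier
# curves, calibrated to printed anchors, and a flat background life table.

#' Survival curve on a monthly grid
#'
#' @param times integer months `0..T`.
#' @param surv survival probability at each time; `surv[1]` (time 0) must be
#'   1, the sequence non-increasing and within `[0, 1]`.
#' @return An object of class `survival_curve`.
#' @export
survival_curve <- function(times, surv) {
  stopifnot(length(times) == length(surv), times[1] == 0,
            all(diff(times) == 1))
  if (abs(surv[1] - 1) > 1e-12) stop("surv[0] must be 1")
  if (any(surv < -1e-12 | surv > 1 + 1e-12)) stop("surv must lie in [0, 1]")
  if (any(diff(surv) > 1e-12)) stop("surv must be non-increasing")
  structure(list(times = as.integer(times), surv = pmin(pmax(surv, 0), 1)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %d monthly points, S(%d) = %.4f\n",
              length(x$times), max(x$times), x$surv[length(x$surv)]))
  invisible(x)
}

#' Fit a Weibull survival curve through two printed anchors
#'
#' Solves `S(t) = exp(-(t/scale)^shape)` for the unique (shape, scale) with
#' `S(median) = 0.5` and `S(24) = s24`, in closed form:
#' `shape = log(log(1/s24)/log 2) / log(24/median)` and
#' `scale = median / (log 2)^(1/shape)`. The exponential curve is the
#' `shape = 1` special case (obtained when `s24 = 0.5^(24/median)`).
#'
#' @param anchors list with `median` (months) and `s24` (survival at 24
#'   months); infeasible combinations (implying `shape <= 0`) are an error.
#' @return list with `shape` (dimensionless) and `scale` (months).
#' @export
fit_weibull_anchors <- function(anchors) {
  m <- anchors$median; s24 <- anchors$s24
  stopifnot(m > 0, s24 > 0, s24 < 1)
  if (m == 24) stop("anchors degenerate: median equal to the 24-month anchor")
  shape <- log(log(1 / s24) / log(2)) / log(24 / m)
  if (!is.finite(shape) || shape <= 0)
    stop("infeasible anchors: median ", m, " with S(24) = ", s24,
         " implies a non-positive Weibull shape")
  scale <- m / log(2)^(1 / shape)
  list(shape = shape, scale = scale)
}

#' Evaluate a Weibull survival curve on the monthly grid
#'
#' @param shape,scale Weibull parameters (both `> 0`).
#' @param horizon last month of the grid.
#' @return A [survival_curve] over `0..horizon`.
#' @export
make_survival_curve <- function(shape, scale, horizon) {
  stopifnot(shape > 0, scale > 0, horizon >= 1)
  t <- 0:horizon
  survival_curve(t, exp(-(t / scale)^shape))
}

#' Background mortality from a sex-mixed annual life table
#'
#' Mixes the male and female annual mortality probabilities by the cohort
#' sex composition and converts to a monthly probability:
#' `q_month = 1 - (1 - q_annual_mixed)^(1/12)`.
#'
#' @param sex_mix fraction male.
#' @param male_annual,female_annual annual death probabilities.
#' @return list with `annual` (mixed annual probability) and `monthly`.
#' @export
make_life_table <- function(sex_mix, male_annual, female_annual) {
  stopifnot(sex_mix >= 0, sex_mix <= 1,
            male_annual >= 0, male_annual <= 1,
            female_annual >= 0, female_annual <= 1)
  annual <- sex_mix * male_annual + (1 - sex_mix) * female_annual
  list(annual = annual, monthly = 1 - (1 - annual)^(1 / 12))
}

# Clip a PFS curve below an OS curve pointwise (progression-free patients
# are a subset of survivors).
clip_pfs <- function(pfs, os) {
  survival_curve(pfs$times, pmin(pfs$surv, os$surv))
}

#' Deterministic survival fixture for both treatment arms
#'
#' Builds the survival inputs the model consumes, calibrated to the printed
#' trial anchors: overall survival (OS) Weibull curves through
#' (median 7.4 mo, 16% at 24 mo) for chemotherapy alone and (10.1 mo, 18%)
#' for the cetuximab arm; progression-free survival (PFS) Weibull curves
#' with medians 3.3 mo and 3.3 + 2.3 mo, using each arm's fitted OS shape
#' parameter (set `survival$pfs_shape` to a number, e.g. 1 for exponential,
#' to override), clipped pointwise so PFS <= OS; and the sex-mixed life
#' table. Fully deterministic: `seed` is accepted for interface symmetry
#' with stochastic generators and recorded, but no randomness is used.
#'
#' @param params a `cea_parameters` object (defaults to the base case).
#' @param horizon months of curve to generate.
#' @param seed recorded in the output for provenance; unused otherwise.
#' @return list with per-arm curves `os_P`, `pfs_P`, `os_C`, `pfs_C`,
#'   `life_table`, the fitted Weibull parameters, and `seed`.
#' @export
make_fixture <- function(params = default_parameters(),
                         horizon = params$settings$horizon, seed = NULL) {
  sv <- params$survival
  fit_P <- fit_weibull_anchors(sv$os_control)
  fit_C <- fit_weibull_anchors(sv$os_cetuximab)
  os_P <- make_survival_curve(fit_P$shape, fit_P$scale, horizon)
  os_C <- make_survival_curve(fit_C$shape, fit_C$scale, horizon)

  pfs_med <- c(P = sv$pfs_control_median,
               C = sv$pfs_control_median + sv$pfs_gain)
  pfs_shape <- function(fit) {
    if (identical(sv$pfs_shape, "os")) fit$shape else as.numeric(sv$pfs_shape)
  }
  pfs_curve <- function(median, shape) {
    make_survival_curve(shape, median / log(2)^(1 / shape), horizon)
  }
  pfs_P <- clip_pfs(pfs_curve(pfs_med["P"], pfs_shape(fit_P)), os_P)
  pfs_C <- clip_pfs(pfs_curve(pfs_med["C"], pfs_shape(fit_C)), os_C)

  lt <- make_life_table(params$settings$sex_mix,
                        sv$life_table$male_annual, sv$life_table$female_annual)
  list(os_P = os_P, pfs_P = pfs_P, os_C = os_C, pfs_C = pfs_C,
       life_table = lt, weibull = list(P = fit_P, C = fit_C), seed = seed)
}

#' Read / write survival curves as two-column CSV
#'
#' @param curve a [survival_curve].
#' @param path CSV path with columns `month`, `survival`.
#' @return `write_survival_curve` returns `path` invisibly;
#'   `read_survival_curve` returns a [survival_curve].
#' @export
write_survival_curve <- function(curve, path) {
  utils::write.csv(data.frame(month = curve$times, survival = curve$surv),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_curve
#' @export
read_survival_curve <- function(path) {
  d <- utils::read.csv(path)
  survival_curve(d$month, d$survival)
}
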