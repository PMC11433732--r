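#' Concentration-time series for one analyte
#'
#' The basic data container for observed or simulated profiles: strictly
#' increasing times (h), concentrations (ug/L), the administered dose (mg),
#' the population group, the assay LLOQ (ug/L) and per-point censoring
#' flags. Censored points carry `NA` concentration.
#'
#' @param analyte One of `NAL, M1, M3, M4, M5`.
#' @param time Sampling times, h.
#' @param conc Concentrations, ug/L (`NA` where censored).
#' @param dose Dose, mg.
#' @param group Population group label.
#' @param lloq Lower limit of quantitation, ug/L.
#' @param censored Logical flags; defaults to `is.na(conc)`.
#' @return Object of class `ct_series`.
#' @export
ct_series <- function(analyte, time, conc, dose, group = "healthy",
                      lloq = 0.05, censored = NULL) {
  analyte <- match.arg(analyte, .analytes)
  time <- as.numeric(time); conc <- as.numeric(conc)
  if (length(time) != length(conc)) stop("time/conc length mismatch")
  if (is.unsorted(time, strictly = TRUE)) stop("times must be strictly increasing")
  if (is.null(censored)) censored <- is.na(conc)
  censored <- as.logical(censored)
  if (any(!censored & (is.na(conc) | conc < 0))) {
    stop("uncensored concentrations must be non-negative and non-missing")
  }
  structure(list(analyte = analyte, time = time, conc = conc,
                 dose = as.numeric(dose), group = group,
                 lloq = as.numeric(lloq), censored = censored),
            class = "ct_series")
}

#' @export
print.ct_series <- function(x, ...) {
  cat(sprintf("<ct_series> %s (%s, %g mg): %d points over %g-%g h, %d censored\n",
              x$analyte, x$group, x$dose, length(x$time), min(x$time),
              max(x$time), sum(x$censored)))
  invisible(x)
}

# Working concentrations for AUC: censored points between quantifiable
# neighbours are imputed at LLOQ/2; leading/trailing censored runs count as
# zero. This is the stated convention for observed data; model output is
# uncensored and unaffected.
.auc_working_conc <- function(series) {
  conc <- series$conc
  cen <- series$censored
  if (!any(cen)) return(conc)
  q <- which(!cen)
  out <- conc
  out[cen] <- 0
  if (length(q) >= 2) {
    interior <- which(cen & seq_along(cen) > min(q) & seq_along(cen) < max(q))
    out[interior] <- series$lloq / 2
  }
  out
}

#' Trapezoidal AUC of an observed series
#'
#' Linear trapezoidal rule on the sampled points over `[t0, t1]`; the
#' interval must be inside the sampled range and endpoints not on the grid
#' are included by linear interpolation. Censored points: LLOQ/2 between
#' quantifiable points, zero in leading/trailing runs.
#'
#' @param series A [ct_series()].
#' @param t0,t1 Interval bounds, h.
#' @return AUC, ug*h/L.
#' @export
auc_trapezoid <- function(series, t0 = min(series$time),
                          t1 = max(series$time)) {
  stopifnot(inherits(series, "ct_series"))
  tt <- series$time
  if (t0 < tt[1] - 1e-9 || t1 > tt[length(tt)] + 1e-9 || t1 <= t0) {
    stop("interval [", t0, ", ", t1, "] outside sampled range")
  }
  cc <- .auc_working_conc(series)
  grid <- sort(unique(c(t0, t1, tt[tt > t0 & tt < t1])))
  vals <- approx(tt, cc, xout = grid)$y
  sum(diff(grid) * (vals[-1] + vals[-length(vals)]) / 2)
}

#' Model AUC by quadrature of the dense solution
#'
#' Integrates the simulated plasma concentration on the solver's dense
#' output grid (not on sparse observation times).
#'
#' @param sim A [simulate_model()] result.
#' @param analyte Analyte name.
#' @param t0,t1 Interval bounds, h.
#' @return AUC, ug*h/L.
#' @export
auc_model <- function(sim, analyte, t0 = 0, t1 = max(sim$time)) {
  auc_trapezoid(sim_ct_series(sim, analyte), t0, t1)
}

#' Interval half-life by log-linear regression
#'
#' `ln(2)` over the negative least-squares slope of log concentration on
#' time within `[t0, t1]`. Requires at least two positive, uncensored
#' points in the window; otherwise (or for a non-decaying profile) returns
#' `NA` with a "not computable" attribute.
#'
#' @param series A [ct_series()].
#' @param t0,t1 Window bounds, h (the 12-24 h and 24-36 h windows match
#'   the reported summaries).
#' @param two_point Use only the first and last point in the window
#'   (two-point slope) instead of the regression.
#' @return Half-life, h, or `NA_real_` when not computable.
#' @export
interval_half_life <- function(series, t0, t1, two_point = FALSE) {
  stopifnot(inherits(series, "ct_series"))
  sel <- series$time >= t0 - 1e-9 & series$time <= t1 + 1e-9 &
    !series$censored & !is.na(series$conc) & series$conc > 0
  tt <- series$time[sel]; cc <- series$conc[sel]
  if (sum(sel) < 2) {
    return(structure(NA_real_, reason = "fewer than 2 usable points"))
  }
  if (two_point) {
    k <- length(tt)
    slope <- (log(cc[k]) - log(cc[1])) / (tt[k] - tt[1])
  } else {
    slope <- unname(coef(lm(log(cc) ~ tt))[2])
  }
  if (!is.finite(slope) || slope >= -1e-12) {
    return(structure(NA_real_, reason = "non-decaying profile"))
  }
  log(2) / (-slope)
}

#' Dose-normalize a series to a reference dose
#'
#' Scales concentrations (and the LLOQ) by `ref_dose / dose`; used to put
#' the 27 mg severe-impairment profiles on the 162 mg scale.
#'
#' @param series A [ct_series()].
#' @param ref_dose Reference dose, mg.
#' @return A new [ct_series()] with updated dose metadata.
#' @export
dose_normalize <- function(series, ref_dose) {
  stopifnot(inherits(series, "ct_series"))
  if (is.null(series$dose) || is.na(series$dose) || series$dose <= 0) {
    stop("series has no valid dose to normalize")
  }
  f <- ref_dose / series$dose
  ct_series(series$analyte, series$time, series$conc * f, ref_dose,
            series$group, series$lloq * f, series$censored)
}

#' Naive-pool a cohort of series on a common schedule
#'
#' Pointwise arithmetic mean and sample standard deviation across subjects.
#' Censored observations are excluded from the statistics; a time point
#' where every subject is censored stays censored in the pooled series.
#'
#' @param cohort List of [ct_series()] for the same analyte on an identical
#'   sampling schedule.
#' @return List with `mean` and `sd` series ([ct_series()] objects) and the
#'   per-point number of quantifiable subjects `n_obs`.
#' @export
naive_pool <- function(cohort) {
  stopifnot(length(cohort) >= 1,
            all(vapply(cohort, inherits, TRUE, "ct_series")))
  tt <- cohort[[1]]$time
  for (s in cohort) {
    if (!isTRUE(all.equal(s$time, tt))) stop("mismatched sampling schedules")
    if (s$analyte != cohort[[1]]$analyte) stop("mixed analytes in cohort")
  }
  cmat <- vapply(cohort, function(s) ifelse(s$censored, NA_real_, s$conc),
                 numeric(length(tt)))
  cmat <- matrix(cmat, nrow = length(tt))
  n_obs <- rowSums(!is.na(cmat))
  mu <- ifelse(n_obs > 0, rowMeans(cmat, na.rm = TRUE), NA_real_)
  sdv <- apply(cmat, 1, function(r) if (sum(!is.na(r)) >= 2) sd(r, na.rm = TRUE) else 0)
  sdv[n_obs == 0] <- NA_real_
  proto <- cohort[[1]]
  list(mean = ct_series(proto$analyte, tt, mu, proto$dose, proto$group,
                        proto$lloq, censored = n_obs == 0),
       sd = ct_series(proto$analyte, tt, sdv, proto$dose, proto$group,
                      proto$lloq, censored = n_obs == 0),
       n_obs = n_obs)
}

#' Average absolute percent error between predicted and observed AUCs
#'
#' @param pred_aucs,obs_aucs Equal-length numeric vectors; observed values
#'   must be positive.
#' @return Mean of `100 * |pred - obs| / obs`, percent.
#' @export
aape <- function(pred_aucs, obs_aucs) {
  if (length(pred_aucs) != length(obs_aucs)) stop("length mismatch")
  if (any(obs_aucs <= 0)) stop("observed AUCs must be positive")
  mean(100 * abs(pred_aucs - obs_aucs) / obs_aucs)
}

#' Ratio of two exposures
#'
#' @param auc_a Numerator exposure.
#' @param auc_b Denominator exposure, `> 0`.
#' @return `auc_a / auc_b`.
#' @export
fold_change <- function(auc_a, auc_b) {
  if (any(auc_b <= 0)) stop("denominator AUC must be positive")
  auc_a / auc_b
}

#' PK summary of a series
#'
#' AUC over the full sampled range (trapezoidal), Cmax/Tmax and the 12-24 h
#' and 24-36 h interval half-lives, mirroring the reported per-panel
#' summaries.
#'
#' @param series A [ct_series()].
#' @return Data frame with one row.
#' @export
pk_summary <- function(series) {
  stopifnot(inherits(series, "ct_series"))
  ok <- !series$censored & !is.na(series$conc)
  cmax <- if (any(ok)) max(series$conc[ok]) else NA_real_
  tmax <- if (any(ok)) series$time[ok][which.max(series$conc[ok])] else NA_real_
  thalf <- function(a, b) {
    if (max(series$time) >= b && min(series$time) <= a) {
      as.numeric(interval_half_life(series, a, b))
    } else NA_real_
  }
  data.frame(group = series$group, analyte = series$analyte,
             dose_mg = series$dose,
             auc = auc_trapezoid(series),
             cmax = cmax, tmax = tmax,
             thalf_12_24 = thalf(12, 24), thalf_24_36 = thalf(24, 36),
             stringsAsFactors = FALSE)
}
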