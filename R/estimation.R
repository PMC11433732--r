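# Parameter transforms for fitting: positive parameters are fitted on the
# log scale; the formation fractions are fitted on the simplex through
# log-ratios against f_m4 (u3 = log(f_m3/f_m4), u5 = log(f_m5/f_m4)), so
# any free subset keeps f_m3 + f_m4 + f_m5 = 1 feasible.

.theta_names <- function(free) {
  vapply(free, function(k) {
    if (k == "f_m3") "u_m3" else if (k == "f_m5") "u_m5" else paste0("log_", k)
  }, "")
}

.params_to_theta <- function(cur, free) {
  th <- vapply(free, function(k) {
    if (k == "f_m3") log(cur$f_m3 / cur$f_m4)
    else if (k == "f_m5") log(cur$f_m5 / cur$f_m4)
    else log(cur[[k]])
  }, 0)
  names(th) <- .theta_names(free)
  th
}

.theta_to_overrides <- function(theta, free, cur) {
  ov <- list()
  frac_free <- intersect(free, c("f_m3", "f_m5"))
  for (k in setdiff(free, frac_free)) {
    ov[[k]] <- exp(theta[[paste0("log_", k)]])
  }
  if (length(frac_free)) {
    u3 <- if ("f_m3" %in% frac_free) theta[["u_m3"]] else log(cur$f_m3 / cur$f_m4)
    u5 <- if ("f_m5" %in% frac_free) theta[["u_m5"]] else log(cur$f_m5 / cur$f_m4)
    den <- 1 + exp(u3) + exp(u5)
    ov$f_m3 <- exp(u3) / den
    ov$f_m5 <- exp(u5) / den
    ov$f_m4 <- 1 / den
  }
  ov
}

#' Build a simulation factory for fitting
#'
#' Returns a closure mapping named parameter overrides (raw parameter keys;
#' formation fractions must be supplied as a consistent triple) to
#' predicted analyte profiles at a fixed sampling schedule. The
#' discretization and tolerances are frozen inside the factory so fitting
#' compares like with like.
#'
#' @param base_params A `nal_params` object supplying every non-free value.
#' @param schedule Sampling times, h (strictly increasing, first `> 0`).
#' @param regimen,grid,meals,transport,physiology Model components; the
#'   default grid is coarser (24 cells) than the reporting default to keep
#'   fitting affordable.
#' @param rtol Solver relative tolerance used during fitting.
#' @return `function(overrides = NULL)` returning a named list of
#'   [ct_series()] predictions, one per analyte.
#' @export
make_sim_factory <- function(base_params, schedule,
                             regimen = dose_regimen("oral-ER", 162),
                             grid = make_grid(24), meals = meal_schedule(),
                             transport = transport_params(),
                             physiology = physiology_default(),
                             rtol = 1e-8) {
  stopifnot(inherits(base_params, "nal_params"))
  if (any(schedule <= 0) || is.unsorted(schedule, strictly = TRUE)) {
    stop("schedule must be strictly increasing and positive")
  }
  raw <- unclass(base_params)[c("group", .param_numeric_keys)]
  force(schedule); force(regimen); force(grid); force(meals)
  force(transport); force(physiology); force(rtol)
  function(overrides = NULL) {
    x <- raw
    if (length(overrides)) x[names(overrides)] <- overrides
    p <- as_parameter_set(x, physiology)
    mod <- assemble(p, physiology, regimen, meals, grid, transport)
    sim <- simulate_model(mod, t_out = c(0, schedule), rtol = rtol)
    keep <- -1L
    out <- lapply(.analytes, function(an) {
      ct_series(an, sim$time[keep], sim$conc[keep, an], regimen$dose,
                p$group, lloq = 0)
    })
    names(out) <- .analytes
    out
  }
}

#' Log-residual least-squares loss
#'
#' Sum over analytes and time points of squared log residuals on
#' uncensored observations (zero-concentration observations carry no log
#' information and are skipped). Censored observations contribute a
#' one-sided penalty `(log(pred / LLOQ))^2` only when the prediction
#' exceeds the LLOQ. Non-positive predictions at uncensored points and
#' infeasible parameter sets incur large finite penalties rather than NaN.
#'
#' @param params Named list/vector of parameter overrides (raw keys).
#' @param data Named list of observed [ct_series()], one per analyte, all
#'   on the factory's schedule.
#' @param factory A [make_sim_factory()] closure.
#' @return Scalar loss.
#' @export
pk_loss <- function(params, data, factory) {
  pred <- tryCatch(factory(params), error = function(e) NULL)
  if (is.null(pred)) return(1e10)
  total <- 0
  for (an in names(data)) {
    obs <- data[[an]]
    pr <- pred[[an]]
    if (!isTRUE(all.equal(obs$time, pr$time))) {
      stop("data schedule does not match factory schedule for ", an)
    }
    unc <- !obs$censored & !is.na(obs$conc) & obs$conc > 0
    pv <- pr$conc[unc]
    bad <- pv <= 0
    if (any(bad)) total <- total + 1e6 * sum(bad)
    if (any(!bad)) {
      total <- total + sum((log(pv[!bad]) - log(obs$conc[unc][!bad]))^2)
    }
    cen <- which(obs$censored)
    if (length(cen) && obs$lloq > 0) {
      pvc <- pr$conc[cen]
      over <- pvc > obs$lloq
      if (any(over)) total <- total + sum(log(pvc[over] / obs$lloq)^2)
    }
  }
  total
}

#' Fit specification
#'
#' @param stages List of character vectors: parameters newly freed at each
#'   stage (cumulative). The default mirrors the stepwise build order of
#'   the model: parent first, then the M5, M3, M1 components, then a joint
#'   polish.
#' @param stage_analytes List (same length) of analyte sets entering the
#'   loss at each stage.
#' @param maxit Nelder-Mead iteration cap per stage.
#' @param multistart Multiplicative perturbations applied to newly freed
#'   parameters to generate additional starts (deterministic).
#' @param seed Recorded in the manifest (the fit itself is deterministic).
#' @return List of class `fit_spec`.
#' @export
fit_spec <- function(stages = list(c("cl_int_h", "k_rel"),
                                   c("f_m5", "cl_elim_m5"),
                                   c("f_m3", "v_m3"),
                                   c("cl_int_m3_to_m1"),
                                   character(0)),
                     stage_analytes = list("NAL",
                                           c("NAL", "M5"),
                                           c("NAL", "M5", "M3"),
                                           c("NAL", "M5", "M3", "M1"),
                                           c("NAL", "M5", "M3", "M1", "M4")),
                     maxit = 150, multistart = c(2, 0.5), seed = 1L) {
  stopifnot(length(stages) == length(stage_analytes))
  all_free <- unlist(stages)
  if (anyDuplicated(all_free)) stop("a parameter may be freed only once")
  structure(list(stages = stages, stage_analytes = stage_analytes,
                 maxit = maxit, multistart = multistart, seed = seed),
            class = "fit_spec")
}

#' Stepwise fit of model parameters to pooled concentration-time data
#'
#' Reproduces the stepwise workflow used to build the model: the parent
#' profile constrains the hepatic intrinsic clearance and tablet release,
#' then each metabolite component is added in turn, finishing with a joint
#' refinement. Each stage runs a bounded Nelder-Mead (Brent in one
#' dimension) search from the current estimate plus deterministic
#' multiplicative perturbations of the newly freed parameters.
#'
#' @param spec A [fit_spec()].
#' @param data Named list of observed [ct_series()] per analyte (pooled
#'   means), on the factory schedule.
#' @param factory A [make_sim_factory()] closure built around the starting
#'   parameter set.
#' @param start_params The starting `nal_params` (defines every fixed
#'   value).
#' @return List of class `fit_result`: `estimates` (named, natural scale),
#'   `objective`, `stage_trace`, `converged`, `n_eval` and a `manifest`.
#' @export
pk_fit <- function(spec, data, factory, start_params) {
  stopifnot(inherits(spec, "fit_spec"), inherits(start_params, "nal_params"))
  cur <- unclass(start_params)[c("group", .param_numeric_keys)]
  trace <- list()
  n_eval <- 0L
  converged <- TRUE
  free_so_far <- character(0)
  best_obj <- NA_real_
  for (stage in seq_along(spec$stages)) {
    new_params <- spec$stages[[stage]]
    free_so_far <- unique(c(free_so_far, new_params))
    # a stage that frees nothing is a joint polish over everything so far
    free <- if (length(new_params)) new_params else free_so_far
    if (!length(free)) next
    analytes <- spec$stage_analytes[[stage]]
    dstage <- data[intersect(analytes, names(data))]
    if (!length(dstage)) next
    theta0 <- .params_to_theta(cur, free)
    lo <- theta0 - log(50)
    hi <- theta0 + log(50)
    obj <- function(theta) {
      # box bounds (x/ / 50 around the stage start on the transformed
      # scale) enforced by clamping plus a quadratic penalty, so the
      # unbounded simplex cannot wander down flat likelihood ridges
      thc <- pmin(pmax(theta, lo), hi)
      names(thc) <- .theta_names(free)
      ov <- .theta_to_overrides(thc, free, cur)
      n_eval <<- n_eval + 1L
      pk_loss(ov, dstage, factory) + 1e3 * sum((theta - thc)^2)
    }
    starts <- if (length(new_params)) {
      lapply(spec$multistart, function(f) theta0 + log(f))
    } else {
      list(theta0)
    }
    polish <- !length(new_params)
    best <- NULL
    for (th0 in starts) {
      fit <- if (length(th0) == 1L) {
        optim(th0, obj, method = "Brent", lower = lo, upper = hi)
      } else if (polish) {
        # restarted Nelder-Mead: a fresh simplex around the interim optimum
        # recovers progress lost to simplex collapse in >5 dimensions
        f1 <- optim(th0, obj, method = "Nelder-Mead",
                    control = list(maxit = spec$maxit, reltol = 1e-9))
        optim(f1$par, obj, method = "Nelder-Mead",
              control = list(maxit = spec$maxit, reltol = 1e-10))
      } else {
        optim(th0, obj, method = "Nelder-Mead",
              control = list(maxit = spec$maxit, reltol = 1e-6))
      }
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (!is.null(best$convergence) && best$convergence != 0) converged <- FALSE
    best_th <- pmin(pmax(best$par, lo), hi)
    ov <- .theta_to_overrides(setNames(best_th, .theta_names(free)),
                              free, cur)
    cur[names(ov)] <- ov
    best_obj <- best$value
    trace[[stage]] <- list(free = free, objective = best$value,
                           analytes = analytes)
  }
  est_keys <- unique(c(unlist(spec$stages),
                       if (any(c("f_m3", "f_m5") %in% unlist(spec$stages))) "f_m4"))
  structure(list(
    estimates = setNames(lapply(est_keys, function(k) cur[[k]]), est_keys),
    params = cur, objective = best_obj, stage_trace = trace,
    converged = converged, n_eval = n_eval,
    manifest = run_manifest(free = unlist(spec$stages), seed = spec$seed,
                            maxit = spec$maxit,
                            multistart = spec$multistart)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective", format(x$objective, digits = 6),
      "after", x$n_eval, "evaluations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  est <- unlist(x$estimates)
  cat(paste0("  ", names(est), " = ", signif(est, 4), collapse = "\n"), "\n")
  invisible(x)
}
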