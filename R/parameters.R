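#' Physiological constants shared by all population groups
#'
#' Returns the system-level physiology: hepatic blood flow, liver volume and
#' extracellular water. Flows are stored in L/h; the conventional hepatic
#' blood flow of 1.45 L/min is converted at construction.
#'
#' @param q_h Hepatic blood flow, L/h. Default `1.45 * 60 = 87` L/h.
#' @param v_liver Liver volume, L.
#' @param v_extracellular Extracellular water, L (the default volume assigned
#'   to glucuronide metabolites).
#' @return A list of class `nal_physiology`.
#' @export
physiology_default <- function(q_h = 1.45 * 60, v_liver = 1.8,
                               v_extracellular = 15) {
  stopifnot(q_h > 0, v_liver > 0, v_extracellular > 0)
  structure(list(q_h = q_h, v_liver = v_liver,
                 v_extracellular = v_extracellular),
            class = "nal_physiology")
}

#' Well-stirred hepatic plasma clearance
#'
#' Maps an intrinsic metabolic clearance to the hepatic plasma clearance
#' under the well-stirred (venous-equilibrium) liver model expressed in
#' blood terms: `CL_H = BP * Q * (fu * CL_int) / (Q + fu * CL_int)`. The
#' unbound fraction `fu` defaults to 1 (no explicit binding term); this is
#' the only form consistent with all three published intrinsic/plasma
#' clearance pairs for nalbuphine across impairment groups.
#'
#' @param cl_int Intrinsic clearance, L/h (blood basis).
#' @param q_h Hepatic blood flow, L/h.
#' @param bp Blood-to-plasma concentration ratio.
#' @param fu Unbound fraction available for sensitivity analyses, default 1.
#' @return Hepatic plasma clearance, L/h. Always `< bp * q_h`.
#' @seealso [well_stirred_clint()] for the exact inverse.
#' @export
#' @examples
#' well_stirred_clh(322, 87, 1.15)  # 78.8 L/h
well_stirred_clh <- function(cl_int, q_h, bp, fu = 1) {
  if (any(q_h <= 0)) stop("q_h must be positive")
  if (any(bp <= 0)) stop("bp must be positive")
  if (any(cl_int < 0)) stop("cl_int must be non-negative")
  bp * q_h * fu * cl_int / (q_h + fu * cl_int)
}

#' Invert the well-stirred model to recover intrinsic clearance
#'
#' Exact inverse of [well_stirred_clh()]:
#' `CL_int = Q * CL_b / (Q - CL_b)` with `CL_b = CL_H / BP`. Defined only
#' below the flow limit `CL_H < bp * q_h`.
#'
#' @param cl_h Hepatic plasma clearance, L/h.
#' @inheritParams well_stirred_clh
#' @return Intrinsic clearance, L/h.
#' @export
#' @examples
#' round(well_stirred_clint(51.5, 87, 1.15))  # 92
well_stirred_clint <- function(cl_h, q_h, bp, fu = 1) {
  if (any(q_h <= 0)) stop("q_h must be positive")
  if (any(bp <= 0)) stop("bp must be positive")
  if (any(cl_h < 0)) stop("cl_h must be non-negative")
  cl_b <- cl_h / bp
  if (any(cl_b >= q_h)) {
    stop("cl_h must be below the flow limit bp * q_h (extraction cannot reach 1)")
  }
  q_h * cl_b / (q_h - cl_b) / fu
}

#' Initial hepatic-impairment scaling factor from observed CL/F
#'
#' Assuming hepatic impairment changes clearance and oral bioavailability
#' reciprocally (CL down by `a`, F up by `a`), the fold change in apparent
#' oral clearance identifies `a = sqrt((CL/F)_healthy / (CL/F)_impaired)`.
#' This is an initializer for fitting only; the optimized group parameters
#' are carried in the packaged parameter sets.
#'
#' @param clf_healthy Observed dose/AUC in the healthy group, L/h.
#' @param clf_impaired Observed dose/AUC in the impaired group, L/h.
#' @return Dimensionless scaling factor, `>= 1` when impaired exposure is
#'   higher.
#' @export
#' @examples
#' initial_factor_a(465, 142)  # 1.81
initial_factor_a <- function(clf_healthy, clf_impaired) {
  if (any(clf_healthy <= 0) || any(clf_impaired <= 0)) {
    stop("observed CL/F values must be positive")
  }
  sqrt(clf_healthy / clf_impaired)
}

#' Partition the parent intrinsic clearance into metabolite formation
#'
#' Splits the nalbuphine hepatic intrinsic clearance into the formation
#' intrinsic clearances of its three primary metabolites. The fractions must
#' sum to one so the partition is exact.
#'
#' @param cl_int_h Parent hepatic intrinsic clearance, L/h.
#' @param f_m3,f_m4,f_m5 Fractions of `cl_int_h` forming M3, M4 and M5.
#' @return Named numeric vector `c(M3 = , M4 = , M5 = )`, L/h, summing to
#'   `cl_int_h`.
#' @export
#' @examples
#' partition_formation_clints(322, 0.5, 0.1, 0.4)
partition_formation_clints <- function(cl_int_h, f_m3, f_m4, f_m5) {
  if (cl_int_h < 0) stop("cl_int_h must be non-negative")
  if (abs(f_m3 + f_m4 + f_m5 - 1) > 1e-9) {
    stop("formation fractions must sum to 1")
  }
  c(M3 = f_m3 * cl_int_h, M4 = f_m4 * cl_int_h, M5 = f_m5 * cl_int_h)
}

.param_numeric_keys <- c(
  "cl_int_h", "cl_nh", "f_m3", "f_m4", "f_m5",
  "cl_int_m3_to_m1", "cl_int_m4_to_m4g", "cl_gi_mult", "k_rel",
  "clf_observed",
  "v_nal", "v_nal_c", "v_nal_p1", "v_nal_p2", "q_nal_p1", "q_nal_p2",
  "v_m1", "v_m3", "v_m3_c", "q_m3_p", "v_m4", "v_m5", "v_m4g",
  "cl_elim_m1", "cl_elim_m3", "cl_elim_m4", "cl_elim_m5", "cl_elim_m4g",
  "cl_exch_met",
  "bp_nal", "bp_m1", "bp_m3", "bp_m4", "bp_m5", "bp_m4g",
  "mw_nal", "mw_m1", "mw_m3", "mw_m4", "mw_m5", "mw_m4g")

#' Construct a population parameter set
#'
#' Builds a validated parameter set from raw values, computing the derived
#' quantities: hepatic plasma clearance (well-stirred), biliary secretory
#' clearances (`cl_gi_p = cl_gi_m = cl_gi_mult * cl_int_h`) and the
#' per-metabolite formation intrinsic clearances.
#'
#' @param x Named list with the group label (`group`) and the numeric keys
#'   documented in the packaged fixture files (see
#'   `system.file("extdata", "params_healthy.txt", package = "nalpbpk")`).
#' @param physiology A [physiology_default()] object supplying `q_h`.
#' @return An object of class `nal_params`.
#' @export
as_parameter_set <- function(x, physiology = physiology_default()) {
  missing_keys <- setdiff(c("group", .param_numeric_keys), names(x))
  if (length(missing_keys)) {
    stop("missing parameter keys: ", paste(missing_keys, collapse = ", "))
  }
  p <- x[c("group", .param_numeric_keys)]
  p[.param_numeric_keys] <- lapply(p[.param_numeric_keys], as.numeric)
  p$q_h <- physiology$q_h
  p$v_liver <- physiology$v_liver
  p$cl_h <- well_stirred_clh(p$cl_int_h, p$q_h, p$bp_nal)
  p$cl_gi_p <- p$cl_gi_mult * p$cl_int_h
  p$cl_gi_m <- p$cl_gi_mult * p$cl_int_h
  p$cl_form <- partition_formation_clints(p$cl_int_h, p$f_m3, p$f_m4, p$f_m5)
  p$v_m3_p <- p$v_m3 - p$v_m3_c
  class(p) <- "nal_params"
  rep_ok <- validate_parameter_set(p)
  if (length(rep_ok)) {
    stop("invalid parameter set: ", paste(rep_ok, collapse = "; "))
  }
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants: formation fractions summing to one,
#' non-negative clearances, strictly positive volumes, blood-to-plasma
#' ratios and molecular weights, and the constrained parent steady-state
#' volume (compartment volumes summing to `v_nal` within 0.1 L).
#'
#' @param p A `nal_params` object (or plain list with the same fields).
#' @return Character vector of violations; empty when the set is valid.
#' @export
validate_parameter_set <- function(p) {
  bad <- character()
  if (!isTRUE(p$group %in% c("healthy", "moderate", "severe"))) {
    bad <- c(bad, "unknown group label")
  }
  if (abs(p$f_m3 + p$f_m4 + p$f_m5 - 1) > 1e-9) {
    bad <- c(bad, "fractions sum != 1")
  }
  cls <- c("cl_int_h", "cl_nh", "cl_int_m3_to_m1", "cl_int_m4_to_m4g",
           "cl_gi_mult", "cl_elim_m1", "cl_elim_m3", "cl_elim_m4",
           "cl_elim_m5", "cl_elim_m4g", "cl_exch_met", "k_rel",
           "q_nal_p1", "q_nal_p2", "q_m3_p")
  for (k in cls) {
    if (is.null(p[[k]]) || !is.finite(p[[k]]) || p[[k]] < 0) {
      bad <- c(bad, paste("negative clearance:", k))
    }
  }
  vols <- c("v_nal", "v_nal_c", "v_nal_p1", "v_nal_p2", "v_m1", "v_m3",
            "v_m3_c", "v_m3_p", "v_m4", "v_m5", "v_m4g")
  for (k in vols) {
    if (is.null(p[[k]]) || !is.finite(p[[k]]) || p[[k]] <= 0) {
      bad <- c(bad, paste("non-positive volume:", k))
    }
  }
  bps <- c("bp_nal", "bp_m1", "bp_m3", "bp_m4", "bp_m5", "bp_m4g")
  for (k in bps) {
    if (is.null(p[[k]]) || !is.finite(p[[k]]) || p[[k]] <= 0) {
      bad <- c(bad, paste("non-positive BP:", k))
    }
  }
  mws <- c("mw_nal", "mw_m1", "mw_m3", "mw_m4", "mw_m5", "mw_m4g")
  for (k in mws) {
    if (is.null(p[[k]]) || !is.finite(p[[k]]) || p[[k]] <= 0) {
      bad <- c(bad, paste("non-positive MW:", k))
    }
  }
  if (!is.null(p$v_nal) && !is.null(p$v_nal_c) &&
      is.finite(p$v_nal) && is.finite(p$v_nal_c) &&
      is.finite(p$v_nal_p1) && is.finite(p$v_nal_p2) &&
      abs(p$v_nal_c + p$v_nal_p1 + p$v_nal_p2 - p$v_nal) > 0.1) {
    bad <- c(bad, "parent compartment volumes do not sum to v_nal (+-0.1 L)")
  }
  bad
}

#' Load a packaged population parameter set
#'
#' Reads the optimized population parameters for one of the three modeled
#' groups from the packaged plain-text fixtures and returns a validated
#' parameter set. The mild impairment group was excluded from modeling
#' (high inter-subject variability) and is rejected.
#'
#' @param group One of `"healthy"`, `"moderate"`, `"severe"`.
#' @param physiology A [physiology_default()] object.
#' @return A `nal_params` object.
#' @export
#' @examples
#' p <- load_parameter_set("healthy")
#' p$cl_int_h  # 322 L/h
load_parameter_set <- function(group, physiology = physiology_default()) {
  if (!is.character(group) || length(group) != 1 ||
      !group %in% c("healthy", "moderate", "severe")) {
    stop("unknown group label: ", paste(group, collapse = ", "),
         " (must be healthy, moderate or severe)")
  }
  path <- system.file("extdata", paste0("params_", group, ".txt"),
                      package = "nalpbpk", mustWork = TRUE)
  as_parameter_set(read_param_config(path), physiology)
}

#' Read a key/value parameter configuration file
#'
#' Parses the structured text format used for parameter sets: one
#' `key: value` pair per line, `#` comments and blank lines ignored. All
#' values except `group` are numeric.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_param_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad)) stop("malformed config line(s): ", paste(bad, collapse = " | "))
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  out <- as.list(vals)
  names(out) <- keys
  for (k in keys) {
    if (k != "group") {
      v <- suppressWarnings(as.numeric(out[[k]]))
      if (is.na(v)) stop("non-numeric value for key '", k, "'")
      out[[k]] <- v
    }
  }
  out
}

#' Write a key/value parameter configuration file
#'
#' Inverse of [read_param_config()]; only the raw (non-derived) keys are
#' serialized so that read/write round-trips through [as_parameter_set()].
#'
#' @param p A `nal_params` object or named list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_param_config <- function(p, path) {
  keys <- c("group", .param_numeric_keys)
  vals <- vapply(keys, function(k) {
    v <- p[[k]]
    if (is.null(v)) stop("missing key '", k, "'")
    format(v, digits = 15)
  }, "")
  writeLines(c(paste0("# nalpbpk parameter set: ", p$group),
               paste0(keys, ": ", vals)), path)
  invisible(path)
}

#' @export
print.nal_params <- function(x, ...) {
  cat("<nal_params> group:", x$group, "\n")
  cat(sprintf("  CL_int,H %.3g L/h -> CL_H %.3g L/h (Q_h %.3g L/h, BP %.3g)\n",
              x$cl_int_h, x$cl_h, x$q_h, x$bp_nal))
  cat(sprintf("  fractions M3/M4/M5: %.3g/%.3g/%.3g; CL_gi %.3g L/h\n",
              x$f_m3, x$f_m4, x$f_m5, x$cl_gi_p))
  invisible(x)
}
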