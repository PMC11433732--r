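.ct_columns <- c("subject", "group", "analyte", "time_h", "conc_ugL",
                 "censored", "dose_mg", "lloq_ugL")

#' Read a concentration-time table
#'
#' Reads the delimited (comma-separated, UTF-8, "." decimal) C-t format:
#' columns `subject, group, analyte, time_h, conc_ugL, censored, dose_mg,
#' lloq_ugL`. Censored rows have empty/NA concentration and `censored =
#' TRUE`. Unknown analytes and malformed rows are rejected with the
#' offending location named.
#'
#' @param path File path.
#' @return A cohort structure: named list of subjects, each a named list of
#'   [ct_series()] per analyte, with class `ct_cohort`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.ct_columns, names(df))
  if (length(missing_cols)) {
    stop("schema violation: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(structure(list(), class = "ct_cohort"))
  }
  bad <- which(!df$analyte %in% .analytes)
  if (length(bad)) {
    stop("schema violation: unknown analyte '", df$analyte[bad[1]],
         "' at row ", bad[1])
  }
  df$censored <- as.logical(df$censored)
  bad <- which(is.na(df$censored))
  if (length(bad)) stop("schema violation: bad censored flag at row ", bad[1])
  bad <- which(!df$censored & (is.na(df$conc_ugL) | df$conc_ugL < 0))
  if (length(bad)) {
    stop("schema violation: missing/negative concentration at row ", bad[1])
  }
  cohort <- list()
  for (subj in unique(df$subject)) {
    dsub <- df[df$subject == subj, , drop = FALSE]
    series <- list()
    for (an in unique(dsub$analyte)) {
      d <- dsub[dsub$analyte == an, , drop = FALSE]
      d <- d[order(d$time_h), , drop = FALSE]
      series[[an]] <- ct_series(an, d$time_h, d$conc_ugL, d$dose_mg[1],
                                d$group[1], d$lloq_ugL[1], d$censored)
    }
    cohort[[as.character(subj)]] <- series
  }
  structure(cohort, class = "ct_cohort")
}

#' Write a cohort to the concentration-time table format
#'
#' Canonical formatting: rows sorted by subject, analyte, time; censored
#' concentrations written empty. `write_ct_table(read_ct_table(x))`
#' round-trips byte-stably for canonically formatted input.
#'
#' @param cohort A `ct_cohort` (or a single subject's named list of
#'   [ct_series()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(cohort, path) {
  if (inherits(cohort, "ct_series")) cohort <- list(s1 = list(cohort))
  if (!inherits(cohort, "ct_cohort") && all(vapply(cohort, inherits, TRUE,
                                                  "ct_series"))) {
    cohort <- list(s1 = cohort)
  }
  rows <- list()
  for (subj in names(cohort)) {
    for (an in intersect(.analytes, names(cohort[[subj]]))) {
      s <- cohort[[subj]][[an]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, group = s$group, analyte = s$analyte,
        time_h = s$time,
        conc_ugL = ifelse(s$censored, NA_real_, s$conc),
        censored = s$censored, dose_mg = s$dose, lloq_ugL = s$lloq,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(numeric(0)), length(.ct_columns)),
                           .ct_columns))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Collects the full configuration of a run (package version, parameter
#' set, solver settings, seed) as a JSON-serializable list; two runs with
#' equal manifests produce equal outputs.
#'
#' @param ... Named configuration elements to embed.
#' @return Named list with `package`, `version` and the supplied elements.
#' @export
run_manifest <- function(...) {
  c(list(package = "nalpbpk",
         version = as.character(packageVersion("nalpbpk"))),
    list(...))
}

#' Write a manifest as JSON
#' @param manifest A [run_manifest()] list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' Plot simulated plasma profiles
#'
#' Static overlay of the five analyte profiles on a log concentration axis.
#'
#' @param sim A [simulate_model()] result.
#' @param analytes Which analytes to draw.
#' @param log Use a log y-axis.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted concentration matrix.
#' @export
plot_profiles <- function(sim, analytes = .analytes, log = TRUE, ...) {
  stopifnot(inherits(sim, "nal_sim"))
  cc <- sim$conc[, analytes, drop = FALSE]
  pos <- cc > 0
  floor_val <- if (any(pos)) min(cc[pos]) else 1e-3
  cc[!pos] <- floor_val
  graphics::matplot(sim$time, cc, type = "l", lty = 1,
                    col = seq_along(analytes),
                    log = if (log) "y" else "",
                    xlab = "time (h)", ylab = "plasma conc (ug/L)", ...)
  graphics::legend("topright", legend = analytes, col = seq_along(analytes),
                   lty = 1, bty = "n")
  invisible(cc)
}
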