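# State vector layout ------------------------------------------------------
# [1] tablet (undissolved) stomach amount, [2] dissolved stomach amount,
# then 16 intestinal blocks (4 layers x 4 lumen species x n_nodes),
# liver (6), gallbladder (3), systemic (9) and a ledger of cumulative
# fluxes (17) that closes the mass balance. All amounts in mg.
.build_index_map <- function(n_nodes) {
  sp <- .lumen_species
  off <- 2L
  lum <- vector("list", 4L)
  names(lum) <- paste0("C", 1:4)
  idx <- off
  for (l in 1:4) {
    lum[[l]] <- sapply(sp, function(s) integer(n_nodes))
    for (s in seq_along(sp)) {
      lum[[l]][, s] <- idx + seq_len(n_nodes)
      idx <- idx + n_nodes
    }
  }
  liver <- setNames(idx + seq_along(.liver_species), .liver_species)
  idx <- idx + length(.liver_species)
  gb <- setNames(idx + 1:3, .biliary_species)
  idx <- idx + 3L
  sysn <- c("nal_c", "nal_p1", "nal_p2", "m1", "m3_c", "m3_p", "m4", "m5",
            "m4g")
  sys <- setNames(idx + seq_along(sysn), sysn)
  idx <- idx + length(sysn)
  led <- setNames(idx + 1:19,
                  c(paste0("abs_", sp), paste0("fecal_", sp),
                    "elim_nal_nh", "elim_m1", "elim_m3", "elim_m4",
                    "elim_m5", "elim_m4g", "elim_gut_NAL", "elim_gut_M4",
                    paste0("eject_", .biliary_species)))
  idx <- idx + 19L
  list(sto_solid = 1L, sto_diss = 2L, lumen = lum, liver = liver, gb = gb,
       sys = sys, led = led, n_state = idx)
}

# Full model right-hand side (mg/h). Strictly linear in `y`; the engine
# linearizes it by probing unit vectors, so no clipping or branching on the
# state is allowed here.
.rhs_full <- function(y, mod, meal_on) {
  im <- mod$im
  p <- mod$params
  tr <- mod$transport
  d <- numeric(im$n_state)

  rel <- dissolution_release(y[im$sto_solid], p$k_rel)
  ge <- tr$k_ge * y[im$sto_diss]
  d[im$sto_solid] <- -rel
  d[im$sto_diss] <- rel - ge

  gb_amt <- setNames(y[im$gb], names(im$gb))
  eject <- (if (meal_on) mod$meals$k_e else 0) * gb_amt

  st <- lapply(.lumen_species, function(s) {
    sapply(1:4, function(l) y[im$lumen[[l]][, s]])
  })
  names(st) <- .lumen_species
  inflow <- c(NAL = ge + eject[["NAL"]], M5 = eject[["M5"]],
              M4G = eject[["M4G"]], M4 = 0)
  gut <- intestinal_rhs(st, tr, mod$grid, inflow, mw = mod$mw_lumen)
  for (l in 1:4) for (s in .lumen_species) {
    d[im$lumen[[l]][, s]] <- gut$d[[s]][, l]
  }

  cp <- c(nal = y[im$sys[["nal_c"]]] / p$v_nal_c,
          m1 = y[im$sys[["m1"]]] / p$v_m1,
          m3 = y[im$sys[["m3_c"]]] / p$v_m3_c,
          m4 = y[im$sys[["m4"]]] / p$v_m4,
          m5 = y[im$sys[["m5"]]] / p$v_m5,
          m4g = y[im$sys[["m4g"]]] / p$v_m4g)
  influx <- c(NAL = p$q_h * p$bp_nal * cp[["nal"]],
              M3 = p$cl_exch_met * p$bp_m3 * cp[["m3"]],
              M4 = p$cl_exch_met * p$bp_m4 * cp[["m4"]],
              M5 = p$cl_exch_met * p$bp_m5 * cp[["m5"]],
              M4G = p$cl_exch_met * p$bp_m4g * cp[["m4g"]],
              M1 = p$cl_exch_met * p$bp_m1 * cp[["m1"]])
  hep <- hepatic_rhs(setNames(y[im$liver], names(im$liver)),
                     portal_in = c(NAL = gut$portal[["NAL"]],
                                   M4 = gut$portal[["M4"]]),
                     influx = influx, params = p)
  d[im$liver] <- hep$d

  d[im$gb] <- hep$secretion - eject

  sys <- systemic_rhs(setNames(y[im$sys], names(im$sys)),
                      liver_out = hep$to_systemic, params = p)
  d[im$sys] <- sys$d

  led <- im$led
  d[led[["abs_NAL"]]] <- gut$portal[["NAL"]]
  d[led[["abs_M4"]]] <- gut$portal[["M4"]]
  d[led[paste0("fecal_", .lumen_species)]] <- gut$fecal
  d[led[["elim_nal_nh"]]] <- sys$elim[["NAL"]]
  d[led[["elim_m1"]]] <- sys$elim[["M1"]]
  d[led[["elim_m3"]]] <- sys$elim[["M3"]]
  d[led[["elim_m4"]]] <- sys$elim[["M4"]]
  d[led[["elim_m5"]]] <- hep$elim[["M5"]]
  d[led[["elim_m4g"]]] <- hep$elim[["M4G"]]
  d[led[["elim_gut_NAL"]]] <- gut$gut_loss[["NAL"]]
  d[led[["elim_gut_M4"]]] <- gut$gut_loss[["M4"]]
  d[led[paste0("eject_", .biliary_species)]] <- eject
  d
}

# Analytic sparse-triplet construction of the system matrices. This is the
# fast path used by assemble(); tests verify column-by-column agreement
# with the modular R right-hand side .rhs_full(), which is the readable
# single source of the model equations.
.build_triplets <- function(mod) {
  im <- mod$im
  p <- mod$params
  tr <- mod$transport
  g <- mod$grid
  n <- g$n_nodes
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    keep <- x != 0
    ii <<- c(ii, i[keep]); jj <<- c(jj, j[keep]); xx <<- c(xx, x[keep])
  }
  rep_add <- function(i, j, x) add(rep(i, length(j)), j, rep(x, length(j)))

  # stomach and duodenal delivery
  add(im$sto_solid, im$sto_solid, -p$k_rel)
  add(im$sto_diss, im$sto_solid, p$k_rel)
  add(im$sto_diss, im$sto_diss, -tr$k_ge)
  add(im$lumen$C1[1L, "NAL"], im$sto_diss, tr$k_ge)

  vdz <- tr$velocity / g$dz
  Ddz2 <- tr$dispersion / g$dz^2
  gus_k <- gus_profile(g, tr$gus_rate)
  mw <- mod$mw_lumen

  for (s in .lumen_species) {
    L1 <- im$lumen$C1[, s]; L2 <- im$lumen$C2[, s]
    L3 <- im$lumen$C3[, s]; L4 <- im$lumen$C4[, s]
    k <- tr$layer_k[[s]]
    ent <- if (s %in% c("NAL", "M4")) tr$enterocyte_loss else 0
    # convection (upwind) + distal outflow to the fecal ledger
    add(L1, L1, rep(-vdz, n))
    add(L1[-1L], L1[-n], rep(vdz, n - 1L))
    add(im$led[[paste0("fecal_", s)]], L1[n], vdz)
    # conservative dispersion across interior faces
    add(L1[-n], L1[-1L], rep(Ddz2, n - 1L))
    add(L1[-1L], L1[-n], rep(Ddz2, n - 1L))
    add(L1[-n], L1[-n], rep(-Ddz2, n - 1L))
    add(L1[-1L], L1[-1L], rep(-Ddz2, n - 1L))
    # cross-layer exchange
    add(L1, L1, rep(-k[["k12"]], n)); add(L2, L1, rep(k[["k12"]], n))
    add(L1, L2, rep(k[["k21"]], n))
    add(L2, L2, rep(-(k[["k21"]] + k[["k23"]]), n))
    add(L3, L2, rep(k[["k23"]], n)); add(L2, L3, rep(k[["k32"]], n))
    add(L3, L3, rep(-(k[["k32"]] + k[["k34"]] + k[["ka"]] + ent), n))
    add(L4, L3, rep(k[["k34"]], n)); add(L3, L4, rep(k[["k43"]], n))
    add(L4, L4, rep(-k[["k43"]], n))
    # GUS hydrolysis of luminal glucuronides (molar, MW-scaled)
    if (s == "M5") {
      add(L1, L1, -gus_k)
      add(im$lumen$C1[, "NAL"], L1, gus_k * mw[["NAL"]] / mw[["M5"]])
    } else if (s == "M4G") {
      add(L1, L1, -gus_k)
      add(im$lumen$C1[, "M4"], L1, gus_k * mw[["M4"]] / mw[["M4G"]])
    }
    # absorption into the portal/liver path
    if (k[["ka"]] > 0) {
      liver_row <- im$liver[[if (s == "NAL") "NAL" else "M4"]]
      rep_add(liver_row, L3, k[["ka"]])
      rep_add(im$led[[paste0("abs_", s)]], L3, k[["ka"]])
    }
    if (ent > 0) {
      rep_add(im$led[[paste0("elim_gut_", s)]], L3, ent)
    }
  }

  vl <- p$v_liver
  liv <- im$liver; sys <- im$sys; led <- im$led
  # liver NAL column
  j <- liv[["NAL"]]
  add(j, j, -(p$q_h + p$cl_int_h + p$cl_gi_p) / vl)
  add(sys[["nal_c"]], j, p$q_h / vl)
  add(liv[["M3"]], j, p$cl_form[["M3"]] / vl * p$mw_m3 / p$mw_nal)
  add(liv[["M4"]], j, p$cl_form[["M4"]] / vl * p$mw_m4 / p$mw_nal)
  add(liv[["M5"]], j, p$cl_form[["M5"]] / vl * p$mw_m5 / p$mw_nal)
  add(im$gb[["NAL"]], j, p$cl_gi_p / vl)
  # liver M3
  j <- liv[["M3"]]
  add(j, j, -(p$cl_exch_met + p$cl_int_m3_to_m1) / vl)
  add(sys[["m3_c"]], j, p$cl_exch_met / vl)
  add(liv[["M1"]], j, p$cl_int_m3_to_m1 / vl * p$mw_m1 / p$mw_m3)
  # liver M4
  j <- liv[["M4"]]
  add(j, j, -(p$cl_exch_met + p$cl_int_m4_to_m4g) / vl)
  add(sys[["m4"]], j, p$cl_exch_met / vl)
  add(liv[["M4G"]], j, p$cl_int_m4_to_m4g / vl * p$mw_m4g / p$mw_m4)
  # liver M5
  j <- liv[["M5"]]
  add(j, j, -(p$cl_exch_met + p$cl_gi_m + p$cl_elim_m5) / vl)
  add(sys[["m5"]], j, p$cl_exch_met / vl)
  add(im$gb[["M5"]], j, p$cl_gi_m / vl)
  add(led[["elim_m5"]], j, p$cl_elim_m5 / vl)
  # liver M4G
  j <- liv[["M4G"]]
  add(j, j, -(p$cl_exch_met + p$cl_gi_m + p$cl_elim_m4g) / vl)
  add(sys[["m4g"]], j, p$cl_exch_met / vl)
  add(im$gb[["M4G"]], j, p$cl_gi_m / vl)
  add(led[["elim_m4g"]], j, p$cl_elim_m4g / vl)
  # liver M1
  j <- liv[["M1"]]
  add(j, j, -p$cl_exch_met / vl)
  add(sys[["m1"]], j, p$cl_exch_met / vl)

  # systemic columns
  j <- sys[["nal_c"]]
  add(j, j, -(p$q_h * p$bp_nal + p$cl_nh + p$q_nal_p1 + p$q_nal_p2) / p$v_nal_c)
  add(liv[["NAL"]], j, p$q_h * p$bp_nal / p$v_nal_c)
  add(led[["elim_nal_nh"]], j, p$cl_nh / p$v_nal_c)
  add(sys[["nal_p1"]], j, p$q_nal_p1 / p$v_nal_c)
  add(sys[["nal_p2"]], j, p$q_nal_p2 / p$v_nal_c)
  j <- sys[["nal_p1"]]
  add(j, j, -p$q_nal_p1 / p$v_nal_p1)
  add(sys[["nal_c"]], j, p$q_nal_p1 / p$v_nal_p1)
  j <- sys[["nal_p2"]]
  add(j, j, -p$q_nal_p2 / p$v_nal_p2)
  add(sys[["nal_c"]], j, p$q_nal_p2 / p$v_nal_p2)
  j <- sys[["m1"]]
  add(j, j, -(p$cl_exch_met * p$bp_m1 + p$cl_elim_m1) / p$v_m1)
  add(liv[["M1"]], j, p$cl_exch_met * p$bp_m1 / p$v_m1)
  add(led[["elim_m1"]], j, p$cl_elim_m1 / p$v_m1)
  j <- sys[["m3_c"]]
  add(j, j, -(p$cl_exch_met * p$bp_m3 + p$cl_elim_m3 + p$q_m3_p) / p$v_m3_c)
  add(liv[["M3"]], j, p$cl_exch_met * p$bp_m3 / p$v_m3_c)
  add(led[["elim_m3"]], j, p$cl_elim_m3 / p$v_m3_c)
  add(sys[["m3_p"]], j, p$q_m3_p / p$v_m3_c)
  j <- sys[["m3_p"]]
  add(j, j, -p$q_m3_p / p$v_m3_p)
  add(sys[["m3_c"]], j, p$q_m3_p / p$v_m3_p)
  j <- sys[["m4"]]
  add(j, j, -(p$cl_exch_met * p$bp_m4 + p$cl_elim_m4) / p$v_m4)
  add(liv[["M4"]], j, p$cl_exch_met * p$bp_m4 / p$v_m4)
  add(led[["elim_m4"]], j, p$cl_elim_m4 / p$v_m4)
  j <- sys[["m5"]]
  add(j, j, -p$cl_exch_met * p$bp_m5 / p$v_m5)
  add(liv[["M5"]], j, p$cl_exch_met * p$bp_m5 / p$v_m5)
  j <- sys[["m4g"]]
  add(j, j, -p$cl_exch_met * p$bp_m4g / p$v_m4g)
  add(liv[["M4G"]], j, p$cl_exch_met * p$bp_m4g / p$v_m4g)

  a0 <- list(i = ii, j = jj, x = xx)

  # meal-window addition: first-order ejection of the gallbladder stores
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ke <- mod$meals$k_e
  for (s in .biliary_species) {
    j <- im$gb[[s]]
    add(j, j, -ke)
    add(im$lumen$C1[1L, s], j, ke)
    add(led[[paste0("eject_", s)]], j, ke)
  }
  list(a0 = a0, am = list(i = ii, j = jj, x = xx))
}

#' Assemble the coupled disposition model
#'
#' Builds the complete stomach-intestine-liver-gallbladder-systemic system
#' for one dose regimen as a pair of sparse rate matrices (base dynamics
#' plus the gallbladder-emptying terms switched on inside meal windows).
#' The matrices are built from analytic triplets; the equivalent modular
#' right-hand side (`hepatic_rhs()`, `systemic_rhs()`, `intestinal_rhs()`,
#' `gallbladder_rhs()` composed) is retained as an independent oracle and
#' the two routes are cross-checked in the test suite.
#'
#' @param params A `nal_params` object (see [load_parameter_set()]).
#' @param physiology A [physiology_default()] object.
#' @param regimen List with `route` (`"oral-ER"` or `"IV-bolus"`) and
#'   `dose` (mg); see [dose_regimen()].
#' @param meals A [meal_schedule()] object.
#' @param grid A [make_grid()] object.
#' @param transport A [transport_params()] object.
#' @return Object of class `nal_model` carrying the index map, sparse
#'   matrices `A0`/`Am`, initial state `y0` and the assembled components.
#' @export
assemble <- function(params, physiology = physiology_default(),
                     regimen = dose_regimen("oral-ER", 162),
                     meals = meal_schedule(), grid = make_grid(),
                     transport = transport_params()) {
  stopifnot(inherits(params, "nal_params"), inherits(grid, "nal_grid"),
            inherits(meals, "nal_meals"), inherits(transport, "nal_transport"))
  bad <- validate_parameter_set(params)
  if (length(bad)) stop("invalid params: ", paste(bad, collapse = "; "))
  im <- .build_index_map(grid$n_nodes)
  mod <- structure(list(
    params = params, phys = physiology, regimen = regimen, meals = meals,
    grid = grid, transport = transport, im = im, n_state = im$n_state,
    mw_lumen = c(NAL = params$mw_nal, M5 = params$mw_m5,
                 M4G = params$mw_m4g, M4 = params$mw_m4)),
    class = "nal_model")

  tr <- .build_triplets(mod)
  mod$A0 <- as(Matrix::sparseMatrix(i = tr$a0$i, j = tr$a0$j, x = tr$a0$x,
                                    dims = c(im$n_state, im$n_state)),
               "CsparseMatrix")
  mod$Am <- as(Matrix::sparseMatrix(i = tr$am$i, j = tr$am$j, x = tr$am$x,
                                    dims = c(im$n_state, im$n_state)),
               "CsparseMatrix")

  y0 <- numeric(im$n_state)
  if (regimen$route == "oral-ER") {
    y0[im$sto_solid] <- regimen$dose
  } else if (regimen$route == "IV-bolus") {
    y0[im$sys[["nal_c"]]] <- regimen$dose
  } else {
    stop("unknown route: ", regimen$route)
  }
  mod$y0 <- y0
  mod$state_count <- c(stomach = 2L,
                       intestine = 16L * grid$n_nodes,
                       liver = length(im$liver), gallbladder = length(im$gb),
                       systemic = length(im$sys), ledger = length(im$led))
  mod
}

#' Dosing regimen
#'
#' @param route `"oral-ER"` (extended-release tablet in the stomach) or
#'   `"IV-bolus"` (parent central compartment).
#' @param dose Dose, mg, `> 0`.
#' @return List of class `nal_regimen`.
#' @export
dose_regimen <- function(route = c("oral-ER", "IV-bolus"), dose) {
  if (!is.character(route) || length(route) != 1 ||
      !route %in% c("oral-ER", "IV-bolus")) {
    stop("unknown route: ", paste(route, collapse = ","))
  }
  if (!is.numeric(dose) || length(dose) != 1 || !is.finite(dose) || dose <= 0) {
    stop("dose must be a positive number (mg)")
  }
  structure(list(route = route, dose = dose), class = "nal_regimen")
}

#' @export
print.nal_model <- function(x, ...) {
  cat("<nal_model>", x$params$group, x$regimen$route, x$regimen$dose, "mg;",
      "state dim", x$n_state, "\n")
  cat("  blocks:", paste(names(x$state_count), x$state_count,
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Integrate an assembled model
#'
#' Adaptive embedded Runge-Kutta integration of the piecewise-linear
#' system with meal-window edges as exact breakpoints. The absolute
#' tolerance is scaled by the dose so trajectories are exactly
#' dose-proportional (the step sequence is invariant under scaling of the
#' state).
#'
#' @param model A [assemble()]d model.
#' @param t_end End of the simulation horizon, h.
#' @param dt_out Output grid spacing, h (ignored when `t_out` is given).
#' @param t_out Optional explicit output times (must start at 0).
#' @param rtol,atol_scale Relative tolerance and absolute-tolerance scale;
#'   `atol = atol_scale * dose`.
#' @return Object of class `nal_sim`: `time` (h), `conc` (matrix, plasma
#'   concentrations of the five analytes in ug/L), `states` (full state
#'   matrix, mg), `diagnostics`, and the model.
#' @export
simulate_model <- function(model, t_end = 120, dt_out = 0.1, t_out = NULL,
                           rtol = 1e-8, atol_scale = 1e-10) {
  stopifnot(inherits(model, "nal_model"))
  if (is.null(t_out)) {
    if (t_end <= 0) stop("t_end must be positive")
    t_out <- seq(0, t_end, by = dt_out)
    if (t_out[length(t_out)] < t_end) t_out <- c(t_out, t_end)
  }
  t_out <- as.numeric(t_out)
  if (t_out[1] != 0 || is.unsorted(t_out, strictly = TRUE)) {
    stop("t_out must start at 0 and be strictly increasing")
  }
  m <- model$meals
  ws <- m$times
  we <- m$times + m$window
  keep <- ws < t_out[length(t_out)]
  res <- .dopri5_lin(model$y0,
                     model$A0@p, model$A0@i, model$A0@x,
                     model$Am@p, model$Am@i, model$Am@x,
                     t_out, ws[keep], we[keep],
                     rtol, atol_scale * model$regimen$dose,
                     hmax = 1, h0 = 1e-4, max_steps = 5e6)
  states <- res$y
  p <- model$params
  im <- model$im
  conc <- cbind(
    NAL = states[im$sys[["nal_c"]], ] / p$v_nal_c,
    M1 = states[im$sys[["m1"]], ] / p$v_m1,
    M3 = states[im$sys[["m3_c"]], ] / p$v_m3_c,
    M4 = states[im$sys[["m4"]], ] / p$v_m4,
    M5 = states[im$sys[["m5"]], ] / p$v_m5) * 1000  # mg/L -> ug/L
  structure(list(time = t_out, conc = conc, states = states,
                 diagnostics = list(naccept = res$naccept,
                                    nreject = res$nreject,
                                    rtol = rtol, atol_scale = atol_scale),
                 model = model),
            class = "nal_sim")
}

#' @export
print.nal_sim <- function(x, ...) {
  mb <- mass_balance(x)
  cat("<nal_sim>", x$model$params$group, x$model$regimen$dose, "mg",
      x$model$regimen$route, "over", max(x$time), "h\n")
  cat(sprintf("  NAL Cmax %.3g ug/L at %.2g h; |mass imbalance|/dose %.2g\n",
              max(x$conc[, "NAL"]), x$time[which.max(x$conc[, "NAL"])],
              mb$max_rel_imbalance))
  invisible(x)
}

#' Molar mass-balance ledger of a simulation
#'
#' Converts every state to moles (each amount is carried in mg of its own
#' species) and checks, at every output time, that dose = drug in system +
#' eliminated (per route) + fecal loss. For a closed run the relative
#' imbalance is at solver tolerance.
#'
#' @param sim A [simulate_model()] result.
#' @return List with the per-time molar `ledger` data frame,
#'   `max_rel_imbalance`, and the terminal route totals
#'   (`eliminated`, `fecal`, mol).
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "nal_sim"))
  mod <- sim$model
  p <- mod$params
  im <- mod$im
  st <- sim$states
  mw_l <- mod$mw_lumen
  mw_liver <- c(NAL = p$mw_nal, M3 = p$mw_m3, M4 = p$mw_m4, M5 = p$mw_m5,
                M4G = p$mw_m4g, M1 = p$mw_m1)
  mw_sys <- c(nal_c = p$mw_nal, nal_p1 = p$mw_nal, nal_p2 = p$mw_nal,
              m1 = p$mw_m1, m3_c = p$mw_m3, m3_p = p$mw_m3, m4 = p$mw_m4,
              m5 = p$mw_m5, m4g = p$mw_m4g)

  moles_of <- function(rows, mw) colSums(st[rows, , drop = FALSE] / mw)
  gut <- 0
  for (l in 1:4) for (s in .lumen_species) {
    gut <- gut + moles_of(im$lumen[[l]][, s], mw_l[[s]])
  }
  stomach <- colSums(st[c(im$sto_solid, im$sto_diss), , drop = FALSE]) / p$mw_nal
  liver <- 0
  for (s in .liver_species) liver <- liver + moles_of(im$liver[[s]], mw_liver[[s]])
  gb <- 0
  for (s in .biliary_species) {
    gb <- gb + moles_of(im$gb[[s]], if (s == "NAL") p$mw_nal else
      if (s == "M5") p$mw_m5 else p$mw_m4g)
  }
  sys <- 0
  for (s in names(im$sys)) sys <- sys + moles_of(im$sys[[s]], mw_sys[[s]])
  fecal <- 0
  for (s in .lumen_species) {
    fecal <- fecal + moles_of(im$led[[paste0("fecal_", s)]], mw_l[[s]])
  }
  elim <- moles_of(im$led[["elim_nal_nh"]], p$mw_nal) +
    moles_of(im$led[["elim_m1"]], p$mw_m1) +
    moles_of(im$led[["elim_m3"]], p$mw_m3) +
    moles_of(im$led[["elim_m4"]], p$mw_m4) +
    moles_of(im$led[["elim_m5"]], p$mw_m5) +
    moles_of(im$led[["elim_m4g"]], p$mw_m4g) +
    moles_of(im$led[["elim_gut_NAL"]], p$mw_nal) +
    moles_of(im$led[["elim_gut_M4"]], p$mw_m4)
  dose_mol <- mod$regimen$dose / p$mw_nal
  total <- stomach + gut + liver + gb + sys + fecal + elim
  ledger <- data.frame(time = sim$time, stomach = stomach, intestine = gut,
                       liver = liver, gallbladder = gb, systemic = sys,
                       fecal = fecal, eliminated = elim, total = total)
  list(ledger = ledger,
       max_rel_imbalance = max(abs(total - dose_mol)) / dose_mol,
       eliminated = elim[length(elim)], fecal = fecal[length(fecal)],
       dose_mol = dose_mol)
}

#' Extract one analyte's predicted plasma profile as a CtSeries
#'
#' @param sim A [simulate_model()] result.
#' @param analyte One of `NAL, M1, M3, M4, M5`.
#' @return A [ct_series()] object (uncensored).
#' @export
sim_ct_series <- function(sim, analyte) {
  stopifnot(inherits(sim, "nal_sim"))
  analyte <- match.arg(analyte, .analytes)
  ct_series(analyte = analyte, time = sim$time,
            conc = sim$conc[, analyte], dose = sim$model$regimen$dose,
            group = sim$model$params$group, lloq = 0)
}
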