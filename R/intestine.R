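#' Build the spatial grid for the intestinal tube
#'
#' The intestine is a normalized 1-D tube on `[0, 1]` discretized into
#' `n_nodes` uniform finite-volume cells (cell `i` owns
#' `[(i-1)/n, i/n)`). Cells whose proximal edge lies at or beyond
#' `gus_zone_start` are flagged beta-glucuronidase (GUS) active: luminal
#' glucuronides are hydrolyzed back to their aglycone only there.
#'
#' @param n_nodes Number of cells; at least 8.
#' @param gus_zone_start Fraction of tube length where the GUS-active zone
#'   begins, in `(0, 1)`.
#' @return Object of class `nal_grid` with node centres `z`, cell width
#'   `dz` and logical `gus_active`.
#' @export
#' @examples
#' g <- make_grid(40, 0.75)
#' sum(g$gus_active)  # 10 distal cells
make_grid <- function(n_nodes = 40, gus_zone_start = 0.75) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 8) {
    stop("n_nodes must be at least 8 (discretization too coarse)")
  }
  if (!(gus_zone_start > 0 && gus_zone_start < 1)) {
    stop("gus_zone_start must lie strictly inside (0, 1)")
  }
  dz <- 1 / n_nodes
  lower <- (seq_len(n_nodes) - 1) * dz
  structure(list(n_nodes = n_nodes, dz = dz, z = lower + dz / 2,
                 gus_zone_start = gus_zone_start,
                 gus_active = lower >= gus_zone_start - 1e-12),
            class = "nal_grid")
}

#' Intestinal transport and exchange parameters
#'
#' Defaults describe a small intestine with a mean transit of about 3.3 h
#' over the normalized tube, weak axial dispersion (an impulse spreads
#' roughly 10% of the length per 3 h), first-order gastric emptying of
#' dissolved drug (4/h), and a distal GUS hydrolysis rate of 2/h. Cross-layer
#' exchange (lumen C1 -> apical membrane C2 -> enterocyte C3 -> lipid C4,
#' C3 -> portal) is expressed as first-order rate constants per layer amount;
#' the glucuronides get zero permeability (they are recycled only through
#' GUS hydrolysis) while the aglycones (NAL, M4) share one permeable set.
#'
#' @param velocity Convective velocity, tube lengths per hour.
#' @param dispersion Axial dispersion coefficient, length^2 per hour.
#' @param k_ge Gastric emptying rate of dissolved drug, 1/h.
#' @param gus_rate GUS hydrolysis rate constant inside the active zone, 1/h.
#' @param layer_k Named list per lumen species of rate constants
#'   `c(k12, k21, k23, k32, k34, k43, ka)`, 1/h.
#' @param enterocyte_loss First-order enterocyte metabolic loss, 1/h
#'   (hook only; default 0, gut metabolism predicted minimal).
#' @return Object of class `nal_transport`.
#' @export
transport_params <- function(velocity = 1 / 3.3, dispersion = 1 / 600,
                             k_ge = 4, gus_rate = 2,
                             layer_k = NULL, enterocyte_loss = 0) {
  perm <- c(k12 = 2, k21 = 1, k23 = 10, k32 = 1, k34 = 0.5, k43 = 0.5, ka = 10)
  none <- c(k12 = 0, k21 = 0, k23 = 0, k32 = 0, k34 = 0, k43 = 0, ka = 0)
  lk <- list(NAL = perm, M5 = none, M4G = none, M4 = perm)
  if (!is.null(layer_k)) lk[names(layer_k)] <- layer_k
  vals <- c(velocity = velocity, dispersion = dispersion, k_ge = k_ge,
            gus_rate = gus_rate, enterocyte_loss = enterocyte_loss,
            unlist(lk))
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all transport parameters must be finite and non-negative")
  }
  structure(list(velocity = velocity, dispersion = dispersion, k_ge = k_ge,
                 gus_rate = gus_rate, layer_k = lk,
                 enterocyte_loss = enterocyte_loss),
            class = "nal_transport")
}

#' First-order tablet release rate
#'
#' Release rate of the extended-release tablet: `k_rel` times the amount
#' still in the tablet. Released (dissolved) drug is then delivered to the
#' duodenum by first-order gastric emptying.
#'
#' @param stomach_amount Drug remaining in the tablet, mg.
#' @param k_rel First-order release constant, 1/h.
#' @return Release rate, mg/h.
#' @export
dissolution_release <- function(stomach_amount, k_rel) {
  if (any(stomach_amount < 0)) stop("stomach amount must be non-negative")
  if (any(k_rel < 0)) stop("k_rel must be non-negative")
  k_rel * stomach_amount
}

#' Per-node GUS hydrolysis rate profile
#'
#' Zero proximal to the GUS zone, `gus_rate` within it. Hydrolysis converts
#' M5 to NAL and M4-G to M4 in molar terms; the engine scales the mass rate
#' by the aglycone/glucuronide molecular-weight ratio.
#'
#' @param grid A [make_grid()] object.
#' @param gus_rate Hydrolysis rate constant, 1/h.
#' @return Numeric vector of per-node rate constants.
#' @export
gus_profile <- function(grid, gus_rate) {
  stopifnot(inherits(grid, "nal_grid"))
  if (gus_rate < 0) stop("gus_rate must be non-negative")
  ifelse(grid$gus_active, gus_rate, 0)
}

# Derivatives of the luminal + tissue-layer amounts of one species.
# `a` is an n_nodes x 4 matrix of amounts (columns C1..C4, mg),
# `inflow` the duodenal input rate (mg/h, cell 1), `gus_k` the per-node
# hydrolysis rate applied to the luminal amount. Returns the derivative
# matrix plus the boundary fluxes. First-order upwind convection,
# conservative central dispersion with zero-flux ends, convective outflow
# at the distal end (fecal loss).
.species_intestine_rhs <- function(a, k, inflow, gus_k, vdz, Ddz2,
                                   enterocyte_loss = 0) {
  n <- nrow(a)
  A1 <- a[, 1L]; A2 <- a[, 2L]; A3 <- a[, 3L]; A4 <- a[, 4L]
  conv <- vdz * (c(0, A1[-n]) - A1)
  disp <- Ddz2 * (c(A1[-1L], A1[n]) - 2 * A1 + c(A1[1L], A1[-n]))
  # reflecting ends: cancel the ghost contributions
  disp[1L] <- Ddz2 * (A1[2L] - A1[1L])
  disp[n] <- Ddz2 * (A1[n - 1L] - A1[n])
  gus_loss <- gus_k * A1
  d1 <- conv + disp - k[["k12"]] * A1 + k[["k21"]] * A2 - gus_loss
  d1[1L] <- d1[1L] + inflow
  d2 <- k[["k12"]] * A1 - (k[["k21"]] + k[["k23"]]) * A2 + k[["k32"]] * A3
  d3 <- k[["k23"]] * A2 -
    (k[["k32"]] + k[["k34"]] + k[["ka"]] + enterocyte_loss) * A3 +
    k[["k43"]] * A4
  d4 <- k[["k34"]] * A3 - k[["k43"]] * A4
  list(d = cbind(d1, d2, d3, d4, deparse.level = 0),
       fecal_rate = vdz * A1[n],
       portal_rate = k[["ka"]] * sum(A3),
       gut_loss_rate = enterocyte_loss * sum(A3),
       gus_loss = gus_loss)
}

#' Time derivative of the intestinal state
#'
#' Method-of-lines right-hand side for all lumen species and layers.
#' Convection and dispersion act on the luminal layer; layers exchange by
#' first-order rates; the enterocyte layer feeds the portal (absorption)
#' output; mass leaving the distal boundary is pre-systemic (fecal) loss.
#' GUS hydrolysis converts luminal M5 to NAL and M4-G to M4 in place, with
#' mass rates scaled by the molecular-weight ratio (molar conservation).
#'
#' @param state Named list of `n_nodes x 4` amount matrices (mg), one per
#'   species in `c("NAL","M5","M4G","M4")`, layers C1..C4 in columns.
#' @param transport A [transport_params()] object.
#' @param grid A [make_grid()] object.
#' @param inflow Named numeric: duodenal input rate per species, mg/h
#'   (stomach delivery and gallbladder ejection at the inlet cell).
#' @param mw Named molecular weights (`NAL`, `M5`, `M4G`, `M4`), g/mol.
#' @return List with per-species derivative matrices `d`, and rates
#'   `fecal`, `portal` (named per species, mg/h).
#' @export
intestinal_rhs <- function(state, transport, grid,
                           inflow = c(NAL = 0, M5 = 0, M4G = 0, M4 = 0),
                           mw = c(NAL = 357.45, M5 = 533.57,
                                  M4G = 549.57, M4 = 373.45)) {
  stopifnot(inherits(grid, "nal_grid"), inherits(transport, "nal_transport"))
  n <- grid$n_nodes
  sp <- .lumen_species
  for (s in sp) {
    if (is.null(state[[s]]) || !identical(dim(state[[s]]), c(n, 4L))) {
      stop("state dimension mismatch for species ", s,
           " (need ", n, " x 4 amounts)")
    }
  }
  vdz <- transport$velocity / grid$dz
  Ddz2 <- transport$dispersion / grid$dz^2
  gus_k <- gus_profile(grid, transport$gus_rate)
  out <- lapply(sp, function(s) {
    .species_intestine_rhs(state[[s]], transport$layer_k[[s]],
                           inflow[[s]], if (s %in% c("M5", "M4G")) gus_k else 0 * gus_k,
                           vdz, Ddz2,
                           if (s %in% c("NAL", "M4")) transport$enterocyte_loss else 0)
  })
  names(out) <- sp
  # GUS products appear in the aglycone lumen, MW-scaled
  out$NAL$d[, 1L] <- out$NAL$d[, 1L] + out$M5$gus_loss * mw[["NAL"]] / mw[["M5"]]
  out$M4$d[, 1L] <- out$M4$d[, 1L] + out$M4G$gus_loss * mw[["M4"]] / mw[["M4G"]]
  list(d = lapply(out, `[[`, "d"),
       fecal = vapply(out, `[[`, 0, "fecal_rate"),
       portal = vapply(out, `[[`, 0, "portal_rate"),
       gut_loss = vapply(out, `[[`, 0, "gut_loss_rate"))
}
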