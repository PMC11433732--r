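#' Interconvert plasma and blood concentrations
#'
#' Blood-to-plasma ratios are used at every liver interface: compartment
#' models live on plasma concentrations while the liver sees blood.
#'
#' @param plasma_conc Plasma concentration.
#' @param bp Blood-to-plasma ratio, `> 0`.
#' @param inverse If `TRUE`, convert blood to plasma instead.
#' @return Converted concentration.
#' @export
#' @examples
#' bp_convert(10, 1.15)  # 11.5
bp_convert <- function(plasma_conc, bp, inverse = FALSE) {
  if (any(bp <= 0)) stop("bp must be positive")
  if (inverse) plasma_conc / bp else plasma_conc * bp
}

#' Time derivative of the systemic compartments
#'
#' Standard linear mammillary kinetics: three compartments for the parent
#' (central A + peripherals B, C; total steady-state volume constrained to
#' the published 267 L), central + peripheral for M3, and a single central
#' compartment each for M1, M4, M5 and M4-G. Elimination sites: parent
#' non-hepatic clearance and M1/M3/M4 elimination act on their central
#' plasma concentrations; M5 and M4-G are eliminated in the liver (handled
#' by [hepatic_rhs()]).
#'
#' @param state Named amounts (mg):
#'   `nal_c, nal_p1, nal_p2, m1, m3_c, m3_p, m4, m5, m4g`.
#' @param liver_out Named rates of mass arriving from the liver, mg/h
#'   (`NAL, M3, M4, M5, M4G, M1`), i.e. the `to_systemic` output of
#'   [hepatic_rhs()].
#' @param params A `nal_params` object.
#' @return List with `d` (derivative), `to_liver` (named rates of mass
#'   returning to the liver, mg/h) and `elim` (named irreversible
#'   elimination rates, mg/h).
#' @export
systemic_rhs <- function(state, liver_out, params) {
  p <- params
  need <- c("nal_c", "nal_p1", "nal_p2", "m1", "m3_c", "m3_p", "m4",
            "m5", "m4g")
  if (!all(need %in% names(state))) {
    stop("systemic state dimension mismatch; need amounts ",
         paste(need, collapse = ", "))
  }
  cp_nal <- state[["nal_c"]] / p$v_nal_c
  cp_p1 <- state[["nal_p1"]] / p$v_nal_p1
  cp_p2 <- state[["nal_p2"]] / p$v_nal_p2
  cp_m1 <- state[["m1"]] / p$v_m1
  cp_m3 <- state[["m3_c"]] / p$v_m3_c
  cp_m3p <- state[["m3_p"]] / p$v_m3_p
  cp_m4 <- state[["m4"]] / p$v_m4
  cp_m5 <- state[["m5"]] / p$v_m5
  cp_m4g <- state[["m4g"]] / p$v_m4g
  to_liver <- c(NAL = p$q_h * p$bp_nal * cp_nal,
                M3 = p$cl_exch_met * p$bp_m3 * cp_m3,
                M4 = p$cl_exch_met * p$bp_m4 * cp_m4,
                M5 = p$cl_exch_met * p$bp_m5 * cp_m5,
                M4G = p$cl_exch_met * p$bp_m4g * cp_m4g,
                M1 = p$cl_exch_met * p$bp_m1 * cp_m1)
  elim <- c(NAL = p$cl_nh * cp_nal,
            M1 = p$cl_elim_m1 * cp_m1,
            M3 = p$cl_elim_m3 * cp_m3,
            M4 = p$cl_elim_m4 * cp_m4)
  d <- c(
    nal_c = liver_out[["NAL"]] - to_liver[["NAL"]] - elim[["NAL"]] -
      p$q_nal_p1 * (cp_nal - cp_p1) - p$q_nal_p2 * (cp_nal - cp_p2),
    nal_p1 = p$q_nal_p1 * (cp_nal - cp_p1),
    nal_p2 = p$q_nal_p2 * (cp_nal - cp_p2),
    m1 = liver_out[["M1"]] - to_liver[["M1"]] - elim[["M1"]],
    m3_c = liver_out[["M3"]] - to_liver[["M3"]] - elim[["M3"]] -
      p$q_m3_p * (cp_m3 - cp_m3p),
    m3_p = p$q_m3_p * (cp_m3 - cp_m3p),
    m4 = liver_out[["M4"]] - to_liver[["M4"]] - elim[["M4"]],
    m5 = liver_out[["M5"]] - to_liver[["M5"]],
    m4g = liver_out[["M4G"]] - to_liver[["M4G"]])
  list(d = d, to_liver = to_liver, elim = elim)
}
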