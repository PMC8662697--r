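## Advective transport of blood species through the sinusoidal chain and
## the body compartment; portal-hypertensive flow scaling; stimulus
## assembly; hepatic clearance.

#' Advection along the sinusoidal chain
#'
#' Mass exchange of one blood species through the porto-central chain:
#' each compartment receives from its upstream neighbor,
#' `dM_i/dt = bf * (M_{i-1} - M_i)` with the body concentration `M0`
#' feeding compartment 1, while the body compartment receives the
#' pericentral outflow diluted by the body-to-hepatic volume ratio,
#' `dM0/dt = bf * (M_N - M0) / s`. With sources and sinks off, the total
#' `sum(M_i) + s * M0` is conserved exactly.
#'
#' @param M length-`N` vector of compartment concentrations.
#' @param M0 body-compartment concentration.
#' @param bf blood flow rate (1/s).
#' @param s body-to-hepatic volume ratio.
#' @return list with `dM` (length `N`) and `dM0`.
#' @export
advection_rhs <- function(M, M0, bf, s) {
  N <- length(M)
  if (N < 2) stop("invalid lobule: need at least 2 compartments",
                  call. = FALSE)
  stopifnot(bf > 0, s > 0)
  list(dM = bf * (c(M0, M[-N]) - M), dM0 = bf * (M[N] - M0) / s)
}

#' Portal-hypertensive blood flow scaling
#'
#' Poiseuille's law relates the pressure differential across the sinusoid
#' linearly to flow at fixed viscosity and geometry, so an `x`-fold
#' increase in portal pressure scales the flow rate `x`-fold.
#'
#' @param bf_normal normotensive flow rate (1/s).
#' @param pressure_fold portal pressure multiplier (>= 1).
#' @return scaled flow rate (1/s).
#' @examples
#' hypertensive_flow(2.25, 3)  # 6.75 /s, severe portal hypertension
#' @export
hypertensive_flow <- function(bf_normal, pressure_fold) {
  stopifnot(bf_normal > 0, pressure_fold >= 1)
  bf_normal * pressure_fold
}

#' Per-cell calcium-mobilizing stimulus
#'
#' Each hepatocyte is stimulated by the catecholamines of its own
#' sinusoidal compartment; innervated cells additionally receive the
#' synaptic norepinephrine term `K_NEpn_stim * CNSAct`.
#'
#' @param Epn per-compartment epinephrine (nM).
#' @param NEpn per-compartment norepinephrine (nM).
#' @param innervation an [innervation_pattern()].
#' @param CNSAct CNS activation.
#' @return length-`N` stimulus vector H (nM).
#' @export
assemble_stimulus <- function(Epn, NEpn, innervation, CNSAct) {
  N <- length(Epn)
  if (length(NEpn) != N) stop("Epn and NEpn lengths differ", call. = FALSE)
  if (length(innervation$innervated_mask) != N)
    stop("innervation mask length mismatch", call. = FALSE)
  Epn + NEpn +
    innervation$K_NEpn_stim * CNSAct * as.numeric(innervation$innervated_mask)
}

#' Hepatic first-order clearance
#'
#' Hormones and catecholamines are cleared only in the liver during their
#' passage through the sinusoids, by mass-action kinetics applied per
#' hepatic compartment (never to the body compartment).
#'
#' @param M_i per-compartment concentration(s).
#' @param k_clear clearance rate (1/s).
#' @return sink term(s), `-k_clear * M_i`.
#' @export
hepatic_clearance_rhs <- function(M_i, k_clear) {
  stopifnot(all(M_i >= 0), k_clear >= 0)
  -k_clear * M_i
}

## Basal steady-state porto-central profile of a species that is secreted
## into the body at a constant rate (sinusoid units, already including any
## volume bridge) and cleared per compartment at rate k_clear. Used to
## initialize catecholamines so that the control run starts on its
## attractor. Returns list(M0, M = length-N profile).
basal_secretion_profile <- function(v_sec, bf, s, k_clear, N) {
  rho <- bf / (bf + k_clear)
  M0 <- if (k_clear > 0) (v_sec / bf) / (1 - rho^N) else NA_real_
  if (k_clear == 0) {
    ## no clearance: no finite steady state; start flat at 0
    return(list(M0 = 0, M = rep(0, N)))
  }
  list(M0 = M0, M = M0 * rho^seq_len(N))
}
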