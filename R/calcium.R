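## Per-hepatocyte IP3-calcium cross-coupling oscillator.
##
## Four state variables per cell: the free alpha-1 adrenergic receptor
## fraction r, cytosolic IP3, cytosolic calcium CaI, and the free IP3
## receptor fraction g on the ER surface. Total cell calcium CaT is held
## constant (closed-cell formulation: there is no plasma-membrane calcium
## flux). Only IP3 crosses gap junctions.

#' Free-receptor fraction balance
#'
#' Rate of change of the free alpha-1 adrenergic receptor fraction `r`:
#' recycling of bound receptors at rate `k_r`, loss through non-specific
#' binding at rate `k_d`, and mass-action binding of the hormone stimulus
#' `H` at rate `k_Hr`.
#'
#' @param r free receptor fraction in \[0, 1\].
#' @param H calcium-mobilizing hormone stimulus (nM).
#' @param k_r receptor recycling rate (1/s).
#' @param k_d hormone-independent binding rate (1/s).
#' @param k_Hr hormone-receptor binding rate (1/nM/s).
#' @return dr/dt (1/s).
#' @export
receptor_rhs <- function(r, H, k_r, k_d = 0.34, k_Hr = 1) {
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]", call. = FALSE)
  if (any(H < 0) || any(c(k_r, k_d, k_Hr) < 0))
    stop("negative rate or stimulus", call. = FALSE)
  k_r * (1 - r) - k_d * r - k_Hr * H * r
}

#' Cytosolic IP3 balance with gap-junction exchange
#'
#' Saturating hormone-induced IP3 synthesis gated by a first-order Hill
#' function of cytosolic calcium (the calcium-to-IP3 positive feedback),
#' first-order degradation, and mass-exchange coupling with the adjacent
#' cells: `-G_ij * sum_j (IP3_i - IP3_j)` over the 1 or 2 chain neighbors.
#'
#' @param IP3_i cytosolic IP3 of the cell (uM).
#' @param r_i free receptor fraction of the cell.
#' @param CaI_i cytosolic calcium of the cell (uM).
#' @param H hormone stimulus at the cell (nM).
#' @param neighbors IP3 values of the adjacent cells (uM); length 1 at
#'   chain ends, 2 in the interior.
#' @param k_IP3 saturating IP3 synthesis rate of the cell (1/s).
#' @param G_ij gap-junction mass-transfer coefficient (1/s).
#' @param k_cat bound-receptor ratio at half-max synthesis.
#' @param k3 calcium half-saturation of synthesis (uM).
#' @param D IP3 degradation rate (1/s).
#' @return dIP3/dt (uM/s).
#' @export
ip3_rhs <- function(IP3_i, r_i, CaI_i, H, neighbors, k_IP3,
                    G_ij = 0, k_cat = 0.45, k3 = 1, D = 0.8) {
  if (any(c(IP3_i, CaI_i, H, neighbors) < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  k_IP3 * H * r_i / (k_cat + r_i) * CaI_i / (CaI_i + k3) -
    D * IP3_i - G_ij * sum(IP3_i - neighbors)
}

#' Cytosolic calcium balance
#'
#' IP3-gated store release through the free IP3R fraction `(1 - g)` with a
#' fourth-order Hill dependence on IP3, a constitutive store leak `L`, and
#' second-order reuptake pumping into the ER.
#'
#' @param CaI cytosolic calcium (uM), at most `CaT`.
#' @param CaT total cell calcium (uM).
#' @param g free IP3R fraction.
#' @param IP3 cytosolic IP3 (uM).
#' @param A max store release rate (uM/s).
#' @param k1 IP3 half-saturation of release (uM).
#' @param L store leak flux (uM/s).
#' @param B max pump rate (uM/s).
#' @param k2 calcium half-saturation of the pump (uM).
#' @return dCaI/dt (uM/s).
#' @export
calcium_rhs <- function(CaI, CaT, g, IP3, A = 0.20, k1 = 1,
                        L = 0.00015, B = 0.082, k2 = 0.15) {
  if (any(CaI > CaT))
    stop("state violation: CaI exceeds total cell calcium CaT",
         call. = FALSE)
  (1 - g) * (A * IP3^4 / (k1 + IP3)^4 + L) * (CaT - CaI) -
    B * CaI^2 / (k2^2 + CaI^2)
}

#' Free IP3 receptor fraction balance
#'
#' Calcium-dependent inactivation of the IP3 receptor (fourth power of
#' cytosolic calcium) against a constitutive reactivation rate `F`. The
#' raw rate law drives `g` below 0 at low calcium (when `E * CaI^4 < F`),
#' so the state is clamped to \[0, 1\] at the integrator level.
#'
#' @param g free IP3R fraction in \[0, 1\].
#' @param CaI cytosolic calcium (uM).
#' @param E inactivation rate (1/uM^4/s).
#' @param F reactivation rate (1/s).
#' @return dg/dt (1/s).
#' @export
ip3r_rhs <- function(g, CaI, E = 1, F = 0.01) {
  if (any(g < 0 | g > 1)) stop("g must lie in [0, 1]", call. = FALSE)
  E * CaI^4 * (1 - g) - F
}

#' Trajectory of one isolated hepatocyte under constant stimulus
#'
#' Integrates the four-variable oscillator for a single uncoupled cell
#' (no gap junctions, no metabolic feedback) from the nominal initial
#' conditions. With `H = 0` the cell relaxes to a non-spiking fixed point;
#' for stimuli above roughly 2.5 nM sustained calcium spiking appears. The
#' default stimulus of 4 nM is the calibrated value at which a mid-lobular
#' cell spikes with an inter-spike interval near 100 s.
#'
#' @param params a [calcium_params()] object.
#' @param H constant hormone stimulus (nM).
#' @param t_end integration horizon (s).
#' @param cell cell index whose zonated rates are used (default: the
#'   mid-lobular cell).
#' @param dt output resolution (s).
#' @param CaI0,g0,IP30,r0 initial conditions (uM / fractions; IP3 in uM).
#' @return data.frame with columns `time`, `r`, `IP3`, `CaI`, `g`.
#' @export
single_cell_trajectory <- function(params = calcium_params(), H = 4,
                                   t_end = 2000,
                                   cell = ceiling(params$N / 2),
                                   dt = 0.5,
                                   CaI0 = 0.2, g0 = 0.25, IP30 = 1e-4,
                                   r0 = 0.5) {
  stopifnot(H >= 0, t_end > 0, cell >= 1, cell <= params$N)
  p <- params
  k_r <- p$k_r_i[cell]
  k_IP3 <- p$k_IP3_i[cell]
  rhs <- function(t, y, parms) {
    g <- min(max(y[4], 0), 1)
    dr <- receptor_rhs(min(max(y[1], 0), 1), H, k_r, p$k_d, p$k_Hr)
    dIP3 <- ip3_rhs(max(y[2], 0), y[1], max(y[3], 0), H,
                    neighbors = max(y[2], 0), k_IP3 = k_IP3, G_ij = 0,
                    k_cat = p$k_cat, k3 = p$k3, D = p$D)
    dCaI <- calcium_rhs(y[3], p$CaT0, g, max(y[2], 0),
                        p$A, p$k1, p$L, p$B, p$k2)
    dg <- ip3r_rhs(g, max(y[3], 0), p$E, p$F)
    if ((y[4] <= 0 && dg < 0) || (y[4] >= 1 && dg > 0)) dg <- 0
    list(c(dr, dIP3, dCaI, dg))
  }
  y0 <- c(r = r0, IP3 = IP30, CaI = CaI0, g = g0)
  out <- deSolve::ode(y0, seq(0, t_end, by = dt), rhs, NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1] < 0)
    stop("single-cell integration failed; istate = ",
         attr(out, "istate")[1], call. = FALSE)
  as.data.frame(unclass(out))
}
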