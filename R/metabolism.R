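## Calcium-potentiated glycogenolysis and the minimal zonated
## glycogen-to-glucose backbone.

#' Glycogen phosphorylase kinase activity
#'
#' Dimensionless GPK activity as a function of cytosolic calcium: basal
#' activity `v0` below the activation threshold `CaI_GPK`, and a
#' Michaelis-Menten form `CaI / (K + CaI)` above it.
#'
#' @param CaI cytosolic calcium (uM).
#' @param CaI_GPK activation threshold (uM).
#' @param K_CaI_GPK Michaelis constant of the active branch (uM).
#' @param v0 basal activity.
#' @return dimensionless activity in (0, 1).
#' @export
gpk_activity <- function(CaI, CaI_GPK = 0.44, K_CaI_GPK = 3, v0 = 0.05) {
  stopifnot(all(CaI >= 0))
  ifelse(CaI > CaI_GPK, CaI / (K_CaI_GPK + CaI), v0)
}

#' Hormone-dependent ceiling of the glycogen breakdown rate
#'
#' The maximum phosphorylation capacity scales with the local
#' glucagon-to-insulin balance: `(Glu + k_LP) / (Ins + k_IP)`, all in pM.
#'
#' @param Glu glucagon (pM).
#' @param Ins insulin (pM).
#' @param k_LP glucagon offset (pM).
#' @param k_IP insulin offset (pM).
#' @return dimensionless ceiling.
#' @export
k_phos_max <- function(Glu, Ins, k_LP = 45, k_IP = 26.66) {
  stopifnot(all(Glu >= 0), all(Ins >= 0))
  if (any(Ins + k_IP == 0)) stop("division by zero: Ins + k_IP = 0",
                                 call. = FALSE)
  (Glu + k_LP) / (Ins + k_IP)
}

#' Zonated, calcium-potentiated glycogenolysis flux
#'
#' Glucose release rate from glycogen breakdown for one hepatocyte
#' (uM/s of glucosyl units, positive = breakdown; the glycogen store
#' changes as the negative of this flux). The rate law combines the
#' hormone-dependent ceiling ([k_phos_max()]), a Hill term in the glycogen
#' store, a phosphate saturation factor, the calcium potentiation factor
#' `1 + v_CaI_max * gpk_activity(CaI)`, and a per-cell zonation weight
#' (periportal-favored).
#'
#' Blood-state glucagon and insulin are supplied in nM and converted to pM
#' at this interface.
#'
#' @param Glyc glycogen store (mM glucosyl units).
#' @param Phos intracellular phosphate (uM).
#' @param Glu local sinusoidal glucagon (nM).
#' @param Ins local sinusoidal insulin (nM).
#' @param CaI cytosolic calcium (uM).
#' @param zonation_weight per-cell multiplicative weight.
#' @param params a [metabolism_params()] object.
#' @return flux (uM/s), positive for breakdown.
#' @export
glycogenolysis_rate <- function(Glyc, Phos, Glu, Ins, CaI,
                                zonation_weight = 1,
                                params = metabolism_params()) {
  stopifnot(all(Glyc >= 0), all(Phos >= 0))
  p <- params
  K <- if (p$use_Km_CaI) p$Km_CaI else p$K_CaI_GPK
  act <- gpk_activity(CaI, p$CaI_GPK, K, p$v0)
  kp <- k_phos_max(Glu * 1000, Ins * 1000, p$k_LP, p$k_IP)
  zonation_weight * p$v_brk * kp *
    Glyc^p$n_brk / (Glyc^p$n_brk + p$Km_Glyc^p$n_brk) *
    Phos / (p$Km_Phos + Phos) *
    (1 + p$v_CaI_max * act)
}

#' First-order hepatocyte-to-sinusoid glucose exchange
#'
#' Free intracellular glucose exchanges with the local sinusoidal blood
#' compartment by first-order kinetics; glycogenolysis feeds intracellular
#' glucose one-to-one upstream of this exchange.
#'
#' @param Glucose_cell intracellular free glucose (uM).
#' @param Glucose_blood local sinusoidal glucose (uM).
#' @param k_export exchange rate (1/s).
#' @return flux into the sinusoid (uM/s); negative values denote uptake.
#' @export
glucose_export_flux <- function(Glucose_cell, Glucose_blood, k_export = 0.1) {
  stopifnot(all(Glucose_cell >= 0), all(Glucose_blood >= 0), k_export >= 0)
  k_export * (Glucose_cell - Glucose_blood)
}
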