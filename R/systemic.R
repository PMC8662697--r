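## Body-compartment dynamics: CNS glucose sensing, pancreatic hormone
## secretion, adrenal catecholamine release, and body glucose consumption.

#' CNS activation by systemic hypoglycemia
#'
#' Dimensionless hypothalamic activation, driven by the deviation of
#' systemic glucose below the sympathetic threshold with saturation
#' kinetics: `(G_symp - GB) / (Km_symp + (G_symp - GB))` for
#' `GB < G_symp`, and 0 otherwise. Continuous and monotone decreasing in
#' `GB` on `[0, G_symp]`.
#'
#' @param GB systemic blood glucose (uM).
#' @param G_symp activation threshold (uM).
#' @param Km_symp half-saturation of the deviation (uM).
#' @return activation value in \[0, 1).
#' @export
cns_activation <- function(GB, G_symp = 4500, Km_symp = 500) {
  stopifnot(all(GB >= 0))
  dev <- pmax(G_symp - GB, 0)
  dev / (Km_symp + dev)
}

#' Pancreatic glucagon and insulin secretion rates
#'
#' Secretion responds to the log-deviation of systemic glucose (in
#' arbitrary units) from the reference `G_ref` through a Hill function:
#' glucagon is secreted only below the reference, insulin only above it,
#' so the two branches are mutually exclusive. In the alternative model
#' variant, CNS activation adds a saturating term to glucagon secretion
#' (an extra-pancreatic activation pathway).
#'
#' @param GB_au systemic glucose in arbitrary units (`GB / G_au_scale`).
#' @param params a [systemic_params()] object.
#' @param variant `"main"` or `"alternative"`.
#' @param CNSAct CNS activation (used by the alternative variant only).
#' @return named numeric vector `c(dGlu, dIns)` of secretion rates (nM/s,
#'   sinusoidal concentration units).
#' @export
pancreas_secretion <- function(GB_au, params = systemic_params(),
                               variant = c("main", "alternative"),
                               CNSAct = 0) {
  variant <- match.arg(variant)
  stopifnot(GB_au > 0)
  p <- params
  x <- log(p$G_ref / GB_au)
  dGlu <- 0
  dIns <- 0
  if (GB_au < p$G_ref)
    dGlu <- (1 / p$tau_glu) * x^p$n_glu / (p$km_glu^p$n_glu + x^p$n_glu)
  if (GB_au > p$G_ref) {
    y <- -x
    dIns <- (1 / p$tau_ins) * y^p$n_ins / (p$km_ins^p$n_ins + y^p$n_ins)
  }
  if (variant == "alternative" && GB_au < p$G_ref)
    dGlu <- dGlu + p$v_glu_alt * CNSAct / (p$km_glu_alt + CNSAct)
  c(dGlu = dGlu, dIns = dIns)
}

#' Adrenal catecholamine secretion rates
#'
#' In the main variant, CNS activation stimulates epinephrine and
#' norepinephrine synthesis linearly:
#' `amplification * v * (1 + X * CNSAct)`. In the alternative variant the
#' adrenal medulla is denervated and secretion stays at the basal rates
#' regardless of CNS activation.
#'
#' @param CNSAct CNS activation in \[0, 1).
#' @param params a [systemic_params()] object.
#' @param variant `"main"` or `"alternative"`.
#' @return named numeric vector `c(dEpn, dNEpn)` (nM/s, sinusoidal
#'   concentration units; the volume bridge `catechol_scale` is applied by
#'   the simulation engine, not here).
#' @export
adrenal_secretion <- function(CNSAct, params = systemic_params(),
                              variant = c("main", "alternative")) {
  variant <- match.arg(variant)
  stopifnot(CNSAct >= 0, CNSAct < 1)
  p <- params
  amp <- p$adrenal_amplification
  if (variant == "main")
    c(dEpn = amp * p$v_Epn * (1 + p$X_Epn * CNSAct),
      dNEpn = amp * p$v_NEpn * (1 + p$X_NEpn * CNSAct))
  else
    c(dEpn = amp * p$v_Epn, dNEpn = amp * p$v_NEpn)
}

#' Whole-body glucose consumption with an exercise window
#'
#' Basal glucose uptake by peripheral tissues, elevated by a constant
#' multiplier (default 3.5-fold) inside the exercise window.
#'
#' @param t time (s).
#' @param u_G_basal basal uptake rate (uM/s, body units).
#' @param exercise_start,exercise_end window bounds (s); use
#'   `exercise_end <= exercise_start` (or a multiplier of 1) for the
#'   no-exercise control.
#' @param multiplier uptake fold-elevation during exercise.
#' @return uptake rate (uM/s).
#' @export
body_glucose_consumption <- function(t, u_G_basal,
                                     exercise_start = 500,
                                     exercise_end = 4100,
                                     multiplier = 3.5) {
  stopifnot(all(t >= 0), u_G_basal >= 0)
  u_G_basal * ifelse(t >= exercise_start & t < exercise_end, multiplier, 1)
}
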