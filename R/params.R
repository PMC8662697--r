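#' Linearly graded per-cell parameter vector along the porto-central axis
#'
#' Hepatocyte-intrinsic calcium signaling rates are zonated: alpha-1
#' adrenergic receptor recycling (`k_r`) and saturating IP3 synthesis
#' (`k_IP3`) increase from the periportal (PP, cell 1) to the pericentral
#' (PC, cell `N`) end of the lobule. The gradient is a deterministic linear
#' interpolation between the two extreme values; for `N = 15` it reproduces
#' the published per-cell tables of both the main and the alternative
#' parameterization to three decimals.
#'
#' @param N number of hepatic layers (>= 2).
#' @param lo value at the periportal end (cell 1).
#' @param hi value at the pericentral end (cell `N`).
#' @return numeric vector of length `N`, linearly spaced from `lo` to `hi`.
#' @examples
#' build_zonation_gradients(15, 0.5, 1.0)[8]  # mid-lobular cell, 0.750
#' @export
build_zonation_gradients <- function(N, lo, hi) {
  if (!is.numeric(N) || length(N) != 1L || N < 2)
    stop("invalid lobule: need at least N = 2 hepatic layers", call. = FALSE)
  if (lo > hi) stop("gradient must be non-decreasing: lo <= hi", call. = FALSE)
  seq(lo, hi, length.out = as.integer(N))
}

#' Intracellular calcium signaling parameters
#'
#' Rate constants of the per-hepatocyte IP3-calcium cross-coupling
#' oscillator: hormone receptor turnover, IP3 synthesis and degradation,
#' ER calcium release/pumping, and IP3 receptor (in)activation. Defaults are
#' the nominal main-model values; the zonated rates `k_r_i` and `k_IP3_i`
#' are length-`N` vectors, non-decreasing from PP to PC.
#'
#' @param N number of hepatic layers.
#' @param A max ER Ca release rate (uM/s).
#' @param B max cytosolic Ca pump rate (uM/s).
#' @param D IP3 degradation rate (1/s).
#' @param E IP3R inactivation rate (1/uM^4/s).
#' @param F IP3R reactivation rate (1/s).
#' @param k1 IP3 half-saturation of store release (uM).
#' @param k2 Ca half-saturation of the reuptake pump (uM).
#' @param k3 Ca half-saturation of IP3 production (uM).
#' @param k_cat bound-receptor ratio at half-max IP3 production.
#' @param k_d hormone-independent receptor binding rate (1/s).
#' @param k_Hr hormone-receptor binding rate (1/nM/s).
#' @param L constitutive store leak flux (uM/s).
#' @param k_r_i per-cell receptor recycling rates (1/s), PP to PC.
#' @param k_IP3_i per-cell saturating IP3 synthesis rates (1/s), PP to PC.
#' @param CaT0 total cell calcium, constant per cell (uM).
#' @return object of class `calcium_params`.
#' @export
calcium_params <- function(N = 15L,
                           A = 0.20, B = 0.082, D = 0.8, E = 1, F = 0.01,
                           k1 = 1, k2 = 0.15, k3 = 1,
                           k_cat = 0.45, k_d = 0.34, k_Hr = 1, L = 0.00015,
                           k_r_i = build_zonation_gradients(N, 0.5, 1.0),
                           k_IP3_i = build_zonation_gradients(N, 0.5, 0.6),
                           CaT0 = 500.2) {
  p <- list(N = as.integer(N), A = A, B = B, D = D, E = E, F = F,
            k1 = k1, k2 = k2, k3 = k3, k_cat = k_cat, k_d = k_d,
            k_Hr = k_Hr, L = L, k_r_i = k_r_i, k_IP3_i = k_IP3_i,
            CaT0 = CaT0)
  scal <- p[setdiff(names(p), c("k_r_i", "k_IP3_i", "N"))]
  if (any(unlist(scal) < 0)) stop("calcium rates must be >= 0", call. = FALSE)
  for (v in c("k_r_i", "k_IP3_i")) {
    if (length(p[[v]]) != p$N) stop(v, " must have length N", call. = FALSE)
    if (is.unsorted(p[[v]])) stop(v, " must be non-decreasing PP to PC",
                                  call. = FALSE)
  }
  structure(p, class = "calcium_params")
}

#' Glycogenolysis and glucose-handling parameters
#'
#' Constants of the calcium-potentiated glycogen breakdown rate law and of
#' the minimal zonated glycogen-to-glucose backbone. Glycogen phosphorylase
#' kinase (GPK) activity follows a thresholded Michaelis-Menten form in
#' cytosolic calcium; the breakdown flux combines a glycogen Hill term, a
#' phosphate saturation factor, and a glucagon/insulin-dependent ceiling.
#' Hormones enter the ceiling in pM while blood-state hormones are stored
#' in nM; the conversion happens at this interface.
#'
#' @param N number of hepatic layers.
#' @param CaI_GPK cytosolic Ca activation threshold for GPK (uM).
#' @param K_CaI_GPK Michaelis constant of the GPK activity term (uM).
#' @param v0 basal (below-threshold) GPK activity, dimensionless.
#' @param v_brk maximum glycogen breakdown rate (uM/s glucosyl units).
#' @param Km_Glyc glycogen half-saturation (mM).
#' @param Km_Phos phosphate half-saturation (uM).
#' @param n_brk Hill exponent of the glycogen term.
#' @param v_CaI_max maximum calcium potentiation factor of glycogenolysis.
#' @param Km_CaI alternative Michaelis constant (uM); stored alongside
#'   `K_CaI_GPK` and used instead of it when `use_Km_CaI = TRUE`.
#' @param use_Km_CaI logical; substitute `Km_CaI` for `K_CaI_GPK` in the
#'   GPK activity term.
#' @param k_LP glucagon offset in the breakdown ceiling (pM).
#' @param k_IP insulin offset in the breakdown ceiling (pM).
#' @param Phos intracellular phosphate, held constant (uM).
#' @param zonation_weight_i per-cell multiplicative weight on the
#'   glycogenolysis flux, non-increasing PP to PC (PP-favored zonation).
#' @param k_export first-order hepatocyte-to-sinusoid glucose exchange
#'   rate (1/s).
#' @param Glyc0 initial glycogen store per cell (mM glucosyl units).
#' @return object of class `metabolism_params`.
#' @export
metabolism_params <- function(N = 15L,
                              CaI_GPK = 0.44, K_CaI_GPK = 3, v0 = 0.05,
                              v_brk = 5, Km_Glyc = 100, Km_Phos = 4000,
                              n_brk = 4, v_CaI_max = 3,
                              Km_CaI = 0.6, use_Km_CaI = TRUE,
                              k_LP = 45, k_IP = 26.66, Phos = 4000,
                              zonation_weight_i =
                                rev(build_zonation_gradients(N, 0.5, 1.0)),
                              k_export = 0.1, Glyc0 = 300) {
  stopifnot(CaI_GPK > 0, v0 > 0, v0 <= 1, n_brk >= 1, k_IP > 0,
            length(zonation_weight_i) == N)
  if (any(zonation_weight_i <= 0) || any(zonation_weight_i > 1) ||
      is.unsorted(rev(zonation_weight_i)))
    stop("zonation_weight_i must lie in (0,1] and be non-increasing PP to PC",
         call. = FALSE)
  structure(list(N = as.integer(N), CaI_GPK = CaI_GPK,
                 K_CaI_GPK = K_CaI_GPK, v0 = v0, v_brk = v_brk,
                 Km_Glyc = Km_Glyc, Km_Phos = Km_Phos, n_brk = n_brk,
                 v_CaI_max = v_CaI_max, Km_CaI = Km_CaI,
                 use_Km_CaI = isTRUE(use_Km_CaI), k_LP = k_LP, k_IP = k_IP,
                 Phos = Phos, zonation_weight_i = zonation_weight_i,
                 k_export = k_export, Glyc0 = Glyc0),
            class = "metabolism_params")
}

#' Systemic (body-compartment) parameters
#'
#' Constants for pancreatic glucagon/insulin secretion, CNS glucose sensing,
#' adrenal catecholamine synthesis, hepatic hormone clearance, and
#' whole-body glucose consumption.
#'
#' The pancreatic rate laws operate on systemic glucose expressed in
#' arbitrary units, `GB_au = GB / G_au_scale`, so that normoglycemia
#' (5000 uM) maps onto the reference value `G_ref = 2`. Secretion fluxes of
#' all body-compartment sources are expressed in sinusoidal-compartment
#' concentration units and are diluted by the body-to-hepatic volume ratio
#' `s` when applied to the body balance, mirroring the dilution of the
#' return-flow term. `catechol_scale` is a dimensionless volume bridge for
#' the adrenal synthesis rates: the absolute systemic catecholamine scale is
#' not identifiable from the printed rate constants alone, and the bridge
#' places the resulting sinusoidal stimulus in the single-digit nanomolar
#' range of the calcium oscillator (commensurate with the 2 nM synaptic
#' norepinephrine stimulus).
#'
#' @param G_ref systemic glucose reference (a.u.).
#' @param tau_glu,tau_ins pancreatic secretion time constants (s).
#' @param km_glu,km_ins half-max constants of the log-deviation Hill terms
#'   (dimensionless magnitudes).
#' @param n_glu,n_ins Hill exponents.
#' @param Km_symp CNS half-saturation (uM).
#' @param G_symp CNS activation threshold (uM).
#' @param v_Epn,v_NEpn basal adrenal synthesis rates (nM/s).
#' @param X_Epn,X_NEpn CNS stimulatory factors on catecholamine synthesis.
#' @param adrenal_amplification scalar multiplier on both synthesis rates
#'   (1 at baseline; 1.2 and 1.4 in the amplified-secretion scenarios).
#' @param catechol_scale dimensionless volume bridge on adrenal synthesis.
#' @param G_au_scale uM per a.u. conversion for the pancreatic rate laws.
#' @param k_clear_ins hepatic first-order clearance of insulin per
#'   sinusoidal compartment (1/s). Hepatic first-pass extraction of
#'   insulin is substantially larger than that of glucagon, so the two
#'   peptides carry separate clearance constants.
#' @param k_clear_glu hepatic first-order clearance of glucagon per
#'   sinusoidal compartment (1/s).
#' @param k_clear_cat hepatic first-order clearance of catecholamines per
#'   sinusoidal compartment (1/s).
#' @param u_G_basal basal body glucose consumption (uM/s in body units);
#'   `NA` = balance basal hepatic glucose export at initialization, times
#'   `u_basal_factor`.
#' @param u_basal_factor overconsumption factor on the balanced basal
#'   uptake. A value slightly above 1 lets the resting system settle just
#'   below the pancreatic glucose reference, where glucagon secretion and
#'   hepatic clearance balance at a regular (nonzero) basal glucagon level.
#' @param exercise_multiplier factor on `u_G_basal` during exercise.
#' @param v_glu_alt max CNS-driven glucagon synthesis, alternative model
#'   variant only (nM/s).
#' @param km_glu_alt half-max CNS activation of the alternative glucagon
#'   term (dimensionless).
#' @param Glu_B0,Ins_B0 initial systemic glucagon and insulin (nM).
#' @param GB0 initial systemic glucose (uM).
#' @return object of class `systemic_params`.
#' @export
systemic_params <- function(G_ref = 2,
                            tau_glu = 1.3, km_glu = 1.3, n_glu = 2,
                            tau_ins = 0.9, km_ins = 0.9, n_ins = 2,
                            Km_symp = 500, G_symp = 4500,
                            v_Epn = 0.5, v_NEpn = 1.5,
                            X_Epn = 6, X_NEpn = 14,
                            adrenal_amplification = 1,
                            catechol_scale = 0.45,
                            G_au_scale = 2500,
                            k_clear_ins = 0.005,
                            k_clear_glu = 0,
                            k_clear_cat = 0.15,
                            u_G_basal = NA_real_,
                            u_basal_factor = 0.5875,
                            exercise_multiplier = 3.5,
                            v_glu_alt = 0.1, km_glu_alt = 0.1,
                            Glu_B0 = 0.8, Ins_B0 = 0.08, GB0 = 5000) {
  stopifnot(G_ref > 0, tau_glu > 0, tau_ins > 0, Km_symp > 0, G_symp > 0,
            v_Epn >= 0, v_NEpn >= 0, adrenal_amplification >= 0,
            G_au_scale > 0, k_clear_ins >= 0, k_clear_glu >= 0,
            k_clear_cat >= 0,
            exercise_multiplier > 0, catechol_scale > 0)
  structure(list(G_ref = G_ref, tau_glu = tau_glu, km_glu = km_glu,
                 n_glu = n_glu, tau_ins = tau_ins, km_ins = km_ins,
                 n_ins = n_ins, Km_symp = Km_symp, G_symp = G_symp,
                 v_Epn = v_Epn, v_NEpn = v_NEpn, X_Epn = X_Epn,
                 X_NEpn = X_NEpn,
                 adrenal_amplification = adrenal_amplification,
                 catechol_scale = catechol_scale, G_au_scale = G_au_scale,
                 k_clear_ins = k_clear_ins, k_clear_glu = k_clear_glu,
                 k_clear_cat = k_clear_cat, u_G_basal = u_G_basal,
                 u_basal_factor = u_basal_factor,
                 exercise_multiplier = exercise_multiplier,
                 v_glu_alt = v_glu_alt, km_glu_alt = km_glu_alt,
                 Glu_B0 = Glu_B0, Ins_B0 = Ins_B0, GB0 = GB0),
            class = "systemic_params")
}

#' Sinusoidal transport parameters
#'
#' Blood flow along the 15-compartment porto-central axis. The
#' per-compartment flow rate scales with the number of layers,
#' `bf = 0.15 * N` per second, and the body-to-hepatic volume ratio is
#' `s = 5 * N`. Portal hypertension scales `bf` proportionally to the
#' portal pressure fold increase (Poiseuille scaling at fixed geometry).
#'
#' @param N number of hepatic layers (>= 2).
#' @param bf per-compartment blood flow rate (1/s); default `0.15 * N`.
#' @param pressure_fold portal pressure multiplier (>= 1).
#' @return object of class `transport_params` with fields `N`, `bf`
#'   (already pressure-scaled), `bf_normal`, `s`, `pressure_fold`.
#' @export
transport_params <- function(N = 15L, bf = 0.15 * N, pressure_fold = 1) {
  if (N < 2) stop("invalid lobule: need at least N = 2 hepatic layers",
                  call. = FALSE)
  stopifnot(bf > 0, pressure_fold >= 1)
  structure(list(N = as.integer(N), bf_normal = bf,
                 bf = hypertensive_flow(bf, pressure_fold),
                 s = 5 * as.integer(N), pressure_fold = pressure_fold),
            class = "transport_params")
}

#' Innervation pattern of the hepatic layers
#'
#' Which hepatocyte layers receive direct synaptic norepinephrine:
#' all of them (human-like extensive innervation), the first four
#' periportal layers (rodent-like minimal innervation), or none
#' (denervated, equivalent to a zero synaptic stimulus).
#'
#' @param pattern one of `"human"`, `"rodent"`, `"denervated"`, or a logical
#'   mask of length `N`.
#' @param N number of hepatic layers.
#' @param K_NEpn_stim synaptic norepinephrine stimulus amplitude (nM);
#'   forced to 0 for the denervated pattern.
#' @return object of class `innervation_pattern` with fields
#'   `innervated_mask` and `K_NEpn_stim`.
#' @export
innervation_pattern <- function(pattern = c("human", "rodent", "denervated"),
                                N = 15L, K_NEpn_stim = 2) {
  if (is.logical(pattern)) {
    if (length(pattern) != N)
      stop("innervation mask length must equal N", call. = FALSE)
    mask <- pattern
    name <- "custom"
  } else {
    name <- match.arg(pattern)
    mask <- switch(name,
                   human = rep(TRUE, N),
                   rodent = seq_len(N) <= 4,
                   denervated = rep(FALSE, N))
    if (name == "denervated") K_NEpn_stim <- 0
  }
  stopifnot(K_NEpn_stim >= 0)
  structure(list(name = name, innervated_mask = mask,
                 K_NEpn_stim = K_NEpn_stim),
            class = "innervation_pattern")
}

#' Assemble a full scenario configuration
#'
#' Bundles all parameter groups, the innervation pattern, the gap-junction
#' coupling strength, the exercise protocol, and the model variant into a
#' single configuration object consumed by [run_scenario()].
#'
#' For `variant = "alternative"` the zonation gradients of `k_r` and
#' `k_IP3` default to the steeper 1-to-2 profiles and adrenal synthesis is
#' decoupled from CNS feedback while glucagon gains an additive CNS term.
#'
#' @param innervation an [innervation_pattern()] or pattern name.
#' @param G_ij gap-junction IP3 mass-transfer coefficient (1/s), uniform
#'   along the chain; 0 / 2.5 / 5 = uncoupled / weak / strong in the main
#'   variant, 0 / 1 / 2 in the alternative variant.
#' @param variant `"main"` or `"alternative"`.
#' @param N number of hepatic layers.
#' @param transport,systemic,calcium,metabolism parameter groups; defaults
#'   are built for `N` and `variant`.
#' @param exercise logical; apply the elevated glucose uptake window.
#' @param exercise_start start of the exercise window (s).
#' @param exercise_duration duration of the exercise window (s).
#' @param t_end end of the simulation (s).
#' @param stimulus_enabled logical; when `FALSE` the hepatocyte
#'   calcium-mobilizing stimulus is forced to zero (control used to isolate
#'   the calcium contribution to glycogenolysis).
#' @param label optional scenario label.
#' @return object of class `lobule_scenario`.
#' @export
scenario_config <- function(innervation = "human", G_ij = 5,
                            variant = c("main", "alternative"),
                            N = 15L,
                            transport = transport_params(N),
                            systemic = systemic_params(),
                            calcium = NULL, metabolism = metabolism_params(N),
                            exercise = TRUE, exercise_start = 500,
                            exercise_duration = 3600, t_end = 4100,
                            stimulus_enabled = TRUE, label = NULL) {
  variant <- match.arg(variant)
  if (is.null(calcium)) {
    calcium <- if (variant == "alternative")
      calcium_params(N, k_r_i = build_zonation_gradients(N, 1, 2),
                     k_IP3_i = build_zonation_gradients(N, 1, 2))
    else calcium_params(N)
  }
  if (!inherits(innervation, "innervation_pattern"))
    innervation <- innervation_pattern(innervation, N = N)
  stopifnot(G_ij >= 0, t_end > 0)
  if (exercise &&
      (exercise_start < 0 || exercise_start + exercise_duration > t_end))
    stop("exercise window must lie within [0, t_end]", call. = FALSE)
  cfg <- structure(list(variant = variant, innervation = innervation,
                        G_ij = G_ij, transport = transport,
                        systemic = systemic, calcium = calcium,
                        metabolism = metabolism, exercise = exercise,
                        exercise_start = exercise_start,
                        exercise_duration = exercise_duration,
                        t_end = t_end,
                        stimulus_enabled = isTRUE(stimulus_enabled),
                        label = label %||% innervation$name),
                   class = "lobule_scenario")
  stopifnot(cfg$transport$N == cfg$calcium$N,
            cfg$transport$N == cfg$metabolism$N,
            length(cfg$innervation$innervated_mask) == cfg$transport$N)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Named scenario presets
#'
#' Shorthand builders for the headline simulation scenarios: innervation
#' pattern (human / rodent / denervated), optional adrenal amplification
#' suffix (`"_1.2x"`, `"_1.4x"`), portal hypertension (`"_hypertensive"`,
#' blood flow scaled 3-fold), and the no-exercise control
#' (`"no_exercise"`, human innervation with a flat uptake profile).
#'
#' @param name preset name, e.g. `"rodent"`, `"denervated_1.4x"`,
#'   `"human_hypertensive"`, `"no_exercise"`.
#' @param G_ij gap-junction coupling strength (1/s).
#' @param variant model variant passed to [scenario_config()].
#' @param exercise override the preset's exercise flag (default: exercise
#'   on for all presets except `"no_exercise"`).
#' @param ... further arguments forwarded to [scenario_config()].
#' @return a `lobule_scenario`.
#' @examples
#' preset("rodent", G_ij = 5)$innervation$innervated_mask
#' @export
preset <- function(name, G_ij = 5, variant = "main", exercise = NULL, ...) {
  stopifnot(is.character(name), length(name) == 1L)
  base <- name
  amp <- 1
  hyper <- FALSE
  exercise_on <- TRUE
  if (grepl("_1\\.2x$", base)) { amp <- 1.2; base <- sub("_1\\.2x$", "", base) }
  if (grepl("_1\\.4x$", base)) { amp <- 1.4; base <- sub("_1\\.4x$", "", base) }
  if (grepl("_hypertensive$", base)) {
    hyper <- TRUE
    base <- sub("_hypertensive$", "", base)
  }
  if (base == "no_exercise") { base <- "human"; exercise_on <- FALSE }
  if (!base %in% c("human", "rodent", "denervated"))
    stop("unknown preset: ", name, call. = FALSE)
  scenario_config(innervation = base, G_ij = G_ij, variant = variant,
                  transport = transport_params(pressure_fold =
                                                 if (hyper) 3 else 1),
                  systemic = systemic_params(adrenal_amplification = amp),
                  exercise = exercise %||% exercise_on, label = name, ...)
}

#' @export
print.lobule_scenario <- function(x, ...) {
  inn <- x$innervation
  cat("Lobule scenario '", x$label, "' (", x$variant, " variant)\n", sep = "")
  cat(sprintf("  N = %d layers; G_ij = %g /s; bf = %g /s (pressure x%g); s = %d\n",
              x$transport$N, x$G_ij, x$transport$bf,
              x$transport$pressure_fold, x$transport$s))
  cat(sprintf("  innervated layers: %s; K_NEpn_stim = %g nM\n",
              if (any(inn$innervated_mask))
                paste(range(which(inn$innervated_mask)), collapse = "-")
              else "none", inn$K_NEpn_stim))
  cat(sprintf("  adrenal amplification x%g; exercise %s; t_end = %g s\n",
              x$systemic$adrenal_amplification,
              if (x$exercise) sprintf("[%g, %g] s (x%g uptake)",
                                      x$exercise_start,
                                      x$exercise_start + x$exercise_duration,
                                      x$systemic$exercise_multiplier)
              else "off", x$t_end))
  invisible(x)
}

## ---- config serialization -------------------------------------------------

#' Write / read a scenario configuration as YAML
#'
#' Every numeric field of the configuration round-trips through the YAML
#' representation exactly (numbers are serialized at full double precision).
#'
#' @param cfg a `lobule_scenario`.
#' @param path file path.
#' @return `scenario_from_yaml()` returns a `lobule_scenario`;
#'   `scenario_to_yaml()` returns `path` invisibly.
#' @export
scenario_to_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "lobule_scenario"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  yaml::write_yaml(strip(cfg), path,
                   precision = 17L, handlers = list(
                     logical = yaml::verbatim_logical))
  invisible(path)
}

#' @rdname scenario_to_yaml
#' @export
scenario_from_yaml <- function(path) {
  raw <- yaml::yaml.load_file(path)
  num <- function(x) if (is.list(x)) unlist(x) else x
  N <- as.integer(raw$transport$N)
  cal <- raw$calcium
  met <- raw$metabolism
  sys <- raw$systemic
  scenario_config(
    innervation = innervation_pattern(num(raw$innervation$innervated_mask),
                                      N = N,
                                      K_NEpn_stim = raw$innervation$K_NEpn_stim),
    G_ij = raw$G_ij, variant = raw$variant, N = N,
    transport = transport_params(N, bf = raw$transport$bf_normal,
                                 pressure_fold = raw$transport$pressure_fold),
    systemic = do.call(systemic_params, lapply(sys, num)),
    calcium = do.call(calcium_params,
                      c(list(N = N),
                        lapply(cal[setdiff(names(cal), "N")], num))),
    metabolism = do.call(metabolism_params,
                         c(list(N = N),
                           lapply(met[setdiff(names(met), "N")], num))),
    exercise = isTRUE(raw$exercise),
    exercise_start = raw$exercise_start,
    exercise_duration = raw$exercise_duration,
    t_end = raw$t_end,
    stimulus_enabled = isTRUE(raw$stimulus_enabled),
    label = raw$label)
}
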