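## Global state assembly and integration of the coupled lobule/body system.
##
## State layout (species-major, compartment-minor), N = number of layers:
##   r[1..N], IP3[1..N], CaI[1..N], g[1..N],          hepatocyte signaling
##   Glyc[1..N], Gcell[1..N],                          hepatocyte metabolism
##   Glc[1..N], Ins[1..N], Glu[1..N], Epn[1..N], NEpn[1..N],   sinusoid blood
##   GB, Ins_B, Glu_B, Epn_B, NEpn_B                   body compartment
## for a total of 11 N + 5 states (170 for N = 15).

.sig_species <- c("r", "IP3", "CaI", "g", "Glyc", "Gcell")
.blood_species <- c("Glc", "Ins", "Glu", "Epn", "NEpn")
.body_species <- c("GB", "Ins_B", "Glu_B", "Epn_B", "NEpn_B")

state_names <- function(N) {
  c(as.vector(vapply(c(.sig_species, .blood_species),
                     function(sp) paste0(sp, ".", seq_len(N)),
                     character(N))),
    .body_species)
}

state_index <- function(species, N) {
  all_sp <- c(.sig_species, .blood_species)
  k <- match(species, all_sp)
  if (is.na(k)) stop("unknown species: ", species, call. = FALSE)
  (k - 1L) * N + seq_len(N)
}

## Flattened parameter vector shared by the R and compiled right-hand sides.
## Scalar block first, then the per-cell vectors k_r, k_IP3, w, mask.
pack_params <- function(cfg, exercise_on = FALSE) {
  ca <- cfg$calcium; met <- cfg$metabolism; sys <- cfg$systemic
  tr <- cfg$transport
  if (tr$N > .max_cells)
    stop("at most ", .max_cells, " hepatic layers supported", call. = FALSE)
  amp <- sys$adrenal_amplification * sys$catechol_scale
  u <- sys$u_G_basal
  if (is.na(u)) u <- basal_uptake_rate(cfg)
  K_gpk <- if (met$use_Km_CaI) met$Km_CaI else met$K_CaI_GPK
  c(N = tr$N,
    A = ca$A, B = ca$B, D = ca$D, E = ca$E, F = ca$F,
    k1 = ca$k1, k2 = ca$k2, k3 = ca$k3, k_cat = ca$k_cat, k_d = ca$k_d,
    k_Hr = ca$k_Hr, L = ca$L, CaT = ca$CaT0,
    Gij = cfg$G_ij,
    CaI_GPK = met$CaI_GPK, K_gpk = K_gpk, v0 = met$v0,
    v_brk = met$v_brk, Km_Glyc = met$Km_Glyc, Km_Phos = met$Km_Phos,
    n_brk = met$n_brk, v_CaI_max = met$v_CaI_max,
    k_LP = met$k_LP, k_IP = met$k_IP, Phos = met$Phos,
    k_export = met$k_export,
    bf = tr$bf, s = tr$s,
    k_clear_ins = sys$k_clear_ins, k_clear_glu = sys$k_clear_glu,
    k_clear_cat = sys$k_clear_cat,
    G_ref = sys$G_ref, tau_glu = sys$tau_glu, km_glu = sys$km_glu,
    n_glu = sys$n_glu, tau_ins = sys$tau_ins, km_ins = sys$km_ins,
    n_ins = sys$n_ins,
    Km_symp = sys$Km_symp, G_symp = sys$G_symp,
    G_au_scale = sys$G_au_scale,
    v_Epn_eff = amp * sys$v_Epn, v_NEpn_eff = amp * sys$v_NEpn,
    X_Epn = sys$X_Epn, X_NEpn = sys$X_NEpn,
    K_stim = cfg$innervation$K_NEpn_stim,
    u_G = u * if (exercise_on) sys$exercise_multiplier else 1,
    variant_alt = as.numeric(cfg$variant == "alternative"),
    v_glu_alt = sys$v_glu_alt, km_glu_alt = sys$km_glu_alt,
    stimulus_enabled = as.numeric(cfg$stimulus_enabled),
    pad_cells(ca$k_r_i), pad_cells(ca$k_IP3_i),
    pad_cells(met$zonation_weight_i),
    pad_cells(as.numeric(cfg$innervation$innervated_mask)))
}
.n_scalar_params <- 52L
## per-cell parameter blocks are padded to a fixed width so the compiled
## side can use constant offsets (mirrors MAXCELLS in src/)
.max_cells <- 64L
pad_cells <- function(v) c(v, numeric(.max_cells - length(v)))

#' Initial global state of a scenario
#'
#' Hepatocyte signaling states start from the nominal initial conditions
#' (CaI 0.2 uM, CaT 500.2 uM, g 0.25, IP3 0.1 nM, r 0.5); glycogen is
#' uniform; blood and body glucose start at normoglycemia. Catecholamines
#' are initialized on their basal porto-central steady-state profile (so
#' the control run starts on its attractor), hormones on the quasi-steady
#' through-liver profile of their initial body values, and intracellular
#' free glucose at export-flux equilibrium with the local sinusoid.
#'
#' @param cfg a `lobule_scenario`.
#' @return named numeric state vector of length `11 N + 5`.
#' @export
initial_state <- function(cfg) {
  N <- cfg$transport$N; sys <- cfg$systemic; met <- cfg$metabolism
  tr <- cfg$transport
  amp <- sys$adrenal_amplification * sys$catechol_scale
  epn <- basal_secretion_profile(amp * sys$v_Epn, tr$bf, tr$s,
                                 sys$k_clear_cat, N)
  nepn <- basal_secretion_profile(amp * sys$v_NEpn, tr$bf, tr$s,
                                  sys$k_clear_cat, N)
  ins_i <- sys$Ins_B0 * (tr$bf / (tr$bf + sys$k_clear_ins))^seq_len(N)
  glu_i <- sys$Glu_B0 * (tr$bf / (tr$bf + sys$k_clear_glu))^seq_len(N)
  glc_i <- rep(sys$GB0, N)
  flux0 <- glycogenolysis_rate(met$Glyc0, met$Phos, glu_i, ins_i, 0.2,
                               met$zonation_weight_i, met)
  y <- c(rep(0.5, N), rep(1e-4, N), rep(0.2, N), rep(0.25, N),
         rep(met$Glyc0, N), glc_i + flux0 / met$k_export,
         glc_i, ins_i, glu_i, epn$M, nepn$M,
         sys$GB0, sys$Ins_B0, sys$Glu_B0, epn$M0, nepn$M0)
  names(y) <- state_names(N)
  y
}

#' Basal body glucose consumption balancing hepatic export
#'
#' The default basal uptake is the rate at which peripheral consumption
#' balances total basal hepatic glycogenolysis, keeping the no-exercise
#' control near its initial normoglycemic value. Because resting
#' sinusoidal catecholamines already elicit calcium activity in the most
#' excitable cells, the static (spike-free) flux underestimates the true
#' basal export; the rate is therefore refined by a short burn-in
#' simulation of the resting system, and the realized mean flux is scaled
#' by `u_basal_factor`.
#'
#' @param cfg a `lobule_scenario`.
#' @param burn_in burn-in horizon (s); the flux is averaged over its
#'   second half.
#' @return uptake rate (uM/s, body units).
#' @export
basal_uptake_rate <- function(cfg, burn_in = 800) {
  N <- cfg$transport$N; sys <- cfg$systemic; met <- cfg$metabolism
  bf <- cfg$transport$bf
  ins_i <- sys$Ins_B0 * (bf / (bf + sys$k_clear_ins))^seq_len(N)
  glu_i <- sys$Glu_B0 * (bf / (bf + sys$k_clear_glu))^seq_len(N)
  flux0 <- glycogenolysis_rate(met$Glyc0, met$Phos, glu_i, ins_i, 0.2,
                               met$zonation_weight_i, met)
  u_static <- sum(flux0) / cfg$transport$s
  ## resting burn-in with the static estimate, then refine from the
  ## realized glycogenolysis (captures basal calcium activity)
  cfg0 <- cfg
  cfg0$exercise <- FALSE
  cfg0$t_end <- burn_in
  cfg0$systemic$u_G_basal <- u_static
  sim <- run_scenario(cfg0, dt = 2)
  sel <- sim$time >= burn_in / 2
  u_real <- mean(rowSums(glycogenolysis_fluxes(sim)[sel, , drop = FALSE])) /
    cfg$transport$s
  sys$u_basal_factor * u_real
}

## Reference right-hand side in pure R, composed from the module-level
## rate functions. Used as the oracle for the compiled derivatives and as
## a fallback engine.
lobule_rhs_R <- function(t, y, p) {
  N <- as.integer(p[["N"]])
  idx <- function(k) (k - 1L) * N + seq_len(N)
  r <- pmin(pmax(y[idx(1)], 0), 1)
  IP3 <- pmax(y[idx(2)], 0)
  CaI <- pmax(y[idx(3)], 0)
  g <- pmin(pmax(y[idx(4)], 0), 1)
  Glyc <- pmax(y[idx(5)], 0)
  Gcell <- y[idx(6)]
  Glc <- y[idx(7)]; Ins <- pmax(y[idx(8)], 0); Glu <- pmax(y[idx(9)], 0)
  Epn <- pmax(y[idx(10)], 0); NEpn <- pmax(y[idx(11)], 0)
  body <- y[11L * N + 1:5]
  GB <- max(body[1], 1e-9)

  cns <- cns_activation(GB, p[["G_symp"]], p[["Km_symp"]])
  mask <- p[.n_scalar_params + 3L * .max_cells + seq_len(N)]
  H <- (Epn + NEpn + p[["K_stim"]] * cns * mask) * p[["stimulus_enabled"]]
  k_r <- p[.n_scalar_params + seq_len(N)]
  k_ip3 <- p[.n_scalar_params + .max_cells + seq_len(N)]
  w <- p[.n_scalar_params + 2L * .max_cells + seq_len(N)]

  dr <- k_r * (1 - r) - p[["k_d"]] * r - p[["k_Hr"]] * H * r
  up <- c(IP3[1], IP3[-N]); dn <- c(IP3[-1], IP3[N])
  couple <- p[["Gij"]] * ((up - IP3) + (dn - IP3))
  dIP3 <- k_ip3 * H * r / (p[["k_cat"]] + r) * CaI / (CaI + p[["k3"]]) -
    p[["D"]] * IP3 + couple
  dCaI <- (1 - g) * (p[["A"]] * IP3^4 / (p[["k1"]] + IP3)^4 + p[["L"]]) *
    (p[["CaT"]] - CaI) - p[["B"]] * CaI^2 / (p[["k2"]]^2 + CaI^2)
  dg <- p[["E"]] * CaI^4 * (1 - g) - p[["F"]]
  dg[(y[idx(4)] <= 0 & dg < 0) | (y[idx(4)] >= 1 & dg > 0)] <- 0

  act <- ifelse(CaI > p[["CaI_GPK"]], CaI / (p[["K_gpk"]] + CaI), p[["v0"]])
  kp <- (Glu * 1000 + p[["k_LP"]]) / (Ins * 1000 + p[["k_IP"]])
  gn <- Glyc^p[["n_brk"]]
  flux <- w * p[["v_brk"]] * kp * gn / (gn + p[["Km_Glyc"]]^p[["n_brk"]]) *
    p[["Phos"]] / (p[["Km_Phos"]] + p[["Phos"]]) *
    (1 + p[["v_CaI_max"]] * act)
  export <- p[["k_export"]] * (Gcell - Glc)
  dGlyc <- -flux / 1000
  dGcell <- flux - export

  bf <- p[["bf"]]; s <- p[["s"]]
  adv <- function(M, M0) bf * (c(M0, M[-N]) - M)
  dGlc <- adv(Glc, GB) + export
  dIns <- adv(Ins, body[2]) - p[["k_clear_ins"]] * Ins
  dGlu <- adv(Glu, body[3]) - p[["k_clear_glu"]] * Glu
  dEpn <- adv(Epn, body[4]) - p[["k_clear_cat"]] * Epn
  dNEpn <- adv(NEpn, body[5]) - p[["k_clear_cat"]] * NEpn

  GB_au <- GB / p[["G_au_scale"]]
  x <- log(p[["G_ref"]] / GB_au)
  sec_glu <- 0; sec_ins <- 0
  if (GB_au < p[["G_ref"]]) {
    sec_glu <- (1 / p[["tau_glu"]]) * x^p[["n_glu"]] /
      (p[["km_glu"]]^p[["n_glu"]] + x^p[["n_glu"]])
    if (p[["variant_alt"]] > 0)
      sec_glu <- sec_glu + p[["v_glu_alt"]] * cns / (p[["km_glu_alt"]] + cns)
  } else if (GB_au > p[["G_ref"]]) {
    sec_ins <- (1 / p[["tau_ins"]]) * (-x)^p[["n_ins"]] /
      (p[["km_ins"]]^p[["n_ins"]] + (-x)^p[["n_ins"]])
  }
  if (p[["variant_alt"]] > 0) {
    sec_epn <- p[["v_Epn_eff"]]
    sec_nepn <- p[["v_NEpn_eff"]]
  } else {
    sec_epn <- p[["v_Epn_eff"]] * (1 + p[["X_Epn"]] * cns)
    sec_nepn <- p[["v_NEpn_eff"]] * (1 + p[["X_NEpn"]] * cns)
  }
  dbody <- c(bf * (Glc[N] - body[1]) / s - p[["u_G"]],
             bf * (Ins[N] - body[2]) / s + sec_ins / s,
             bf * (Glu[N] - body[3]) / s + sec_glu / s,
             bf * (Epn[N] - body[4]) / s + sec_epn / s,
             bf * (NEpn[N] - body[5]) / s + sec_nepn / s)

  list(c(dr, dIP3, dCaI, dg, dGlyc, dGcell,
         dGlc, dIns, dGlu, dEpn, dNEpn, dbody))
}

#' Run a scenario simulation
#'
#' Integrates the full coupled system over `[0, t_end]` with a stiff
#' implicit solver (lsoda, rtol 1e-6, atol 1e-9, dense output at 1 s by
#' default). The exercise step is handled exactly: integration is
#' restarted at the window boundaries with the uptake rate switched, so
#' the discontinuity falls on a segment edge. Identical configurations
#' give bit-identical results at fixed integrator settings; the model
#' contains no randomness.
#'
#' @param cfg a `lobule_scenario`, e.g. from [preset()].
#' @param dt output resolution (s).
#' @param engine `"compiled"` (C right-hand side) or `"R"` (reference
#'   implementation); both produce the same derivatives to machine
#'   precision.
#' @param rtol,atol integrator tolerances.
#' @return object of class `lobule_sim`: list with `time`, the state
#'   trajectory matrix `states` (one named column per state), the
#'   scenario `config`, the basal uptake rate `u_G_basal`, a config
#'   `hash`, and integrator `diagnostics`.
#' @export
run_scenario <- function(cfg, dt = 1, engine = c("compiled", "R"),
                         rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(cfg, "lobule_scenario"))
  engine <- match.arg(engine)
  N <- cfg$transport$N
  u_basal <- cfg$systemic$u_G_basal
  if (is.na(u_basal)) u_basal <- basal_uptake_rate(cfg)
  cfg_run <- cfg
  cfg_run$systemic$u_G_basal <- u_basal

  breaks <- c(0, cfg$t_end)
  if (cfg$exercise) {
    ex0 <- cfg$exercise_start
    ex1 <- min(cfg$exercise_start + cfg$exercise_duration, cfg$t_end)
    breaks <- sort(unique(c(0, ex0, ex1, cfg$t_end)))
  }
  y <- initial_state(cfg_run)
  times_all <- NULL
  states_all <- NULL
  istates <- integer(0)
  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    if (t1 <= t0) next
    on_ex <- cfg$exercise && t0 >= cfg$exercise_start &&
      t0 < cfg$exercise_start + cfg$exercise_duration
    pv <- pack_params(cfg_run, exercise_on = on_ex)
    tt <- seq(t0, t1, by = dt)
    if (tt[length(tt)] < t1) tt <- c(tt, t1)
    out <- if (engine == "compiled")
      deSolve::ode(y, tt, func = "hepacal_derivs", parms = unname(pv),
                   dllname = "hepacal", initfunc = "hepacal_initmod",
                   method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 50000)
    else
      deSolve::ode(y, tt, lobule_rhs_R, pv, method = "lsoda",
                   rtol = rtol, atol = atol, maxsteps = 50000)
    ist <- attr(out, "istate")[1]
    istates <- c(istates, ist)
    if (ist < 0)
      stop(sprintf("integration failed on segment [%g, %g] (istate %d)",
                   t0, t1, ist), call. = FALSE)
    y <- out[nrow(out), -1]
    keep <- if (k == 1L) seq_len(nrow(out)) else -1L
    times_all <- c(times_all, out[keep, 1])
    states_all <- rbind(states_all, out[keep, -1, drop = FALSE])
  }
  colnames(states_all) <- state_names(N)
  worst <- min(states_all[, c(state_index("CaI", N), state_index("Glc", N),
                              11 * N + 1)], 0)
  if (worst < -1e-6 * max(atol / 1e-9, 1))
    warning("negative concentration excursion: ", signif(worst, 3))
  structure(list(time = times_all, states = states_all, config = cfg,
                 u_G_basal = u_basal,
                 hash = config_hash(cfg_run),
                 diagnostics = list(istate = istates, engine = engine,
                                    rtol = rtol, atol = atol,
                                    min_state = worst)),
            class = "lobule_sim")
}

config_hash <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  txt <- paste(deparse(strip(cfg), control = "all"), collapse = "")
  ## small stable polynomial hash; avoids external digest dependencies
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run several scenarios on a common time grid
#'
#' @param cfgs list of `lobule_scenario` objects sharing `N` and `t_end`.
#' @param ... passed to [run_scenario()].
#' @return named list of `lobule_sim` results.
#' @export
run_comparison <- function(cfgs, ...) {
  stopifnot(length(cfgs) >= 1)
  Ns <- vapply(cfgs, function(cf) cf$transport$N, integer(1))
  te <- vapply(cfgs, function(cf) cf$t_end, numeric(1))
  if (length(unique(Ns)) != 1L || length(unique(te)) != 1L)
    stop("incompatible configs: N and t_end must match", call. = FALSE)
  nm <- vapply(cfgs, function(cf) cf$label, character(1))
  out <- lapply(cfgs, run_scenario, ...)
  names(out) <- make.unique(nm)
  out
}

## ---- accessors and methods ------------------------------------------------

#' Extract a species trajectory matrix
#'
#' @param sim a `lobule_sim`.
#' @param species one of `"r"`, `"IP3"`, `"CaI"`, `"g"`, `"Glyc"`,
#'   `"Gcell"`, `"Glc"`, `"Ins"`, `"Glu"`, `"Epn"`, `"NEpn"` (per
#'   compartment), or a body state `"GB"`, `"Ins_B"`, `"Glu_B"`,
#'   `"Epn_B"`, `"NEpn_B"`.
#' @return numeric matrix (time x compartments) or vector for body states.
#' @export
get_species <- function(sim, species) {
  stopifnot(inherits(sim, "lobule_sim"))
  N <- sim$config$transport$N
  if (species %in% .body_species) return(sim$states[, species])
  sim$states[, state_index(species, N), drop = FALSE]
}

#' Per-layer glycogenolysis flux time series
#'
#' Recomputed algebraically from the state trajectory via the metabolic
#' rate law (uM/s of glucosyl units per hepatocyte).
#'
#' @param sim a `lobule_sim`.
#' @return matrix (time x layers).
#' @export
glycogenolysis_fluxes <- function(sim) {
  cfg <- sim$config; met <- cfg$metabolism
  CaI <- get_species(sim, "CaI")
  Glyc <- get_species(sim, "Glyc")
  Glu <- get_species(sim, "Glu")
  Ins <- get_species(sim, "Ins")
  out <- matrix(0, nrow(CaI), ncol(CaI))
  for (i in seq_len(ncol(CaI)))
    out[, i] <- glycogenolysis_rate(Glyc[, i], met$Phos, pmax(Glu[, i], 0),
                                    pmax(Ins[, i], 0), pmax(CaI[, i], 0),
                                    met$zonation_weight_i[i], met)
  out
}

#' Per-layer hepatocyte-to-sinusoid glucose export flux time series
#'
#' @param sim a `lobule_sim`.
#' @return matrix (time x layers), uM/s.
#' @export
export_fluxes <- function(sim) {
  k <- sim$config$metabolism$k_export
  k * (get_species(sim, "Gcell") - get_species(sim, "Glc"))
}

#' @export
print.lobule_sim <- function(x, ...) {
  cfg <- x$config
  cat("Lobule simulation '", cfg$label, "' (", cfg$variant,
      " variant, config ", x$hash, ")\n", sep = "")
  cat(sprintf("  %d layers, t in [0, %g] s, %d time points, engine %s\n",
              cfg$transport$N, max(x$time), length(x$time),
              x$diagnostics$engine))
  cat(sprintf("  basal uptake %.4g uM/s; final systemic glucose %.0f uM\n",
              x$u_G_basal, x$states[nrow(x$states), "GB"]))
  invisible(x)
}

#' @export
summary.lobule_sim <- function(object, ...) {
  sim <- object
  cfg <- sim$config
  tN <- length(sim$time)
  win <- c(if (cfg$exercise) cfg$exercise_start else 0, max(sim$time))
  go <- glucose_outputs(sim, win)
  trains <- lapply(seq_len(cfg$transport$N), function(i)
    detect_spikes(data.frame(time = sim$time,
                             CaI = get_species(sim, "CaI")[, i])))
  wm <- tryCatch(wave_metrics(trains), error = function(e) NULL)
  out <- list(label = cfg$label, hash = sim$hash,
              t_end = max(sim$time),
              GB_final = unname(sim$states[tN, "GB"]),
              cns_final = cns_activation(sim$states[tN, "GB"],
                                         cfg$systemic$G_symp,
                                         cfg$systemic$Km_symp),
              catechol_final =
                unname(sim$states[tN, "Epn_B"] + sim$states[tN, "NEpn_B"]),
              glucagon_final = unname(sim$states[tN, "Glu_B"]),
              total_glucose = go$total, per_layer_glucose = go$per_layer,
              spikes_per_cell = vapply(trains, function(tr)
                length(tr$times), integer(1)),
              wave = wm)
  class(out) <- "summary.lobule_sim"
  out
}

#' @export
print.summary.lobule_sim <- function(x, ...) {
  cat("Scenario '", x$label, "' (config ", x$hash, ")\n", sep = "")
  cat(sprintf("  systemic glucose at t = %g s: %.0f uM (CNS activation %.3f)\n",
              x$t_end, x$GB_final, x$cns_final))
  cat(sprintf("  systemic catecholamines %.3g nM, glucagon %.3g nM\n",
              x$catechol_final, x$glucagon_final))
  cat(sprintf("  total hepatic glucose output %.4g umol per unit volume\n",
              x$total_glucose))
  if (!is.null(x$wave))
    cat(sprintf("  calcium wave: direction %s, lag %.1f s, velocity %.2f cells/s\n",
                x$wave$direction, x$wave$lag_time, x$wave$velocity))
  invisible(x)
}

#' @export
plot.lobule_sim <- function(x, species = "CaI", cells = NULL, ...) {
  N <- x$config$transport$N
  if (is.null(cells)) cells <- unique(round(seq(1, N, length.out = 5)))
  if (species %in% .body_species) {
    graphics::plot(x$time, get_species(x, species), type = "l",
                   xlab = "time (s)", ylab = species, ...)
    return(invisible(x))
  }
  m <- get_species(x, species)[, cells, drop = FALSE]
  graphics::matplot(x$time, m, type = "l", lty = 1,
                    col = grDevices::hcl.colors(length(cells), "Zissou 1"),
                    xlab = "time (s)", ylab = species, ...)
  graphics::legend("topright", legend = paste0("cell ", cells), lty = 1,
                   col = grDevices::hcl.colors(length(cells), "Zissou 1"),
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Tidy long-format trajectory
#'
#' @param x a `lobule_sim`.
#' @param row.names,optional,... ignored (method signature).
#' @return data.frame with columns `time`, `entity`, `variable`, `value`.
#' @export
as.data.frame.lobule_sim <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  nm <- colnames(x$states)
  sp <- sub("\\..*$", "", nm)
  comp <- ifelse(grepl("\\.", nm) & !nm %in% .body_species,
                 sub("^.*\\.", "", nm), "body")
  data.frame(time = rep(x$time, times = length(nm)),
             entity = rep(comp, each = length(x$time)),
             variable = rep(sp, each = length(x$time)),
             value = as.vector(x$states))
}
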