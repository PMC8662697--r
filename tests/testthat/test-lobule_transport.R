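test_that("advection matches the compartment mass balance", {
  # uniform concentrations are an equilibrium
  eq <- advection_rhs(rep(3, 15), 3, 2.25, 75)
  expect_equal(eq$dM, rep(0, 15))
  expect_equal(eq$dM0, 0)
  # a body-side pulse enters only the first compartment
  pulse <- advection_rhs(rep(0, 15), 1, 2.25, 75)
  expect_equal(pulse$dM[1], 2.25)
  expect_equal(pulse$dM[-1], rep(0, 14))
  # telescoping conservation on random states
  set.seed(11)
  for (k in 1:20) {
    M <- runif(15, 0, 10); M0 <- runif(1, 0, 10)
    d <- advection_rhs(M, M0, 2.25, 75)
    expect_equal(sum(d$dM) + 75 * d$dM0, 0, tolerance = 1e-12)
  }
  expect_error(advection_rhs(1, 0, 2.25, 75), "invalid lobule")
})

test_that("stimulus assembly respects the innervation pattern", {
  epn <- seq(1, 0.5, length.out = 15)
  nepn <- seq(2, 1, length.out = 15)
  den <- innervation_pattern("denervated")
  expect_equal(assemble_stimulus(epn, nepn, den, CNSAct = 0.8), epn + nepn)
  hum <- innervation_pattern("human")
  expect_equal(assemble_stimulus(epn, nepn, hum, CNSAct = 1),
               epn + nepn + 2)
  rod <- innervation_pattern("rodent")
  h <- assemble_stimulus(epn, nepn, rod, CNSAct = 1)
  expect_equal(h[1:4], epn[1:4] + nepn[1:4] + 2)
  expect_equal(h[5:15], epn[5:15] + nepn[5:15])
  expect_error(assemble_stimulus(epn[1:10], nepn[1:10], hum, 0), "mismatch")
})

test_that("hepatic clearance gives first-order sinks and gradients", {
  expect_equal(hepatic_clearance_rhs(c(1, 2, 3), 0), c(0, 0, 0))
  expect_equal(hepatic_clearance_rhs(4, 0.15), -0.6)
  # single compartment without flow decays exponentially: verify the
  # closed form against a numeric integration of the sink alone
  k <- 0.15
  sol <- deSolve::ode(c(M = 2), seq(0, 30, 1),
                      function(t, y, p) list(hepatic_clearance_rhs(y, k)),
                      NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(sol[, "M"], 2 * exp(-k * sol[, "time"]), tolerance = 1e-8)
  # steady state under constant inflow: M* = bf c / (bf + k) per step,
  # giving a geometric porto-central gradient
  bf <- 2.25; cin <- 1
  M <- numeric(15)
  up <- cin
  for (i in 1:15) {
    M[i] <- bf * up / (bf + k)
    up <- M[i]
  }
  expect_true(all(diff(M) < 0))
  expect_equal(M[15] / M[1], (bf / (bf + k))^14)
})

test_that("the engine conserves advected mass with sinks off", {
  # clearance and all sources disabled; integrate the full right-hand
  # side from a randomly perturbed blood state and check every species
  cfg <- scenario_config(
    "denervated", 0, exercise = FALSE, t_end = 200,
    stimulus_enabled = FALSE,
    systemic = systemic_params(k_clear_ins = 0, k_clear_glu = 0,
                               k_clear_cat = 0, v_Epn = 0, v_NEpn = 0,
                               tau_glu = 1e12, tau_ins = 1e12,
                               v_glu_alt = 0, u_G_basal = 0),
    metabolism = metabolism_params(v_brk = 0))
  pv <- hepacal:::pack_params(cfg)
  set.seed(3)
  y0 <- initial_state(cfg)
  N <- 15
  for (sp in c("Glc", "Ins", "Glu", "Epn", "NEpn"))
    y0[hepacal:::state_index(sp, N)] <- runif(N, 0.5, 5) *
      y0[hepacal:::state_index(sp, N)] + runif(N, 0, 0.1)
  out <- deSolve::ode(y0, seq(0, 200, 10), hepacal:::lobule_rhs_R, pv,
                      rtol = 1e-10, atol = 1e-12)
  s <- cfg$transport$s
  for (sp in c("Ins", "Glu", "Epn", "NEpn")) {
    comp <- out[, 1 + hepacal:::state_index(sp, N), drop = FALSE]
    body <- out[, 1 + 11 * N + match(sp, c("GB", "Ins", "Glu", "Epn",
                                           "NEpn"))]
    tot <- rowSums(comp) + s * body
    expect_lt(max(abs(tot - tot[1])) / max(tot[1], 1e-12), 1e-8)
  }
  # glucose additionally exchanges with the (inert) hepatocyte pool
  tot_g <- rowSums(out[, 1 + hepacal:::state_index("Glc", N)]) +
    s * out[, 1 + 11 * N + 1] +
    rowSums(out[, 1 + hepacal:::state_index("Gcell", N)])
  expect_lt(max(abs(tot_g - tot_g[1])) / tot_g[1], 1e-8)
})

test_that("raising blood flow flattens the catecholamine gradient", {
  norm <- cached_run("rod5", preset("rodent", 5))
  hyp <- cached_run("rodh5", preset("rodent_hypertensive", 5))
  grad <- function(sim) {
    epn <- state_at(sim, "Epn"); nepn <- state_at(sim, "NEpn")
    h <- epn + nepn
    h[1] / h[15]
  }
  expect_gt(grad(norm), grad(hyp))
  # and the porto-central profile is monotone under clearance
  h_norm <- state_at(norm, "Epn") + state_at(norm, "NEpn")
  expect_true(all(diff(h_norm) < 0))
})
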