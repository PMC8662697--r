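test_that("initial state carries the nominal conditions and layout", {
  cfg <- preset("human", 5)
  y0 <- initial_state(cfg)
  expect_length(y0, 11 * 15 + 5)
  expect_equal(unname(y0[hepacal:::state_index("CaI", 15)]), rep(0.2, 15))
  expect_equal(unname(y0[hepacal:::state_index("g", 15)]), rep(0.25, 15))
  expect_equal(unname(y0[hepacal:::state_index("IP3", 15)]), rep(1e-4, 15))
  expect_equal(unname(y0[hepacal:::state_index("r", 15)]), rep(0.5, 15))
  expect_equal(unname(y0[hepacal:::state_index("Glyc", 15)]), rep(300, 15))
  expect_equal(unname(y0["GB"]), 5000)
  # catecholamines start on a decreasing porto-central profile
  epn <- y0[hepacal:::state_index("Epn", 15)]
  expect_true(all(diff(epn) < 0))
})

test_that("compiled and reference right-hand sides agree", {
  cfg <- preset("rodent", 2.5)
  cfg$systemic$u_G_basal <- 0.45
  pv <- hepacal:::pack_params(cfg, exercise_on = TRUE)
  set.seed(5)
  N <- 15
  for (k in 1:100) {
    y <- c(runif(N), runif(N, 0, 0.5), runif(N, 0, 2), runif(N),
           runif(N, 100, 300), runif(N, 4000, 6000), runif(N, 3000, 6000),
           runif(N, 0, 0.3), runif(N, 0, 2), runif(N, 0, 3),
           runif(N, 0, 8), runif(1, 3000, 6000), runif(1, 0, 0.3),
           runif(1, 0, 2), runif(1, 0, 3), runif(1, 0, 8))
    dR <- hepacal:::lobule_rhs_R(0, y, pv)[[1]]
    dC <- deSolve::DLLfunc(y = y, times = 0, func = "hepacal_derivs",
                           parms = unname(pv), dllname = "hepacal",
                           initfunc = "hepacal_initmod")$dy
    expect_equal(unname(dC), unname(dR), tolerance = 1e-12)
  }
})

test_that("scenario runs are deterministic and respect state bounds", {
  a <- cached_run("hum5", preset("human", 5))
  b <- run_scenario(preset("human", 5))
  expect_identical(a$states, b$states)
  expect_identical(a$hash, b$hash)
  # fraction states stay in [0, 1]; concentrations non-negative
  expect_true(all(get_species(a, "g") >= -1e-9 &
                    get_species(a, "g") <= 1 + 1e-9))
  expect_true(all(get_species(a, "r") >= -1e-9 &
                    get_species(a, "r") <= 1 + 1e-9))
  expect_true(all(get_species(a, "CaI") > -1e-6))
  expect_true(all(get_species(a, "Glc") > 0))
  expect_true(all(get_species(a, "GB") > 0))
  # time grid strictly increasing at the requested resolution
  expect_true(all(diff(a$time) > 0))
})

test_that("the exercise step is applied exactly at the window edge", {
  ex <- cached_run("hum5", preset("human", 5))
  ctl <- cached_run("ctl", preset("no_exercise", 5))
  # both presets share the configuration until exercise begins at 500 s
  pre <- ex$time <= 500
  expect_equal(ex$states[pre, "GB"], ctl$states[pre, "GB"],
               tolerance = 1e-8)
  # immediately afterwards systemic glucose declines in the exercise run
  i0 <- match(500, ex$time)
  d_ex <- ex$states[i0 + 5, "GB"] - ex$states[i0, "GB"]
  d_ctl <- ctl$states[i0 + 5, "GB"] - ctl$states[i0, "GB"]
  expect_lt(d_ex, d_ctl - 1)
})

test_that("disabling the calcium arm removes stimulus dependence", {
  # with v_CaI_max = 0, glycogenolysis loses all calcium sensitivity:
  # fluxes are identical whether or not the stimulus acts
  met0 <- metabolism_params(v_CaI_max = 0)
  sysp <- systemic_params(u_G_basal = 0.45)
  on <- run_scenario(scenario_config("human", 5, metabolism = met0,
                                     systemic = sysp, t_end = 1200,
                                     exercise_start = 200,
                                     exercise_duration = 900),
                     dt = 2)
  off <- run_scenario(scenario_config("human", 5, metabolism = met0,
                                      systemic = sysp, t_end = 1200,
                                      exercise_start = 200,
                                      exercise_duration = 900,
                                      stimulus_enabled = FALSE),
                      dt = 2)
  g_on <- glucose_outputs(on, c(0, 1200))$total
  g_off <- glucose_outputs(off, c(0, 1200))$total
  expect_equal(g_on, g_off, tolerance = 1e-6)
})

test_that("run_comparison aligns compatible scenarios and rejects others", {
  cmp <- run_comparison(list(preset("human", 5, t_end = 600,
                                    exercise_start = 100,
                                    exercise_duration = 400),
                             preset("denervated", 5, t_end = 600,
                                    exercise_start = 100,
                                    exercise_duration = 400)),
                        dt = 2)
  expect_named(cmp, c("human", "denervated"))
  expect_identical(cmp[[1]]$time, cmp[[2]]$time)
  bad <- preset("human", 5)
  bad$t_end <- 900
  expect_error(run_comparison(list(preset("human", 5), bad)),
               "incompatible")
})

test_that("simulation accessors expose fluxes and tidy output", {
  sim <- cached_run("hum5", preset("human", 5))
  fl <- glycogenolysis_fluxes(sim)
  ex <- export_fluxes(sim)
  expect_equal(dim(fl), c(length(sim$time), 15))
  expect_true(all(fl >= 0))
  df <- as.data.frame(sim)
  expect_named(df, c("time", "entity", "variable", "value"))
  expect_equal(nrow(df), length(sim$time) * ncol(sim$states))
  expect_true("GB" %in% df$variable)
})
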