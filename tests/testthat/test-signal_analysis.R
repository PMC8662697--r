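test_that("spike detection finds constructed pulses and applies thresholds", {
  tt <- seq(0, 400, by = 0.5)
  gauss <- function(t0, amp) amp * exp(-(tt - t0)^2 / (2 * 3^2))
  trace <- 0.1 + gauss(100, 0.8) + gauss(200, 0.8) + gauss(300, 0.8)
  sp <- detect_spikes(data.frame(time = tt, CaI = trace))
  expect_length(sp$times, 3)
  expect_equal(sp$times, c(100, 200, 300), tolerance = 0.5)
  expect_equal(sp$amplitudes, rep(0.9, 3), tolerance = 1e-2)
  # constant trace: nothing to find
  expect_length(detect_spikes(data.frame(tt, rep(0.7, length(tt))))$times, 0)
  # pulse below the absolute height threshold is excluded
  low <- 0.1 + gauss(100, 0.8) + gauss(200, 0.2)
  expect_equal(detect_spikes(data.frame(tt, low))$times, 100,
               tolerance = 0.5)
  # small ripples below the prominence threshold are excluded
  ripple <- 0.6 + 0.04 * sin(tt / 3)
  expect_length(detect_spikes(data.frame(tt, ripple))$times, 0)
  # refractory pruning keeps the taller of two close peaks
  pair <- 0.1 + gauss(100, 0.8) + gauss(110, 0.6)
  expect_equal(detect_spikes(data.frame(tt, pair))$times, 100,
               tolerance = 0.5)
  expect_error(detect_spikes(numeric(0)), "empty trace")
})

test_that("inter-spike intervals average successive differences", {
  expect_equal(interspike_interval(c(0, 100, 200)), 100)
  expect_equal(interspike_interval(c(0, 90, 210)), 105)
  expect_error(interspike_interval(c(42)), "fewer than 2")
})

test_that("wave metrics classify constructed spike trains", {
  mk_train <- function(times) structure(list(times = times,
                                             amplitudes = rep(1, length(times))),
                                        class = "spike_train")
  base <- seq(100, 1000, by = 100)
  # PC leads by 10 s, linear front across 15 cells
  lead <- lapply(seq_len(15), function(i)
    mk_train(base + 10 * (15 - i) / 14))
  wm <- wave_metrics(lead)
  expect_equal(wm$direction, "PC->PP")
  expect_equal(wm$lag_time, 10)
  expect_equal(wm$velocity, 1.4)
  expect_equal(wm$period, 100)
  expect_equal(wm$start_site, 15L)
  # velocity in um/s with a 25 um cell
  expect_equal(wave_metrics(lead, cell_length = 25)$velocity, 35)
  # reversed front travels PP -> PC
  rev_front <- lapply(seq_len(15), function(i)
    mk_train(base + 10 * (i - 1) / 14))
  expect_equal(wave_metrics(rev_front)$direction, "PP->PC")
  expect_equal(wave_metrics(rev_front)$lag_time, -10)
  # synchronous spiking: no direction
  sync <- lapply(seq_len(15), function(i) mk_train(base))
  expect_equal(wave_metrics(sync)$direction, "none")
  # unsynchronized trains at drifting frequencies: no coherent wave
  set.seed(9)
  drift <- lapply(seq_len(15), function(i)
    mk_train(seq(100, 1000, by = 60 + 5 * i)))
  expect_equal(wave_metrics(drift)$direction, "none")
  # |velocity| equals (N-1)/|lag| whenever a direction is assigned
  expect_equal(wm$velocity, 14 / abs(wm$lag_time))
})

test_that("wave pairing unwraps lags larger than half a period", {
  mk_train <- function(times) structure(list(times = times,
                                             amplitudes = rep(1, length(times))),
                                        class = "spike_train")
  base <- seq(100, 1500, by = 100)
  # a front spreading over 60 s of a 100 s period: pairing only the
  # extreme cells would wrap the phase to +40 s; tracing the front cell
  # by cell recovers the true 60 s periportal lead
  wrap <- lapply(seq_len(15), function(i)
    mk_train(base + 60 * (i - 1) / 14))
  wm <- wave_metrics(wrap)
  expect_equal(wm$direction, "PP->PC")
  expect_equal(wm$lag_time, -60)
})

test_that("glucose output integrals match analytic cases", {
  sim <- cached_run("hum5", preset("human", 5))
  # window calculus on a synthetic constant-flux object is exact:
  # constant flux f over T integrates to f T per layer
  fake <- sim
  fake$states[, hepacal:::state_index("Gcell", 15)] <-
    sweep(fake$states[, hepacal:::state_index("Glc", 15)], 2,
          rep(10, 15), "+")
  go <- glucose_outputs(fake, c(0, 1000))
  expect_equal(go$per_layer, rep(0.1 * 10 * 1000, 15), tolerance = 1e-9)
  expect_equal(go$total, 15 * 1000)
  # zero gradient, zero output
  fake$states[, hepacal:::state_index("Gcell", 15)] <-
    fake$states[, hepacal:::state_index("Glc", 15)]
  expect_equal(glucose_outputs(fake, c(0, 1000))$total, 0)
  expect_error(glucose_outputs(sim, c(0, 1e6)))
})

test_that("percent change follows its definition", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(1.1327, 1), 13.27)
  expect_equal(percent_change(2, 1), 100)
  expect_error(percent_change(1, 0), "zero")
})

test_that("spike amplitudes increase from periportal to pericentral cells", {
  sim <- cached_run("hum5", preset("human", 5))
  trains <- spike_trains(sim, window = c(500, 4100))
  amps <- vapply(trains, function(tr) mean(tr$amplitudes), numeric(1))
  expect_true(all(!is.na(amps)))
  # PP cells spike lower than mid-lobular and PC cells
  expect_lt(amps[1], amps[8])
  expect_lt(amps[8], amps[15])
})
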