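# Shared simulation cache: scenario runs are deterministic, so test files
# reuse them instead of re-integrating.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, cfg, ...) {
  if (!exists(name, envir = .run_cache))
    assign(name, run_scenario(cfg, ...), envir = .run_cache)
  get(name, envir = .run_cache)
}

state_at <- function(sim, species, t = 4000) {
  x <- get_species(sim, species)
  i <- match(t, sim$time)
  if (is.matrix(x)) x[i, ] else x[i]
}

wave_dir <- function(sim, window = c(500, 4100)) {
  wave_metrics(spike_trains(sim, window = window))$direction
}
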