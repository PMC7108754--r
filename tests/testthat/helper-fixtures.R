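# small protocols/scenes for fast unit tests; the reference-condition
# defaults are exercised in test-acceptance.R

quick_protocol <- function(poststim_s = 2.5, n_trials = 3, n_z = 48,
                           n_x = 48, ...) {
  ins_protocol(poststim_s = poststim_s, n_trials = n_trials,
               n_z = n_z, n_x = n_x, ...)
}

quiet_scene <- function(p, ...) {
  # noise-free, jitter-free, avascular: deterministic response
  ins_scene(p, noise_sd = 0, trial_cv = 0, vessels = list(), ...)
}

# shared cache so the expensive default-scale runs are computed once
# per test session
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_foct_run <- function() {
  cached("foct_run", {
    p <- ins_protocol(oct_fps = 240, oisi_fps = 60)
    run_foct_pipeline(p, ins_scene(p), exposure = 1.0, seed = 1)
  })
}

default_oisi_course <- function() {
  cached("oisi_tc", {
    p <- ins_protocol(oct_fps = 240, oisi_fps = 60)
    os <- simulate_oisi_series(p, ins_scene(p), exposure = 1, seed = 1001)
    oisi_signal(os)
  })
}
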