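# Shared fixtures, built once per test run and memoised.

.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(key, builder) {
  if (!exists(key, envir = .fx_cache)) assign(key, builder(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

# small forward model shared by many tests
fx_space <- function() fx_get("space", function() source_space(200, 6, seed = 2))
fx_lf <- function() fx_get("lf", function()
  lead_field(head_model(n_terms = 40), montage(), fx_space()))

# one full-size synthetic study (28 subjects, 60 ch, 256 samples)
fx_study <- function() fx_get("study", function()
  generate_study("paper_like", seed = 3))

# reduced null study used for calibration checks
fx_null_study <- function(seed) generate_study(
  "null", seed = seed, n_trials = 8L, n_samples = 64L, artifact_prob = 0)
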