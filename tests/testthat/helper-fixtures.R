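# Shared fixtures, built once per test run: the packaged bundle and its
# base-case run are deterministic, so every test file can reuse them.
.fix <- new.env(parent = emptyenv())

test_bundle <- function() {
  if (is.null(.fix$bundle)) .fix$bundle <- default_bundle()
  .fix$bundle
}

test_base_run <- function() {
  if (is.null(.fix$base_run)) .fix$base_run <- run_scenario(scenario(), test_bundle())
  .fix$base_run
}

# a bundle with uniform stratum counts and flat prevalences, for
# construction-level checks
uniform_bundle <- function(count = 10) {
  b <- test_bundle()
  b$demography$init_counts <- rep(count, 24)
  b
}

# window mean of an annual outcome column
wmean <- function(run, var, end, start = 2012) {
  o <- if (inherits(run, "cvd_run")) run$outcomes else run
  mean(o[[var]][o$year >= start & o$year <= end])
}
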