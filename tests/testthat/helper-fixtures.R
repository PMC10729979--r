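# Shared fixtures, built in code once per test run.

test_cams <- default_cameras()
test_cal <- make_calibration_fixture(test_cams)
test_dlt_a <- dlt_fit(test_cal, 1)
test_dlt_b <- dlt_fit(test_cal, 2)

# One small noiseless analyzed cohort reused by several test files.
make_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(n_pitchers = 5, n_trials = 6,
                                coupling_c1 = 28, seed = 20260930)
    }
    cache
  }
})

# A single noiseless trial (truth + analysis), cached.
make_single_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- make_population(4, coupling_c1 = 28, seed = 99)
      truth <- simulate_trial(pop[[1]], seed = 12345)
      tracks <- project_trial(truth, test_cams, sigma_px = 0)
      trial <- analyze_trial(test_dlt_a, test_dlt_b, tracks$a, tracks$b,
                             handedness = pop[[1]]$handedness)
      cache <<- list(profile = pop[[1]], truth = truth, tracks = tracks,
                     trial = trial)
    }
    cache
  }
})
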