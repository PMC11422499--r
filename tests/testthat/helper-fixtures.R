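# Shared fixtures, computed once per test run and memoised.  Everything is
# generated in code from the seeded synthetic-data module; no data files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fix_truth <- function() fixture("truth", function() generate_truth(42, "exponential"))

fix_runs_clean <- function() {
  fixture("runs_clean", function() render_runs(fix_truth(), noise_scale = 0))
}

fix_runs_noisy <- function() {
  fixture("runs_noisy", function() render_runs(fix_truth(), noise_scale = 1))
}

fix_acs_clean <- function() {
  fixture("acs_clean",
          function() process_acs_run(fix_runs_clean()$acs, fix_runs_clean()$coeffs))
}

fix_acs_noisy <- function() {
  fixture("acs_noisy",
          function() process_acs_run(fix_runs_noisy()$acs, fix_runs_noisy()$coeffs))
}

# total and dissolved absorption spectra evaluated from truth (analytic),
# for driving the scatter pipeline without going through the AC-S chain
truth_absorption_pair <- function(truth, wl = seq(370, 730, 1)) {
  list(
    a_sc = spectrum(wl, truth_a_p(truth, wl) + truth_a_g(truth, wl)),
    a_g = spectrum(wl, truth_a_g(truth, wl)))
}

# a small flat spectral time series for arithmetic tests
flat_series <- function(value = 0.5, wl = c(440, 550, 660), n_t = 10) {
  ts <- tidyr::expand_grid(time_s = seq_len(n_t) - 1, wavelength = wl)
  ts$value <- value
  ts
}
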