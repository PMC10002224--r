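## Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

## small three-group cohort with the default group parameters
test_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(cohort_spec(
      n_per_group = c(SG = 3, FG = 3, RG = 3),
      record_duration = 180, fs = 40, seed = 42))
  }
  .fixtures$cohort
}

test_series <- function() {
  if (is.null(.fixtures$series))
    .fixtures$series <- extract_cohort(test_cohort())
  .fixtures$series
}

test_dataset1 <- function() {
  if (is.null(.fixtures$d1)) .fixtures$d1 <- dataset1(test_series())
  .fixtures$d1
}

test_dataset2 <- function() {
  if (is.null(.fixtures$d2))
    .fixtures$d2 <- dataset2(test_series(), "bior1.3")
  .fixtures$d2
}

## a noise-free, modulation-free parameter set (degenerate-variance cases)
quiet_params <- function(mean_ttot = 4, mean_rr = 1) {
  group_params(mean_ttot = mean_ttot, mod_amp_range = c(0, 0),
               ttot_jitter_sd = 0, vt_sd = 0, mean_rr = mean_rr,
               rr_lf_amp = 0, rr_hf_amp = 0, rr_jitter_sd = 0, noise_sd = 0)
}

quiet_subject <- function(duration = 60, fs = 250, mean_ttot = 4,
                          mean_rr = 1, seed = 1) {
  generate_subject(quiet_params(mean_ttot, mean_rr), duration, fs, seed)
}

## well-separated two-class Gaussian toy (means `sep` SDs apart on axis 1)
gaussian_toy <- function(n = 30, d = 2, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n * d), n, d),
             sweep(matrix(stats::rnorm(n * d), n, d), 2,
                   c(sep, rep(0, d - 1)), "+"))
  list(X = X, y = rep(c("A", "B"), each = n))
}
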