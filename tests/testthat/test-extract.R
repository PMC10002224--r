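test_that("preprocessing removes linear trends and isolated spikes", {
  t <- seq(0, 10, by = 0.01)
  ramp <- 2 + 3 * t
  expect_true(max(abs(preprocess_signal(ramp))) < 1e-8)

  clean <- sin(2 * pi * t / 4)
  spiked <- clean
  spiked[301] <- 100
  fixed <- preprocess_signal(spiked, outlier_z = 5, detrend = FALSE)
  expect_lt(max(abs(fixed - clean)), 0.1)

  ## clean signal passes through untouched (detrending aside)
  expect_equal(preprocess_signal(clean, detrend = FALSE), clean)
  expect_error(preprocess_signal(c(1, NA, 3)), "finite")
})

test_that("a pure sinusoid segments into equal half-cycles", {
  fs <- 100
  t <- seq(0, 48 - 1 / fs, by = 1 / fs)
  flow <- sin(2 * pi * t / 4)
  br <- segment_breaths(flow, fs)
  expect_equal(nrow(br), 10)  # interior breaths only; boundary lobes dropped
  expect_true(all(abs((br$t_exp - br$t_insp) - 2) < 1 / fs))
  expect_true(all(abs((br$t_next - br$t_exp) - 2) < 1 / fs))
  expect_error(segment_breaths(rep(0, 1000), fs), "breaths")
})

test_that("segmentation recovers generator onsets at zero noise", {
  rec <- quiet_subject(duration = 120, fs = 100)
  br <- segment_breaths(rec$flow, rec$fs)
  truth <- rec$truth$onset
  matched <- truth[truth > 0.01 & truth < 116]
  for (on in matched[2:5])
    expect_lt(min(abs(br$t_insp - on)), 1 / rec$fs)
})

test_that("series definitions follow the breath-wise formulas", {
  ## one half-sine inspiration (A = 1, TI = 2) + expiration, VT = 2*A*TI/pi
  fs <- 200
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  flow <- ifelse(t < 4, sin(pi * t / 2) * (t < 2),
                 -sin(pi * (t - 4) / 2) * (t >= 4 & t < 6))
  flow <- rep(flow, 4)
  t <- seq_along(flow) / fs
  br <- segment_breaths(flow, fs, min_breaths = 2)
  s <- build_series(flow, fs, br, r_peaks = c(0, 0.8, 1.7))
  expect_equal(s$VT$value, rep(4 / pi, nrow(s$VT)), tolerance = 1e-3)
  ## f/VT = (60 / TTot) / VT
  expect_equal(s[["f/VT"]]$value,
               (60 / s$TTot$value) / s$VT$value, tolerance = 1e-12)
  expect_equal(s[["TI/TTot"]]$value,
               s$TI$value / s$TTot$value, tolerance = 1e-12)
  ## RR from the given peaks, stamped at the later peak
  expect_equal(s$RR$value, c(0.8, 0.9))
  expect_equal(s$RR$t, c(0.8, 1.7))
})

test_that("structural invariants hold across an extracted cohort", {
  cs <- test_series()
  coh <- test_cohort()
  for (id in names(cs)) {
    s <- cs[[id]]
    expect_equal(s$TTot$value, s$TI$value + s$TE$value)
    expect_true(all(s$TI$value > 0 & s$TE$value > 0))
    expect_true(all(s[["TI/TTot"]]$value > 0 & s[["TI/TTot"]]$value < 1))
    expect_true(all(diff(s$TI$t) > 0))
    expect_length(s$RR$value, length(coh[[id]]$r_peaks) - 1)
  }
})

test_that("round-trip against generator ground truth at zero noise", {
  rec <- quiet_subject(duration = 120, fs = 100, mean_ttot = 3.5)
  s <- extract_series(rec, detrend = FALSE)
  truth <- rec$truth
  ## align: drop boundary breaths lost to segmentation
  k <- match(round(s$TI$t, 1), round(truth$onset, 1))
  expect_true(all(!is.na(k)))
  expect_true(all(abs(s$TI$value - truth$ti[k]) < 2 / rec$fs))
  expect_true(all(abs(s$VT$value - truth$vt[k]) < 0.02 * truth$vt[k]))
})
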