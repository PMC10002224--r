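test_that("resampling is the identity on grid-aligned events and linear in between", {
  ev <- data.frame(t = seq(0, 10, by = 0.5), value = rnorm(21))
  rs <- resample_series(ev, rate = 2)
  expect_equal(rs$values, ev$value)
  rs2 <- resample_series(data.frame(t = c(0, 2), value = c(0, 2)), rate = 1)
  expect_equal(rs2$values, c(0, 1, 2))
  expect_error(resample_series(ev, rate = 0), "positive")
})

test_that("Welch PSD locates a single tone and obeys Parseval", {
  t <- seq(0, 511.5, by = 0.5)
  x <- sin(2 * pi * 0.25 * t)
  p <- psd_welch(x, rate = 2)
  expect_equal(p$freq[which.max(p$power)], 0.25, tolerance = 2 / 256)

  set.seed(1)
  w <- rnorm(4096)
  pw <- psd_welch(w, rate = 2)
  df <- pw$freq[2] - pw$freq[1]
  expect_equal(sum(pw$power) * df, var(w), tolerance = 0.05)

  pc <- psd_welch(rep(3, 256), rate = 2)
  expect_true(all(pc$power < 1e-20))
})

test_that("PSD descriptors measure peak, spread and total power", {
  t <- seq(0, 2047.5, by = 0.5)
  x <- sin(2 * pi * 0.25 * t)
  d <- psd_descriptors(psd_welch(x, rate = 2))
  expect_equal(unname(d["PF"]), 0.25, tolerance = 0.01)
  expect_gt(d["PA"], 0)
  ## a single tone has a narrow spectral width; white noise a wide one
  set.seed(2)
  dn <- psd_descriptors(psd_welch(rnorm(4096), rate = 2))
  expect_lt(d["IQR"], dn["IQR"])
  ## P is 98% of total power
  p <- psd_welch(x, rate = 2)
  tot <- sum(p$power[-1]) * (p$freq[2] - p$freq[1])
  expect_equal(unname(d["P"]), 0.98 * tot, tolerance = 1e-10)
})

test_that("resampling loss is ~0 for aligned grids and decreases with rate", {
  ev <- data.frame(t = seq(0, 400, by = 0.5),
                   value = sin(2 * pi * 0.05 * seq(0, 400, by = 0.5)))
  loss <- resampling_loss(ev, candidate_rates = c(0.5, 2), reference_rate = 4)
  expect_lt(loss["2"], 0.1)
  expect_lt(loss["2"], loss["0.5"])
  ## band-limited synthetic series: loss at 2 Hz below the 2% working point
  s <- test_series()[[1]][["TTot"]]
  l <- resampling_loss(s, candidate_rates = 2, reference_rate = 4)
  expect_lt(l, 2)
})

test_that("a modulated breath series shows its modulation frequency at 2 Hz", {
  gp <- group_params(mod_amp_range = c(0.5, 0.5), mod_freq = 0.05,
                     ttot_jitter_sd = 0, vt_sd = 0, noise_sd = 0)
  rec <- generate_subject(gp, duration = 400, fs = 50, seed = 2)
  s <- extract_series(rec, detrend = FALSE)
  rs <- resample_series(s$TTot, 2)
  p <- psd_welch(rs, nperseg = 512)
  expect_lt(abs(p$freq[which.max(p$power[-1]) + 1] - 0.05), 0.011)
})

test_that("dataset1 has the fixed 32-column schema and is row-deterministic", {
  d1 <- test_dataset1()
  fcols <- setdiff(colnames(d1), c("subject_id", "group"))
  expect_length(fcols, 32)
  expect_true(all(c("PA(TI)", "PF(f/VT)", "IQR(RR)", "P(VT/TI)") %in% fcols))
  expect_equal(nrow(d1), length(test_series()))
  ## identical subjects give identical rows
  cs <- test_series()[c(1, 1)]
  names(cs) <- c("x1", "x2")
  attr(cs, "groups") <- c(x1 = "SG", x2 = "SG")
  dd <- dataset1(cs)
  expect_equal(unlist(dd[1, -1]), unlist(dd[2, -1]))
})
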