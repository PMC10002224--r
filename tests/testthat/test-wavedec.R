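test_that("the catalog contains the full candidate set", {
  cat <- wavelet_catalog()
  expect_length(cat, 45 + 5 + 29 + 15)
  expect_true(all(c("db1", "db45", "sym29", "coif5", "bior6.8") %in% cat))
  expect_error(wavelet_filters("db99"), "unknown")
})

test_that("level-1 detail coefficients match a direct convolution oracle", {
  w <- wavelet_filters("db3")
  n <- 32
  x <- numeric(n); x[13] <- 1  # Kronecker delta
  dec <- dwt_decompose(x, "db3", levels = 1)
  ## independent oracle: explicit symmetric extension + direct convolution,
  ## decimated on the odd phase
  L <- w$length
  ext <- c(rev(x[1:(L - 1)]), x, rev(x[(n - L + 2):n]))
  full <- numeric(length(ext) + L - 1)
  for (k in seq_len(L))
    full[k:(k + length(ext) - 1)] <- full[k:(k + length(ext) - 1)] + w$dec_hi[k] * ext
  expected <- full[seq(L + 1, by = 2, length.out = floor((n + L - 1) / 2))]
  expect_equal(dec$coefficients$DC1, expected, tolerance = 1e-14)
})

test_that("the transform is linear and perfectly invertible", {
  set.seed(4)
  x <- rnorm(256)
  d1 <- dwt_decompose(x, "bior2.4", 4)
  d2 <- dwt_decompose(2 * x, "bior2.4", 4)
  for (nm in names(d1$coefficients))
    expect_equal(2 * d1$coefficients[[nm]], d2$coefficients[[nm]], tolerance = 1e-12)
  expect_equal(dwt_reconstruct(d1), x, tolerance = 1e-10)
})

test_that("every catalog wavelet reconstructs random signals below 1e-10 relative error", {
  set.seed(5)
  x <- rnorm(512)
  errs <- vapply(wavelet_catalog(), function(wn) {
    dec <- dwt_decompose(x, wn, 8)
    max(abs(dwt_reconstruct(dec) - x)) / max(abs(x))
  }, numeric(1))
  expect_lt(max(errs), 1e-10)
})

test_that("wavelet selection is scale-invariant and breaks ties by filter length", {
  set.seed(6)
  x <- rnorm(300)
  cat <- c("db2", "db8", "sym4", "bior2.2", "bior3.1")
  s1 <- select_wavelet(x, cat, levels = 4)
  s2 <- select_wavelet(10 * x, cat, levels = 4)
  expect_identical(s1$wavelet, s2$wavelet)
  ## constant series: every candidate is exact, shortest filter wins
  sc <- select_wavelet(rep(1, 300), c("db1", "db5", "bior1.1"), levels = 4)
  expect_true(sc$wavelet %in% c("db1", "bior1.1"))  # both length-2 filters
  expect_lt(unname(sc$mse), 1e-20)
  expect_error(dwt_decompose(rnorm(100), "db2", levels = 8), "at least")
})

test_that("coefficient statistics implement the moment definitions", {
  v <- c(1, 2, 3, 4, 10)
  cs <- coeff_stats(v)
  m <- mean(v)
  expect_equal(unname(cs["Xbar"]), m)
  expect_equal(unname(cs["S"]), sd(v))
  expect_equal(unname(cs["SK"]), mean((v - m)^3) / mean((v - m)^2)^1.5)
  expect_equal(unname(cs["K"]), mean((v - m)^4) / mean((v - m)^2)^2 - 3)
  expect_equal(unname(cs["IQR"]), IQR(v))
  ## constant vector: shape statistics fall back to 0
  cc <- coeff_stats(rep(2, 10))
  expect_equal(unname(cc[c("S", "SK", "K", "IQR")]), c(0, 0, 0, 0))
})

test_that("dataset2 has the fixed 640-column schema, cohort-independent", {
  d2 <- test_dataset2()
  fcols <- setdiff(colnames(d2), c("subject_id", "group"))
  expect_length(fcols, 8 * 8 * 2 * 5)
  expect_true(all(c("Xbar(CA7-f/VT)", "S(CD1-TTot)", "K(CD8-RR)",
                    "IQR(CD2-TI/TTot)") %in% fcols))
  ## schema identical for a different cohort subset
  cs <- test_series()[1:2]
  attr(cs, "groups") <- attr(test_series(), "groups")[1:2]
  d2b <- dataset2(cs, "db2")
  expect_identical(setdiff(colnames(d2b), c("subject_id", "group")), fcols)
})
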