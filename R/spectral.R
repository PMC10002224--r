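#' Resample an event series onto a uniform grid by linear interpolation
#'
#' @param series data.frame with columns `t` (strictly increasing timestamps,
#'   seconds) and `value`.
#' @param rate target uniform rate (Hz).
#' @return Object of class `resampled_series`: list with `values`, `rate`,
#'   `t0` (time of the first grid sample) and `name` (if the input carried one).
#' @export
resample_series <- function(series, rate) {
  if (rate <= 0) stop("resample_series: rate must be positive")
  stopifnot(nrow(series) >= 2, all(diff(series$t) > 0))
  grid <- seq(series$t[1], series$t[nrow(series)], by = 1 / rate)
  vals <- stats::approx(series$t, series$value, xout = grid)$y
  structure(list(values = vals, rate = rate, t0 = series$t[1]),
            class = "resampled_series")
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: Hann window, 50% overlap, per-segment mean
#' removal, one-sided density scaling (so that `sum(power) * df` approximates
#' the series variance).
#'
#' @param x a `resampled_series` or plain numeric vector.
#' @param rate sampling rate (Hz); taken from `x` when it is a
#'   `resampled_series`.
#' @param nperseg segment length in samples; default `min(256, floor(N/2))`.
#' @param overlap fractional overlap between segments.
#' @return List with `freq` (Hz) and `power` (one-sided density).
#' @export
psd_welch <- function(x, rate = NULL, nperseg = NULL, overlap = 0.5) {
  if (inherits(x, "resampled_series")) {
    rate <- x$rate
    x <- x$values
  }
  if (is.null(rate)) stop("psd_welch: rate required")
  n <- length(x)
  if (n < 32) stop("psd_welch: series too short (need >= 32 samples)")
  if (is.null(nperseg)) nperseg <- min(256L, floor(n / 2))
  nperseg <- as.integer(min(nperseg, n))
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  if (length(starts) == 0) starts <- 1L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(w^2)
  x <- x - mean(x)
  nf <- nperseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  p <- acc / (length(starts) * u * rate)
  ## one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * rate / nperseg, power = p * dbl)
}

#' Spectral descriptors of a variability series
#'
#' Four descriptors of the PSD (DC bin excluded): peak amplitude `PA`, peak
#' frequency `PF`, the interquartile spectral width `IQR = f75 - f25` where
#' `f_q` is the frequency below which q% of the total power lies, and `P`, the
#' cumulative power up to the 98% point.
#'
#' @param psd list with `freq` and `power` (e.g. from [psd_welch()]).
#' @return Named numeric vector `c(PA, PF, IQR, P)`.
#' @export
psd_descriptors <- function(psd) {
  f <- psd$freq[-1]
  p <- psd$power[-1]
  tot <- sum(p)
  if (tot <= 0)
    return(c(PA = 0, PF = 0, IQR = 0, P = 0))
  i <- which.max(p)
  cum <- cumsum(p) / tot
  fq <- function(q) {
    j <- which(cum >= q)[1]
    if (j == 1) return(f[1])
    ## linear interpolation on the cumulative power curve
    f[j - 1] + (q - cum[j - 1]) / (cum[j] - cum[j - 1]) * (f[j] - f[j - 1])
  }
  df <- f[2] - f[1]
  c(PA = p[i], PF = f[i], IQR = fq(0.75) - fq(0.25), P = 0.98 * tot * df)
}

#' Spectral loss of candidate resampling rates against a dense reference
#'
#' For each candidate rate the event series is resampled at that rate and at
#' the dense `reference_rate`; both PSDs are estimated with equal-duration
#' Welch segments (`seg_duration` seconds, so the frequency grids coincide up
#' to the candidate Nyquist) and the loss is the mean squared PSD difference on
#' the common grid \eqn{[0, rate/2]}, normalised by the reference PSD's mean
#' squared power, in percent.
#'
#' @param series event series data.frame (`t`, `value`).
#' @param candidate_rates candidate rates (Hz).
#' @param reference_rate dense reference rate (Hz), must exceed all candidates.
#' @param seg_duration Welch segment duration in seconds.
#' @return Named numeric vector of losses (%), one per candidate rate.
#' @export
resampling_loss <- function(series, candidate_rates = c(0.5, 1, 1.5, 2, 2.5, 3),
                            reference_rate = 4, seg_duration = 128) {
  stopifnot(length(candidate_rates) >= 1,
            reference_rate > max(candidate_rates))
  ref <- resample_series(series, reference_rate)
  out <- vapply(candidate_rates, function(r) {
    cand <- resample_series(series, r)
    ## equal-duration segments for both estimates so the frequency grids nest
    seg <- floor(min(seg_duration,
                     floor(length(cand$values) / 2) / r,
                     floor(length(ref$values) / 2) / reference_rate))
    pc <- psd_welch(cand, nperseg = round(seg * r))
    pref <- psd_welch(ref, nperseg = round(seg * reference_rate))
    pr_i <- stats::approx(pref$freq, pref$power, xout = pc$freq, rule = 2)$y
    100 * mean((pc$power - pr_i)^2) / mean(pr_i^2)
  }, numeric(1))
  names(out) <- as.character(candidate_rates)
  out
}

#' Dataset1: the 32 spectral descriptors per subject
#'
#' For each of the eight variability series, the four PSD descriptors `PA`,
#' `PF`, `IQR` and `P` (see [psd_descriptors()]) of the series resampled at
#' `rate`, giving 32 named columns (e.g. `PA(f/VT)`).
#'
#' @param cohort_series named list of `breath_series_set`s (see
#'   [extract_cohort()]); its `groups` attribute supplies the labels.
#' @param rate analysis rate (Hz).
#' @return data.frame: `subject_id`, `group`, then the 32 feature columns.
#' @export
dataset1 <- function(cohort_series, rate = 2) {
  groups <- attr(cohort_series, "groups")
  sn <- series_names()
  desc <- c("PA", "PF", "IQR", "P")
  cols <- as.vector(t(outer(sn, desc, function(s, d) sprintf("%s(%s)", d, s))))
  rows <- list()
  for (id in names(cohort_series)) {
    feats <- tryCatch({
      unlist(lapply(sn, function(s) {
        rs <- resample_series(cohort_series[[id]][[s]], rate)
        d <- psd_descriptors(psd_welch(rs))
        names(d) <- sprintf("%s(%s)", c("PA", "PF", "IQR", "P"), s)
        d
      }))
    }, error = function(e) {
      message(sprintf("dataset1: dropping subject %s (%s)", id,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(feats)) rows[[id]] <- feats
  }
  if (length(rows) == 0)
    stop("dataset1: every subject failed spectral feature extraction")
  mat <- do.call(rbind, rows)
  out <- data.frame(subject_id = rownames(mat),
                    group = unname(groups[rownames(mat)]),
                    check.names = FALSE)
  out[cols] <- mat[, cols]
  rownames(out) <- NULL
  out
}
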