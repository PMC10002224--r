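#' Preprocess a sampled signal: outlier replacement and linear detrending
#'
#' Samples whose z-score (after detrending) exceeds `outlier_z` are replaced by
#' linear interpolation between the neighbouring retained samples; the linear
#' trend is then removed when `detrend` is set. Length is preserved.
#'
#' @param x numeric signal samples (finite).
#' @param outlier_z z-score threshold for spike replacement; `Inf` disables it.
#' @param detrend remove the least-squares linear trend.
#' @return Numeric vector, same length as `x`.
#' @export
preprocess_signal <- function(x, outlier_z = 5, detrend = TRUE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("preprocess_signal: input must be finite numeric")
  n <- length(x)
  idx <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, idx), x)
  resid <- fit$residuals
  s <- stats::sd(resid)
  ## an (all but) exactly-fit signal has no outliers, only float noise
  s_floor <- 1e-10 * max(1, diff(range(x)))
  if (s > s_floor && is.finite(outlier_z)) {
    bad <- abs(resid) / s > outlier_z
    if (any(bad)) {
      good <- which(!bad)
      if (length(good) >= 2)
        x[bad] <- stats::approx(good, x[good], xout = which(bad),
                                rule = 2)$y
      fit <- stats::lm.fit(cbind(1, idx), x)
      resid <- fit$residuals
    }
  }
  if (detrend) resid else x
}

## refined (sub-sample) zero-crossing times of a sampled signal, with direction
zero_crossings <- function(x, fs) {
  s <- sign(x)
  s[s == 0] <- 1L
  ch <- which(diff(s) != 0)
  if (length(ch) == 0)
    return(data.frame(time = numeric(0), up = logical(0)))
  frac <- x[ch] / (x[ch] - x[ch + 1])
  data.frame(time = (ch - 1 + frac) / fs, up = s[ch + 1] > 0)
}

#' Segment a respiratory flow signal into breaths
#'
#' Inspiration onsets are negative-to-positive zero crossings and expiration
#' onsets positive-to-negative crossings, with crossing times refined by linear
#' interpolation between the bracketing samples. Lobes whose extremum does not
#' exceed `noise_floor_frac` of the signal's robust amplitude (95th percentile
#' of |flow|) are merged into their neighbours.
#'
#' @param flow preprocessed flow samples.
#' @param fs sampling rate (Hz).
#' @param noise_floor_frac fraction of the robust amplitude a lobe must reach.
#' @param min_breaths minimum number of valid breaths, else an error.
#' @param subject_id used in error messages.
#' @return data.frame with columns `t_insp`, `t_exp`, `t_next` (seconds).
#' @export
segment_breaths <- function(flow, fs, noise_floor_frac = 0.1,
                            min_breaths = 10, subject_id = "<unknown>") {
  stopifnot(fs > 0)
  zc <- zero_crossings(flow, fs)
  if (nrow(zc) < 3)
    stop(sprintf("segment_breaths: subject %s: no usable breaths", subject_id))
  thr <- noise_floor_frac * stats::quantile(abs(flow), 0.95, names = FALSE)

  ## lobe amplitudes between consecutive crossings; merge shallow lobes by
  ## deleting their two bounding crossings (neighbouring lobes of equal sign
  ## coalesce)
  repeat {
    nzc <- nrow(zc)
    if (nzc < 3) break
    samp <- round(zc$time * fs) + 1
    amp <- vapply(seq_len(nzc - 1), function(i) {
      lo <- min(samp[i] + 1, length(flow)); hi <- min(samp[i + 1], length(flow))
      if (hi < lo) return(0)
      max(abs(flow[lo:hi]))
    }, numeric(1))
    shallow <- which(amp < thr)
    if (length(shallow) == 0) break
    i <- shallow[1]
    zc <- zc[-c(i, i + 1), , drop = FALSE]
  }

  up <- which(zc$up)
  nzc <- nrow(zc)
  ok <- up + 2 <= nzc
  ok[ok] <- !zc$up[up[ok] + 1] & zc$up[up[ok] + 2]
  i <- up[ok]
  breaths <- data.frame(t_insp = zc$time[i], t_exp = zc$time[i + 1],
                        t_next = zc$time[i + 2])
  if (nrow(breaths) < min_breaths)
    stop(sprintf("segment_breaths: subject %s: fewer than %d valid breaths",
                 subject_id, min_breaths))
  breaths
}

#' Build the eight per-event variability series of one subject
#'
#' From the segmented breaths: TI, TE, TTot = TI + TE, the tidal volume VT
#' (trapezoidal integral of flow over the inspiration), TI/TTot, VT/TI, and
#' f/VT with f the instantaneous respiratory rate 60/TTot (breaths/min); from
#' the R-peaks: RR (successive differences, stamped at the later peak). Breath
#' series are stamped at the inspiration onset.
#'
#' @param flow preprocessed flow samples.
#' @param fs sampling rate (Hz).
#' @param breaths data.frame from [segment_breaths()].
#' @param r_peaks strictly increasing R-peak times (s), at least 2.
#' @param max_discard_frac error if more than this fraction of breaths has a
#'   non-positive inspiratory integral.
#' @return Object of class `breath_series_set`: a named list of eight
#'   data.frames `(t, value)` for `TI`, `TE`, `TTot`, `VT`, `TI/TTot`,
#'   `VT/TI`, `f/VT`, `RR`.
#' @export
build_series <- function(flow, fs, breaths, r_peaks, max_discard_frac = 0.2) {
  stopifnot(nrow(breaths) >= 1, length(r_peaks) >= 2,
            all(diff(r_peaks) > 0))
  t_grid <- (seq_along(flow) - 1) / fs
  ## cumulative trapezoid of flow; VT_k = I(t_exp) - I(t_insp), with I
  ## interpolated linearly (flow ~ 0 at the crossings, so the error is tiny)
  I <- c(0, cumsum((flow[-1] + flow[-length(flow)]) / 2)) / fs
  I_at <- function(tt) stats::approx(t_grid, I, xout = tt)$y
  vt <- I_at(breaths$t_exp) - I_at(breaths$t_insp)
  ok <- vt > 0
  if (mean(!ok) > max_discard_frac)
    stop(sprintf("build_series: %.0f%% of breaths discarded (VT <= 0)",
                 100 * mean(!ok)))
  if (any(!ok))
    message(sprintf("build_series: discarded %d breaths with VT <= 0", sum(!ok)))
  b <- breaths[ok, , drop = FALSE]
  vt <- vt[ok]
  ti <- b$t_exp - b$t_insp
  te <- b$t_next - b$t_exp
  ttot <- ti + te
  tb <- b$t_insp
  rr <- diff(r_peaks)
  series <- list(
    "TI"      = data.frame(t = tb, value = ti),
    "TE"      = data.frame(t = tb, value = te),
    "TTot"    = data.frame(t = tb, value = ttot),
    "VT"      = data.frame(t = tb, value = vt),
    "TI/TTot" = data.frame(t = tb, value = ti / ttot),
    "VT/TI"   = data.frame(t = tb, value = vt / ti),
    "f/VT"    = data.frame(t = tb, value = (60 / ttot) / vt),
    "RR"      = data.frame(t = r_peaks[-1], value = rr)
  )
  structure(series, class = "breath_series_set")
}

#' Canonical ordering of the eight variability series
#' @return Character vector of series names.
#' @export
series_names <- function() {
  c("TI", "TE", "TTot", "VT", "TI/TTot", "VT/TI", "f/VT", "RR")
}

#' Extract the eight variability series from a subject record
#'
#' Convenience wrapper: [preprocess_signal()] (detrending disabled by default
#' for flow, which is already zero-mean by construction of breathing),
#' [segment_breaths()] and [build_series()].
#'
#' @param record a `subject_record` (see [generate_cohort()]).
#' @param outlier_z,detrend passed to [preprocess_signal()].
#' @param noise_floor_frac,min_breaths passed to [segment_breaths()].
#' @return A `breath_series_set`.
#' @export
extract_series <- function(record, outlier_z = 5, detrend = TRUE,
                           noise_floor_frac = 0.1, min_breaths = 10) {
  flow <- preprocess_signal(record$flow, outlier_z = outlier_z,
                            detrend = detrend)
  br <- segment_breaths(flow, record$fs, noise_floor_frac = noise_floor_frac,
                        min_breaths = min_breaths,
                        subject_id = record$subject_id %||% "<unknown>")
  build_series(flow, record$fs, br, record$r_peaks)
}

#' Extract series for every subject of a cohort
#' @param cohort list of `subject_record`s.
#' @param ... passed to [extract_series()].
#' @return Named list of `breath_series_set`s, with a `groups` attribute.
#' @export
extract_cohort <- function(cohort, ...) {
  out <- lapply(cohort, extract_series, ...)
  attr(out, "groups") <- vapply(cohort, function(r) r$group, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
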