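#' Per-group parameter set for the synthetic cohort generator
#'
#' Describes the breath-period process, tidal-volume process, flow noise and the
#' RR-interval process of one outcome group. All durations are in seconds, the
#' tidal-volume scale is in arbitrary flow x s units (litres if flow is L/s).
#'
#' The breath period of breath \eqn{k} starting at time \eqn{t_k} is
#' \deqn{TTot_k = \mu + a \sin(2\pi f_m t_k + \phi) + \epsilon_k,}
#' with \eqn{\epsilon_k} white Gaussian jitter; the subject-level modulation
#' amplitude \eqn{a} is drawn uniformly from `mod_amp_range` and the phase
#' \eqn{\phi} uniformly from \eqn{[0, 2\pi)}. The instantaneous RR interval is
#' the group mean plus a low-frequency sinusoid, a component locked to the
#' concurrent breath phase (respiratory sinus arrhythmia) and white jitter.
#'
#' @param mean_ttot mean breath period (s).
#' @param ti_frac inspiratory fraction TI/TTot of each breath.
#' @param mod_amp_range range (2-vector, s) of the subject-level sinusoidal
#'   breath-period modulation amplitude.
#' @param mod_freq breath-period modulation frequency (Hz): a single value, or
#'   a range (2-vector) from which each subject's frequency is drawn uniformly.
#'   Keep below 0.2 Hz so event series stay band-limited at the 2 Hz analysis
#'   rate.
#' @param ttot_jitter_sd SD (s) of white breath-to-breath period jitter.
#' @param ttot_jitter_df degrees of freedom of the (scaled Student-t) jitter
#'   distribution; `Inf` gives Gaussian jitter, small values give heavy tails
#'   at the same SD.
#' @param sigh_prob per-breath probability of a sigh-type prolonged breath.
#' @param sigh_range range (s) of the uniform prolongation added to a sigh
#'   breath's period.
#' @param vt_mean,vt_sd mean and breath-to-breath SD of tidal volume (flow x s).
#' @param mean_rr mean RR interval (s).
#' @param rr_lf_amp,rr_lf_freq amplitude (s) and frequency (Hz) of the
#'   low-frequency RR modulation.
#' @param rr_hf_amp amplitude (s) of the respiration-locked RR modulation.
#' @param rr_jitter_sd SD (s) of white beat-to-beat jitter.
#' @param noise_sd SD of additive white Gaussian noise on the flow signal
#'   (flow units).
#' @return A list of class `group_params`.
#' @export
group_params <- function(mean_ttot = 4, ti_frac = 0.4,
                         mod_amp_range = c(0.1, 0.3), mod_freq = 0.05,
                         ttot_jitter_sd = 0.1, ttot_jitter_df = Inf,
                         sigh_prob = 0, sigh_range = c(0.4, 1.0),
                         vt_mean = 0.5, vt_sd = 0.04,
                         mean_rr = 0.85, rr_lf_amp = 0.03, rr_lf_freq = 0.09,
                         rr_hf_amp = 0.03, rr_jitter_sd = 0.01,
                         noise_sd = 0.01) {
  p <- list(mean_ttot = mean_ttot, ti_frac = ti_frac,
            mod_amp_range = mod_amp_range, mod_freq = mod_freq,
            ttot_jitter_sd = ttot_jitter_sd, ttot_jitter_df = ttot_jitter_df,
            sigh_prob = sigh_prob, sigh_range = sigh_range,
            vt_mean = vt_mean, vt_sd = vt_sd,
            mean_rr = mean_rr, rr_lf_amp = rr_lf_amp, rr_lf_freq = rr_lf_freq,
            rr_hf_amp = rr_hf_amp, rr_jitter_sd = rr_jitter_sd,
            noise_sd = noise_sd)
  stopifnot(mean_ttot > 0, ti_frac > 0, ti_frac < 1, mean_rr > 0,
            length(mod_amp_range) == 2, all(mod_amp_range >= 0),
            length(mod_freq) %in% 1:2, all(mod_freq > 0),
            ttot_jitter_sd >= 0, ttot_jitter_df > 2,
            sigh_prob >= 0, sigh_prob < 1, length(sigh_range) == 2,
            all(sigh_range >= 0),
            vt_sd >= 0, rr_lf_amp >= 0, rr_hf_amp >= 0,
            rr_jitter_sd >= 0, noise_sd >= 0, vt_mean > 0)
  class(p) <- "group_params"
  p
}

#' Default group parameter sets emulating the three weaning-outcome groups
#'
#' The groups share mean breath period, tidal volume and mean RR; they differ in
#' the *variability spectrum* of the breath-period process: the successful group
#' (SG) has weak modulation, the failure group (FG) strong slow modulation and
#' the reintubated group (RG) strong fast modulation. The discriminative
#' structure therefore lives in the spectral/wavelet descriptors of the event
#' series rather than in their means.
#'
#' @return Named list of [group_params()] for `SG`, `FG`, `RG`.
#' @export
default_group_params <- function() {
  list(
    SG = group_params(mod_amp_range = c(0.05, 0.15), mod_freq = 0.05,
                      ttot_jitter_sd = 0.08),
    FG = group_params(mod_amp_range = c(0.5, 0.9), mod_freq = 0.02,
                      ttot_jitter_sd = 0.10),
    RG = group_params(mod_amp_range = c(0.35, 0.65), mod_freq = 0.12,
                      ttot_jitter_sd = 0.10)
  )
}

#' Specification of a synthetic cohort
#'
#' @param n_per_group named integer vector, subjects per group label; names
#'   become the group labels (typically `SG`, `FG`, `RG`).
#' @param record_duration record length in seconds (> 60).
#' @param fs flow sampling rate in Hz.
#' @param seed master seed; per-subject streams are derived by a fixed counter
#'   scheme (`seed * 1009 + group_index * 10^5 + subject_index`, mod 2^31) so
#'   changing one group's size never reshuffles other subjects.
#' @param group_params named list of [group_params()], one per group label.
#' @param ttot_floor lower truncation bound (s) for drawn breath durations.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(SG = 10, FG = 10, RG = 10),
                        record_duration = 1800, fs = 250, seed = 1,
                        group_params = default_group_params(),
                        ttot_floor = 0.5) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    stop("n_per_group must be a named vector of group sizes")
  if (!all(names(n_per_group) %in% names(group_params)))
    stop("every group label needs an entry in group_params")
  stopifnot(all(n_per_group >= 2), record_duration > 60, fs > 0,
            ttot_floor > 0)
  structure(list(n_per_group = n_per_group,
                 record_duration = record_duration, fs = fs, seed = seed,
                 group_params = group_params, ttot_floor = ttot_floor),
            class = "cohort_spec")
}

#' Two-group cohort with a fast breath-to-breath variability difference
#'
#' Canonical parameter-recovery experiment: two groups that share the mean
#' breathing pattern and a strong, subject-varying slow breath-period
#' modulation (the nuisance), and differ only in the fast breath-to-breath
#' jitter of the period process — group `FAST` has twice the jitter SD and
#' heavy (Student-t, df = 3) tails, i.e. occasional single-breath
#' irregularities. After 2 Hz resampling this difference is expressed in the
#' finest detail levels of the wavelet decomposition, so Q-index selection
#' should mark low-level detail blocks for the period-derived series (TTot,
#' f/VT), while the shared slow modulation confounds the approximation blocks
#' and the global spectral descriptors.
#'
#' @param n_per_group subjects per group.
#' @param record_duration,fs record length (s) and flow sampling rate (Hz).
#' @param seed master seed.
#' @return A [cohort_spec()] with groups `BASE` and `FAST`.
#' @export
injection_cohort_spec <- function(n_per_group = 30, record_duration = 360,
                                  fs = 50, seed = 1) {
  shared <- list(mean_ttot = 2.4, mod_amp_range = c(0.2, 1.2),
                 mod_freq = c(0.015, 0.04), vt_sd = 0.002, noise_sd = 0.002)
  base <- do.call(group_params, c(shared, list(ttot_jitter_sd = 0.08)))
  fast <- do.call(group_params, c(shared, list(ttot_jitter_sd = 0.16,
                                               ttot_jitter_df = 3)))
  cohort_spec(n_per_group = c(BASE = n_per_group, FAST = n_per_group),
              record_duration = record_duration, fs = fs, seed = seed,
              group_params = list(BASE = base, FAST = fast),
              ttot_floor = 0.6)
}

## deterministic per-subject seed, kept below 2^31
subject_seed <- function(master, group_index, subject_index) {
  as.integer((as.numeric(master) * 1009 + group_index * 1e5 + subject_index) %%
               2147483647)
}

#' Generate one synthetic subject record
#'
#' Flow is a concatenation of breath cycles: inspiration is a positive half-sine
#' of duration TI_k, expiration a negative half-sine of duration TE_k, with the
#' inspiratory amplitude set so the inspiratory integral equals the drawn tidal
#' volume VT_k. R-peaks are produced by stepping an instantaneous RR process
#' (low-frequency sinusoid + breath-phase-locked component + white jitter).
#'
#' @param gp a [group_params()] object.
#' @param duration record length (s).
#' @param fs sampling rate (Hz).
#' @param seed integer seed for this subject's stream.
#' @param ttot_floor truncation floor (s) for breath durations.
#' @return List of class `subject_record` with elements `flow` (numeric),
#'   `fs`, `r_peaks` (seconds), `group`, `subject_id` and `truth` (the drawn
#'   per-breath onsets, TI, TE and VT, for round-trip validation).
#' @export
generate_subject <- function(gp, duration, fs, seed, ttot_floor = 0.5) {
  stopifnot(inherits(gp, "group_params"), duration > 0, fs > 0)
  set.seed(seed)
  mod_amp <- stats::runif(1, gp$mod_amp_range[1], gp$mod_amp_range[2])
  mod_freq <- if (length(gp$mod_freq) == 2)
    stats::runif(1, gp$mod_freq[1], gp$mod_freq[2]) else gp$mod_freq
  mod_phase <- stats::runif(1, 0, 2 * pi)

  ## ---- breath-period process ------------------------------------------------
  n_max <- ceiling(duration / ttot_floor) + 2L
  onset <- 0
  onsets <- ti <- te <- vt <- numeric(0)
  n_clipped <- 0L
  while (onset < duration) {
    jit <- if (is.finite(gp$ttot_jitter_df)) {
      df <- gp$ttot_jitter_df
      gp$ttot_jitter_sd * stats::rt(1, df) / sqrt(df / (df - 2))
    } else stats::rnorm(1, 0, gp$ttot_jitter_sd)
    tt <- gp$mean_ttot + mod_amp * sin(2 * pi * mod_freq * onset + mod_phase) +
      jit
    if (gp$sigh_prob > 0 && stats::runif(1) < gp$sigh_prob)
      tt <- tt + stats::runif(1, gp$sigh_range[1], gp$sigh_range[2])
    if (tt < ttot_floor) {
      tt <- ttot_floor
      n_clipped <- n_clipped + 1L
    }
    v <- stats::rnorm(1, gp$vt_mean, gp$vt_sd)
    if (v < 0.05 * gp$vt_mean) v <- 0.05 * gp$vt_mean
    onsets <- c(onsets, onset)
    ti <- c(ti, gp$ti_frac * tt)
    te <- c(te, (1 - gp$ti_frac) * tt)
    vt <- c(vt, v)
    onset <- onset + tt
    if (length(onsets) > n_max) stop("breath process runaway")
  }
  if (n_clipped > 0)
    message(sprintf("generate_subject: %d breath durations clipped at floor %.2f s",
                    n_clipped, ttot_floor))
  ## drop the trailing breath that would overrun the record
  keep <- (onsets + ti + te) <= duration + 1e-9
  keep[length(keep)] <- keep[length(keep)] && TRUE
  onsets <- onsets[keep]; ti <- ti[keep]; te <- te[keep]; vt <- vt[keep]

  ## ---- flow waveform --------------------------------------------------------
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  k <- findInterval(t, onsets)
  flow <- numeric(n)
  inb <- k >= 1
  tk <- t[inb] - onsets[k[inb]]
  tik <- ti[k[inb]]; tek <- te[k[inb]]; vtk <- vt[k[inb]]
  insp <- tk < tik
  amp_i <- vtk * pi / (2 * tik)
  amp_e <- vtk * pi / (2 * tek)
  val <- numeric(sum(inb))
  val[insp] <- (amp_i * sin(pi * tk / tik))[insp]
  expi <- !insp & tk < (tik + tek)
  val[expi] <- (-amp_e * sin(pi * (tk - tik) / tek))[expi]
  flow[inb] <- val
  if (gp$noise_sd > 0) flow <- flow + stats::rnorm(n, 0, gp$noise_sd)

  ## ---- R-peaks by stepping the instantaneous RR process --------------------
  breath_phase <- function(tt) {
    kk <- findInterval(tt, onsets)
    kk[kk < 1] <- 1L
    ph <- (tt - onsets[kk]) / (ti[kk] + te[kk])
    2 * pi * pmin(ph, 1)
  }
  peaks <- numeric(ceiling(duration / max(gp$mean_rr / 4, 0.1)) + 2L)
  np <- 1L
  peaks[1L] <- 0
  tcur <- 0
  repeat {
    rr <- gp$mean_rr +
      gp$rr_lf_amp * sin(2 * pi * gp$rr_lf_freq * tcur) +
      gp$rr_hf_amp * sin(breath_phase(tcur)) +
      if (gp$rr_jitter_sd > 0) stats::rnorm(1, 0, gp$rr_jitter_sd) else 0
    rr <- max(rr, 0.25)
    tcur <- tcur + rr
    if (tcur > duration) break
    np <- np + 1L
    peaks[np] <- tcur
  }
  r_peaks <- peaks[seq_len(np)]

  structure(list(flow = flow, fs = fs, r_peaks = r_peaks,
                 duration = duration,
                 truth = data.frame(onset = onsets, ti = ti, te = te, vt = vt)),
            class = "subject_record")
}

#' Generate a synthetic cohort
#'
#' Deterministic given the spec (including its seed): each subject draws from an
#' independent stream derived from the master seed by a fixed counter scheme.
#'
#' @param spec a [cohort_spec()].
#' @return List of `subject_record` objects with `subject_id` and `group` set.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   n_per_group = c(SG = 2, FG = 2, RG = 2), record_duration = 120, fs = 50))
#' length(cohort)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list()
  for (gi in seq_along(spec$n_per_group)) {
    g <- names(spec$n_per_group)[gi]
    gp <- spec$group_params[[g]]
    for (si in seq_len(spec$n_per_group[[gi]])) {
      rec <- generate_subject(gp, spec$record_duration, spec$fs,
                              seed = subject_seed(spec$seed, gi, si),
                              ttot_floor = spec$ttot_floor)
      rec$subject_id <- sprintf("%s%03d", g, si)
      rec$group <- g
      out[[rec$subject_id]] <- rec
    }
  }
  out
}

#' Write / read a cohort as plain-text signal files
#'
#' One tab-separated flow file (`time`, `flow`) and one R-peak file (one event
#' time per line) per subject, plus a `manifest.tsv` (subject_id, group, paths).
#'
#' @param cohort list of `subject_record`s from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(subject_id = character(0), group = character(0),
                    flow_file = character(0), rpeak_file = character(0),
                    fs = numeric(0))
  for (rec in cohort) {
    ff <- paste0(rec$subject_id, "_flow.tsv")
    rf <- paste0(rec$subject_id, "_rpeaks.txt")
    n <- length(rec$flow)
    utils::write.table(
      data.frame(time = (seq_len(n) - 1) / rec$fs, flow = rec$flow),
      file.path(dir, ff), sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(format(rec$r_peaks, digits = 10, trim = TRUE,
                      scientific = FALSE), file.path(dir, rf))
    man <- rbind(man, data.frame(subject_id = rec$subject_id,
                                 group = rec$group, flow_file = ff,
                                 rpeak_file = rf, fs = rec$fs))
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"))
  out <- list()
  for (i in seq_len(nrow(man))) {
    fl <- utils::read.delim(file.path(dir, man$flow_file[i]))
    rp <- as.numeric(readLines(file.path(dir, man$rpeak_file[i])))
    rec <- structure(list(flow = fl$flow, fs = man$fs[i], r_peaks = rp,
                          duration = length(fl$flow) / man$fs[i],
                          subject_id = man$subject_id[i],
                          group = man$group[i]),
                     class = "subject_record")
    out[[rec$subject_id]] <- rec
  }
  out
}
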