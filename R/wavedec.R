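## Wavelet filter bank: catalog loading, multilevel DWT/IDWT with symmetric
## extension, mother-wavelet selection by reconstruction MSE, and the
## 640-column coefficient-statistics feature table (Dataset2).

.ww <- new.env(parent = emptyenv())

load_filter_tables <- function() {
  if (!is.null(.ww$filters)) return(invisible())
  files <- c("wavelet_filters_db.tsv", "wavelet_filters_symcoif.tsv",
             "wavelet_filters_bior.tsv")
  rows <- do.call(rbind, lapply(files, function(f) {
    path <- system.file("extdata", f, package = "weanwave")
    if (path == "") path <- file.path("inst", "extdata", f)
    utils::read.delim(path, colClasses = "character")
  }))
  filters <- list()
  for (i in seq_len(nrow(rows))) {
    dec_lo <- as.numeric(strsplit(rows$dec_lo[i], ",")[[1]])
    rec_lo <- if (rows$rec_lo[i] == ".") rev(dec_lo) else
      as.numeric(strsplit(rows$rec_lo[i], ",")[[1]])
    L <- length(dec_lo)
    k <- seq_len(L) - 1
    filters[[rows$name[i]]] <- list(
      name = rows$name[i], family = rows$family[i], length = L,
      dec_lo = dec_lo,
      dec_hi = (-1)^(k + 1) * rec_lo,
      rec_lo = rec_lo,
      rec_hi = (-1)^k * dec_lo)
  }
  .ww$filters <- filters
  invisible()
}

#' The wavelet catalog
#'
#' Candidate mother wavelets: Daubechies 1-45, Coiflets 1-5, Symlets 1-29 and
#' the spline-biorthogonal family (1.1, 1.3, 1.5, 2.2, 2.4, 2.6, 2.8, 3.1,
#' 3.3, 3.5, 3.7, 3.9, 4.4, 5.5, 6.8).
#'
#' @return Character vector of wavelet identifiers.
#' @export
wavelet_catalog <- function() {
  load_filter_tables()
  names(.ww$filters)
}

#' Analysis/synthesis filter quadruple of a catalog wavelet
#'
#' @param name wavelet identifier, e.g. `"bior2.4"` or `"db4"`.
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`, `length`.
#' @export
wavelet_filters <- function(name) {
  load_filter_tables()
  f <- .ww$filters[[name]]
  if (is.null(f)) stop("unknown wavelet id: ", name)
  f
}

## linear convolution (full), small helper kept explicit for clarity
conv_full <- function(x, h) {
  if (length(x) >= 64)
    stats::convolve(x, rev(h), type = "open")
  else {
    n <- length(x); L <- length(h)
    out <- numeric(n + L - 1)
    for (k in seq_len(L)) out[k:(k + n - 1)] <- out[k:(k + n - 1)] + h[k] * x
    out
  }
}

## symmetric (half-point) extension by L-1 samples each side
sym_ext <- function(x, L) {
  n <- length(x)
  if (n < L - 1) stop("signal too short for this filter")
  e <- L - 1
  if (e == 0) return(x)
  c(rev(x[seq_len(e)]), x, rev(x[(n - e + 1):n]))
}

## one analysis step: returns approximation and detail coefficient vectors
dwt_step <- function(x, w) {
  L <- w$length
  n <- length(x)
  ext <- sym_ext(x, L)
  nc <- floor((n + L - 1) / 2)
  idx <- seq(L + 1, by = 2, length.out = nc)
  list(a = conv_full(ext, w$dec_lo)[idx],
       d = conv_full(ext, w$dec_hi)[idx])
}

## one synthesis step: inverse of dwt_step, trimmed to out_len
idwt_step <- function(a, d, w, out_len) {
  L <- w$length
  up <- function(c) {
    u <- numeric(2 * length(c))
    u[seq(1, length(u), by = 2)] <- c
    u
  }
  rec <- conv_full(up(a), w$rec_lo) + conv_full(up(d), w$rec_hi)
  rec[(L - 1):(L - 2 + out_len)]
}

#' Multilevel discrete wavelet transform
#'
#' Cascade analysis filter bank with down-sampling by two per level and
#' symmetric (half-point) boundary extension. The approximation output of
#' *every* level is retained alongside the detail output.
#'
#' @param x numeric vector or `resampled_series`; length must be at least
#'   `2^levels`.
#' @param wavelet catalog wavelet identifier.
#' @param levels number of decomposition levels J.
#' @return Object of class `wavelet_decomposition`: list with `wavelet`,
#'   `levels`, `n` and `coefficients`, a list with entries `AC1..ACJ` and
#'   `DC1..DCJ`.
#' @export
dwt_decompose <- function(x, wavelet, levels = 8) {
  if (inherits(x, "resampled_series")) x <- x$values
  if (length(x) < 2^levels)
    stop(sprintf("dwt_decompose: need at least %d samples for %d levels, got %d",
                 2^levels, levels, length(x)))
  w <- wavelet_filters(wavelet)
  coefs <- list()
  lens <- integer(levels)
  cur <- x
  for (j in seq_len(levels)) {
    lens[j] <- length(cur)
    st <- dwt_step(cur, w)
    coefs[[paste0("AC", j)]] <- st$a
    coefs[[paste0("DC", j)]] <- st$d
    cur <- st$a
  }
  structure(list(wavelet = wavelet, levels = levels, n = length(x),
                 input_lengths = lens, coefficients = coefs),
            class = "wavelet_decomposition")
}

#' Reconstruct a signal from its multilevel decomposition
#'
#' Inverts [dwt_decompose()] from the level-J approximation and the detail
#' coefficients of every level; exact to machine precision for every catalog
#' wavelet (perfect-reconstruction filter banks).
#'
#' @param dec a `wavelet_decomposition`.
#' @return Numeric vector of length `dec$n`.
#' @export
dwt_reconstruct <- function(dec) {
  w <- wavelet_filters(dec$wavelet)
  cur <- dec$coefficients[[paste0("AC", dec$levels)]]
  for (j in rev(seq_len(dec$levels))) {
    cur <- idwt_step(cur, dec$coefficients[[paste0("DC", j)]], w,
                     dec$input_lengths[j])
  }
  cur
}

#' Select the mother wavelet minimising reconstruction error
#'
#' Each catalog candidate decomposes the series to `levels` levels and
#' reconstructs it; the candidate with the smallest mean squared
#' reconstruction error wins. Ties are broken by shorter filter, then by
#' lexicographic identifier.
#'
#' @param x numeric vector, `resampled_series`, or a *list* of numeric vectors
#'   (the MSE is then averaged over the list, e.g. one entry per subject).
#' @param catalog candidate identifiers, default the full [wavelet_catalog()].
#' @param levels decomposition depth.
#' @return List with `wavelet`, `levels`, `mse`, and `all` (per-candidate MSE).
#' @export
select_wavelet <- function(x, catalog = wavelet_catalog(), levels = 8) {
  if (inherits(x, "resampled_series")) x <- x$values
  xs <- if (is.list(x)) x else list(x)
  mse <- vapply(catalog, function(wn) {
    mean(vapply(xs, function(v) {
      r <- dwt_reconstruct(dwt_decompose(v, wn, levels))
      mean((r - v)^2)
    }, numeric(1)))
  }, numeric(1))
  len <- vapply(catalog, function(wn) wavelet_filters(wn)$length, numeric(1))
  ord <- order(mse, len, catalog)
  best <- ord[1]
  list(wavelet = catalog[best], levels = levels, mse = mse[best], all = mse)
}

#' Coefficient-vector statistics
#'
#' Mean, standard deviation, skewness, kurtosis and interquartile range of a
#' coefficient vector. Skewness and excess kurtosis use the
#' bias-uncorrected moment definitions; for an (effectively) constant vector
#' both are 0 by convention.
#'
#' @param v numeric vector.
#' @return Named numeric vector `c(Xbar, S, SK, K, IQR)`.
#' @export
coeff_stats <- function(v) {
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (s2 <= .Machine$double.eps * max(1, m^2)) {
    sk <- 0; ku <- 0
  } else {
    sk <- mean((v - m)^3) / s2^1.5
    ku <- mean((v - m)^4) / s2^2 - 3
  }
  c(Xbar = m, S = stats::sd(v), SK = sk, K = ku,
    IQR = stats::IQR(v))
}

dataset2_colnames <- function(levels = 8) {
  sn <- series_names()
  stats <- c("Xbar", "S", "SK", "K", "IQR")
  cols <- character(0)
  for (s in sn)
    for (j in seq_len(levels))
      for (ct in c("CA", "CD"))
        for (st in stats)
          cols <- c(cols, sprintf("%s(%s%d-%s)", st, ct, j, s))
  cols
}

#' Dataset2: wavelet coefficient statistics per subject
#'
#' For each of the eight variability series (resampled at `rate`), each
#' decomposition level `1..levels`, each coefficient type (approximation `CA`,
#' detail `CD`) and each statistic (`Xbar`, `S`, `SK`, `K`, `IQR`):
#' one feature, e.g. `Xbar(CA7-f/VT)` — 8 x 8 x 2 x 5 = 640 columns at the
#' default depth.
#'
#' @param cohort_series named list of `breath_series_set`s with a `groups`
#'   attribute (see [extract_cohort()]).
#' @param wavelets named character vector: wavelet id per series (names =
#'   [series_names()]); a single unnamed id is recycled for all series.
#' @param rate analysis rate (Hz).
#' @param levels decomposition depth J.
#' @return data.frame: `subject_id`, `group`, then the 640 feature columns.
#' @export
dataset2 <- function(cohort_series, wavelets, rate = 2, levels = 8) {
  sn <- series_names()
  if (length(wavelets) == 1 && is.null(names(wavelets)))
    wavelets <- stats::setNames(rep(wavelets, length(sn)), sn)
  stopifnot(all(sn %in% names(wavelets)))
  groups <- attr(cohort_series, "groups")
  cols <- dataset2_colnames(levels)
  rows <- list()
  for (id in names(cohort_series)) {
    feats <- tryCatch({
      unlist(lapply(sn, function(s) {
        rs <- resample_series(cohort_series[[id]][[s]], rate)
        dec <- dwt_decompose(rs$values, wavelets[[s]], levels)
        out <- numeric(0)
        for (j in seq_len(levels))
          for (ct in c("CA", "CD")) {
            cs <- coeff_stats(dec$coefficients[[paste0(sub("C", "", ct), "C", j)]])
            ## AC stored as ACj, DC as DCj
            out <- c(out, cs)
          }
        out
      }))
    }, error = function(e) {
      message(sprintf("dataset2: dropping subject %s (%s)", id,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(feats)) rows[[id]] <- feats
  }
  if (length(rows) == 0)
    stop("dataset2: no subject could be decomposed (series too short?)")
  mat <- do.call(rbind, rows)
  colnames(mat) <- cols
  out <- data.frame(subject_id = rownames(mat),
                    group = unname(groups[rownames(mat)]),
                    check.names = FALSE)
  out[cols] <- mat
  rownames(out) <- NULL
  out
}
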