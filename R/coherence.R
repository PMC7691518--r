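#' First eigenvariate of a parcel's voxel signals
#'
#' Summarizes a voxel x sample matrix as its first principal time course,
#' the standard way a parcel's representative series is extracted before
#' connectivity estimation. The component is rescaled to unit standard
#' deviation and sign-aligned so that it correlates positively with the
#' across-voxel mean signal.
#'
#' @param voxel_signals Numeric matrix, voxels in rows, samples in columns.
#' @return Numeric vector of length `ncol(voxel_signals)`.
#' @export
#' @examples
#' v <- matrix(rnorm(5 * 100), 5, 100)
#' ev <- extract_eigenvariate(v)
extract_eigenvariate <- function(voxel_signals) {
  X <- as.matrix(voxel_signals)
  if (ncol(X) < 2) abort_data("need at least 2 samples")
  if (all(X == 0)) abort_data("all-zero voxel signals")
  Xc <- sweep(X, 1, rowMeans(X))
  if (all(abs(Xc) < .Machine$double.eps)) {
    # constant voxels: fall back to the (constant) mean series, centered
    abort_data("voxel signals have zero temporal variance")
  }
  # first right singular vector of the centered voxel x time matrix
  sv <- svd(Xc, nu = 0, nv = 1)
  ev <- drop(sv$v[, 1])
  m <- colMeans(X)
  if (sd(m) > 0 && cor(ev, m) < 0) ev <- -ev
  ev / sd(ev)
}

#' Welch magnitude-squared coherence averaged over a frequency band
#'
#' Estimates the spectral association between two series as
#' \eqn{C(f) = |S_{xy}(f)|^2 / (S_{xx}(f) S_{yy}(f))}, with auto- and
#' cross-spectra obtained by Welch segment averaging (Hann taper, mean
#' removed per segment), then averages \eqn{C(f)} over the frequency bins
#' falling inside `band`. The estimate is invariant to scaling or sign
#' flips of either input.
#'
#' @param x,y Numeric vectors of equal length.
#' @param dt Sampling interval in seconds.
#' @param band Length-2 numeric, frequency band in Hz (within (0, Nyquist]).
#' @param segment_len Welch segment length in samples; `NULL` (default)
#'   uses 128, shortened to the largest power of two giving at least four
#'   non-overlapping segments for short sessions.
#' @param overlap Fractional segment overlap in [0, 1); default 0.5.
#' @return A list with `coherence` (band-averaged MSC in [0, 1]),
#'   `n_segments` (Welch segments averaged), and `d_equiv` (equivalent
#'   number of non-overlapping segments, used for the analytic null).
#' @export
magnitude_squared_coherence <- function(x, y, dt = 0.72, band = c(0.01, 0.17),
                                        segment_len = NULL, overlap = 0.5) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) abort_param("x and y must have equal length")
  if (is.null(segment_len)) segment_len <- default_segment_len(length(x))
  if (segment_len >= length(x)) abort_param("segment_len must be shorter than the series")
  if (var(x) == 0 || var(y) == 0) abort_data("zero-variance input")
  sp <- welch_spectra(rbind(x, y), dt, segment_len, overlap, band)
  Sxy <- vapply(seq_len(sp$n_bins), function(f) {
    mean(sp$Z[1, , f] * Conj(sp$Z[2, , f]))
  }, complex(1))
  Sxx <- vapply(seq_len(sp$n_bins), function(f) mean(Mod(sp$Z[1, , f])^2), numeric(1))
  Syy <- vapply(seq_len(sp$n_bins), function(f) mean(Mod(sp$Z[2, , f])^2), numeric(1))
  C <- Mod(Sxy)^2 / (Sxx * Syy)
  list(
    coherence = min(max(mean(C), 0), 1),
    n_segments = sp$n_segments,
    d_equiv = sp$d_equiv
  )
}

# Default Welch segment length: 128 samples, shortened (as a power of two)
# for sessions too short to hold at least 4 non-overlapping segments.
default_segment_len <- function(n_samples) {
  min(128L, 2^max(2, floor(log2(n_samples / 4))))
}

# Shared Welch engine: tapered segment FFTs of a node x sample signal
# matrix, restricted to the frequency bins inside `band`.
# Returns Z[node, segment, bin].
welch_spectra <- function(signals, dt, segment_len, overlap, band) {
  signals <- as.matrix(signals)
  n <- ncol(signals)
  p <- nrow(signals)
  if (segment_len >= n) abort_param("segment_len must be shorter than the series")
  step <- max(1, floor(segment_len * (1 - overlap)))
  starts <- seq(1, n - segment_len + 1, by = step)
  k <- length(starts)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(segment_len) / (segment_len + 1))) # Hann
  nf <- floor(segment_len / 2)
  freq <- (1:nf) / (segment_len * dt)
  keep <- which(freq >= band[1] & freq <= band[2])
  if (length(keep) == 0) abort_param("band contains no frequency bins at this segment length")
  Z <- array(0 + 0i, dim = c(p, k, length(keep)))
  for (s in seq_len(k)) {
    seg <- signals[, starts[s]:(starts[s] + segment_len - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, win, `*`)
    F <- stats::mvfft(t(seg))
    Z[, s, ] <- t(F[keep + 1, , drop = FALSE])
  }
  list(
    freq = freq[keep], Z = Z, n_bins = length(keep),
    n_segments = k, d_equiv = max(1L, floor(n / segment_len))
  )
}

#' Band-averaged coherence matrix for a multi-node signal matrix
#'
#' Computes Welch magnitude-squared coherence between every pair of rows of
#' `signals`, averaged over the frequency bins in `band`. The workhorse
#' behind [daily_coherence_matrix()].
#'
#' @param signals Node x sample numeric matrix.
#' @inheritParams magnitude_squared_coherence
#' @return A list with `C` (symmetric node x node matrix, diagonal 1),
#'   `n_segments` and `d_equiv`.
#' @export
coherence_matrix <- function(signals, dt = 0.72, band = c(0.01, 0.17),
                             segment_len = NULL, overlap = 0.5) {
  signals <- as.matrix(signals)
  if (is.null(segment_len)) segment_len <- default_segment_len(ncol(signals))
  v <- apply(signals, 1, var)
  if (any(v == 0)) abort_data(sprintf("zero-variance node series (node %d)", which(v == 0)[1]))
  sp <- welch_spectra(signals, dt, segment_len, overlap, band)
  p <- nrow(signals)
  Csum <- matrix(0, p, p)
  for (f in seq_len(sp$n_bins)) {
    Zf <- matrix(sp$Z[, , f], nrow = p)
    S <- (Zf %*% Conj(t(Zf))) / sp$n_segments
    d <- Re(diag(S))
    Csum <- Csum + Mod(S)^2 / outer(d, d)
  }
  C <- Csum / sp$n_bins
  C <- pmin(pmax((C + t(C)) / 2, 0), 1)
  diag(C) <- 1
  list(C = C, n_segments = sp$n_segments, d_equiv = sp$d_equiv,
       n_bins = sp$n_bins)
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up false-discovery-rate control: rejects every hypothesis whose
#' BH-adjusted p-value is at most `q`. Thin wrapper around
#' [stats::p.adjust()] that validates its input and returns a logical mask.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param q FDR level in (0, 1).
#' @return Logical vector, `TRUE` where rejected.
#' @export
#' @examples
#' fdr_bh(c(0.001, 0.02, 0.03, 0.8), q = 0.05)
fdr_bh <- function(pvalues, q = 0.05) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0) || any(p > 1)) abort_data("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) abort_param("q must lie in (0, 1)")
  p.adjust(p, method = "BH") <= q
}

#' Analytic null p-value for band-averaged magnitude-squared coherence
#'
#' Under independence, the MSC estimated from `d` independent segments at
#' one frequency follows Beta(1, d-1), with the classic tail
#' `P(C > c) = (1 - c)^(d - 1)`. Averaging over `n_bins` frequency bins
#' preserves the mean 1/d and shrinks the variance; the null for the
#' band-averaged estimate is moment-matched as Beta(n_bins, n_bins(d-1)),
#' which reduces exactly to the single-bin form when `n_bins = 1`. Using
#' the non-overlapping equivalent segment count for `d` keeps the p-value
#' conservative under overlapping Welch estimation.
#'
#' @param coherence Band-averaged MSC value(s) in [0, 1].
#' @param d Number of (equivalent non-overlapping) segments, >= 2.
#' @param n_bins Number of frequency bins averaged over the band.
#' @return Upper-tail p-value(s).
#' @export
msc_null_pvalue <- function(coherence, d, n_bins = 1) {
  if (d < 2) abort_param("need at least 2 segments for a coherence null")
  stats::pbeta(coherence, n_bins, n_bins * (d - 1), lower.tail = FALSE)
}

#' Per-day FDR-thresholded coherence matrix
#'
#' The per-session connectivity estimator: each node series is band-limited
#' with [modwt_band_filter()], pairwise band-averaged magnitude-squared
#' coherence is estimated by Welch averaging, a per-edge p-value under the
#' independence null is computed analytically ([msc_null_pvalue()]), and
#' edges not surviving Benjamini-Hochberg FDR at level `q` are set to
#' zero.
#'
#' @param ts A daily timeseries, either a node x sample matrix or a list
#'   with elements `signals` (matrix) and `dt`.
#' @param dt Sampling interval in seconds (ignored when `ts` carries one).
#' @param scales MODWT levels retained before coherence estimation.
#' @param band Frequency band (Hz) over which coherence is averaged.
#' @param segment_len,overlap Welch parameters.
#' @param q FDR level for the per-day edge threshold; `NA` disables
#'   thresholding.
#' @return An object of class `coherence_matrix`: a list with `values`
#'   (node x node matrix, diagonal 1, sub-threshold edges 0), `day`,
#'   `qvalue_threshold`, `n_segments`, `d_equiv`, and `band`.
#' @export
daily_coherence_matrix <- function(ts, dt = 0.72, scales = 3:6,
                                   band = NULL, segment_len = NULL,
                                   overlap = 0.5, q = 0.05) {
  day <- NA_integer_
  if (is.list(ts) && !is.null(ts$signals)) {
    dt <- ts$dt
    if (!is.null(ts$day)) day <- ts$day
    signals <- as.matrix(ts$signals)
  } else {
    signals <- as.matrix(ts)
  }
  if (ncol(signals) < 64) abort_data("need at least 64 samples per session")
  if (is.null(band)) band <- modwt_band_hz(scales, dt)
  filtered <- band_filter_matrix(signals, scales)
  cm <- coherence_matrix(filtered, dt = dt, band = band,
                         segment_len = segment_len, overlap = overlap)
  C <- cm$C
  if (!is.na(q)) {
    pe <- msc_null_pvalue(edges_from_mat(C), cm$d_equiv, n_bins = cm$n_bins)
    keep <- fdr_bh(pe, q)
    vals <- edges_from_mat(C)
    vals[!keep] <- 0
    C <- mat_from_edges(vals, nrow(C), diag_value = 1)
  }
  structure(
    list(
      day = day, values = C, qvalue_threshold = q,
      n_segments = cm$n_segments, d_equiv = cm$d_equiv,
      n_bins = cm$n_bins, band = band
    ),
    class = "coherence_matrix"
  )
}

#' Coherence matrices for every session of a study
#'
#' @param sessions List of daily timeseries (see [daily_coherence_matrix()]).
#' @param ... Passed on to [daily_coherence_matrix()].
#' @return List of `coherence_matrix` objects, one per session.
#' @export
coherence_stack <- function(sessions, ...) {
  lapply(sessions, daily_coherence_matrix, ...)
}
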