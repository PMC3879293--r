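# EEG preprocessing and feature extraction: surface Laplacian referencing,
# zero-phase Butterworth band-pass, epoch extraction, one-versus-rest common
# spatial patterns with log-variance features, and Welch band-power (PSD)
# features. Filtering is delegated to the `signal` package; the Welch
# estimator is a small in-package FFT routine (see the methods vignette).

#' A set of multichannel trials
#'
#' @param trials list of channels x time numeric matrices (all the same
#'   channel count), amplitudes in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels integer class label per trial.
#' @param channel_names optional channel names.
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(trials, fs, labels, channel_names = NULL) {
  stopifnot(length(trials) >= 1L, length(labels) == length(trials), fs > 0)
  nch <- nrow(trials[[1L]])
  for (tr in trials)
    if (nrow(tr) != nch) stop("all trials must have the same channel count")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  structure(list(trials = trials, fs = fs, labels = as.integer(labels),
                 channel_names = channel_names),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %d channels, fs = %g Hz, classes: %s\n",
              length(x$trials), nrow(x$trials[[1L]]), x$fs,
              paste(sort(unique(x$labels)), collapse = " ")))
  invisible(x)
}

map_trials <- function(ts, f) {
  ts$trials <- lapply(ts$trials, f)
  ts
}

#' Surface Laplacian spatial filter
#'
#' Subtracts from each mapped channel the (equal-weight) mean of its four
#' surrounding channels, attenuating large-scale scalp potentials and
#' sharpening localized activity. Channels without an entry in
#' `neighbor_map` pass through unchanged with a warning.
#'
#' @param ts a [trial_set()].
#' @param neighbor_map named list: channel name -> character vector of
#'   exactly 4 neighbor channel names.
#' @return the filtered `trial_set`.
#' @export
surface_laplacian <- function(ts, neighbor_map) {
  ch <- ts$channel_names
  for (nm in names(neighbor_map)) {
    nbs <- neighbor_map[[nm]]
    if (length(nbs) != 4L)
      stop("channel ", nm, " must map to exactly 4 neighbors")
    if (!all(nbs %in% ch) || !(nm %in% ch))
      stop("neighbor map references unknown channel: ",
           paste(setdiff(c(nm, nbs), ch), collapse = ","))
  }
  unmapped <- setdiff(ch, names(neighbor_map))
  if (length(unmapped))
    warning("channels without neighbor map pass through unchanged: ",
            paste(unmapped, collapse = ","))
  center <- match(names(neighbor_map), ch)
  nb_idx <- lapply(neighbor_map, match, table = ch)
  map_trials(ts, function(X) {
    out <- X
    for (j in seq_along(center))
      out[center[j], ] <- X[center[j], ] - colMeans(X[nb_idx[[j]], ,
                                                      drop = FALSE])
    out
  })
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the requested final order (`order`
#' must be even: a band-pass of order `2n` comes from an order-`n`
#' prototype) and applies it forward-backward (`signal::filtfilt`) per
#' channel, so the net phase response is zero. Suitable for offline
#' analysis only.
#'
#' @param ts a [trial_set()].
#' @param low_hz,high_hz band edges, `0 < low < high < fs/2`.
#' @param order final filter order (default 6, the motor-imagery standard).
#' @return the filtered `trial_set`.
#' @export
butterworth_bandpass <- function(ts, low_hz = 5, high_hz = 30, order = 6L) {
  fs <- ts$fs
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2))
    stop("need 0 < low_hz < high_hz < fs/2")
  if (order %% 2L != 0L) stop("band-pass order must be even")
  bf <- signal::butter(order / 2L, c(low_hz, high_hz) / (fs / 2),
                       type = "pass")
  map_trials(ts, function(X)
    t(apply(X, 1L, function(row) signal::filtfilt(bf, row))))
}

#' Extract a time epoch from every trial
#'
#' Keeps samples `[round(t_start * fs), round(t_end * fs))` (half-open,
#' 0-based, seconds from trial onset) of every trial.
#'
#' @param ts a [trial_set()].
#' @param t_start_s,t_end_s epoch window in seconds.
#' @return the epoched `trial_set`.
#' @export
extract_epoch <- function(ts, t_start_s, t_end_s) {
  i0 <- round(t_start_s * ts$fs)
  i1 <- round(t_end_s * ts$fs)
  len <- ncol(ts$trials[[1L]])
  if (i0 < 0 || i1 > len || i1 <= i0)
    stop(sprintf("epoch [%g, %g) s is outside the trial (or empty)",
                 t_start_s, t_end_s))
  map_trials(ts, function(X) X[, (i0 + 1L):i1, drop = FALSE])
}

# -- common spatial patterns -------------------------------------------------

# Trace-normalized spatial covariance of one trial.
trial_cov <- function(X) {
  S <- tcrossprod(X) / ncol(X)
  S / sum(diag(S))
}

# Two-class CSP: eigenvectors of the whitened class-1 covariance; columns
# ordered by decreasing eigenvalue (first maximize class-1 variance, last
# maximize the rest's).
csp_two_class <- function(S1, S2, ridge) {
  Sc <- S1 + S2
  Sc <- Sc + ridge * sum(diag(Sc)) * diag(nrow(Sc))
  e <- eigen(Sc, symmetric = TRUE)
  if (min(e$values) < .Machine$double.eps * max(e$values) * 1e3)
    stop("composite covariance is singular; increase the ridge regularizer")
  Wh <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  ew <- eigen(Wh %*% S1 %*% Wh, symmetric = TRUE)
  list(filters = Wh %*% ew$vectors, eigenvalues = ew$values)
}

#' Fit one-versus-rest common spatial patterns
#'
#' For each class, the average trace-normalized trial covariance of that
#' class is contrasted against the average covariance of all other classes;
#' the generalized eigenproblem yields spatial filters ordered from
#' maximal-variance-for-the-class to maximal-variance-for-the-rest, of which
#' the first and last `m` are retained. Filters are concatenated across
#' classes, giving `2 m C` filters for `C` classes. Trials should already be
#' band-passed and epoch-extracted.
#'
#' @param ts a [trial_set()] with >= 2 classes and >= 2 trials per class.
#' @param m filters retained per end of the spectrum (default 3).
#' @param ridge trace-scaled ridge added to the composite covariance
#'   (default 1e-8).
#' @return an object of class `csp_model` with `filters` (channels x 2mC),
#'   per-subproblem eigenvalues, and the class list.
#' @export
fit_csp_ovr <- function(ts, m = 3L, ridge = 1e-8) {
  m <- as.integer(m)
  classes <- sort(unique(ts$labels))
  if (length(classes) < 2L) stop("need at least two classes")
  counts <- table(factor(ts$labels, levels = classes))
  if (any(counts < 2L)) stop("need at least two trials per class")
  nch <- nrow(ts$trials[[1L]])
  if (2L * m > nch) stop("2*m cannot exceed the channel count")
  covs <- lapply(ts$trials, trial_cov)
  filters <- vector("list", length(classes))
  eigenvalues <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    in_c <- ts$labels == classes[ci]
    S1 <- Reduce(`+`, covs[in_c]) / sum(in_c)
    S2 <- Reduce(`+`, covs[!in_c]) / sum(!in_c)
    fit <- csp_two_class(S1, S2, ridge)
    ev <- fit$eigenvalues
    if (max(abs(ev - 0.5)) < 0.02)
      message("class ", classes[ci],
              " vs rest: eigenvalues all near 0.5, no discriminative filter")
    keep <- c(seq_len(m), nch - m + seq_len(m))
    filters[[ci]] <- fit$filters[, keep, drop = FALSE]
    eigenvalues[[ci]] <- ev
  }
  structure(list(filters = do.call(cbind, filters),
                 eigenvalues = eigenvalues, classes = classes, m = m,
                 n_channels = nch),
            class = "csp_model")
}

#' Log-variance CSP features of one trial
#'
#' Projects the trial through the model's spatial filters and returns, per
#' filter, the log of its share of the total projected variance:
#' `f_j = log(var_j / sum_k var_k)`.
#'
#' @param model a `csp_model`.
#' @param trial a channels x time matrix.
#' @param normalize if `FALSE`, plain `log(var_j)` without the total-variance
#'   normalization.
#' @return numeric feature vector of length `2 m C`.
#' @export
csp_features <- function(model, trial, normalize = TRUE) {
  if (nrow(trial) != model$n_channels)
    stop("trial has ", nrow(trial), " channels; model expects ",
         model$n_channels)
  P <- t(model$filters) %*% trial
  v <- apply(P, 1L, stats::var)
  tot <- sum(v)
  if (tot <= 0) stop("zero total projected variance")
  if (normalize) log(v / tot) else log(v)
}

#' CSP feature matrix for a whole trial set
#'
#' @param model a `csp_model`.
#' @param ts a [trial_set()].
#' @param normalize passed to [csp_features()].
#' @return trials x features matrix.
#' @export
csp_feature_matrix <- function(model, ts, normalize = TRUE) {
  t(vapply(ts$trials, csp_features, numeric(2L * model$m *
                                              length(model$classes)),
           model = model, normalize = normalize))
}

# -- Welch band power --------------------------------------------------------

# Welch PSD of one signal: segments of `nseg` samples, 50% overlap, averaged
# periodograms. Returns power at frequencies k * fs / nseg. The default
# rectangular taper keeps on-grid band components exactly on their bin
# (segment length is matched to the requested resolution); a Hamming taper
# is available for signals with strong off-grid components.
welch_psd <- function(x, fs, nseg, taper = c("rectangular", "hamming")) {
  taper <- match.arg(taper)
  n <- length(x)
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- if (taper == "hamming")
    0.54 - 0.46 * cos(2 * pi * (seq_len(nseg) - 1L) / (nseg - 1L))
  else rep(1, nseg)
  scale <- sum(w^2) * fs
  acc <- numeric(nseg %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    sp <- abs(stats::fft(seg))^2 / scale
    acc <- acc + sp[seq_len(nseg %/% 2L + 1L)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything but DC and Nyquist
  inner <- 2:(length(psd) - if (nseg %% 2L == 0L) 1L else 0L)
  psd[inner] <- 2 * psd[inner]
  list(freq = (seq_along(psd) - 1L) * fs / nseg, psd = psd)
}

#' Welch band-power (PSD) features
#'
#' Estimates the power spectral density over the last `window_s` seconds of
#' each trial and channel (Welch's method: half-window segments with 50%
#' overlap, Hamming-tapered), and keeps the band values at
#' `band[1], band[1] + resolution_hz, ..., band[2]`. Channels are
#' concatenated, so 8 channels in the 8-30 Hz band at 2 Hz resolution give
#' a 96-dimensional vector (12 bins per channel).
#'
#' @param ts a [trial_set()].
#' @param band frequency band in Hz (default `c(8, 30)`).
#' @param resolution_hz frequency resolution (segment length is
#'   `fs / resolution_hz` samples; default 2 Hz).
#' @param window_s analysis window taken from the end of each trial
#'   (default 1 s).
#' @param taper segment taper, `"rectangular"` (default; exact for
#'   components on the resolution grid) or `"hamming"`.
#' @return trials x features matrix.
#' @export
psd_features <- function(ts, band = c(8, 30), resolution_hz = 2,
                         window_s = 1, taper = "rectangular") {
  fs <- ts$fs
  nwin <- round(window_s * fs)
  nseg <- round(fs / resolution_hz)
  if (nseg > nwin) stop("resolution too fine for the analysis window")
  freqs <- seq(band[1L], band[2L], by = resolution_hz)
  t(vapply(ts$trials, function(X) {
    if (ncol(X) < nwin)
      stop("trial shorter than the ", window_s, " s analysis window")
    tail_idx <- (ncol(X) - nwin + 1L):ncol(X)
    unlist(lapply(seq_len(nrow(X)), function(ch) {
      est <- welch_psd(X[ch, tail_idx], fs, nseg, taper = taper)
      est$psd[match(freqs, est$freq)]
    }))
  }, numeric(length(freqs) * nrow(ts$trials[[1L]]))))
}

#' Unit-length normalization and first-of-k downsampling
#'
#' `unit_normalize` scales a vector to unit Euclidean norm (rows of a
#' matrix are normalized independently). `downsample_first_of_k` keeps the
#' first element of every block of `k` consecutive elements (indices 1,
#' k+1, 2k+1, ...), the de-overlapping step for sliding-window features.
#'
#' @param x numeric vector (or matrix of row vectors) with nonzero norm.
#' @return the normalized vector/matrix.
#' @export
unit_normalize <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1L, unit_normalize)))
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot unit-normalize a zero vector")
  x / nrm
}

#' @rdname unit_normalize
#' @param s a sequence (vector, list, or matrix of rows).
#' @param k block size (default 8).
#' @export
downsample_first_of_k <- function(s, k = 8L) {
  n <- if (is.matrix(s)) nrow(s) else length(s)
  idx <- seq(1L, n, by = as.integer(k))
  if (is.matrix(s)) s[idx, , drop = FALSE] else s[idx]
}

# -- serialization -----------------------------------------------------------

#' Read and write trial sets as TSV plus a manifest
#'
#' Each trial is one TSV (rows = channels); a manifest TSV lists trial
#' files, labels, the sampling rate and channel names.
#'
#' @param ts a [trial_set()].
#' @param dir directory to write into (created if missing).
#' @return `read_trialset` returns a `trial_set`; `write_trialset` the
#'   manifest path, invisibly.
#' @export
write_trialset <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("trial_%04d.tsv", seq_along(ts$trials))
  for (i in seq_along(ts$trials))
    utils::write.table(ts$trials[[i]], file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  manifest <- data.frame(file = files, label = ts$labels,
                         fs = ts$fs,
                         channels = paste(ts$channel_names, collapse = ","))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' @rdname write_trialset
#' @export
read_trialset <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  trials <- lapply(manifest$file, function(f)
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t",
                                header = FALSE)))
  trial_set(trials, fs = manifest$fs[1L], labels = manifest$label,
            channel_names = strsplit(manifest$channels[1L], ",",
                                     fixed = TRUE)[[1L]])
}
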