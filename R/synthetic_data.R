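# Synthetic benchmarks: the three-class Gaussian triangle dataset with three
# complementary views (class means cyclically rotated around an equilateral
# triangle), and band-limited oscillatory multichannel trials with planted
# spatial patterns for testing the CSP/PSD stages.

#' Specification of the triangle benchmark
#'
#' Three two-dimensional Gaussian classes (identity covariance) whose means
#' sit on the vertices of an equilateral triangle of side `d`; `d` controls
#' the class overlap and hence the label uncertainty (the reference
#' conditions use sides 1, 2 and 3 for high, medium and low uncertainty,
#' with 150/300/500 train/validation/test samples).
#'
#' @param d triangle side length (> 0).
#' @param n_train,n_val,n_test set totals, split as evenly as possible over
#'   the three classes (remainders to the lowest class indices).
#' @param seed integer seed.
#' @return a list of class `triangle_spec`.
#' @export
triangle_spec <- function(d = 1, n_train = 150L, n_val = 300L,
                          n_test = 500L, seed = 1L) {
  stopifnot(d > 0, n_train >= 3L, n_val >= 3L, n_test >= 3L)
  structure(list(d = d, n_train = as.integer(n_train),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 seed = as.integer(seed)),
            class = "triangle_spec")
}

# Vertices of an equilateral triangle of side d, centroid at the origin,
# vertex 1 on the positive y-axis, listed in clockwise order.
triangle_vertices <- function(d) {
  r <- d / sqrt(3)
  ang <- pi / 2 - 2 * pi * (0:2) / 3
  cbind(r * cos(ang), r * sin(ang))
}

split_evenly <- function(total, groups = 3L) {
  base <- total %/% groups
  extra <- total %% groups
  base + (seq_len(groups) <= extra)
}

#' Generate the three complementary triangle views
#'
#' View 1 places class `i` at vertex `i`; views 2 and 3 advance every class
#' mean one vertex clockwise per view. All views share the same sample
#' labels, but coordinates are drawn independently per view, so each view is
#' a genuinely complementary representation: a sample deep in the overlap
#' region of one view is usually better separated in another.
#'
#' @param spec a [triangle_spec()].
#' @return a list of class `triangle_data` with elements `views` (three
#'   lists of `train`/`val`/`test` matrices), `labels` (shared
#'   `train`/`val`/`test` integer vectors), `means` (per view, a 3 x 2
#'   matrix of class means), and `spec`.
#' @export
make_triangle_views <- function(spec) {
  stopifnot(inherits(spec, "triangle_spec"))
  V <- triangle_vertices(spec$d)
  counts <- lapply(list(train = spec$n_train, val = spec$n_val,
                        test = spec$n_test), split_evenly)
  labels <- lapply(counts, function(ct) rep(1:3, times = ct))
  # class i's mean in view v is vertex ((i - 1 + v - 1) mod 3) + 1
  means <- lapply(1:3, function(v) {
    M <- V[((0:2 + v - 1L) %% 3L) + 1L, , drop = FALSE]
    rownames(M) <- paste0("class", 1:3)
    M
  })
  views <- withr::with_seed(spec$seed, {
    lapply(1:3, function(v)
      lapply(labels, function(y)
        means[[v]][y, , drop = FALSE] +
          matrix(stats::rnorm(2L * length(y)), length(y), 2L)))
  })
  structure(list(views = views, labels = labels, means = means,
                 spec = spec),
            class = "triangle_data")
}

#' @export
print.triangle_data <- function(x, ...) {
  cat(sprintf("<triangle_data> side %g, %d/%d/%d train/val/test, seed %d\n",
              x$spec$d, x$spec$n_train, x$spec$n_val, x$spec$n_test,
              x$spec$seed))
  invisible(x)
}

#' Feature-space views of triangle data for the ensemble
#'
#' @param td a `triangle_data`.
#' @param set one of `"train"`, `"val"`, `"test"`.
#' @return a list of three [feature_space_view()]s.
#' @export
triangle_fsv <- function(td, set = c("train", "val", "test")) {
  set <- match.arg(set)
  lapply(1:3, function(v)
    feature_space_view(td$views[[v]][[set]], td$labels[[set]],
                       name = paste0("view", v)))
}

#' Nearest-class-mean classifier on one triangle view
#'
#' The plug-in Bayes rule for equal spherical Gaussians; used as an
#' independent anchor for the uncertainty level of a side-`d` dataset.
#'
#' @param x feature matrix.
#' @param means 3 x 2 matrix of class means.
#' @return integer vector of predicted classes.
#' @export
nearest_mean_classify <- function(x, means) {
  d2 <- sapply(seq_len(nrow(means)), function(cc)
    rowSums(sweep(as.matrix(x), 2L, means[cc, ])^2))
  max.col(-d2, "first")
}

#' Synthetic band-limited oscillatory trials with planted spatial patterns
#'
#' Each class projects a band-limited source (white noise band-passed to
#' `band`) along its own spatial pattern, scaled so that the source variance
#' equals the class's `band_powers` entry, on top of white sensor noise.
#' The planted patterns are returned for filter-recovery tests.
#'
#' @param n_classes number of classes.
#' @param n_channels number of channels.
#' @param fs sampling rate (Hz).
#' @param duration_s trial duration (s).
#' @param spatial_patterns channels x classes matrix of linearly independent
#'   unit patterns; default: the first `n_classes` canonical basis vectors.
#' @param band_powers per-class source variance (default 10 for every
#'   class).
#' @param n_trials_per_class trials per class.
#' @param seed integer seed.
#' @param noise_sd white sensor-noise standard deviation (default 1).
#' @param band source frequency band in Hz (default `c(8, 30)`).
#' @return a [trial_set()] with the planted patterns in attribute
#'   `patterns`.
#' @export
make_synthetic_trials <- function(n_classes = 2L, n_channels = 8L, fs = 250,
                                  duration_s = 2,
                                  spatial_patterns = NULL,
                                  band_powers = rep(10, n_classes),
                                  n_trials_per_class = 20L, seed = 1L,
                                  noise_sd = 1, band = c(8, 30)) {
  n_classes <- as.integer(n_classes)
  n_channels <- as.integer(n_channels)
  if (is.null(spatial_patterns))
    spatial_patterns <- diag(n_channels)[, seq_len(n_classes), drop = FALSE]
  stopifnot(nrow(spatial_patterns) == n_channels,
            ncol(spatial_patterns) == n_classes,
            all(band_powers >= 0))
  if (qr(spatial_patterns)$rank < n_classes)
    stop("spatial patterns must be linearly independent")
  nt <- round(duration_s * fs)
  bf <- signal::butter(3, pmin(band, fs / 2 - 1) / (fs / 2), type = "pass")
  labels <- rep(seq_len(n_classes), each = n_trials_per_class)
  trials <- withr::with_seed(as.integer(seed), {
    lapply(labels, function(cls) {
      src <- signal::filtfilt(bf, stats::rnorm(nt))
      if (stats::sd(src) > 0) src <- src / stats::sd(src)
      X <- spatial_patterns[, cls] %o% (src * sqrt(band_powers[cls]))
      X + matrix(stats::rnorm(n_channels * nt, sd = noise_sd),
                 n_channels, nt)
    })
  })
  ts <- trial_set(trials, fs = fs, labels = labels)
  attr(ts, "patterns") <- spatial_patterns
  ts
}
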