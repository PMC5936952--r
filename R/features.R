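# Canonical per-electrode feature list (schema version 1). Order matters:
# persisted models index features by these names.
.electrode_feature_names <- c(
  "v_max", "v_min", "v_mean", "v_var", "skewness", "kurtosis",
  "first_stationary_idx", "max_abs_dvdt", "intensity",
  "dom_freq", "dom_freq_mag", "n_deflections")

.feature_schema_version <- 1L

#' Feature schema
#'
#' @return list with the per-electrode feature names, the full feature-vector
#'   column names (9 electrodes x 12 statistics, x/y gradients of each
#'   statistic, wavefront direction), and the schema version.
#' @export
feature_schema <- function() {
  per <- .electrode_feature_names
  list(version = .feature_schema_version,
       electrode_features = per,
       columns = c(paste0("e", rep(1:9, each = length(per)), "_", per),
                   paste0("delay_e", 1:9),
                   paste0("grad_x_", c(per, "delay")),
                   paste0("grad_y_", c(per, "delay")),
                   c("wf_angle", "wf_ux", "wf_uy")))
}

# vectorized feature computation for a duration x m voltage matrix;
# returns an m x 12 matrix (one row per electrode)
features_matrix <- function(V) {
  V <- as.matrix(V)
  n <- nrow(V); m <- ncol(V)
  stopifnot(n >= 8L)
  mu <- colMeans(V)
  Cn <- sweep(V, 2L, mu)
  v_var <- colMeans(Cn^2)
  sdv <- sqrt(v_var)
  m3 <- colMeans(Cn^3); m4 <- colMeans(Cn^4)
  skew <- ifelse(sdv > 0, m3 / sdv^3, 0)       # 0 for constant series
  kurt <- ifelse(sdv > 0, m4 / v_var^2, 0)
  v_max <- apply(V, 2L, max); v_min <- apply(V, 2L, min)
  D <- diff(V)
  max_dvdt <- apply(abs(D), 2L, max)
  intensity <- colSums(abs(V))
  # first interior local extremum, reported as 0-based offset into the window
  P <- D[-nrow(D), , drop = FALSE] * D[-1L, , drop = FALSE]
  fsi <- vapply(seq_len(m), function(k) {
    w <- which(P[, k] < 0)
    if (length(w)) w[1] else 0L
  }, integer(1))
  # discrete-Fourier magnitudes at nonzero frequencies (cycles per window)
  Fm <- Mod(stats::mvfft(Cn))
  ks <- 2:(n %/% 2 + 1)
  sub <- Fm[ks, , drop = FALSE]
  dom_idx <- apply(sub, 2L, which.max)
  dom_mag <- sub[cbind(dom_idx, seq_len(m))]
  dom_freq <- ifelse(dom_mag > 0, dom_idx, 0L)
  # activations: contiguous runs with |V| at or above 25% of the window max
  ndef <- vapply(seq_len(m), function(k) {
    a <- abs(V[, k]); thr <- 0.25 * max(a)
    if (thr == 0) return(0L)
    r <- rle(a >= thr)
    sum(r$values)
  }, integer(1))
  out <- cbind(v_max, v_min, v_mean = mu, v_var, skewness = skew,
               kurtosis = kurt, first_stationary_idx = fsi,
               max_abs_dvdt = max_dvdt, intensity,
               dom_freq = as.numeric(dom_freq), dom_freq_mag = dom_mag,
               n_deflections = as.numeric(ndef))
  colnames(out) <- .electrode_feature_names
  out
}

#' Waveform statistics of one electrogram series
#'
#' Computes the canonical 12 per-electrode statistics on the raw window:
#' extremes, mean, variance, standardized skewness and kurtosis (defined as 0
#' for a constant series), the 0-based index of the first interior local
#' extremum, the maximum one-step voltage change, the signal intensity
#' (sum of |V|), the dominant nonzero discrete-Fourier frequency (in cycles
#' per window) and its magnitude, and the number of threshold-crossing
#' activations (runs with |V| >= 25% of the window maximum).
#'
#' @param series numeric voltage series, length >= 8.
#' @return named numeric vector of length 12.
#' @export
#' @examples
#' electrode_features(sin(2 * pi * 2 * (0:119) / 120))["dom_freq"]  # 2
electrode_features <- function(series) {
  drop(features_matrix(matrix(series, ncol = 1)))
}

#' Cross-probe feature gradients
#'
#' For every scalar electrode statistic, the mean finite-difference gradient
#' along x over the six x-adjacent electrode pairs, and along y over the six
#' y-adjacent pairs, normalized by the 3-cell electrode spacing so gradients
#' are per cell. Averaging over all parallel pairs damps the local
#' zig-zagging of discrete wavefronts.
#'
#' @param fmat 9 x 12 matrix of per-electrode statistics in multiprobe
#'   electrode order (row-major grid, see [make_multiprobe()]).
#' @return named numeric vector `grad_x_*`, `grad_y_*` (length 24).
#' @export
feature_gradients <- function(fmat) {
  stopifnot(nrow(fmat) == 9L)
  left <- c(1, 2, 4, 5, 7, 8); bottom <- 1:6
  gx <- colMeans(fmat[left + 1L, , drop = FALSE] -
                 fmat[left, , drop = FALSE]) / 3
  gy <- colMeans(fmat[bottom + 3L, , drop = FALSE] -
                 fmat[bottom, , drop = FALSE]) / 3
  c(setNames(gx, paste0("grad_x_", colnames(fmat))),
    setNames(gy, paste0("grad_y_", colnames(fmat))))
}

#' Activation times across a multiprobe recording
#'
#' The activation time of an electrode is the first step (0-based) at which
#' its voltage magnitude reaches 25% of that electrode's window maximum;
#' `NA` for an all-zero series.
#'
#' @param V duration x 9 voltage matrix.
#' @param frac threshold fraction of the per-electrode window max (default
#'   0.25).
#' @return numeric vector of 9 activation times.
#' @export
activation_times <- function(V, frac = 0.25) {
  vapply(seq_len(ncol(V)), function(k) {
    a <- abs(V[, k]); thr <- frac * max(a)
    if (thr == 0) return(NA_real_)
    which(a >= thr)[1] - 1
  }, numeric(1))
}

#' Relative activation delays across a multiprobe recording
#'
#' The delay of each electrode relative to the centre electrode, estimated
#' as the lag maximizing the cross-correlation of the two series over
#' `-max_lag..max_lag` steps. Cross-correlation uses every wavefront
#' crossing in the window, which makes the relative timing far more robust
#' to local zig-zag and fractionation than any single threshold crossing.
#'
#' @param V duration x 9 voltage matrix in multiprobe electrode order.
#' @param max_lag lag search half-width in steps (default 15; the grid spans
#'   6 cells, and conduction takes at most a few steps per cell).
#' @return numeric vector of 9 signed delays (steps; positive = later than
#'   the centre electrode). `NA` for an all-zero electrode.
#' @export
relative_delays <- function(V, max_lag = 15L) {
  n <- nrow(V)
  ref <- V[, 5] - mean(V[, 5])
  lags <- (-max_lag):max_lag
  vapply(seq_len(ncol(V)), function(k) {
    v <- V[, k] - mean(V[, k])
    if (all(v == 0) || all(ref == 0)) return(NA_real_)
    cc <- vapply(lags, function(l) {
      if (l >= 0) sum(ref[1:(n - l)] * v[(1 + l):n])
      else sum(ref[(1 - l):n] * v[1:(n + l)])
    }, numeric(1))
    as.numeric(lags[which.max(cc)])
  }, numeric(1))
}

#' Wavefront direction from relative activation times
#'
#' Least-squares plane fit `t(x, y) = a x + b y + c` over the electrode
#' offsets; the propagation direction is the unit vector along `(a, b)`
#' (the wave moves towards later activation).
#'
#' @param times 9 activation times (NAs allowed; at least 3 finite values
#'   required).
#' @param offsets 9 x 2 matrix of electrode (dx, dy) offsets; default the
#'   standard multiprobe grid.
#' @return list with `angle` (radians, `atan2(b, a)`), `ux`, `uy` and
#'   `defined` (FALSE when the fit is degenerate, e.g. simultaneous arrival).
#' @export
wavefront_direction <- function(times, offsets = NULL) {
  if (is.null(offsets)) {
    offs <- c(-3, 0, 3)
    g <- expand.grid(dx = offs, dy = offs)
    offsets <- cbind(g$dx, g$dy)
  }
  ok <- is.finite(times)
  undef <- list(angle = NA_real_, ux = 0, uy = 0, defined = FALSE)
  if (sum(ok) < 3L) return(undef)
  fit <- lsfit(offsets[ok, , drop = FALSE], times[ok])
  a <- fit$coefficients[2]; b <- fit$coefficients[3]
  nrm <- sqrt(a^2 + b^2)
  if (!is.finite(nrm) || nrm < 1e-12) return(undef)
  list(angle = unname(atan2(b, a)), ux = unname(a / nrm),
       uy = unname(b / nrm), defined = TRUE)
}

#' Full feature vector of a multiprobe recording
#'
#' Concatenates the 12 per-electrode statistics of all 9 electrodes, the
#' cross-correlation delay of each electrode relative to the grid centre,
#' the x/y gradients of each statistic and of the delay field across the
#' grid, and the wavefront direction (angle and unit-vector components;
#' zero vector when undefined) fitted to the delays.
#'
#' @param V duration x 9 voltage matrix in multiprobe electrode order.
#' @return named numeric vector matching `feature_schema()$columns`
#'   (length 146).
#' @export
feature_vector <- function(V) {
  fmat <- features_matrix(V)
  delays <- relative_delays(V)
  fmat2 <- cbind(fmat, delay = ifelse(is.finite(delays), delays, 0))
  per <- as.vector(t(fmat))
  names(per) <- paste0("e", rep(1:9, each = ncol(fmat)), "_", colnames(fmat))
  wf <- wavefront_direction(delays)
  ang <- if (wf$defined) wf$angle else 0
  c(per, setNames(fmat2[, "delay"], paste0("delay_e", 1:9)),
    feature_gradients(fmat2),
    wf_angle = ang, wf_ux = wf$ux, wf_uy = wf$uy)
}

#' Build a vector feature map
#'
#' Aggregates a feature over many recordings by the probe's displacement from
#' the driver centre: the map holds the per-bin mean and sample count on an
#' integer (dx, dy) grid.
#'
#' @param samples data frame with columns `dx`, `dy` (displacement of the
#'   probe centre from the driver centre, in cells) and `value`.
#' @param feature name of the mapped feature (metadata).
#' @return object of class `vfm`: `mean` and `count` matrices with
#'   dimnames giving the displacement bins (empty bins have count 0 and
#'   `NA` mean).
#' @export
build_vfm <- function(samples, feature = "feature") {
  stopifnot(nrow(samples) >= 1L)
  bx <- round(samples$dx); by <- round(samples$dy)
  xs <- seq(min(bx), max(bx)); ys <- seq(min(by), max(by))
  cnt <- matrix(0L, length(xs), length(ys), dimnames = list(xs, ys))
  sm <- matrix(0, length(xs), length(ys), dimnames = list(xs, ys))
  ix <- match(bx, xs); iy <- match(by, ys)
  for (k in seq_along(ix)) {
    cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1L
    sm[ix[k], iy[k]] <- sm[ix[k], iy[k]] + samples$value[k]
  }
  mean <- ifelse(cnt > 0, sm / pmax(cnt, 1L), NA_real_)
  structure(list(feature = feature, mean = mean, count = cnt),
            class = "vfm")
}

#' Fold a vector feature map across both axes
#'
#' Averages the four mirror bins (+/-dx, +/-dy), weighting by bin counts, so
#' the folded map is symmetric across the X- and Y-axes. A map built from
#' symmetric samples is a fixed point of the fold.
#'
#' @param vfm a [build_vfm()] result.
#' @return a `vfm` on the same grid.
#' @export
fold_vfm <- function(vfm) {
  xs <- as.integer(rownames(vfm$mean)); ys <- as.integer(colnames(vfm$mean))
  m <- vfm$mean; cnt <- vfm$count
  fm <- m; fc <- cnt
  for (i in seq_along(xs)) for (j in seq_along(ys)) {
    mi <- match(-xs[i], xs); mj <- match(-ys[j], ys)
    ii <- c(i, if (!is.na(mi)) mi else NULL)
    jj <- c(j, if (!is.na(mj)) mj else NULL)
    cells <- unique(expand.grid(ii, jj))
    cs <- cnt[as.matrix(cells)]
    ms <- m[as.matrix(cells)]
    tot <- sum(cs)
    fc[i, j] <- tot
    fm[i, j] <- if (tot > 0) sum(ms[cs > 0] * cs[cs > 0]) / tot else NA_real_
  }
  structure(list(feature = vfm$feature, mean = fm, count = fc),
            class = "vfm")
}

#' @export
print.vfm <- function(x, ...) {
  cat(sprintf("<vfm> %s: %d x %d bins, %d samples\n", x$feature,
              nrow(x$mean), ncol(x$mean), sum(x$count)))
  invisible(x)
}

#' Export a vector feature map as a CSV grid
#'
#' @param vfm a `vfm`.
#' @param path output path; mean grid is written with dx as rows.
#' @return `path`, invisibly.
#' @export
write_vfm_csv <- function(vfm, path) {
  write.csv(vfm$mean, path)
  invisible(path)
}
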