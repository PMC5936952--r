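#' Construct a 3 x 3 multiprobe
#'
#' Nine unipolar point electrodes on a 3 x 3 grid with nearest-neighbour
#' spacing of 3 cells, spanning a 7 x 7 cell region centred on `centre`:
#' the geometry of a multi-contact mapping catheter. Electrode order is
#' row-major in the offsets \{-3, 0, +3\}^2: electrodes 1..3 at row offset
#' -3 (columns -3, 0, +3), and so on.
#'
#' @param centre integer `(row, col)` centre cell.
#' @param L lattice side length.
#' @param h electrode height above the tissue plane, in cell units
#'   (default 1).
#' @return object of class `multiprobe` with `centre`, `h` and `electrodes`
#'   (data frame of `x` = column and `y` = row coordinates; rows wrap
#'   periodically, columns must not cross the open boundary).
#' @export
make_multiprobe <- function(centre, L, h = 1) {
  r <- centre[1]; c <- centre[2]
  if (c < 4 || c > L - 3)
    stop("multiprobe placement error: 7x7 region crosses an open column ",
         "boundary", call. = FALSE)
  offs <- c(-3, 0, 3)
  grid <- expand.grid(dx = offs, dy = offs)      # row-major in dy rows
  structure(list(centre = c(row = r, col = c), h = h,
                 electrodes = data.frame(x = c + grid$dx, y = r + grid$dy,
                                         dx = grid$dx, dy = grid$dy)),
            class = "multiprobe")
}

#' Probe-centre placement bounds
#'
#' @param L lattice side length.
#' @return valid column range for a multiprobe centre (rows are periodic, so
#'   any row is valid).
#' @export
probe_col_range <- function(L) c(4L, L - 3L)

#' Sample a unipolar electrogram at one instant
#'
#' The virtual unipolar potential is a current-dipole sum over coupled cell
#' pairs: each bond (i, j) contributes
#' `(u_i - u_j) * ((r_i - r_j) . (r_m - r_e)) / |r_m - r_e|^3`,
#' where `u` is the [membrane_potential()], `r_m` the in-plane bond midpoint
#' and `r_e` the electrode position at height `h` above the plane. Transverse
#' bond displacements respect row periodicity (minimum image). Contributions
#' are truncated beyond an in-plane `cutoff` radius (inverse-square falloff
#' makes the remainder negligible).
#'
#' @param tissue a `cmp_tissue`.
#' @param state state matrix.
#' @param x,y electrode in-plane position in cell units (cell `(r, c)` sits
#'   at `x = c`, `y = r`).
#' @param h electrode height (default 1).
#' @param cutoff in-plane truncation radius in cells (default 25; `Inf`
#'   sums every pair).
#' @return voltage in arbitrary units.
#' @export
electrogram_sample <- function(tissue, state, x, y, h = 1, cutoff = 25) {
  a <- .core_args(tissue)
  L <- tissue$config$L
  if (!is.finite(cutoff)) cutoff <- 2 * L
  .egm_sample_cpp(state, a$trans_up, a$tau, x - 1, y - 1, h, cutoff)
}

# internal: record arbitrary electrodes while advancing the simulation
record_electrodes <- function(tissue, state, ex, ey, t0, duration,
                              pacing = TRUE, h = 1, cutoff = 25) {
  a <- .core_args(tissue)
  res <- .cmp_record_cpp(state, a$trans_up, a$dysf, a$tau, a$eps,
                         as.integer(t0), as.integer(duration), pacing,
                         tissue$config$T_pace, a$ectopic, a$ect_period,
                         ex - 1, ey - 1, h, cutoff)
  list(voltages = res$voltages, state = res$state,
       t_end = as.integer(t0) + as.integer(duration))
}

#' Record a multiprobe electrogram
#'
#' Advances the simulation `duration` steps, sampling all nine electrodes
#' after every step. The default window of 120 steps spans two 60-step
#' circuit cycles (360 ms at 3 ms per step, under the 400 ms budget a search
#' recording is allowed).
#'
#' @param tissue a `cmp_tissue`.
#' @param state current state (normally post-[initialize_af()]).
#' @param probe a [make_multiprobe()].
#' @param t0 current step index.
#' @param duration recording length in steps (default 120).
#' @param pacing pacemaker enabled while recording (default TRUE).
#' @param cutoff kernel truncation radius (default 25).
#' @return object of class `electrogram_record`: `voltages` (duration x 9
#'   matrix, arbitrary units), `probe`, `t_start`, `duration`, plus the
#'   advanced simulation `state` and `t_end` so recording composes with the
#'   ongoing simulation.
#' @export
record_multiprobe <- function(tissue, state, probe, t0 = 0L, duration = 120L,
                              pacing = TRUE, cutoff = 25) {
  stopifnot(inherits(probe, "multiprobe"))
  rec <- record_electrodes(tissue, state, probe$electrodes$x,
                           probe$electrodes$y, t0, duration, pacing,
                           h = probe$h, cutoff = cutoff)
  structure(list(voltages = rec$voltages, probe = probe,
                 t_start = as.integer(t0), duration = as.integer(duration),
                 state = rec$state, t_end = rec$t_end),
            class = "electrogram_record")
}

#' @export
print.electrogram_record <- function(x, ...) {
  cat(sprintf("<electrogram_record> %d electrodes x %d steps from t=%d\n",
              ncol(x$voltages), x$duration, x$t_start))
  invisible(x)
}

#' Export an electrogram record as CSV
#'
#' Writes columns `step, electrode_1..electrode_9` and, alongside, a JSON
#' sidecar with the probe centre and window metadata.
#'
#' @param record an `electrogram_record`.
#' @param path CSV output path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_electrogram_csv <- function(record, path) {
  v <- record$voltages
  colnames(v) <- paste0("electrode_", seq_len(ncol(v)))
  df <- data.frame(step = record$t_start + seq_len(nrow(v)), v)
  write.csv(df, path, row.names = FALSE)
  meta <- list(centre = unname(record$probe$centre), h = record$probe$h,
               t_start = record$t_start, duration = record$duration)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

# R reference kernel over an arbitrary potential field (vectorized, no
# truncation by default) -- independent route used to cross-check the
# compiled kernel
egm_sample_field <- function(u, trans_up, L, x, y, h = 1, cutoff = Inf) {
  minimg <- function(d) d - L * round(d / L)
  phi <- 0
  # longitudinal bonds (r, c)-(r, c+1)
  cs <- 1:(L - 1)
  for (cc in cs) {
    dx <- cc + 0.5 - x
    dy <- minimg(seq_len(L) - y)
    r2 <- dx^2 + dy^2
    keep <- r2 <= cutoff^2
    if (any(keep)) {
      du <- u[keep, cc] - u[keep, cc + 1]
      phi <- phi + sum(du * (-dx) / (r2[keep] + h^2)^1.5)
    }
  }
  # transverse bonds (r, c)-((r %% L) + 1, c)
  for (cc in seq_len(L)) {
    rs <- which(trans_up[, cc])
    if (!length(rs)) next
    dx <- cc - x
    dy <- minimg(rs + 0.5 - y)  # bond midpoint at row rs + 0.5
    r2 <- dx^2 + dy^2
    keep <- r2 <= cutoff^2
    if (any(keep)) {
      up <- (rs[keep] %% L) + 1L
      du <- u[cbind(rs[keep], cc)] - u[cbind(up, cc)]
      phi <- phi + sum(du * (-dy[keep]) / (r2[keep] + h^2)^1.5)
    }
  }
  phi
}
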