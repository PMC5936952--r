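# Constraint regions are admissibility masks over the L columns (open axis)
# and L rows (periodic axis). Each jump infers, from the sign of the
# constrained prediction's displacement, the half-space (half-circle in y)
# containing the driver, and the region is intersected with it. The region
# starts as the whole tissue; its collapse below one probe footprint, or a
# proposal revisiting an earlier centre, raises a prediction error.

#' Full-tissue constraint region
#'
#' @param L lattice side length.
#' @return object of class `constraint_region` with logical masks
#'   `x_allowed` (columns) and `y_allowed` (rows), and a `provenance` list of
#'   the half-space inferences applied so far.
#' @export
constraint_region <- function(L) {
  structure(list(L = L, x_allowed = rep(TRUE, L), y_allowed = rep(TRUE, L),
                 provenance = list()),
            class = "constraint_region")
}

#' @export
print.constraint_region <- function(x, ...) {
  xi <- range(which(x$x_allowed)); yn <- sum(x$y_allowed)
  cat(sprintf(
    "<constraint_region> x in [%d, %d] (%d cols), %d rows admissible\n",
    xi[1], xi[2], sum(x$x_allowed), yn))
  invisible(x)
}

#' Start a driver search
#'
#' @param tissue a fibrillating `cmp_tissue`.
#' @param constraints initial [constraint_region()] (default: whole tissue).
#' @return object of class `search_state`: current probe `centre`, ordered
#'   `visited` list, `constraints` and the `jumps` counter. The initial
#'   centre is uniform over the placements admitted by the constraints.
#' @export
init_search <- function(tissue, constraints = NULL) {
  L <- tissue$config$L
  if (is.null(constraints)) constraints <- constraint_region(L)
  cr <- probe_col_range(L)
  cols <- which(constraints$x_allowed)
  cols <- cols[cols >= cr[1] & cols <= cr[2]]
  if (!length(cols)) cols <- cr[1]:cr[2]
  rows <- which(constraints$y_allowed)
  centre <- c(row = sample(rows, 1L), col = sample(cols, 1L))
  structure(list(centre = centre, visited = list(),
                 constraints = constraints, jumps = 0L),
            class = "search_state")
}

# nearest admissible coordinate to `coord` within a mask (x: linear metric;
# y: circular metric)
.nearest_allowed <- function(coord, mask, periodic, L) {
  allowed <- which(mask)
  if (!length(allowed)) return(NA_integer_)
  d <- if (periodic) abs(.minimg(allowed - coord, L)) else abs(allowed - coord)
  allowed[which.min(d)]
}

# midpoint (for tie-breaking) of an admissible set
.region_mid <- function(mask, periodic, L) {
  allowed <- which(mask)
  if (periodic && mask[1] && mask[L] && !all(mask)) {
    # contiguous arc wrapping the seam: unwrap before taking the midpoint
    gap <- which(!mask)
    allowed2 <- ifelse(allowed < gap[1], allowed + L, allowed)
    return(((round(mean(range(allowed2))) - 1) %% L) + 1)
  }
  round(mean(range(allowed)))
}

# constrained argmax along one axis: zero out mass mapping outside the
# region, renormalize, pick the max (ties -> bin nearest the region
# midpoint, then the smaller coordinate), return the clipped coordinate
.propose_axis <- function(dist, midpoints, probe_coord, mask, periodic, L) {
  coord <- if (periodic) {
    ((round(probe_coord + midpoints) - 1) %% L) + 1
  } else {
    round(probe_coord + midpoints)
  }
  inside <- coord >= 1 & coord <= L
  inside[inside] <- mask[coord[inside]]
  p <- dist$prob
  if (!any(inside & p > 0)) {
    # all mass outside the region: fall back to the region midpoint
    return(list(coord = .region_mid(mask, periodic, L), fallback = TRUE))
  }
  p[!inside] <- 0
  p <- p / sum(p)
  best <- which(p == max(p))
  if (length(best) > 1L) {
    mid <- .region_mid(mask, periodic, L)
    dmid <- if (periodic) abs(.minimg(coord[best] - mid, L)) else
      abs(coord[best] - mid)
    best <- best[order(dmid, coord[best])][1]
  } else best <- best[1]
  list(coord = coord[best], fallback = FALSE)
}

#' Propose the next probe centre
#'
#' Per axis, takes the vote-fraction distribution of the probabilistic
#' locator, removes the probability mass lying outside the constraint
#' region, renormalizes, selects the argmax displacement bin and maps its
#' midpoint through the current probe position; the result is clipped to the
#' admissible region and clamped to a valid probe placement. Ties break to
#' the bin nearest the region midpoint, then to the smaller coordinate; if
#' an axis has no admissible mass the region midpoint is used.
#'
#' @param bundle an `af_model_bundle`.
#' @param features feature vector of the current recording.
#' @param state a `search_state`.
#' @return integer `(row, col)` proposal.
#' @export
propose_position <- function(bundle, features, state) {
  L <- state$constraints$L
  dx <- class_probabilities(bundle$prob_x, features)
  dy <- class_probabilities(bundle$prob_y, features)
  px <- .propose_axis(dx, bundle$x_map$midpoint, state$centre["col"],
                      state$constraints$x_allowed, FALSE, L)
  py <- .propose_axis(dy, bundle$y_map$midpoint, state$centre["row"],
                      state$constraints$y_allowed, TRUE, L)
  col <- .nearest_allowed(px$coord, state$constraints$x_allowed, FALSE, L)
  row <- .nearest_allowed(py$coord, state$constraints$y_allowed, TRUE, L)
  cr <- probe_col_range(L)
  c(row = row, col = min(max(col, cr[1]), cr[2]))
}

#' Shrink the constraint region after a jump
#'
#' The sign of the constrained proposal's displacement from the current
#' probe marks, per axis, the half-space (half-circle across rows) that the
#' driver is inferred to lie in; the region is intersected with it, keeping
#' a safety `margin` of cells on the probe side of the cut (and, across
#' rows, past the antipode) so that the occasional mis-signed inference near
#' the axis or near the antipode does not expel the driver from the region.
#' The row inference is reliable at any range, but the column inference is
#' only trustworthy once the driver is predicted to be nearby across rows,
#' so the column cut is applied only when the proposal's row displacement is
#' at most `x_gate`. Declares a prediction error when the region narrows
#' below one probe footprint (7 cells) on either axis, or when the proposal
#' revisits an earlier centre.
#'
#' @param state a `search_state` (its `centre` is the probe just recorded).
#' @param proposal the accepted `(row, col)` proposal.
#' @param margin safety margin in cells retained behind each cut
#'   (default 8; 0 gives the plain half-space rule).
#' @param x_gate apply the column cut only when the proposal's row
#'   displacement is at most this many cells (default 12; `Inf` cuts
#'   unconditionally).
#' @return list with the updated `constraints` and logical
#'   `prediction_error`.
#' @export
update_constraints <- function(state, proposal, margin = 8L, x_gate = 12L) {
  con <- state$constraints
  L <- con$L
  ctr <- state$centre
  ddx <- proposal["col"] - ctr["col"]
  ddy <- .minimg(proposal["row"] - ctr["row"], L)
  cut_x <- ddx != 0 && abs(ddy) <= x_gate
  if (cut_x && ddx > 0 && ctr["col"] - margin >= 1)
    con$x_allowed[1:(ctr["col"] - margin)] <- FALSE
  if (cut_x && ddx < 0 && ctr["col"] + margin <= L)
    con$x_allowed[(ctr["col"] + margin):L] <- FALSE
  if (ddy != 0) {
    span <- (1 - margin):(L %/% 2 + margin)
    half <- if (ddy > 0) .wrap_row(ctr["row"] + span, L)
            else .wrap_row(ctr["row"] - span, L)
    keep <- rep(FALSE, L); keep[half] <- TRUE
    con$y_allowed <- con$y_allowed & keep
  }
  con$provenance <- c(con$provenance,
                      list(list(probe = unname(ctr),
                                side = c(if (cut_x) sign(ddx) else 0L,
                                         sign(ddy)))))
  revisit <- any(vapply(state$visited, function(v)
    all(v == proposal), logical(1)))
  err <- revisit || sum(con$x_allowed) < 7L || sum(con$y_allowed) < 7L
  list(constraints = con, prediction_error = err)
}

#' On-driver test at the current probe
#'
#' TRUE iff both band classifiers assert their axis: the conjunction of
#' "probe on the driver's X-band" and "on its Y-band" is exactly "probe
#' window overlaps the circuit footprint" for the rectangular circuits used
#' here.
#'
#' @param bundle an `af_model_bundle`.
#' @param features feature vector of the current recording.
#' @return logical.
#' @export
check_positive <- function(bundle, features) {
  df <- .as_feature_df(features, bundle$feature_names)
  px <- stats::predict(bundle$clf_x, data = df, num.threads = 1L)$predictions
  py <- stats::predict(bundle$clf_y, data = df, num.threads = 1L)$predictions
  identical(as.character(px), "TRUE") && identical(as.character(py), "TRUE")
}

# sub-bin row refinement from the delay field of the firing recording:
# a driver between the electrode rows makes the grid-row mean delays
# v-shaped (waves diverge from the source row); the parabola vertex
# estimates the driver's row offset to ~1-2 cells. NA when the delays are
# not convex (no straddled source).
.delay_vertex <- function(fv) {
  d <- fv[paste0("delay_e", 1:9)]
  tb <- mean(d[1:3]); tm <- mean(d[4:6]); tt <- mean(d[7:9])
  A <- (tt + tb - 2 * tm) / 18
  if (!is.finite(A) || A <= 1e-9) return(NA_real_)
  B <- (tt - tb) / 6
  -B / (2 * A)
}

# does a probe window centred at `centre` overlap a circuit footprint?
window_on_circuit <- function(centre, circuit, L) {
  lab <- .axis_labels(centre[1], centre[2], circuit, L)
  unname(lab[1] && lab[2])
}

#' Locate a re-entrant driver
#'
#' The recursive search: record a multiprobe at the current centre, extract
#' features, stop with a positive if both band classifiers fire, otherwise
#' propose the next centre from the constrained locator distributions,
#' shrink the constraint region from the proposal's direction and move.
#' Terminates on a positive or on the jump limit; every multiprobe
#' recording counts as one jump. A prediction error (collapsed region or a
#' looping proposal) restarts the search from a fresh random placement with
#' its initial constraints, keeping the cumulative jump count; a search
#' that exhausts the jump budget inside a prediction-error state reports
#' `prediction_error`.
#'
#' @param tissue a `cmp_tissue` with its circuit(s).
#' @param bundle trained `af_model_bundle`.
#' @param state fibrillating state field (from [initialize_af()]).
#' @param t0 current step index.
#' @param jump_limit maximum number of recordings (default 30).
#' @param search initial `search_state` (default [init_search()] with the
#'   full tissue admissible).
#' @param duration recording window (default 120 steps).
#' @param exclude circuits already found (their footprints are not accepted
#'   as ground-truth matches).
#' @param margin,x_gate constraint-update calibration, see
#'   [update_constraints()].
#' @param pacing pacemaker enabled while recording (default TRUE).
#' @param snap `(x, y)` clamp, in cells, on the final locator refinement:
#'   when the classifiers assert a positive, the reported centre is the
#'   probe moved by the locators' predicted displacement, clamped to at
#'   most one probe footprint (`c(10, 5)` by default).
#' @return object of class `af_search_result`: `final_centre`, `positive`
#'   (classifier assertion), `success` (positive and the final window
#'   overlaps a not-yet-found circuit), `matched_circuit`, `jumps`,
#'   `failure_mode` (`"none"`, `"prediction_error"` or `"jump_limit"`),
#'   `visited`, and the advanced `state`/`t_end` for chained searches.
#' @export
locate_driver <- function(tissue, bundle, state, t0 = 0L, jump_limit = 30L,
                          search = NULL, duration = 120L,
                          exclude = integer(0), margin = 8L, x_gate = 12L,
                          snap = c(10L, 5L), pacing = TRUE) {
  L <- tissue$config$L
  if (is.null(search)) search <- init_search(tissue)
  init_constraints <- search$constraints
  sim_state <- state; t <- as.integer(t0)
  positive <- FALSE; failure <- "none"
  cr <- probe_col_range(L)

  repeat {
    if (search$jumps >= jump_limit) { failure <- "jump_limit"; break }
    probe <- make_multiprobe(search$centre, L)
    rec <- record_multiprobe(tissue, sim_state, probe, t0 = t,
                             duration = duration, pacing = pacing)
    sim_state <- rec$state; t <- rec$t_end
    search$jumps <- search$jumps + 1L
    search$visited <- c(search$visited, list(unname(search$centre)))
    fv <- feature_vector(rec$voltages)
    if (check_positive(bundle, fv)) {
      # the reported ablation target is the locators' final prediction:
      # the probe refined by the predicted displacement, clamped to at
      # most one probe footprint (the classifiers already assert the
      # probe is on the driver's bands, so larger corrections are not
      # credible)
      prop <- propose_position(bundle, fv, search)
      ddx <- min(max(prop[["col"]] - search$centre[["col"]], -snap[1]),
                 snap[1])
      ddy <- .minimg(prop[["row"]] - search$centre[["row"]], L)
      vtx <- .delay_vertex(fv)          # sub-bin row estimate if available
      if (is.finite(vtx)) ddy <- round(vtx)
      ddy <- min(max(ddy, -snap[2]), snap[2])
      positive <- TRUE
      search$centre <- c(
        row = .wrap_row(search$centre[["row"]] + ddy, L),
        col = min(max(search$centre[["col"]] + ddx, cr[1]), cr[2]))
      break
    }
    if (search$jumps >= jump_limit) { failure <- "jump_limit"; break }
    prop <- propose_position(bundle, fv, search)
    upd <- update_constraints(search, prop, margin = margin, x_gate = x_gate)
    search$constraints <- upd$constraints
    if (upd$prediction_error) {
      if (search$jumps >= jump_limit - 1L) {
        failure <- "prediction_error"
        break
      }
      # restart from a fresh placement under the initial constraints,
      # keeping the cumulative jump count
      jumps_so_far <- search$jumps
      visited_so_far <- search$visited
      search <- init_search(tissue, init_constraints)
      search$jumps <- jumps_so_far
      search$visited <- visited_so_far
      next
    }
    search$centre <- prop
  }

  matched <- NA_integer_
  if (positive) {
    for (k in seq_along(tissue$circuits)) {
      if (k %in% exclude) next
      if (window_on_circuit(search$centre, tissue$circuits[[k]], L)) {
        matched <- k; break
      }
    }
  }
  structure(list(final_centre = search$centre, positive = positive,
                 success = positive && !is.na(matched),
                 matched_circuit = matched, jumps = search$jumps,
                 failure_mode = failure, visited = search$visited,
                 state = sim_state, t_end = t),
            class = "af_search_result")
}

#' @export
print.af_search_result <- function(x, ...) {
  cat(sprintf("<af_search_result> centre (%d, %d); %s after %d jumps%s\n",
              x$final_centre[1], x$final_centre[2],
              if (x$success) "success" else
                if (x$positive) "false positive" else "failure",
              x$jumps,
              if (x$failure_mode == "none") "" else
                paste0(" [", x$failure_mode, "]")))
  invisible(x)
}

#' Expected wavefront-collision rows
#'
#' On the row-periodic tissue, waves emitted by a driver propagate both ways
#' around the cylinder and collide on the far side: for one driver the
#' expected collision row is its antipode; for several drivers, the arc
#' midpoints between circularly adjacent drivers (equal wave speeds).
#'
#' @param rows driver row(s), 1-based.
#' @param L lattice side length.
#' @return integer collision row(s).
#' @export
expected_collision_rows <- function(rows, L) {
  if (length(rows) == 1L)
    return(.wrap_row(as.integer(rows) + L %/% 2L, L))
  r <- sort(((as.integer(rows) - 1L) %% L))
  nxt <- c(r[-1L], r[1L] + L)
  mids <- ((r + nxt) %/% 2L) %% L
  .wrap_row(mids + 1L, L)
}

# local transverse flow at a probe: sign of the top-row minus bottom-row
# mean relative delay (+1 = waves travel towards +y, so their source is on
# the -y side); 0 when indeterminate
.row_flow <- function(tissue, state, t0, centre, duration, pacing) {
  L <- tissue$config$L
  cr <- probe_col_range(L)
  centre <- c(row = .wrap_row(centre[1], L),
              col = min(max(centre[2], cr[1]), cr[2]))
  rec <- record_multiprobe(tissue, state, make_multiprobe(centre, L),
                           t0 = t0, duration = duration, pacing = pacing)
  at <- relative_delays(rec$voltages)
  g <- mean(at[7:9], na.rm = TRUE) - mean(at[1:3], na.rm = TRUE)
  list(flow = if (is.finite(g)) sign(g) else 0L,
       state = rec$state, t_end = rec$t_end)
}

# localize a collision line known to lie between crow-offset and
# crow+offset by bisection on the local flow sign; returns the line's
# offset from crow and the number of recordings used
.bisect_collision <- function(tissue, state, t0, centre, offset = 12L,
                              iters = 2L, duration = 120L, pacing = TRUE) {
  lo <- -offset; hi <- offset
  n <- 0L
  for (k in seq_len(iters)) {
    mid <- round((lo + hi) / 2)
    fl <- .row_flow(tissue, state, t0,
                    c(centre[1] + mid, centre[2]), duration, pacing)
    state <- fl$state; t0 <- fl$t_end; n <- n + 1L
    if (fl$flow == 0) break
    if (fl$flow > 0) lo <- mid else hi <- mid   # +y flow: line above
  }
  list(delta = round((lo + hi) / 2), state = state, t_end = t0,
       n_recordings = n)
}

# classify the activity around an expected collision row by straddling it
# with two probes `offset` rows apart: opposing local flows (converging
# towards the middle) mean the wave trains collide between the probes;
# a common flow direction is through-traffic whose source lies on the
# opposite side; diverging flows mean a wave source sits between the
# probes. Two recordings.
collision_check <- function(tissue, state, t0, centre, duration = 120L,
                            pacing = TRUE, offset = 12L) {
  L <- tissue$config$L
  below <- .row_flow(tissue, state, t0, c(centre[1] - offset, centre[2]),
                     duration, pacing)
  above <- .row_flow(tissue, below$state, below$t_end,
                     c(centre[1] + offset, centre[2]), duration, pacing)
  gb <- below$flow; ga <- above$flow
  res <- if (gb > 0 && ga < 0) {
    list(collision = TRUE, from_side = 0L, between = FALSE)
  } else if (gb < 0 && ga > 0) {
    list(collision = FALSE, from_side = 0L, between = TRUE)
  } else if (gb == 0 || ga == 0 || gb != ga) {
    list(collision = TRUE, from_side = 0L, between = FALSE)
  } else {
    # consistent flow: source side is opposite the travel direction
    list(collision = FALSE, from_side = -gb, between = FALSE)
  }
  c(res, list(state = above$state, t_end = above$t_end,
              n_recordings = 2L, centre = centre))
}

#' Locate several drivers
#'
#' Runs the single-driver search; if more drivers are expected, records one
#' multiprobe at the expected collision row of the found driver. A clean
#' collision (activation times peaking between the electrode rows) means no
#' further driver is detectable and the search stops; through-traffic
#' constrains the next search to the row arc on the side the waves come
#' from, excluding the found driver's rows, and the single-driver search is
#' re-run inside it. The models remain those trained on single-driver
#' tissues.
#'
#' @param tissue a `cmp_tissue` with 1 or more circuits.
#' @param bundle trained `af_model_bundle`.
#' @param state fibrillating state field.
#' @param t0 current step index.
#' @param n_expected number of drivers to look for (default 1).
#' @param jump_limit per-search jump limit (default 30).
#' @param margin rows around a found driver's centre excluded from later
#'   searches (default 8: wide enough that no admissible probe window can
#'   overlap the found circuit again).
#' @param pacing pacemaker enabled while recording (default TRUE).
#' @return list of `af_search_result` (length <= `n_expected`); the
#'   collision-check recording is counted in the following search's jumps.
#' @export
locate_all <- function(tissue, bundle, state, t0 = 0L, n_expected = 1L,
                       jump_limit = 30L, margin = 8L, pacing = TRUE) {
  L <- tissue$config$L
  results <- list()
  found_rows <- integer(0)
  y_mask <- rep(TRUE, L)
  sim_state <- state; t <- as.integer(t0)

  for (d in seq_len(n_expected)) {
    extra_jumps <- 0L
    con <- constraint_region(L)
    con$y_allowed <- y_mask
    if (d > 1L) {
      prev <- results[[d - 1L]]
      if (!prev$positive) break
      crow <- expected_collision_rows(prev$final_centre["row"], L)
      chk <- collision_check(tissue, sim_state, t,
                             c(crow, prev$final_centre[["col"]]),
                             pacing = pacing)
      sim_state <- chk$state; t <- chk$t_end
      extra_jumps <- extra_jumps + chk$n_recordings
      keep <- rep(FALSE, L)
      if (chk$collision) {
        # a collision line displaced from the expected row betrays a second
        # driver close to the first: line at (d1 + d2)/2 + L/2, so
        # d2 = d1 + 2 * displacement. Localize the line by bisection.
        bis <- .bisect_collision(tissue, sim_state, t,
                                 c(crow, prev$final_centre[["col"]]),
                                 pacing = pacing)
        sim_state <- bis$state; t <- bis$t_end
        extra_jumps <- extra_jumps + bis$n_recordings
        if (abs(bis$delta) <= 5L) break
        d2row <- .wrap_row(prev$final_centre[["row"]] + 2L * bis$delta, L)
        keep[.wrap_row(d2row + (-14):14, L)] <- TRUE
      } else if (chk$between) {
        # a source sits between the straddling probes
        keep[.wrap_row(crow + (-14):14, L)] <- TRUE
      } else {
        # admissible arc: from the collision row towards the incoming
        # waves, stopping short of the found driver
        steps <- seq_len(L %/% 2 - margin)
        keep[.wrap_row(crow + chk$from_side * steps, L)] <- TRUE
      }
      con$y_allowed <- con$y_allowed & keep
      if (!any(con$y_allowed)) break
    }
    # exclude previously found drivers' neighbourhoods
    for (fr in found_rows) {
      band <- .wrap_row(fr + (-margin):margin, L)
      con$y_allowed[band] <- FALSE
    }
    if (sum(con$y_allowed) < 7L) break
    search <- init_search(tissue, con)
    res <- locate_driver(tissue, bundle, sim_state, t0 = t,
                         jump_limit = jump_limit, search = search,
                         pacing = pacing,
                         exclude = which(vapply(seq_along(tissue$circuits),
                           function(k) any(vapply(results, function(r)
                             identical(r$matched_circuit, k), logical(1))),
                           logical(1))))
    res$jumps <- res$jumps + extra_jumps
    sim_state <- res$state; t <- res$t_end
    results <- c(results, list(res))
    if (res$positive) found_rows <- c(found_rows, res$final_centre[["row"]])
    if (!res$positive) break
  }
  results
}
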