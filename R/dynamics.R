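# internal: pieces handed to the compiled core
.core_args <- function(tissue) {
  tu <- tissue$trans_up; storage.mode(tu) <- "integer"
  dy <- tissue$dysfunctional; storage.mode(dy) <- "integer"
  ect <- if (is.null(tissue$ectopic)) integer(0) else
    as.integer(tissue$ectopic$position - 1L)
  list(trans_up = tu, dysf = dy, tau = tissue$config$tau,
       eps = if (any(tissue$dysfunctional)) tissue$config$epsilon else 0,
       ectopic = ect,
       ect_period = if (is.null(tissue$ectopic)) 0L else tissue$ectopic$period)
}

#' Fresh resting state field
#'
#' @param tissue a `cmp_tissue`.
#' @return L x L integer matrix of zeros.
#' @export
new_state <- function(tissue) matrix(0L, tissue$config$L, tissue$config$L)

#' Advance the automaton
#'
#' Synchronous update: a resting cell with at least one excited coupled
#' neighbour becomes excited (unless dysfunctional and the epsilon-failure
#' fires); an excited cell becomes refractory; refractory clocks count down
#' and reach resting after `tau` steps. If pacing is on and `t %% T_pace == 0`
#' the resting cells of column 1 are excited before the update, and likewise
#' for a registered ectopic focus at its own period.
#'
#' @param tissue a `cmp_tissue`.
#' @param state current L x L integer clock field.
#' @param t current step index (determines pacemaker/ectopic firing).
#' @param nsteps number of steps to advance (default 1).
#' @param pacing logical; pacemaker enabled (default TRUE).
#' @return the state `nsteps` later.
#' @export
cmp_step <- function(tissue, state, t = 0L, nsteps = 1L, pacing = TRUE) {
  a <- .core_args(tissue)
  .cmp_run_cpp(state, a$trans_up, a$dysf, a$tau, a$eps,
               as.integer(t), as.integer(nsteps), pacing,
               tissue$config$T_pace, a$ectopic, a$ect_period)
}

#' Count excited cells / test for fibrillation
#'
#' The tissue is fibrillating when more than `1.1 * L` cells are excited
#' (221 cells at the default L = 200), which separates fibrillatory activity
#' from a sinus plane wave (at most L cells).
#'
#' @param state state matrix.
#' @param config a [model_config()].
#' @return `count_active`: integer; `is_fibrillating`: logical.
#' @export
count_active <- function(state) .cmp_count_active_cpp(state)

#' @rdname count_active
#' @export
is_fibrillating <- function(state, config) {
  count_active(state) > 1.1 * config$L
}

#' Membrane potential assigned to a cell clock
#'
#' Excited cells sit at 1, refractory cells repolarize linearly back to 0
#' over the `tau` refractory stages, resting cells are at 0. Arbitrary units;
#' this is the source mapping behind the electrogram kernel.
#'
#' @param clock integer clock value(s) in `0..tau+1`.
#' @param tau refractory period.
#' @return numeric potential(s) in \[0, 1\].
#' @export
membrane_potential <- function(clock, tau) {
  if (any(clock < 0 | clock > tau + 1)) stop("invalid clock value")
  ifelse(clock == 0, 0, ifelse(clock == 1, 1, 1 - (clock - 1) / tau))
}

#' Run the automaton until fibrillation is established
#'
#' Advances the seeded tissue until every column of the lattice has hosted at
#' least one excitation and the fibrillation criterion has held at least
#' once, i.e. until the activity from the re-entrant circuit(s) has reached
#' the whole tissue.
#'
#' @param tissue a `cmp_tissue` with its circuit(s) inserted.
#' @param state seeded state field; default seeds every inserted circuit into
#'   one fresh field via [seed_circuit_excitation()].
#' @param t0 starting step index (default 0).
#' @param pacing pacemaker enabled during initialization (default TRUE).
#' @param max_steps give up after this many steps (default `20 * L`).
#' @return list with `state` (the fibrillating field) and `t_ready` (steps
#'   elapsed). Throws an initialization error if activity dies out or the
#'   step budget is exhausted (e.g. an unsustainable circuit).
#' @export
initialize_af <- function(tissue, state = NULL, t0 = 0L, pacing = TRUE,
                          max_steps = 20L * tissue$config$L) {
  stopifnot(inherits(tissue, "cmp_tissue"))
  if (is.null(state)) {
    if (!length(tissue$circuits))
      stop("no circuit to seed; insert one first", call. = FALSE)
    state <- new_state(tissue)
    for (k in seq_along(tissue$circuits))
      state <- seed_circuit_excitation(tissue, k, state)
  }
  a <- .core_args(tissue)
  # monitor the first circuit's seeded head cell: fibrillation only counts
  # as established while the inserted driver is still re-exciting it
  monitor <- integer(0); window <- 120L
  if (length(tissue$circuits)) {
    circ <- tissue$circuits[[1]]
    monitor <- c(circ$rows[1] - 1L, circ$cols[2] - 1L)
    window <- 2L * circ$path_length
  }
  res <- .cmp_init_cpp(state, a$trans_up, a$dysf, a$tau, a$eps,
                       as.integer(t0), as.integer(max_steps), pacing,
                       tissue$config$T_pace, a$ectopic, a$ect_period,
                       1.1 * tissue$config$L, monitor, window)
  if (!res$success)
    stop("initialization failure: ", res$reason, call. = FALSE)
  list(state = res$state, t_ready = res$t_ready)
}
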