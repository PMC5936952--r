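#' Model configuration
#'
#' Parameters of the atrial cellular automaton. Rows of the lattice are muscle
#' fibres with complete longitudinal coupling and open ends; adjacent fibres
#' are coupled transversally with probability `nu` (the periodic direction).
#' A cell is excited for one step, then refractory for `tau` steps, then
#' resting. Pacemaker cells along column 1 fire every `T_pace` steps. A
#' fraction `delta` of cells is dysfunctional and fails to excite with
#' probability `epsilon` per excitation attempt.
#'
#' @param L lattice side length in cells (default 200).
#' @param nu transverse coupling fraction in \[0, 1\] (default 0.2, the
#'   coupling at which paroxysmal fibrillation emerges in this model family).
#' @param delta dysfunctional-cell fraction in \[0, 1\] (default 0: circuits
#'   are inserted artificially rather than forming spontaneously).
#' @param epsilon per-attempt excitation-failure probability for dysfunctional
#'   cells (default 0.05; inert when `delta = 0`).
#' @param tau refractory period in time steps (default 50).
#' @param T_pace pacing period in time steps (default 220); must exceed `tau`.
#' @param dt_ms physical duration of one step in milliseconds (metadata only;
#'   default 3.0, so the refractory period is 150 ms and sinus rhythm beats
#'   every 660 ms).
#' @param seed optional RNG seed stored with the configuration; used by
#'   [build_tissue()] for reproducible tissue construction.
#' @return an object of class `cmp_config`.
#' @export
#' @examples
#' cfg <- model_config(L = 50, tau = 20, T_pace = 100)
#' timescales(cfg)
model_config <- function(L = 200L, nu = 0.2, delta = 0, epsilon = 0.05,
                         tau = 50L, T_pace = 220L, dt_ms = 3.0, seed = NULL) {
  L <- as.integer(L); tau <- as.integer(tau); T_pace <- as.integer(T_pace)
  if (is.na(L) || L < 10L)
    stop("`L` must be an integer >= 10", call. = FALSE)
  for (p in c(nu = nu, delta = delta, epsilon = epsilon)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
      stop("`nu`, `delta` and `epsilon` must lie in [0, 1]", call. = FALSE)
  }
  if (is.na(tau) || tau < 1L) stop("`tau` must be >= 1", call. = FALSE)
  if (is.na(T_pace) || T_pace <= tau)
    stop("`T_pace` must exceed `tau`", call. = FALSE)
  structure(list(L = L, nu = nu, delta = delta, epsilon = epsilon, tau = tau,
                 T_pace = T_pace, dt_ms = dt_ms,
                 seed = if (!is.null(seed)) as.integer(seed) else NULL),
            class = "cmp_config")
}

#' Physical timescales implied by a configuration
#'
#' @param config a [model_config()].
#' @return list with `dt_ms` (step duration), `refractory_ms` (`tau * dt_ms`)
#'   and `pacing_ms` (`T_pace * dt_ms`).
#' @export
timescales <- function(config) {
  stopifnot(inherits(config, "cmp_config"))
  list(dt_ms = config$dt_ms,
       refractory_ms = config$tau * config$dt_ms,
       pacing_ms = config$T_pace * config$dt_ms)
}

#' Read a model configuration from a YAML or JSON file
#'
#' The file holds a mapping with any subset of the [model_config()] fields;
#' missing fields take their defaults.
#'
#' @param path file path.
#' @return a `cmp_config`.
#' @export
read_model_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(model_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(model_config, vals)
}

#' @export
print.cmp_config <- function(x, ...) {
  ts <- timescales(x)
  cat(sprintf(
    "<cmp_config> L=%d nu=%.3g delta=%.3g epsilon=%.3g tau=%d T_pace=%d\n",
    x$L, x$nu, x$delta, x$epsilon, x$tau, x$T_pace))
  cat(sprintf("  dt=%.1f ms; refractory %.0f ms; pacing period %.0f ms\n",
              ts$dt_ms, ts$refractory_ms, ts$pacing_ms))
  invisible(x)
}
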