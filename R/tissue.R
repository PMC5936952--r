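#' Build a random tissue
#'
#' Draws the stochastic transverse couplings (Bernoulli `nu` per cell, linking
#' each cell to the fibre above, rows periodic) and the dysfunctional flags
#' (Bernoulli `delta`). Longitudinal couplings are implicit and complete along
#' every row, open at the two column boundaries.
#'
#' @param config a [model_config()]. If `config$seed` is set the global RNG is
#'   seeded with it first, so construction is reproducible.
#' @return an object of class `cmp_tissue` with elements `config`,
#'   `trans_up` (L x L logical: bond from `(r, c)` to `(r %% L + 1, c)`),
#'   `dysfunctional` (L x L logical), `circuits` (list of inserted circuit
#'   specs) and `ectopic` (optional forced-beat site).
#' @export
#' @examples
#' tis <- build_tissue(model_config(L = 20, nu = 1, seed = 1))
#' sum(tis$trans_up)  # all 400 transverse couplings present
build_tissue <- function(config) {
  stopifnot(inherits(config, "cmp_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$L
  trans_up <- matrix(runif(L * L) < config$nu, L, L)
  dysf <- matrix(runif(L * L) < config$delta, L, L)
  structure(list(config = config, trans_up = trans_up, dysfunctional = dysf,
                 circuits = list(), ectopic = NULL),
            class = "cmp_tissue")
}

#' @export
print.cmp_tissue <- function(x, ...) {
  L <- x$config$L
  cat(sprintf("<cmp_tissue> %d x %d; transverse fill %.3f; %d circuit(s)%s\n",
              L, L, mean(x$trans_up), length(x$circuits),
              if (is.null(x$ectopic)) "" else "; ectopic site"))
  invisible(x)
}

# wrap a row index onto 1..L
.wrap_row <- function(r, L) ((r - 1L) %% L) + 1L

#' Insert a rectangular re-entrant circuit
#'
#' Decouples the `segment_length` cells to the right of `anchor` from the
#' fibres above and below, and guarantees the transverse couplings at the two
#' ends of the span, producing a closed two-fibre loop of path length
#' `2 * segment_length + 4` (60 for the default 28-cell segment) around which
#' an excitation can circulate indefinitely once seeded, provided the path
#' length exceeds the refractory period.
#'
#' @param tissue a `cmp_tissue`.
#' @param anchor integer `(row, col)` of the anchor cell, or `NULL` to sample
#'   uniformly over all valid placements. The decoupled span must fit inside
#'   the open column boundaries: `anchor[2] <= L - segment_length - 1`.
#' @param segment_length number of decoupled cells to the right of the anchor
#'   (default 28).
#' @return the tissue with the new circuit appended to `$circuits`; each
#'   circuit spec holds `anchor`, `segment_length`, `rows` (the two fibre
#'   rows), `cols` (the 30-column footprint span), `path_length` and `centre`.
#' @export
insert_circuit <- function(tissue, anchor = NULL, segment_length = 28L) {
  stopifnot(inherits(tissue, "cmp_tissue"))
  L <- tissue$config$L
  segment_length <- as.integer(segment_length)
  span <- segment_length + 2L                      # footprint columns
  max_anchor_col <- L - segment_length - 1L        # span end at col L
  if (is.null(anchor)) {
    anchor <- c(sample.int(L, 1L), sample.int(max_anchor_col, 1L))
  }
  r0 <- as.integer(anchor[1]); c0 <- as.integer(anchor[2])
  if (r0 < 1L || r0 > L || c0 < 1L)
    stop("circuit anchor outside the lattice", call. = FALSE)
  if (c0 > max_anchor_col)
    stop("circuit anchor too close to the right boundary", call. = FALSE)

  r_up <- .wrap_row(r0 + 1L, L)
  r_dn <- .wrap_row(r0 - 1L, L)
  interior <- (c0 + 1L):(c0 + segment_length)
  tissue$trans_up[r0, interior] <- FALSE    # bonds to the fibre above
  tissue$trans_up[r_dn, interior] <- FALSE  # bonds to the fibre below
  tissue$trans_up[r0, c0] <- TRUE           # closing bonds at the span ends
  tissue$trans_up[r0, c0 + span - 1L] <- TRUE

  spec <- structure(list(
    anchor = c(r0, c0), segment_length = segment_length,
    rows = c(r0, r_up), cols = c(c0, c0 + span - 1L),
    path_length = 2L * segment_length + 4L,
    centre = c(row = r0 + 0.5, col = c0 + (span - 1) / 2)),
    class = "circuit_spec")
  tissue$circuits <- c(tissue$circuits, list(spec))
  tissue
}

#' Register an ectopic focus
#'
#' The cell at `position` is forcibly excited every `period` steps whenever it
#' is resting (a refractory cell skips that beat). Used to generate the
#' focal-source corpora behind vector feature maps.
#'
#' @param tissue a `cmp_tissue`.
#' @param position integer `(row, col)`.
#' @param period steps between forced excitations (default 60).
#' @return the tissue with `$ectopic` set.
#' @export
insert_ectopic <- function(tissue, position, period = 60L) {
  stopifnot(inherits(tissue, "cmp_tissue"))
  L <- tissue$config$L
  position <- as.integer(position); period <- as.integer(period)
  if (any(position < 1L) || any(position > L))
    stop("ectopic position outside the lattice", call. = FALSE)
  if (period < 1L) stop("`period` must be >= 1", call. = FALSE)
  tissue$ectopic <- list(position = position, period = period)
  tissue
}

# cells of a circuit footprint as a 2-column (row, col) matrix
circuit_footprint <- function(circuit, L) {
  rows <- .wrap_row(circuit$rows, L)
  cols <- circuit$cols[1]:circuit$cols[2]
  cbind(row = rep(rows, each = length(cols)), col = rep(cols, 2L))
}

#' Seed unidirectional circulation in an inserted circuit
#'
#' Produces a fresh cell-state field in which the rightmost cell of the lower
#' circuit fibre is excited and the `min(tau, path_length - 1)` cells behind
#' it along the intended circulation path carry a descending refractory
#' countdown, so propagation proceeds in exactly one direction around the
#' loop. All other cells rest.
#'
#' @param tissue a `cmp_tissue` with at least one circuit.
#' @param circuit which circuit to seed (index into `tissue$circuits`,
#'   default the last inserted), or a circuit spec.
#' @param state optional existing state matrix to seed into (so several
#'   circuits can share one field); default a fresh resting field.
#' @return an L x L integer state matrix (0 resting, 1 excited, 2..tau+1
#'   refractory).
#' @export
seed_circuit_excitation <- function(tissue, circuit = NULL, state = NULL) {
  stopifnot(inherits(tissue, "cmp_tissue"))
  if (is.null(circuit)) circuit <- length(tissue$circuits)
  if (!inherits(circuit, "circuit_spec")) circuit <- tissue$circuits[[circuit]]
  cfg <- tissue$config
  L <- cfg$L
  if (circuit$path_length <= cfg$tau)
    warning("circuit path length does not exceed the refractory period; ",
            "circulation cannot self-sustain", call. = FALSE)
  if (is.null(state)) state <- matrix(0L, L, L)

  r0 <- circuit$rows[1]; r_up <- circuit$rows[2]
  c0 <- circuit$cols[1]; c1 <- circuit$cols[2]
  # circulation order: rightward along the lower fibre, up at the right end,
  # leftward along the upper fibre, down at the left end
  path <- rbind(cbind(r0, c0:c1), cbind(r_up, c1:c0))
  head_idx <- which(path[, 1] == r0 & path[, 2] == c1)
  n <- nrow(path)
  state[path[head_idx, 1], path[head_idx, 2]] <- 1L
  wake <- min(cfg$tau, n - 1L)
  for (j in seq_len(wake)) {
    p <- path[((head_idx - 1L - j) %% n) + 1L, ]
    state[p[1], p[2]] <- j + 1L
  }
  state
}
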