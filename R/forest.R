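# Displacement-bin geometry for the probabilistic locators. Classes are
# signed driver-minus-probe displacements in 5-cell bins: the gradient
# features are translation invariant, so learning displacements (rather than
# absolute coordinates) is the well-posed formulation; the probe's known
# position converts a displacement class back to a tissue coordinate.
.bin_width <- 5

.bin_of <- function(d, half_range) floor((d + half_range) / .bin_width)
.bin_mid <- function(bin, half_range) .bin_width * bin - half_range + 2

# signed minimum-image row displacement, in (-L/2, L/2]
.minimg <- function(d, L) {
  m <- ((d + L / 2) %% L) - L / 2
  ifelse(m == -L / 2, L / 2, m)
}

#' Recording accounting
#'
#' Each tissue carries `probes_per_tissue` multiprobes of
#' `electrodes_per_probe` unipolar electrodes, so a corpus of `n_tissues`
#' tissues contains `n_tissues * probes_per_tissue * electrodes_per_probe`
#' electrogram recordings (2,880,000 at the full scale of 5000 tissues).
#'
#' @param n_tissues number of tissues.
#' @param probes_per_tissue multiprobes per tissue (default 64).
#' @param electrodes_per_probe electrodes per multiprobe (default 9).
#' @return total number of electrode recordings.
#' @export
recording_count <- function(n_tissues, probes_per_tissue = 64L,
                            electrodes_per_probe = 9L) {
  as.numeric(n_tissues) * probes_per_tissue * electrodes_per_probe
}

# uniform 8x8 (or k x k) arrangement of probe centres
.probe_grid <- function(L, probes_per_tissue) {
  k <- round(sqrt(probes_per_tissue))
  stopifnot(k * k == probes_per_tissue)
  rows <- round((seq_len(k) - 0.5) * L / k)
  cr <- probe_col_range(L)
  cols <- round(cr[1] + (seq_len(k) - 0.5) * (cr[2] - cr[1] + 1) / k)
  expand.grid(row = rows, col = cols)
}

# axis-overlap labels of a probe window against a circuit footprint
.axis_labels <- function(centre_row, centre_col, circuit, L) {
  wc <- (centre_col - 3):(centre_col + 3)
  wr <- .wrap_row((centre_row - 3):(centre_row + 3), L)
  on_x <- any(wc >= circuit$cols[1] & wc <= circuit$cols[2])
  on_y <- any(wr %in% .wrap_row(circuit$rows, L))
  c(on_x = on_x, on_y = on_y)
}

#' Generate the labelled training corpus
#'
#' For each tissue: draw random transverse couplings, insert one randomly
#' placed re-entrant circuit, seed it and run until fibrillation fills the
#' tissue, then record two fibrillatory cycles simultaneously at 64 uniformly
#' placed multiprobes and reduce each recording to its feature vector. Rows
#' are labelled with the signed displacement of the driver centre from the
#' probe (minimum image across rows) and with the on-axis/on-circuit
#' indicators (the probe is on the circuit if any footprint cell lies in its
#' 7 x 7 region). Tissues whose initialization fails are resampled.
#'
#' @param n_tissues number of tissues to simulate.
#' @param probes_per_tissue multiprobes per tissue, a perfect square
#'   (default 64).
#' @param config lattice configuration (default [model_config()]).
#' @param seed RNG seed for the whole corpus.
#' @param duration recording window in steps (default 120, two circuit
#'   cycles).
#' @param pacing pacemaker enabled during initialization and recording
#'   (default TRUE).
#' @param progress print a note every `progress` tissues (0 = silent).
#' @return data frame with the feature columns of [feature_schema()] plus
#'   `tissue_id`, `probe_row`, `probe_col`, `driver_row`, `driver_col`,
#'   `dx`, `dy`, `on_x_axis`, `on_y_axis`, `on_circuit`. Attributes:
#'   `n_recordings` (accounting identity), `schema_version`, `n_resampled`.
#' @export
generate_training_set <- function(n_tissues, probes_per_tissue = 64L,
                                  config = model_config(), seed = NULL,
                                  duration = 120L, pacing = TRUE,
                                  progress = 0L) {
  stopifnot(n_tissues >= 1L)
  if (!is.null(seed)) set.seed(seed)
  L <- config$L
  grid <- .probe_grid(L, probes_per_tissue)
  sch <- feature_schema()
  rows <- vector("list", n_tissues)
  n_resampled <- 0L
  cfg <- config; cfg$seed <- NULL   # one RNG stream for the whole corpus

  for (i in seq_len(n_tissues)) {
    repeat {
      tis <- build_tissue(cfg)
      tis <- insert_circuit(tis)
      init <- tryCatch(initialize_af(tis, pacing = pacing),
                       error = function(e) NULL)
      if (!is.null(init)) break
      n_resampled <- n_resampled + 1L
    }
    circuit <- tis$circuits[[1]]
    ex <- rep(grid$col, each = 9L) + rep(c(-3, 0, 3), 3L * probes_per_tissue)
    ey <- rep(grid$row, each = 9L) + rep(rep(c(-3, 0, 3), each = 3L),
                                         probes_per_tissue)
    rec <- record_electrodes(tis, init$state, ex, ey,
                             t0 = init$t_ready, duration = duration,
                             pacing = pacing)
    feats <- matrix(NA_real_, probes_per_tissue, length(sch$columns),
                    dimnames = list(NULL, sch$columns))
    for (p in seq_len(probes_per_tissue)) {
      V <- rec$voltages[, ((p - 1L) * 9L + 1L):(p * 9L), drop = FALSE]
      feats[p, ] <- feature_vector(V)
    }
    lab <- t(vapply(seq_len(probes_per_tissue), function(p)
      .axis_labels(grid$row[p], grid$col[p], circuit, L), logical(2)))
    dx <- circuit$centre["col"] - grid$col
    dy <- .minimg(circuit$centre["row"] - grid$row, L)
    rows[[i]] <- data.frame(tissue_id = i, probe_row = grid$row,
                            probe_col = grid$col,
                            driver_row = unname(circuit$centre["row"]),
                            driver_col = unname(circuit$centre["col"]),
                            dx = unname(dx), dy = unname(dy),
                            on_x_axis = lab[, 1], on_y_axis = lab[, 2],
                            on_circuit = lab[, 1] & lab[, 2],
                            feats, check.names = FALSE)
    if (progress > 0L && i %% progress == 0L)
      message("corpus: ", i, "/", n_tissues, " tissues")
  }
  out <- do.call(rbind, rows)
  attr(out, "n_recordings") <- recording_count(n_tissues, probes_per_tissue)
  attr(out, "schema_version") <- sch$version
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Train the four random-forest models
#'
#' Two binary classifiers decide whether the probe lies on the driver's
#' X-band (its 7 x 7 window's columns overlap the circuit's column extent)
#' or Y-band (row analogue); two probabilistic locators predict the signed
#' driver-minus-probe displacement along each axis, discretized into 5-cell
#' bins. Class imbalance in the band classifiers is handled by a balanced
#' bootstrap (equal per-class sampling per tree). Forest induction is
#' delegated to
#' \pkg{ranger}; class probabilities are exposed as ensemble vote fractions
#' via [class_probabilities()].
#'
#' @param table a [generate_training_set()] corpus.
#' @param num_trees trees per forest (default 100).
#' @param seed RNG seed for the forests.
#' @return object of class `af_model_bundle` holding `clf_x`, `clf_y`,
#'   `prob_x`, `prob_y`, the class-to-displacement maps, the feature schema
#'   and training metadata.
#' @export
train_models <- function(table, num_trees = 100L, seed = 1L) {
  sch <- feature_schema()
  X <- table[, sch$columns, drop = FALSE]
  # bin half-ranges follow the lattice: x spans +/- (L-1), y +/- L/2
  hx <- max(200, .bin_width * ceiling(max(abs(table$dx)) / .bin_width))
  hy <- max(100, .bin_width * ceiling(max(abs(table$dy)) / .bin_width))

  fit_clf <- function(y, s) {
    y <- factor(y, levels = c(FALSE, TRUE))
    if (length(unique(y[!is.na(y)])) < 2L)
      stop("degenerate labels: both classes required", call. = FALSE)
    # on-band positives are rare (~20% in x, ~4% in y): balanced bootstrap
    # (equal per-class draws with replacement per tree) keeps the trees
    # sensitive to the positive class
    np <- min(table(y)) / length(y)
    ranger::ranger(x = X, y = y, num.trees = num_trees, seed = s,
                   num.threads = 1L, importance = "impurity",
                   replace = TRUE, sample.fraction = c(np, np))
  }
  fit_prob <- function(d, half, s) {
    y <- droplevels(factor(.bin_of(d, half)))
    # leaves of >= 25 samples: regularizes the displacement distributions
    # (higher end-to-end localization accuracy than fully grown trees) and
    # keeps the forests an order of magnitude leaner to evaluate
    ranger::ranger(x = X, y = y, num.trees = num_trees, seed = s,
                   num.threads = 1L, importance = "impurity",
                   min.node.size = 25L)
  }
  clf_x <- fit_clf(table$on_x_axis, seed)
  clf_y <- fit_clf(table$on_y_axis, seed + 1L)
  prob_x <- fit_prob(table$dx, hx, seed + 2L)
  prob_y <- fit_prob(table$dy, hy, seed + 3L)
  structure(list(
    clf_x = clf_x, clf_y = clf_y, prob_x = prob_x, prob_y = prob_y,
    x_map = data.frame(class = prob_x$forest$levels,
                       midpoint = .bin_mid(as.integer(prob_x$forest$levels), hx)),
    y_map = data.frame(class = prob_y$forest$levels,
                       midpoint = .bin_mid(as.integer(prob_y$forest$levels), hy)),
    schema_version = sch$version, feature_names = sch$columns,
    metadata = list(n_tissues = length(unique(table$tissue_id)),
                    n_rows = nrow(table), num_trees = num_trees,
                    seed = seed)),
    class = "af_model_bundle")
}

#' @export
print.af_model_bundle <- function(x, ...) {
  cat(sprintf(paste0("<af_model_bundle> %d trees/forest; trained on %d rows",
                     " from %d tissues (schema v%d)\n"),
              x$metadata$num_trees, x$metadata$n_rows,
              x$metadata$n_tissues, x$schema_version))
  invisible(x)
}

#' Ensemble vote fractions
#'
#' Converts per-class vote counts into probabilities `P_i = k_i / k` with
#' `k = sum_i k_i`.
#'
#' @param k non-negative vote counts.
#' @return probabilities summing to 1.
#' @export
#' @examples
#' vote_fractions(c(2, 3, 5))  # 0.2 0.3 0.5
vote_fractions <- function(k) {
  if (any(k < 0) || sum(k) <= 0) stop("invalid vote counts", call. = FALSE)
  k / sum(k)
}

.as_feature_df <- function(features, feature_names) {
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  features <- as.data.frame(features)
  missing <- setdiff(feature_names, colnames(features))
  if (length(missing))
    stop("feature schema mismatch; missing: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  features[, feature_names, drop = FALSE]
}

#' Class distribution of a forest prediction
#'
#' Tallies the per-tree votes of a trained classification forest on one
#' feature vector and returns the vote-fraction distribution over classes.
#'
#' @param model a ranger classification forest (e.g. `bundle$prob_x`).
#' @param features named feature vector or 1-row data frame matching the
#'   training schema.
#' @param feature_names training column order (default: taken from the
#'   model's forest).
#' @return data frame with `class` and `prob` (vote fractions summing to 1).
#' @export
class_probabilities <- function(model, features,
                                feature_names = model$forest$independent.variable.names) {
  df <- .as_feature_df(features, feature_names)
  pr <- stats::predict(model, data = df, predict.all = TRUE,
                       num.threads = 1L)$predictions
  lv <- model$forest$levels
  votes <- tabulate(pr[1, ], nbins = length(lv))
  data.frame(class = lv, prob = vote_fractions(votes))
}

#' Gini feature importance
#'
#' Mean-impurity-decrease importance per feature, normalized to sum to 1 and
#' sorted descending.
#'
#' @param model a trained ranger forest.
#' @return data frame with `feature` and `importance`.
#' @export
feature_importance <- function(model) {
  imp <- ranger::importance(model)
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]))
}

#' Persist / restore a model bundle
#'
#' @param bundle an `af_model_bundle`.
#' @param path file path.
#' @return `save_model_bundle`: `path` invisibly; `load_model_bundle`: the
#'   bundle (with a schema-version check).
#' @export
save_model_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "af_model_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "af_model_bundle") ||
      !identical(b$schema_version, .feature_schema_version))
    stop("incompatible model bundle (schema mismatch)", call. = FALSE)
  b
}
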