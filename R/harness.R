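#' Experiment configuration
#'
#' @param n_train_tissues tissues in the training corpus (default 500; the
#'   full-scale reference uses 5000).
#' @param n_eval_runs independent evaluation tissues (default 200; full
#'   scale 1500).
#' @param n_drivers 1 or 2 re-entrant circuits per evaluation tissue.
#' @param jump_limit per-search recording budget (default 30).
#' @param train_seed,eval_seed RNG seeds for the two phases.
#' @param model configuration of the lattice (default [model_config()]).
#' @param pacing pacemaker enabled during the experiments (default TRUE).
#' @param scale free-text scale label (default "desk").
#' @return object of class `af_experiment_config`.
#' @export
experiment_config <- function(n_train_tissues = 500L, n_eval_runs = 200L,
                              n_drivers = 1L, jump_limit = 30L,
                              train_seed = 20260101L, eval_seed = 20260102L,
                              model = model_config(), pacing = TRUE,
                              scale = "desk") {
  stopifnot(n_train_tissues >= 1L, n_eval_runs >= 1L,
            n_drivers %in% c(1L, 2L), jump_limit >= 0L)
  structure(list(n_train_tissues = as.integer(n_train_tissues),
                 n_eval_runs = as.integer(n_eval_runs),
                 n_drivers = as.integer(n_drivers),
                 jump_limit = as.integer(jump_limit),
                 train_seed = as.integer(train_seed),
                 eval_seed = as.integer(eval_seed),
                 model = model, pacing = pacing, scale = scale),
            class = "af_experiment_config")
}

# one evaluation tissue: 1 or 2 circuits (two circuits keep a minimum
# vertical separation of 10 rows), seeded and initialized; resampled on
# initialization failure
.eval_tissue <- function(config, n_drivers, min_sep = 10L, pacing = TRUE) {
  cfg <- config; cfg$seed <- NULL
  repeat {
    tis <- build_tissue(cfg)
    tis <- insert_circuit(tis)
    if (n_drivers == 2L) {
      r1 <- tis$circuits[[1]]$anchor[1]
      repeat {
        tis2 <- insert_circuit(tis)
        r2 <- tis2$circuits[[2]]$anchor[1]
        if (abs(.minimg(r2 - r1, cfg$L)) >= min_sep) { tis <- tis2; break }
        tis2 <- NULL
      }
    }
    init <- tryCatch(initialize_af(tis, pacing = pacing),
                     error = function(e) NULL)
    if (!is.null(init)) return(list(tissue = tis, init = init))
  }
}

#' Evaluate the search algorithm over an ensemble of tissues
#'
#' Generates `n_eval_runs` independent fibrillating tissues with 1 or 2
#' randomly placed drivers, runs the (multi-)driver search on each and
#' summarizes per-driver success fractions, jump statistics and failure
#' modes, in the format of the headline localization table: success is a
#' final positive prediction whose probe window overlaps a circuit, i.e. a
#' position whose ablation would terminate that circuit.
#'
#' @param config an [experiment_config()].
#' @param bundle trained `af_model_bundle`.
#' @param progress print a note every `progress` runs (0 = silent).
#' @return object of class `af_evaluation_summary`: per-driver rows with
#'   success fraction, mean and SD of jumps over successful searches,
#'   failure-mode counts and run counts, plus the per-run detail in
#'   `$runs`.
#' @export
run_table1 <- function(config, bundle, progress = 0L) {
  stopifnot(inherits(config, "af_experiment_config"),
            inherits(bundle, "af_model_bundle"))
  set.seed(config$eval_seed)
  nd <- config$n_drivers
  runs <- vector("list", config$n_eval_runs)
  for (i in seq_len(config$n_eval_runs)) {
    et <- .eval_tissue(config$model, nd, pacing = config$pacing)
    res <- locate_all(et$tissue, bundle, et$init$state, t0 = et$init$t_ready,
                      n_expected = nd, jump_limit = config$jump_limit,
                      pacing = config$pacing)
    row <- lapply(seq_len(nd), function(d) {
      if (d <= length(res)) {
        r <- res[[d]]
        data.frame(run = i, driver = d, success = r$success,
                   positive = r$positive, jumps = r$jumps,
                   failure_mode = r$failure_mode)
      } else {
        data.frame(run = i, driver = d, success = FALSE, positive = FALSE,
                   jumps = NA_integer_, failure_mode = "not_searched")
      }
    })
    runs[[i]] <- do.call(rbind, row)
    if (progress > 0L && i %% progress == 0L)
      message("evaluation: ", i, "/", config$n_eval_runs, " runs")
  }
  runs <- do.call(rbind, runs)
  per <- lapply(seq_len(nd), function(d) {
    sub <- runs[runs$driver == d, ]
    ok <- sub$success
    data.frame(driver = d, n_runs = nrow(sub),
               success_fraction = mean(ok),
               mean_jumps = mean(sub$jumps[ok]),
               sd_jumps = sd(sub$jumps[ok]),
               n_prediction_error = sum(sub$failure_mode == "prediction_error"),
               n_jump_limit = sum(sub$failure_mode == "jump_limit"),
               n_not_searched = sum(sub$failure_mode == "not_searched"),
               n_false_positive = sum(sub$positive & !sub$success))
  })
  structure(list(summary = do.call(rbind, per), runs = runs,
                 config = config),
            class = "af_evaluation_summary")
}

#' @export
print.af_evaluation_summary <- function(x, ...) {
  cat(sprintf("<af_evaluation_summary> %d runs, %d driver(s) [%s scale]\n",
              x$config$n_eval_runs, x$config$n_drivers, x$config$scale))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  driver %d: success %.1f%%, jumps %.1f +/- %.1f\n",
                s$driver[i], 100 * s$success_fraction[i], s$mean_jumps[i],
                s$sd_jumps[i]))
  invisible(x)
}

#' Random-placement baseline by exact enumeration
#'
#' The probability that a single uniformly random multiprobe placement lands
#' on the re-entrant circuit, i.e. that its 7 x 7 window contains a
#' footprint cell: the chance level that the guided search is compared
#' against. Enumerates every valid probe centre (all L rows, columns
#' restricted so the window stays inside the open boundary).
#'
#' @param L lattice side length (default 200).
#' @param circuit a circuit spec, or `NULL` for a default circuit placed
#'   centrally.
#' @param window probe window side (default 7).
#' @return list with `fraction`, `n_on`, `n_total`.
#' @export
random_placement_baseline <- function(L = 200L, circuit = NULL, window = 7L) {
  hw <- window %/% 2L
  cr <- c(1L + hw, L - hw)
  if (is.null(circuit)) {
    tis <- build_tissue(model_config(L = L, seed = 1L))
    tis <- insert_circuit(tis, anchor = c(L %/% 2L, (L - 30L) %/% 2L))
    circuit <- tis$circuits[[1]]
  }
  n_total <- L * (cr[2] - cr[1] + 1L)
  if (is.null(circuit$rows) || !length(circuit$rows))
    return(list(fraction = 0, n_on = 0L, n_total = n_total))
  crows <- unique(.wrap_row(circuit$rows, L))
  n_on <- 0L
  for (r in seq_len(L)) {
    wr <- .wrap_row((r - hw):(r + hw), L)
    if (!any(crows %in% wr)) next
    for (cc in cr[1]:cr[2]) {
      wc <- (cc - hw):(cc + hw)
      if (any(wc >= circuit$cols[1] & wc <= circuit$cols[2]))
        n_on <- n_on + 1L
    }
  }
  list(fraction = n_on / n_total, n_on = n_on, n_total = n_total)
}

#' Evaluation report
#'
#' Renders an evaluation summary side by side with reference success rates,
#' with binomial standard-error confidence intervals at the run count used,
#' and returns the same content as a JSON-ready list.
#'
#' @param summary an `af_evaluation_summary`.
#' @param targets optional numeric vector of reference success fractions per
#'   driver (for side-by-side display).
#' @param path optional path to write the JSON report to.
#' @return list with `text` (character lines) and `data` (the report list).
#' @export
report <- function(summary, targets = NULL, path = NULL) {
  stopifnot(inherits(summary, "af_evaluation_summary"))
  s <- summary$summary
  if (any(s$n_runs == 0)) stop("no runs to report", call. = FALSE)
  lines <- character(0)
  data <- list(scale = summary$config$scale, n_runs = summary$config$n_eval_runs,
               drivers = list())
  for (i in seq_len(nrow(s))) {
    p <- s$success_fraction[i]; n <- s$n_runs[i]
    half <- 1.96 * sqrt(p * (1 - p) / n)
    tgt <- if (!is.null(targets) && length(targets) >= i)
      sprintf(" (reference %.1f%%)", 100 * targets[i]) else ""
    lines <- c(lines, sprintf(
      "driver %d: success %.1f%% +/- %.1f pp [n=%d]%s; jumps %.1f +/- %.1f",
      s$driver[i], 100 * p, 100 * half, n, tgt, s$mean_jumps[i], s$sd_jumps[i]))
    data$drivers[[i]] <- list(
      driver = s$driver[i], success_fraction = p, ci_halfwidth = half,
      mean_jumps = s$mean_jumps[i], sd_jumps = s$sd_jumps[i],
      reference = if (!is.null(targets) && length(targets) >= i)
        targets[i] else NULL,
      failure_modes = list(prediction_error = s$n_prediction_error[i],
                           jump_limit = s$n_jump_limit[i],
                           not_searched = s$n_not_searched[i]))
  }
  if (!is.null(path))
    jsonlite::write_json(data, path, auto_unbox = TRUE, digits = NA)
  list(text = lines, data = data)
}
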