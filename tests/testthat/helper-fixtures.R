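# Shared fixtures. Everything is generated in code; the expensive objects
# (training corpus, model bundle, evaluation runs) are built once per test
# session and reused across files via this cache.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# desk-scale study conditions: 500 training tissues, evaluations of 200
# tissues per driver count (the full-scale reference is 5000 / 1500)
N_TRAIN_TISSUES <- 500L
N_EVAL_RUNS <- 200L
TRAIN_SEED <- 20260101L
EVAL_SEED_1 <- 20260102L
EVAL_SEED_2 <- 20260103L

shared_corpus <- function() {
  cached("corpus", generate_training_set(N_TRAIN_TISSUES, seed = TRAIN_SEED))
}

shared_bundle <- function() {
  cached("bundle", train_models(shared_corpus(), seed = TRAIN_SEED))
}

shared_eval <- function(n_drivers = 1L) {
  key <- paste0("eval", n_drivers)
  cached(key, {
    cfg <- experiment_config(
      n_train_tissues = N_TRAIN_TISSUES, n_eval_runs = N_EVAL_RUNS,
      n_drivers = n_drivers,
      train_seed = TRAIN_SEED,
      eval_seed = if (n_drivers == 1L) EVAL_SEED_1 else EVAL_SEED_2)
    run_table1(cfg, shared_bundle())
  })
}

# a fibrillating single-driver tissue for probing (fixed seed)
fib_tissue <- function(seed = 421L, anchor = NULL) {
  set.seed(seed)
  tis <- build_tissue(model_config())
  tis <- insert_circuit(tis, anchor = anchor)
  init <- initialize_af(tis)
  list(tissue = tis, state = init$state, t0 = init$t_ready,
       circuit = tis$circuits[[1]])
}

# brute-force oracle: does the 7x7 window centred at (r, c) contain any
# footprint cell? (independent of the package's label computation)
oracle_on_circuit <- function(r, c, circuit, L) {
  wrap <- function(z) ((z - 1) %% L) + 1
  fp <- expand.grid(row = wrap(circuit$rows), col = circuit$cols[1]:circuit$cols[2])
  win <- expand.grid(row = wrap((r - 3):(r + 3)), col = (c - 3):(c + 3))
  any(interaction(win$row, win$col) %in% interaction(fp$row, fp$col))
}

# synthetic corpus-shaped table whose labels are a clean threshold function
# of one feature; used for separability / importance tests
synthetic_table <- function(n = 400, seed = 1) {
  set.seed(seed)
  sch <- feature_schema()
  X <- matrix(rnorm(n * length(sch$columns)), n,
              dimnames = list(NULL, sch$columns))
  df <- data.frame(tissue_id = seq_len(n), probe_row = 1L, probe_col = 100L,
                   driver_row = 1, driver_col = 100,
                   dx = runif(n, -150, 150), dy = runif(n, -90, 90),
                   X, check.names = FALSE)
  # push the planted features away from the threshold so the labels are
  # separable with a margin
  df$e1_v_max <- df$e1_v_max + 0.5 * sign(df$e1_v_max)
  df$e1_v_min <- df$e1_v_min + 0.5 * sign(df$e1_v_min)
  df$on_x_axis <- df$e1_v_max > 0
  df$on_y_axis <- df$e1_v_min > 0
  df$on_circuit <- df$on_x_axis & df$on_y_axis
  df
}

# a bundle whose band classifiers always assert TRUE on real recordings:
# trained on a synthetic threshold placed below any realistic feature value
always_positive_bundle <- function() {
  cached("always_positive_bundle", {
    df <- synthetic_table(400, seed = 2)
    df$e1_intensity[1:60] <- -100           # a separable negative class
    df$on_x_axis <- df$e1_intensity > -50   # real intensities are >= 0
    df$on_y_axis <- df$e1_intensity > -50
    df$on_circuit <- df$on_x_axis & df$on_y_axis
    train_models(df, num_trees = 20, seed = 3)
  })
}
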