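test_that("configuration validation and physical timescales", {
  expect_error(model_config(L = 5), "L")
  expect_error(model_config(nu = 1.2), "\\[0, 1\\]")
  expect_error(model_config(tau = 0), "tau")
  expect_error(model_config(T_pace = 50, tau = 50), "T_pace")
  ts <- timescales(model_config())
  expect_equal(ts$dt_ms, 3.0)
  expect_equal(ts$refractory_ms, 150)
  expect_equal(ts$pacing_ms, 660)
})

test_that("tissue construction draws Bernoulli couplings", {
  tis <- build_tissue(model_config(L = 10, nu = 1, delta = 0, seed = 1))
  expect_equal(sum(tis$trans_up), 100)
  expect_equal(sum(tis$dysfunctional), 0)

  # nu = 0: no transverse couplings, a wave never leaves its fibre
  t0 <- build_tissue(model_config(L = 20, nu = 0, seed = 2))
  expect_equal(sum(t0$trans_up), 0)
  st <- new_state(t0); st[10, 10] <- 1L
  st <- cmp_step(t0, st, t = 1, nsteps = 8, pacing = FALSE)
  expect_true(all(which(st != 0L, arr.ind = TRUE)[, 1] == 10))

  # binomial sampling at nu = 0.2 over 10 seeds
  fr <- vapply(1:10, function(s)
    mean(build_tissue(model_config(L = 200, nu = 0.2, seed = s))$trans_up),
    numeric(1))
  expect_lt(abs(mean(fr) - 0.2), 3 * sqrt(0.2 * 0.8 / 40000))
})

test_that("circuit insertion decouples the segment and is idempotent", {
  tis <- build_tissue(model_config(seed = 3))
  tis <- insert_circuit(tis, anchor = c(50, 60))
  circ <- tis$circuits[[1]]
  expect_equal(circ$path_length, 60L)
  expect_equal(diff(circ$cols) + 1L, 30L)           # 2 x 30 footprint
  expect_equal(length(unique(circ$rows)), 2L)
  expect_equal(unname(circ$centre), c(50.5, 74.5))
  # interior bonds removed, end bonds present
  expect_false(any(tis$trans_up[50, 61:88]))
  expect_false(any(tis$trans_up[49, 61:88]))
  expect_true(tis$trans_up[50, 60] && tis$trans_up[50, 89])

  tis2 <- insert_circuit(tis, anchor = c(50, 60))
  expect_identical(tis2$trans_up, tis$trans_up)      # idempotent

  expect_error(insert_circuit(tis, anchor = c(10, 180)), "boundary")
})

test_that("seeded circuit circulates unidirectionally with period 60", {
  tis <- build_tissue(model_config(seed = 42))
  tis <- insert_circuit(tis, anchor = c(100, 80))
  st <- seed_circuit_excitation(tis)
  expect_equal(count_active(st), 1L)

  head_cell <- c(tis$circuits[[1]]$rows[1], tis$circuits[[1]]$cols[2])
  times <- integer(0)
  s <- st
  for (t in 1:250) {
    s <- cmp_step(tis, s, t = t - 1, pacing = FALSE)
    if (s[head_cell[1], head_cell[2]] == 1L) times <- c(times, t)
  }
  expect_equal(diff(c(0L, times)), rep(60L, 4))      # exact circuit period

  # an unsustainable circuit (tau >= path length) warns; the circulation is
  # blocked by its own refractory tail within the first lap, so the seeded
  # cell is not re-excited at the loop period
  tshort <- build_tissue(model_config(tau = 70, T_pace = 220, seed = 5))
  tshort <- insert_circuit(tshort, anchor = c(100, 80))
  expect_warning(st2 <- seed_circuit_excitation(tshort), "self-sustain")
  refires <- 0L
  for (t in 1:70) {
    st2 <- cmp_step(tshort, st2, t = t - 1, pacing = FALSE)
    if (st2[100, 109] == 1L) refires <- refires + 1L
  }
  expect_equal(refires, 0L)
})

test_that("synchronous update follows the excitation rules", {
  # interior excited cell with full coupling excites its 4 neighbours
  tis <- build_tissue(model_config(L = 11, nu = 1, seed = 1))
  st <- new_state(tis); st[6, 6] <- 1L
  nx <- cmp_step(tis, st, t = 1, pacing = FALSE)
  expect_equal(nx[6, 6], 2L)
  expect_equal(sort(which(nx == 1L)),
               sort(c(11 * 4 + 6, 11 * 6 + 6, 11 * 5 + 5, 11 * 5 + 7)))

  # a refractory neighbour is not re-excited
  st2 <- new_state(tis); st2[6, 6] <- 1L; st2[6, 7] <- 5L
  nx2 <- cmp_step(tis, st2, t = 1, pacing = FALSE)
  expect_equal(nx2[6, 7], 6L)

  # a dysfunctional cell with epsilon = 1 never fires
  td <- build_tissue(model_config(L = 11, nu = 1, delta = 1, epsilon = 1,
                                  seed = 1))
  std <- new_state(td); std[6, 6] <- 1L
  set.seed(1)
  nxd <- cmp_step(td, std, t = 1, pacing = FALSE)
  expect_equal(count_active(nxd), 0L)
})

test_that("pacemaker fires every T_pace and respects refractoriness", {
  tis <- build_tissue(model_config(L = 20, nu = 1, tau = 5, T_pace = 10,
                                   seed = 1))
  st <- cmp_step(tis, new_state(tis), t = 0, pacing = TRUE)
  expect_true(all(st[, 1] == 2L))                   # paced then refractory
  expect_true(all(st[, 2] == 1L))

  # refractory boundary cells are not reset by the pacemaker
  st2 <- new_state(tis); st2[, 1] <- 3L
  nx <- cmp_step(tis, st2, t = 0, pacing = TRUE)    # t %% T == 0
  expect_true(all(nx[, 1] == 4L))
})

test_that("excited-cell count and the fibrillation threshold", {
  cfg <- model_config()
  st <- matrix(0L, 200, 200)
  st[seq_len(220)] <- 1L
  expect_equal(count_active(st), 220L)
  expect_false(is_fibrillating(st, cfg))            # strict inequality
  st[221] <- 1L
  expect_true(is_fibrillating(st, cfg))

  # a plane wave occupies one column: L excited cells, not fibrillating
  tis <- build_tissue(model_config(nu = 1, seed = 1))
  pw <- cmp_step(tis, new_state(tis), t = 0, nsteps = 50)
  expect_equal(count_active(pw), 200L)
  expect_false(is_fibrillating(pw, cfg))
})

test_that("plane-wave conduction speed is exactly one column per step", {
  tis <- build_tissue(model_config(nu = 1, seed = 1))
  st <- new_state(tis)
  for (t in c(10, 120)) {
    s <- cmp_step(tis, st, t = 0, nsteps = t)
    expect_equal(unique(which(s == 1L, arr.ind = TRUE)[, 2]), t + 1)
  }
  s <- cmp_step(tis, st, t = 0, nsteps = 200)       # crossed in L steps
  expect_equal(count_active(s), 0L)
})

test_that("cell state machine is sound on random fibrillating tissue", {
  set.seed(7)
  cfg <- model_config(L = 40, tau = 12, T_pace = 30, seed = 8)
  tis <- build_tissue(cfg)
  tis <- insert_circuit(tis, anchor = c(20, 5))
  st <- seed_circuit_excitation(tis)
  prev <- st
  for (t in 1:120) {
    nxt <- cmp_step(tis, prev, t = t - 1, pacing = FALSE)
    tau <- cfg$tau
    # legal transitions only
    expect_true(all(nxt[prev == 1L] == 2L))
    mid <- prev >= 2L & prev <= tau
    expect_true(all(nxt[mid] == prev[mid] + 1L))
    expect_true(all(nxt[prev == tau + 1L] == 0L))
    expect_true(all(nxt[prev == 0L] %in% c(0L, 1L)))
    prev <- nxt
  }
})

test_that("dynamics are equivariant under row translation", {
  cfg <- model_config(L = 60, seed = 12)
  tis <- build_tissue(cfg)
  tis <- insert_circuit(tis, anchor = c(10, 15))
  k <- 23L
  shift <- function(m, k) m[((seq_len(nrow(m)) - 1L - k) %% nrow(m)) + 1L, ]
  tis2 <- tis
  tis2$trans_up <- shift(tis$trans_up, k)
  tis2$circuits <- list()
  tis2 <- insert_circuit(tis2, anchor = c(10 + k, 15))
  s1 <- seed_circuit_excitation(tis)
  s2 <- seed_circuit_excitation(tis2)
  expect_identical(shift(s1, k), s2)
  a <- cmp_step(tis, s1, t = 0, nsteps = 90, pacing = TRUE)
  b <- cmp_step(tis2, s2, t = 0, nsteps = 90, pacing = TRUE)
  expect_identical(shift(a, k), b)
})

test_that("AF initialization reaches fibrillation or fails loudly", {
  set.seed(31)
  tis <- build_tissue(model_config())
  tis <- insert_circuit(tis)
  init <- initialize_af(tis)
  expect_true(is_fibrillating(init$state, tis$config))
  expect_lt(init$t_ready, 20 * 200)

  # sinus plane wave alone is never fibrillating (onset monotonicity)
  iso <- build_tissue(model_config(nu = 1, seed = 1))
  st <- new_state(iso)
  fib <- vapply(1:200, function(t) {
    st <<- cmp_step(iso, st, t = t - 1)
    is_fibrillating(st, iso$config)
  }, logical(1))
  expect_false(any(fib))

  # unsustainable circuit in decoupled tissue: the blocked beat's emission
  # runs off the open fibre ends and everything extinguishes
  tbad <- build_tissue(model_config(nu = 0, tau = 70, seed = 5))
  tbad <- insert_circuit(tbad, anchor = c(100, 80))
  expect_warning(stbad <- seed_circuit_excitation(tbad), "self-sustain")
  expect_error(initialize_af(tbad, state = stbad, pacing = FALSE),
               "initialization failure")
})

test_that("an ectopic focus beats at its period and skips refractory beats", {
  tis <- build_tissue(model_config(L = 40, nu = 1, tau = 10, T_pace = 100,
                                   seed = 2))
  tis <- insert_ectopic(tis, c(20, 20), period = 30)
  st <- new_state(tis)
  hits <- integer(0)
  for (t in 1:100) {
    st <- cmp_step(tis, st, t = t - 1, pacing = FALSE)
    if (st[20, 20] == 2L) hits <- c(hits, t)   # just past excitation
  }
  expect_equal(hits, c(1, 31, 61, 91))
  # forced beat is skipped while the focus is refractory
  st2 <- new_state(tis); st2[20, 20] <- 5L
  nx <- cmp_step(tis, st2, t = 0, pacing = FALSE)   # t %% 30 == 0
  expect_equal(nx[20, 20], 6L)
})
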