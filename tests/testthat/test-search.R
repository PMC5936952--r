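test_that("a fresh search starts unconstrained with zero jumps", {
  fx <- fib_tissue()
  set.seed(71)
  s <- init_search(fx$tissue)
  expect_equal(s$jumps, 0L)
  expect_true(all(s$constraints$x_allowed) && all(s$constraints$y_allowed))
  cr <- probe_col_range(200)
  expect_true(s$centre["col"] >= cr[1] && s$centre["col"] <= cr[2])

  set.seed(72); a <- init_search(fx$tissue)
  set.seed(72); b <- init_search(fx$tissue)
  expect_identical(a$centre, b$centre)             # seeded reproducibility

  # initial centres always satisfy placement bounds
  set.seed(73)
  for (i in 1:25) {
    ctr <- init_search(fx$tissue)$centre
    expect_no_error(make_multiprobe(ctr, 200))
  }
})

test_that("constrained axis proposals take the admissible argmax", {
  L <- 200L
  mask <- rep(TRUE, L)
  dist <- data.frame(class = 1:3, prob = c(0.2, 0.7, 0.1))
  mids <- c(-50, 20, 60)
  # argmax inside the region: its mapped coordinate
  p <- aflocate:::.propose_axis(dist, mids, 100, mask, FALSE, L)
  expect_equal(p$coord, 120)
  # all mass left of an x cut gets clipped to the admissible set
  mask2 <- rep(FALSE, L); mask2[140:200] <- TRUE
  p2 <- aflocate:::.propose_axis(dist, mids, 100, mask2, FALSE, L)
  expect_equal(p2$coord, 160)                      # only +60 bin admissible
  # no admissible mass at all: fall back to the region midpoint
  d0 <- data.frame(class = 1, prob = 1)
  p3 <- aflocate:::.propose_axis(d0, -50, 100, mask2, FALSE, L)
  expect_true(p3$fallback)
  expect_equal(p3$coord, 170)
  # uniform distribution: tie-break to the bin nearest the region midpoint
  du <- data.frame(class = 1:3, prob = rep(1 / 3, 3))
  p4 <- aflocate:::.propose_axis(du, c(-60, 10, 80), 100, mask, FALSE, L)
  expect_equal(p4$coord, 110)
})

test_that("half-space constraint updates shrink the region soundly", {
  fx <- fib_tissue()
  set.seed(74)
  s <- init_search(fx$tissue)
  s$centre <- c(row = 50, col = 80)
  s$visited <- list(c(50, 80))

  # plain half-space rule (margin 0): +40 in x leaves [81, L]
  upd <- update_constraints(s, c(row = 50, col = 120), margin = 0L)
  expect_false(upd$prediction_error)
  expect_equal(min(which(upd$constraints$x_allowed)), 81)
  expect_true(all(upd$constraints$y_allowed))      # no row displacement

  # default margin retains a buffer behind the cut
  upd8 <- update_constraints(s, c(row = 50, col = 120))
  expect_equal(min(which(upd8$constraints$x_allowed)), 80 - 8 + 1)

  # row inference keeps the half-circle (plus margin) on the proposal side
  updy <- update_constraints(s, c(row = 90, col = 80), margin = 0L)
  yr <- which(updy$constraints$y_allowed)
  expect_true(all(yr %in% (50 + 1:100)))

  # revisiting a previous centre is a prediction error
  updr <- update_constraints(s, c(row = 50, col = 80))
  expect_true(updr$prediction_error)

  # alternating-sign cuts shrink the x-width monotonically
  s2 <- init_search(fx$tissue)
  s2$centre <- c(row = 50, col = 100)
  widths <- sum(s2$constraints$x_allowed)
  props <- list(c(50, 160), c(50, 110), c(50, 125))
  centres <- list(c(50, 140), c(50, 118), c(50, 122))
  for (i in 1:3) {
    upd <- update_constraints(s2, c(row = 50, col = props[[i]][2]),
                              margin = 0L)
    s2$constraints <- upd$constraints
    s2$centre <- c(row = 50, col = centres[[i]][2])
    widths <- c(widths, sum(s2$constraints$x_allowed))
  }
  expect_true(all(diff(widths) < 0))
})

test_that("the driver never leaves the region under ground-truth side
           inferences", {
  set.seed(75)
  L <- 200L
  for (rep in 1:20) {
    driver <- c(row = sample(L, 1), col = sample(4:197, 1))
    s <- structure(list(centre = c(row = sample(L, 1),
                                   col = sample(4:197, 1)),
                        visited = list(),
                        constraints = constraint_region(L), jumps = 0L),
                   class = "search_state")
    for (k in 1:12) {
      # oracle proposal: the true driver position itself
      upd <- update_constraints(s, driver, margin = 0L, x_gate = Inf)
      s$constraints <- upd$constraints
      expect_true(s$constraints$x_allowed[driver["col"]])
      expect_true(s$constraints$y_allowed[driver["row"]])
      if (upd$prediction_error) break
      s$visited <- c(s$visited, list(unname(s$centre)))
      # move towards the driver within the region
      nxt <- c(row = aflocate:::.nearest_allowed(driver["row"],
                 s$constraints$y_allowed, TRUE, L),
               col = aflocate:::.nearest_allowed(driver["col"],
                 s$constraints$x_allowed, FALSE, L))
      if (all(nxt == s$centre)) break
      s$centre <- nxt
    }
  }
})

test_that("band classifiers separate on-circuit from far-field probes", {
  bundle <- shared_bundle()
  set.seed(76)
  on_rate <- c(); far_rate <- c()
  for (i in 1:12) {
    fx <- fib_tissue(seed = 1000 + i)
    ctr_on <- round(fx$circuit$centre)
    ctr_on[2] <- min(max(ctr_on[2], 4), 197)
    ctr_far <- c(aflocate:::.wrap_row(ctr_on[1] + 100, 200),
                 ((ctr_on[2] + 70) %% 194) + 4)
    st <- fx$state; t <- fx$t0
    for (ctr in list(ctr_on, ctr_far)) {
      rec <- record_multiprobe(fx$tissue, st, make_multiprobe(ctr, 200),
                               t0 = t)
      st <- rec$state; t <- rec$t_end
      pos <- check_positive(bundle, feature_vector(rec$voltages))
      if (identical(unname(ctr), unname(ctr_on)))
        on_rate <- c(on_rate, pos) else far_rate <- c(far_rate, pos)
    }
  }
  expect_gt(mean(on_rate), mean(far_rate) + 0.3)
  expect_lt(mean(far_rate), 0.2)
})

test_that("an always-negative classifier never declares a positive", {
  bundle <- always_positive_bundle()
  # flip the classifiers: train on labels that no real recording satisfies
  df <- synthetic_table(300, seed = 77)
  df$e1_intensity[1:150] <- 1e6                    # unreachable positives
  df$on_x_axis <- df$e1_intensity > 1e5
  df$on_y_axis <- df$e1_intensity > 1e5
  neg <- train_models(df, num_trees = 20, seed = 78)
  fx <- fib_tissue()
  rec <- record_multiprobe(fx$tissue, fx$state,
                           make_multiprobe(c(50, 100), 200), t0 = fx$t0)
  fv <- feature_vector(rec$voltages)
  expect_false(check_positive(neg, fv))
  expect_true(check_positive(bundle, fv))
})

test_that("search terminates within the jump budget and counts recordings", {
  fx <- fib_tissue(seed = 2001)
  bundle <- shared_bundle()
  expect_equal(locate_driver(fx$tissue, bundle, fx$state, t0 = fx$t0,
                             jump_limit = 0)$failure_mode, "jump_limit")
  set.seed(79)
  res <- locate_driver(fx$tissue, bundle, fx$state, t0 = fx$t0,
                       jump_limit = 4)
  expect_lte(res$jumps, 4L)
  expect_equal(res$jumps, length(res$visited))
  if (res$success) expect_true(res$positive)       # success implies positive
})

test_that("a search started on the circuit with a firing classifier stops
           in one jump", {
  fx <- fib_tissue(seed = 2002)
  bundle <- always_positive_bundle()
  ctr <- round(fx$circuit$centre)
  ctr[2] <- min(max(ctr[2], 4), 197)
  s <- structure(list(centre = c(row = unname(ctr[1]), col = unname(ctr[2])),
                      visited = list(),
                      constraints = constraint_region(200), jumps = 0L),
                 class = "search_state")
  res <- locate_driver(fx$tissue, bundle, fx$state, t0 = fx$t0, search = s)
  expect_true(res$positive)
  expect_true(res$success)
  expect_equal(res$jumps, 1L)
})

test_that("expected collision rows sit at antipodes and arc midpoints", {
  expect_equal(expected_collision_rows(1, 200), 101L)
  expect_equal(expected_collision_rows(101, 200), 1L)
  expect_equal(expected_collision_rows(50, 200), 150L)
  # two symmetric drivers: collisions at the two mid-rows between them
  expect_equal(sort(expected_collision_rows(c(1, 101), 200)), c(51L, 151L))
  expect_equal(sort(expected_collision_rows(c(40, 120), 200)),
               c(80L, 180L))
})

test_that("multi-driver search stops after an observed collision on
           single-driver tissue", {
  bundle <- shared_bundle()
  set.seed(80)
  n_second <- 0L; n_spurious <- 0L
  for (i in 1:6) {
    fx <- fib_tissue(seed = 3000 + i)
    res <- locate_all(fx$tissue, bundle, fx$state, t0 = fx$t0,
                      n_expected = 2)
    if (length(res) > 1L) {
      n_second <- n_second + 1L
      n_spurious <- n_spurious + res[[2]]$positive
    }
  }
  expect_lte(n_second, 2L)   # collisions observed in most single-driver runs
  expect_equal(n_spurious, 0L)  # and no phantom second driver is reported
})

test_that("second search is confined away from the first driver", {
  bundle <- shared_bundle()
  set.seed(81)
  for (i in 1:4) {
    tis <- build_tissue(model_config())
    tis <- insert_circuit(tis, anchor = c(40, 60))
    tis <- insert_circuit(tis, anchor = c(140, 100))
    init <- initialize_af(tis)
    res <- locate_all(tis, bundle, init$state, t0 = init$t_ready,
                      n_expected = 2)
    if (length(res) == 2L && res[[1]]$positive) {
      d1row <- res[[1]]$final_centre[["row"]]
      rows2 <- vapply(res[[2]]$visited, `[`, numeric(1), 1)
      expect_true(all(abs(aflocate:::.minimg(rows2 - d1row, 200)) > 4))
    }
  }
})
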