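test_that("blocking probability laws match their closed forms", {
  geo <- vessel_schedule("geometric", p0 = 0.5, r = 0.999876, p_floor = 0.001)
  expect_equal(blocking_probability(geo, t = 1), 0.5 * 0.999876)
  expect_equal(blocking_probability(geo, t = 0), 0.5)
  # floor engaged for all later times
  tf <- ceiling(log(0.001 / 0.5) / log(0.999876))
  expect_equal(blocking_probability(geo, t = tf + c(0, 100, 1e5)),
               rep(0.001, 3))
  fb <- vessel_schedule("density_feedback")
  expect_equal(blocking_probability(fb, coverage = 0), 0.001)
  expect_equal(blocking_probability(fb, coverage = 1), 0.5)
  expect_error(blocking_probability(fb, coverage = 2), "coverage")
  cons <- vessel_schedule("constant", p0 = 0.25)
  expect_equal(blocking_probability(cons, t = 123), 0.25)
})

test_that("vessel state chain: frozen at P=0, symmetric stationary state", {
  expect_identical(update_vessel_states(c(TRUE, FALSE), 0), c(TRUE, FALSE))
  set.seed(3)
  # 200 vessels, 5000 MCS at P=0.5: active fraction ~ 0.5
  act <- rep(TRUE, 200)
  frac <- 0
  for (i in 1:5000) {
    act <- update_vessel_states(act, 0.5)
    frac <- frac + mean(act)
  }
  expect_equal(frac / 5000, 0.5, tolerance = 0.02)
  # mean contiguous active duration ~ 1/P at P = 0.1
  set.seed(4)
  one <- logical(2e4); s <- TRUE
  for (i in seq_along(one)) { s <- update_vessel_states(s, 0.1); one[i] <- s }
  r <- rle(one)
  durations <- r$lengths[r$values]
  expect_equal(mean(durations), 10, tolerance = 0.15)
})

test_that("vessel boundary clamps and inactive-vessel policies", {
  st <- make_bare_state(12, 12, g = 0.3, o2 = 0.2, l = 0.7)
  ec <- add_block_cell(st, 5, 6, 5, 6, v_t = 4, type = 2L)
  st$vessel_ids <- ec; st$vessel_active <- TRUE
  st$vessel_sites <- list(c(4 + 12 * 4, 5 + 12 * 4, 4 + 12 * 5, 5 + 12 * 5))
  st$n_ec_sites <- 4L
  apply_vessel_boundary(st)
  expect_true(all(st$g[5:6, 5:6] == 1))
  expect_true(all(st$o2[5:6, 5:6] == 1))
  expect_true(all(st$lac[5:6, 5:6] == 0))
  # lactate produced next to an active vessel is removed at the vessel each
  # substep
  st$lac[4, 5] <- 5
  step_fields(st)
  expect_true(all(st$lac[5:6, 5:6] == 0))
  # inert policy: a blocked vessel's sites evolve exactly like plain
  # diffusion (compare against a clamp-free twin)
  st2 <- make_bare_state(12, 12, g = 0.3, o2 = 0.2, l = 0)
  st2$g[3, 3] <- 1 # some structure
  st3 <- make_bare_state(12, 12, g = 0.3, o2 = 0.2, l = 0)
  st3$g[3, 3] <- 1
  ec2 <- add_block_cell(st2, 5, 6, 5, 6, v_t = 4, type = 2L)
  st2$vessel_ids <- ec2; st2$vessel_active <- FALSE
  st2$vessel_sites <- st$vessel_sites
  step_fields(st2); step_fields(st3)
  expect_equal(st2$g, st3$g, tolerance = 1e-12)
  # zero policy clamps blocked vessels to zero
  st2$params$fields$inactive_vessel <- "zero"
  step_fields(st2)
  expect_true(all(st2$g[5:6, 5:6] == 0))
})

test_that("explicit field stepping: zero fixed point, mass conservation, symmetry", {
  st <- make_bare_state(16, 16, g = 0, o2 = 0, l = 0)
  step_fields(st)
  expect_equal(sum(st$g) + sum(st$o2) + sum(st$lac), 0)
  # mass conservation on the periodic lattice without clamps
  st$g[] <- matrix(runif(256), 16)
  m0 <- sum(st$g)
  step_fields(st)
  expect_equal(sum(st$g), m0, tolerance = 1e-9)
  # single centered clamp on a symmetric lattice keeps 4-fold symmetry
  sts <- make_bare_state(15, 15, g = 0, o2 = 0, l = 0)
  ec <- add_block_cell(sts, 8, 8, 8, 8, v_t = 1, type = 2L)
  sts$vessel_ids <- ec; sts$vessel_active <- TRUE
  sts$vessel_sites <- list(7 + 15 * 7)
  step_fields(sts)
  expect_equal(sts$o2, sts$o2[15:1, ], tolerance = 1e-12)
  expect_equal(sts$o2, t(sts$o2), tolerance = 1e-12)
})

test_that("quasi-steady relaxation solver approaches the clamped fixed point", {
  st <- make_bare_state(12, 12, g = 0, o2 = 0, l = 0,
                        fields = field_params(glucose_solver = "relax",
                                              relax_maxiter = 5000,
                                              relax_tol = 1e-10))
  ec <- add_block_cell(st, 6, 6, 6, 6, v_t = 1, type = 2L)
  st$vessel_ids <- ec; st$vessel_active <- TRUE
  st$vessel_sites <- list(5 + 12 * 5)
  step_fields(st)
  # harmonic fixed point on a periodic lattice with one Dirichlet site is
  # the constant field
  expect_equal(max(abs(st$g - 1)), 0, tolerance = 1e-4)
})

test_that("initial regime equilibrates, leaves no lactate, and checkpoints reproduce", {
  cfg <- experiment_config(width = 40, height = 40, mcs = 0, seed = 9,
                           mutation_rate = 0.1, equilibrate = TRUE)
  st <- build_initial_state(cfg)
  expect_equal(sum(st$lac), 0)   # all cells respiratory during the regime
  expect_equal(st$t, 0L)
  expect_gt(mean(st$g), 0.5)     # fields filled from the vessels
  # convergence criterion actually holds at exit
  g0 <- st$g; o0 <- st$o2
  st$frozen <- TRUE
  saved <- st$vessel_active
  st$vessel_active <- rep(TRUE, length(st$vessel_ids))
  run_mcs(st, 100)
  expect_lt(sum(abs(st$g - g0)), 0.05 * sum(g0))
  expect_lt(sum(abs(st$o2 - o0)), 0.05 * sum(o0))
  st$frozen <- FALSE; st$vessel_active <- saved

  # serialization round-trip: same seed-continuation, same trajectory
  f <- tempfile(fileext = ".rds")
  save_state(st, f)
  run_mcs(st, 5)
  after1 <- list(grid = st$grid, vt = st$VT, g = st$g)
  st2 <- load_state(f)
  run_mcs(st2, 5)
  expect_identical(st2$grid, after1$grid)
  expect_identical(st2$VT, after1$vt)
  expect_identical(st2$g, after1$g)
  unlink(f)
})

test_that("average vessel-active fraction is P-independent", {
  set.seed(21)
  for (p in c(0.5, 0.1, 0.01)) {
    act <- rep(c(TRUE, FALSE), 50)
    tot <- 0; n <- 4000
    for (i in seq_len(n)) {
      act <- update_vessel_states(act, p)
      tot <- tot + mean(act)
    }
    expect_equal(tot / n, 0.5, tolerance = 0.06)
  }
})
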