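test_that("target-volume growth terms behave as specified", {
  gw <- growth_params()
  e_m <- metabolic_params()$e_m
  # all terms vanish: balanced cell at rest
  r <- update_target_volume(25, 25, e_prod = e_m, zeta = 0)
  expect_equal(r$v_t, 25); expect_false(r$dead)
  # ROS above tolerance contributes exactly -gamma
  r2 <- update_target_volume(25, 25, e_prod = e_m, zeta = gw$theta_r + 1)
  expect_equal(r2$v_t, 25 - gw$gamma)
  # compressed cell grows more slowly than an uncompressed one
  rc <- update_target_volume(20, 30, e_prod = e_m + 1, zeta = 0)
  ru <- update_target_volume(30, 30, e_prod = e_m + 1, zeta = 0)
  expect_lt(rc$v_t - 30, ru$v_t - 30)
  # catabolism: deficit paid from biomass, no pressure/ROS terms
  rn <- update_target_volume(10, 30, e_prod = e_m - 2, zeta = 10)
  expect_equal(rn$v_t, 30 - gw$alpha * 2)
  # mass exhaustion flags death and floors at zero
  rd <- update_target_volume(1, 0.1, e_prod = 0, zeta = 0)
  expect_true(rd$dead); expect_equal(rd$v_t, 0)
})

test_that("division probability has the published branch structure", {
  w <- 0.05 * 50
  expect_equal(division_probability(50, 50), 0.5)
  expect_equal(division_probability(50 - 3 * w - 1, 50), 0)
  expect_equal(division_probability(50 + 3 * w, 50), 1)
  expect_equal(division_probability(60, 50), 1)
  # interior form
  v <- 48
  expect_equal(division_probability(v, 50),
               (v - 50) / (2 * sqrt(w^2 + (v - 50)^2)) + 0.5)
  p <- division_probability(seq(30, 70, by = 0.5), 50)
  expect_true(all(diff(p) >= 0)) # monotone gate
})

test_that("division conserves sites and target volume and copies state", {
  st <- make_bare_state(14, 14)
  id <- add_block_cell(st, 3, 10, 5, 8, v_t = 31.25) # 8x4 cell
  st$h[id] <- 0.3; st$zeta[id] <- 1.2
  set.seed(2)
  ids <- divide_cell(st, id, mutate = FALSE)
  expect_equal(sum(st$V[ids]), 32)
  expect_equal(abs(diff(st$V[ids])), 0) # even split of an even cell
  expect_equal(sum(st$VT[ids]), 31.25)  # exact conservation
  expect_equal(st$pheno[ids[1], ], st$pheno[ids[2], ])
  expect_equal(st$generation[ids], c(1L, 1L))
  expect_equal(st$h[ids[2]], 0.3)
  expect_equal(st$zeta[ids[2]], 1.2)
  expect_identical(tabulate(st$grid[st$grid > 0], nbins = length(st$V)),
                   st$V)
  # the cut is across the long axis: daughters split the x-extent
  xs <- range(which(rowSums(st$grid == ids[2]) > 0))
  expect_lt(xs[2] - xs[1], 7)
  # single-site cells cannot divide
  st2 <- make_bare_state(8, 8)
  one <- add_block_cell(st2, 4, 4, 4, 4, v_t = 5)
  expect_error(divide_cell(st2, one), ">= 2 sites")
})

test_that("mutation rate zero leaves daughter phenotypes identical", {
  st <- make_bare_state(14, 14, mut = mutation_spec(rate = 0))
  id <- add_block_cell(st, 3, 8, 3, 8, v_t = 36)
  ids <- divide_cell(st, id, mutate = TRUE)
  expect_equal(st$pheno[ids[1], ], st$pheno[ids[2], ])
  expect_equal(unname(st$pheno[ids[1], ]), unname(initial_phenotype()))
})

test_that("death step marks, shrinks and removes cells", {
  set.seed(6)
  # apoptosis initiations are Bernoulli(p) per cell
  n_marked <- 0; trials <- 400
  for (i in seq_len(trials)) {
    st <- make_bare_state(10, 10,
                          growth = growth_params(p_apoptosis = 0.05))
    add_block_cell(st, 2, 4, 2, 4)
    add_block_cell(st, 6, 8, 6, 8)
    death_step(st)
    n_marked <- n_marked + sum(st$apoptotic)
  }
  expect_equal(n_marked / (2 * trials), 0.05, tolerance = 0.25)
  # apoptotic cells shrink at the constant rate and die at v_t = 0
  st <- make_bare_state(10, 10, growth = growth_params(p_apoptosis = 0))
  id <- add_block_cell(st, 2, 4, 2, 4, v_t = 2.5)
  st$apoptotic[id] <- TRUE
  death_step(st)
  expect_equal(st$VT[id], 1.5)
  death_step(st); dead <- death_step(st)
  expect_equal(dead, id)
  expect_true(all(st$grid == 0L))       # sites converted to medium
  expect_equal(st$cell_type[id], 0L)
  # with apoptosis off and ample energy, population only changes by division
  st2 <- make_bare_state(10, 10, growth = growth_params(p_apoptosis = 0))
  add_block_cell(st2, 2, 4, 2, 4)
  n0 <- n_cells(st2)
  for (i in 1:20) death_step(st2)
  expect_equal(n_cells(st2), n0)
})

test_that("no live cell survives an MCS with zero target volume", {
  cfg <- experiment_config(width = 40, height = 40, mcs = 0, seed = 31,
                           mutation_rate = 0.1, equilibrate = FALSE,
                           growth = growth_params(p_apoptosis = 0.05))
  st <- build_initial_state(cfg)
  for (i in 1:30) {
    run_mcs(st)
    live <- which(st$cell_type == 1L)
    expect_true(all(st$VT[live] > 0))
    expect_true(all(st$V[live] > 0))
  }
})
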