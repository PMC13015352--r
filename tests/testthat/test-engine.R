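test_that("runs are reproducible under a seed and diverge across seeds", {
  rule <- frag_rule("stochastic_in_time", 2e-3)
  a <- simulate_filaments(rule, n_events = 20, seed = 5)
  b <- simulate_filaments(rule, n_events = 20, seed = 5)
  expect_identical(a$events, b$events)
  c <- simulate_filaments(rule, n_events = 20, seed = 6)
  expect_false(identical(a$events$time, c$events$time))
})

test_that("compiled and reference engines agree event for event", {
  cases <- list(
    list(rule = frag_rule("cell_age", 3)),
    list(rule = frag_rule("connection_age", 4.5)),
    list(rule = frag_rule("compound", 150)),
    list(rule = frag_rule("stress", 7)),
    list(rule = frag_rule("stochastic_at_division", 0.1)),
    list(rule = frag_rule("stochastic_in_time", 1e-3)),
    list(rule = frag_rule("cell_age", 3, death = TRUE)),
    list(rule = frag_rule("connection_age", 4.5, death = TRUE)),
    list(rule = frag_rule("connection_age", 8), aging = TRUE),
    list(rule = combined_rule(frag_rule("cell_age", 3),
                              frag_rule("compound", 120), "AND")),
    list(rule = combined_rule(frag_rule("cell_age", 3.2),
                              frag_rule("compound", 120), "OR")),
    list(rule = combined_rule(frag_rule("compound", 120),
                              frag_rule("connection_age", 4.5), "OR"))
  )
  for (case in cases) {
    aging <- isTRUE(case$aging)
    cpp <- simulate_filaments(case$rule, n_events = 12, seed = 31,
                              aging = aging, backend = "cpp")
    ref <- simulate_filaments(case$rule, n_events = 12, seed = 31,
                              aging = aging, backend = "r")
    expect_identical(cpp$events, ref$events)
    expect_identical(cpp$n_shed, ref$n_shed)
  }
})

test_that("the stress rule locks onto a fixed adult size and equal splits", {
  for (seed in 1:5) {
    sim <- simulate_filaments(frag_rule("stress", 15), n_events = 100,
                              seed = seed)
    expect_equal(unique(sim$events$parent_size), 33)
    expect_true(all(sim$events$mode == "equal_binary"))
  }
})

test_that("deterministic rules settle into a steady parent-size cycle", {
  sim <- simulate_filaments(frag_rule("connection_age", 4.5), n_events = 100,
                            seed = 2)
  late <- sim$events$parent_size[51:100]
  expect_lte(diff(range(late)), 1)
})

test_that("certain per-step breakage dissociates the first two-cell filament", {
  sim <- simulate_filaments(frag_rule("stochastic_in_time", 1), n_events = 1,
                            seed = 1)
  expect_equal(sim$events$parent_size, 2L)
  expect_equal(sim$events$offspring[[1]], c(1L, 1L))
  expect_equal(as.character(sim$events$mode), "complete_dissociation")
})

test_that("aging delays divisions by at least the cell's age", {
  f <- filament(1, pole_left = 6, pole_right = 6)
  set.seed(3)
  g <- divide_cell(f, 1, now = 10, aging = TRUE)
  # each daughter inherits one age-6 pole, so its age is 3
  expect_true(all(g$next_div >= 10 + 3 + 0.01))
  set.seed(3)
  h <- divide_cell(f, 1, now = 10, aging = FALSE)
  expect_equal(g$next_div - h$next_div, c(3, 3))
})

test_that("an unreachable threshold trips the non-termination guards", {
  expect_error(
    simulate_filaments(frag_rule("stress", 100), n_events = 1, seed = 1,
                       max_cells = 128),
    "128 cells")
  expect_error(
    simulate_filaments(frag_rule("cell_age", 50), n_events = 1, seed = 1,
                       max_steps = 200),
    "step budget")
})

test_that("pooled batches keep exactly the requested number of events", {
  rule <- frag_rule("connection_age", 4.5)
  ev <- simulate_batch(rule, n_events_total = 250, events_per_run = 100,
                       seed = 9)
  expect_equal(nrow(ev), 250)
  expect_equal(max(ev$run), 3)
  expect_identical(ev, simulate_batch(rule, 250, events_per_run = 100,
                                      seed = 9))
})

test_that("event logs conserve cells for severing rules", {
  for (rule in list(frag_rule("cell_age", 3),
                    frag_rule("stochastic_in_time", 1e-3))) {
    sim <- simulate_filaments(rule, n_events = 50, seed = 13)
    expect_equal(vapply(sim$events$offspring, sum, 1L),
                 sim$events$parent_size)
  }
  # death variant: one cell lost per event at most, never more than the
  # number of severed connections
  sim <- simulate_filaments(frag_rule("cell_age", 3, death = TRUE),
                            n_events = 50, seed = 13)
  lost <- sim$events$parent_size - vapply(sim$events$offspring, sum, 1L)
  expect_true(all(lost >= 1))
})

test_that("glance() summarises a simulation in one row", {
  sim <- simulate_filaments(frag_rule("stress", 15), n_events = 50, seed = 1)
  g <- glance(sim, target_size = 32)
  expect_equal(nrow(g), 1)
  expect_equal(g$sd_adult_size, 0)
  expect_equal(g$modal_mode, "equal_binary")
  expect_equal(g$modal_frequency, 1)
  expect_identical(tidy(sim), sim$events)
})
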