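fake_events <- function(parent_sizes, offspring) {
  tibble::tibble(
    event = seq_along(parent_sizes),
    time = as.double(seq_along(parent_sizes)),
    parent_size = as.integer(parent_sizes),
    n_offspring = lengths(offspring),
    offspring = offspring,
    mode = classify_events(parent_sizes, offspring),
    rule = "fake"
  )
}

test_that("adult-size summaries report mean, spread, and target error", {
  ev <- fake_events(rep(32, 10), replicate(10, c(16L, 16L), simplify = FALSE))
  s <- adult_size_summary(ev, 32)
  expect_equal(s$sd_adult_size, 0)
  expect_equal(s$mse_vs_target, 0)
  expect_equal(s$fraction_at_target, 1)
  ev2 <- fake_events(c(31, 33), list(c(15L, 16L), c(16L, 17L)))
  s2 <- adult_size_summary(ev2, 32)
  expect_equal(s2$mean_adult_size, 32)
  expect_equal(s2$mse_vs_target, 1)
})

test_that("mse decomposes into variance plus squared bias", {
  set.seed(21)
  for (rep in 1:20) {
    sizes <- sample(2:120, sample(5:60, 1), replace = TRUE)
    ev <- fake_events(sizes, lapply(sizes, function(n) {
      k <- sample(n - 1, 1); c(k, n - k)
    }))
    s <- adult_size_summary(ev, 32)
    expect_equal(s$mse_vs_target,
                 s$sd_adult_size^2 + (s$mean_adult_size - 32)^2,
                 tolerance = 1e-9)
  }
})

test_that("mode frequencies cover all five modes and sum to one", {
  ev <- fake_events(c(32, 32, 10), list(c(16L, 16L), c(1L, 31L), c(2L, 3L, 5L)))
  mf <- mode_frequencies(ev)
  expect_equal(nrow(mf), 5)
  expect_equal(sum(mf$frequency), 1, tolerance = 1e-9)
  expect_equal(mf$n[mf$mode == "complete_dissociation"], 0L)
  expect_equal(mf$frequency[mf$mode == "other"], 1 / 3)
})

test_that("binned mode frequencies match direct counting and flag empty bins", {
  sizes <- c(5, 10, 14, 40, 44)
  off <- list(c(1L, 4L), c(5L, 5L), c(7L, 7L), c(20L, 20L), c(4L, 40L))
  ev <- fake_events(sizes, off)
  b <- binned_mode_frequencies(ev, c(0, 16, 32, 48))
  # (0,16]: 3 events, one propagule and two equal
  first <- b[b$size_bin == levels(b$size_bin)[1], ]
  expect_equal(sum(first$n), 3L)
  expect_equal(first$frequency[first$mode == "unicellular_propagule"], 1 / 3)
  expect_equal(first$frequency[first$mode == "equal_binary"], 2 / 3)
  # (16,32] holds no events and is flagged, not zero-filled
  second <- b[b$size_bin == levels(b$size_bin)[2], ]
  expect_true(all(second$empty))
  expect_true(all(is.na(second$frequency)))
  # frequencies in each non-empty bin sum to 1
  third <- b[b$size_bin == levels(b$size_bin)[3], ]
  expect_equal(sum(third$frequency), 1, tolerance = 1e-9)
})

test_that("calibration scores candidates on paired batches and picks the mean-matcher", {
  cal <- calibrate_threshold("stress", target_size = 32,
                             events_per_candidate = 200, grid = c(10, 14, 15, 20),
                             refine = FALSE, seed = 1)
  # achievable deterministic sizes are 23, 31, 33, 43: ties resolve low
  expect_equal(cal$theta, 14)
  expect_equal(nrow(cal$grid), 4)
  g <- glance(cal)
  expect_equal(g$mean_adult_size, 31)
  expect_equal(g$sd_adult_size, 0)
})

test_that("a degenerate one-point scan reproduces the calibration objective", {
  theta1 <- 3; theta2 <- 120
  scan <- grid_scan("cell_age", "compound", logic = "AND",
                    theta1 = theta1, theta2 = theta2,
                    target_size = 32, events_per_cell = 200, seed = 7)
  expect_equal(nrow(scan), 1)
  rule <- combined_rule(frag_rule("cell_age", theta1),
                        frag_rule("compound", theta2), "AND")
  ev <- simulate_batch(rule, 200, events_per_run = 100, seed = 7)
  s <- adult_size_summary(ev, 32)
  expect_equal(scan$deviation, s$mean_adult_size - 32)
  expect_equal(scan$mse, s$mse_vs_target)
  expect_equal(scan$l2, sqrt(s$mse_vs_target))
})

test_that("scans are reproducible and tidyable", {
  scan <- grid_scan("cell_age", "compound", logic = "OR",
                    theta1 = c(3, 3.2), theta2 = c(120, 160),
                    events_per_cell = 100, seed = 3)
  scan2 <- grid_scan("cell_age", "compound", logic = "OR",
                     theta1 = c(3, 3.2), theta2 = c(120, 160),
                     events_per_cell = 100, seed = 3)
  expect_identical(tidy(scan), tidy(scan2))
  expect_equal(nrow(scan), 4)
  g <- glance(scan)
  expect_equal(g$logic, "OR")
  expect_equal(g$n_cells, 4L)
})
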