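#' Summarise the adult-size distribution of an event log
#'
#' Adult size is the parent filament's cell count immediately before a
#' fragmentation event. The standard deviation reported is the population
#' form (denominator `n`), so the mean-squared-error identity
#' `mse = sd^2 + (mean - target)^2` holds exactly.
#'
#' @param events An event tibble from [simulate_filaments()] or
#'   [simulate_batch()].
#' @param target_size Target adult size for the error columns.
#' @return A one-row tibble: `n_events`, `mean_adult_size`,
#'   `sd_adult_size`, `mse_vs_target`, `fraction_at_target`.
#' @export
adult_size_summary <- function(events, target_size = 32) {
  x <- events$parent_size
  stopifnot(length(x) > 0)
  m <- mean(x)
  tibble::tibble(
    n_events = length(x),
    mean_adult_size = m,
    sd_adult_size = sqrt(mean((x - m)^2)),
    mse_vs_target = mean((x - target_size)^2),
    fraction_at_target = mean(x == target_size)
  )
}

#' Histogram of adult sizes
#'
#' @inheritParams adult_size_summary
#' @return A tibble with `parent_size` and `n`, covering observed sizes.
#' @export
size_histogram <- function(events) {
  dplyr::count(events, .data$parent_size, name = "n")
}

#' Reproduction-mode frequencies
#'
#' Counts and frequencies over all five reproduction modes (zero rows are
#' kept so absent modes — complete dissociation in particular — are
#' explicit). Events without a mode (logged sheddings) are dropped.
#'
#' @inheritParams adult_size_summary
#' @return A tibble with `mode`, `n`, `frequency`; frequencies sum to 1.
#' @export
mode_frequencies <- function(events) {
  modes <- events$mode[!is.na(events$mode)]
  tab <- table(factor(modes, levels = reproduction_modes()))
  tibble::tibble(
    mode = factor(names(tab), levels = reproduction_modes()),
    n = as.integer(tab),
    frequency = as.integer(tab) / sum(tab)
  )
}

#' Mode frequencies by adult-size class
#'
#' Groups events into adult-size bins (left-open intervals as in
#' [cut()]) and tabulates reproduction-mode frequencies within each.
#' Bins with no events are kept and flagged empty rather than zero-filled.
#'
#' @inheritParams adult_size_summary
#' @param bin_edges Strictly increasing numeric vector of bin boundaries.
#' @return A tibble with `size_bin`, `empty`, `mode`, `n`, `frequency`;
#'   within each non-empty bin the frequencies sum to 1.
#' @export
binned_mode_frequencies <- function(events, bin_edges) {
  stopifnot(length(bin_edges) >= 2, all(diff(bin_edges) > 0))
  ev <- dplyr::filter(events, !is.na(.data$mode))
  ev$size_bin <- cut(ev$parent_size, breaks = bin_edges,
                     include.lowest = TRUE)
  all_bins <- levels(ev$size_bin)
  out <- tidyr::expand_grid(
    size_bin = factor(all_bins, levels = all_bins),
    mode = factor(reproduction_modes(), levels = reproduction_modes())
  )
  counts <- dplyr::count(ev, .data$size_bin, .data$mode, name = "n",
                         .drop = FALSE)
  out <- dplyr::left_join(out, counts, by = c("size_bin", "mode"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::group_by(out, .data$size_bin)
  out <- dplyr::mutate(out,
    empty = sum(.data$n) == 0L,
    frequency = ifelse(.data$empty, NA_real_, .data$n / sum(.data$n)))
  dplyr::ungroup(out)
}

# Shared objective for calibration and grid scans: mean squared error of
# parent sizes against the target over a common-random-number batch.
batch_objective <- function(rule, target_size, n_events, events_per_run,
                            seed, ...) {
  events <- tryCatch(
    simulate_batch(rule, n_events_total = n_events,
                   events_per_run = events_per_run, seed = seed, ...),
    error = function(e) NULL)
  if (is.null(events)) {
    return(tibble::tibble(mean_adult_size = NA_real_, sd_adult_size = NA_real_,
                          mse = Inf, fraction_at_target = NA_real_))
  }
  s <- adult_size_summary(events, target_size)
  tibble::tibble(mean_adult_size = s$mean_adult_size,
                 sd_adult_size = s$sd_adult_size,
                 mse = s$mse_vs_target,
                 fraction_at_target = s$fraction_at_target)
}

#' Default threshold search grid for each cue
#'
#' Coarse grids bracket the thresholds that yield mean adult sizes from a
#' few cells to well past 32 under the default growth law: linear grids
#' for the age cues and the compound (whose scale is set by the +1-per-step
#' production), the integer range for stress, and logarithmic grids for the
#' two per-event probabilities.
#'
#' @param cue A cue name as in [frag_rule()].
#' @return Numeric vector of candidate thresholds.
#' @export
default_calibration_grid <- function(cue) {
  switch(cue,
    cell_age = seq(0.25, 8, by = 0.25),
    connection_age = seq(0.5, 20, by = 0.5),
    compound = seq(10, 400, by = 10),
    stress = 1:30,
    stochastic_in_time = 10^seq(-4.5, -2, by = 0.1),
    stochastic_at_division = 10^seq(-2.5, -0.5, by = 0.1),
    stop("unknown cue: ", cue)
  )
}

refine_grid <- function(cue, theta, coarse) {
  step <- min(diff(coarse))
  if (cue == "stress") return(NULL)  # integer-valued, nothing to refine
  if (cue %in% c("stochastic_in_time", "stochastic_at_division")) {
    ratio <- coarse[2] / coarse[1]
    return(theta * ratio^seq(-1, 1, by = 0.05))
  }
  theta + seq(-step, step, by = step / 20)
}

#' Calibrate a rule threshold to a target mean adult size
#'
#' Grid search choosing the threshold whose *mean* adult size is closest
#' to `target_size` (squared deviation of the mean), with a coarse pass
#' over `grid` (defaulting to [default_calibration_grid()]) followed by
#' one refinement pass around the coarse optimum. Matching the mean — as
#' opposed to minimising the full mean squared error over sizes — makes
#' rules with very different size variances comparable at a common
#' average adult size; the full per-size mean squared error is still
#' recorded for every candidate. Every candidate is scored on a batch
#' generated from the same master seed (common random numbers), so the
#' comparison is paired and the search is reproducible; ties go to the
#' smaller threshold. A candidate under which the rule never fires scores
#' infinity.
#'
#' @param cue A cue name as in [frag_rule()].
#' @param target_size Target mean adult size (cells).
#' @param events_per_candidate Fragmentation events simulated per
#'   candidate threshold.
#' @param grid Optional coarse grid of thresholds.
#' @param refine Run the refinement pass.
#' @param seed Master seed for the calibration batches.
#' @param events_per_run Events per independent run inside each batch.
#' @param death,aging Variant flags, passed to the simulations (a variant
#'   changes the dynamics, so it is calibrated under its own dynamics).
#' @param ... Further arguments to [simulate_filaments()].
#' @return A `"filament_calibration"` object: `theta` (the optimum), `cue`,
#'   `target_size`, and `grid` (a tibble of all scored candidates with
#'   `theta`, `mean_adult_size`, `sd_adult_size`, `mse`,
#'   `fraction_at_target`, `pass`).
#' @examples
#' \donttest{
#' cal <- calibrate_threshold("stress", target_size = 32,
#'                            events_per_candidate = 200)
#' cal$theta
#' }
#' @export
calibrate_threshold <- function(cue, target_size = 32,
                                events_per_candidate = 2000, grid = NULL,
                                refine = TRUE, seed = 1,
                                events_per_run = 100, death = FALSE,
                                aging = FALSE, ...) {
  stopifnot(target_size >= 2)
  if (is.null(grid)) grid <- default_calibration_grid(cue)
  stopifnot(length(grid) >= 1, all(grid >= 0))
  score_grid <- function(thetas, pass) {
    purrr::map_dfr(thetas, function(th) {
      obj <- batch_objective(frag_rule(cue, th, death = death), target_size,
                             events_per_candidate, events_per_run, seed,
                             aging = aging, ...)
      dplyr::mutate(obj, theta = th, pass = pass, .before = 1)
    })
  }
  scored <- score_grid(sort(grid), "coarse")
  best <- pick_best(scored, target_size)
  if (refine) {
    fine <- refine_grid(cue, best, sort(grid))
    fine <- fine[!is.na(fine) & fine >= 0]
    if (cue %in% c("stochastic_in_time", "stochastic_at_division"))
      fine <- fine[fine <= 1]
    if (length(fine)) {
      scored <- dplyr::bind_rows(scored, score_grid(sort(fine), "fine"))
      best <- pick_best(scored, target_size)
    }
  }
  structure(list(theta = best, cue = cue, target_size = target_size,
                 death = death, aging = aging, grid = scored),
            class = "filament_calibration")
}

pick_best <- function(scored, target_size) {
  objective <- (scored$mean_adult_size - target_size)^2
  objective[!is.finite(scored$mse)] <- Inf
  if (all(!is.finite(objective)))
    stop("no candidate threshold produced any fragmentation")
  # ties toward the smaller threshold
  ord <- order(objective, scored$theta)
  scored$theta[ord[1]]
}

#' @export
print.filament_calibration <- function(x, ...) {
  cat("<filament_calibration> ", x$cue,
      if (x$death) " (death)", if (x$aging) " (aging)",
      ": theta* = ", format(x$theta),
      " for target adult size ", x$target_size, "\n", sep = "")
  best <- x$grid[x$grid$theta == x$theta, ][1, ]
  cat("  mean adult size ", format(best$mean_adult_size, digits = 4),
      ", sd ", format(best$sd_adult_size, digits = 4),
      ", mse ", format(best$mse, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Scan a threshold grid for a Boolean rule combination
#'
#' For every pair on the `theta1` x `theta2` grid, simulates a batch under
#' the combined rule and records the signed deviation of the mean adult
#' size from the target and the L2 error (root mean squared deviation).
#' All cells use the same master seed (common random numbers).
#'
#' @param cue1,cue2 Cue names for the two sub-rules (cell-level cues for
#'   `AND`, see [combined_rule()]).
#' @param logic `"AND"` or `"OR"`.
#' @param theta1,theta2 Strictly increasing grids of thresholds.
#' @param target_size Target adult size.
#' @param events_per_cell Fragmentation events per grid cell.
#' @param seed Master seed.
#' @param events_per_run Events per independent run inside each batch.
#' @param ... Further arguments to [simulate_filaments()].
#' @return A `"filament_scan"` tibble: one row per grid cell with `theta1`,
#'   `theta2`, `mean_adult_size`, `sd_adult_size`, `deviation`
#'   (mean - target), `l2` (sqrt of mse), `mse`; the logic and target are
#'   attached as attributes.
#' @export
grid_scan <- function(cue1, cue2, logic = c("AND", "OR"), theta1, theta2,
                      target_size = 32, events_per_cell = 2000, seed = 1,
                      events_per_run = 100, ...) {
  logic <- match.arg(logic)
  stopifnot(all(diff(theta1) > 0) || length(theta1) == 1,
            all(diff(theta2) > 0) || length(theta2) == 1)
  cells <- tidyr::expand_grid(theta1 = theta1, theta2 = theta2)
  out <- purrr::pmap_dfr(cells, function(theta1, theta2) {
    rule <- combined_rule(frag_rule(cue1, theta1), frag_rule(cue2, theta2),
                          logic = logic)
    obj <- batch_objective(rule, target_size, events_per_cell,
                           events_per_run, seed, ...)
    tibble::tibble(theta1 = theta1, theta2 = theta2,
                   mean_adult_size = obj$mean_adult_size,
                   sd_adult_size = obj$sd_adult_size,
                   deviation = obj$mean_adult_size - target_size,
                   l2 = sqrt(obj$mse), mse = obj$mse)
  })
  structure(out, logic = logic, target_size = target_size,
            class = c("filament_scan", class(out)))
}
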