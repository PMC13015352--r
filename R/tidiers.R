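#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the event log of a simulation
#'
#' @param x A `"filament_sim"` from [simulate_filaments()].
#' @param ... Unused.
#' @return The event tibble (one row per fragmentation event).
#' @export
tidy.filament_sim <- function(x, ...) x$events

#' One-row summary of a simulation
#'
#' @param x A `"filament_sim"` from [simulate_filaments()].
#' @param target_size Target adult size for the error columns.
#' @param ... Unused.
#' @return A one-row tibble combining [adult_size_summary()] with the
#'   frequency of the modal reproduction mode and the shedding count.
#' @export
glance.filament_sim <- function(x, target_size = 32, ...) {
  sizes <- adult_size_summary(x$events, target_size)
  freqs <- mode_frequencies(x$events)
  top <- freqs[which.max(freqs$frequency), ]
  dplyr::mutate(sizes,
    modal_mode = as.character(top$mode),
    modal_frequency = top$frequency,
    n_shed = x$n_shed,
    rule = rule_label(x$config$rule))
}

#' Tidy a calibration: all scored candidates
#'
#' @param x A `"filament_calibration"` from [calibrate_threshold()].
#' @param ... Unused.
#' @return The candidate tibble (`theta`, `mean_adult_size`,
#'   `sd_adult_size`, `mse`, `fraction_at_target`, `pass`).
#' @export
tidy.filament_calibration <- function(x, ...) x$grid

#' One-row summary of a calibration
#'
#' @param x A `"filament_calibration"` from [calibrate_threshold()].
#' @param ... Unused.
#' @return A one-row tibble with the chosen threshold and its scores.
#' @export
glance.filament_calibration <- function(x, ...) {
  best <- x$grid[x$grid$theta == x$theta, ]
  best <- best[which.min(best$mse), ]
  tibble::tibble(cue = x$cue, theta = x$theta,
                 target_size = x$target_size,
                 mean_adult_size = best$mean_adult_size,
                 sd_adult_size = best$sd_adult_size, mse = best$mse,
                 fraction_at_target = best$fraction_at_target,
                 death = x$death, aging = x$aging)
}

#' Tidy a threshold scan
#'
#' @param x A `"filament_scan"` from [grid_scan()].
#' @param ... Unused.
#' @return The scan tibble, one row per grid cell.
#' @export
tidy.filament_scan <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a threshold scan
#'
#' @param x A `"filament_scan"` from [grid_scan()].
#' @param ... Unused.
#' @return A one-row tibble with the scanned logic, the share of cells
#'   overshooting the target, and the best (minimum-L2) cell.
#' @export
glance.filament_scan <- function(x, ...) {
  best <- x[which.min(x$l2), ]
  tibble::tibble(
    logic = attr(x, "logic"),
    target_size = attr(x, "target_size"),
    n_cells = nrow(x),
    fraction_overshoot = mean(x$deviation > 0),
    min_l2 = best$l2,
    best_theta1 = best$theta1,
    best_theta2 = best$theta2
  )
}
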