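#' Advance all ages by one step
#'
#' Adds `dt` to both pole ages of every cell and to every connection age.
#' Nothing else changes.
#'
#' @param filament A [filament()].
#' @param dt Time increment, > 0.
#' @return The aged filament.
#' @export
advance_ages <- function(filament, dt) {
  stopifnot(dt > 0)
  f <- filament
  f$pole_l <- f$pole_l + dt
  f$pole_r <- f$pole_r + dt
  if (length(f$conn_age)) f$conn_age <- f$conn_age + dt
  f
}

#' One production-plus-diffusion update of the compound
#'
#' Each cell first produces `production` units of compound, and an explicit
#' first-order exchange (computed on the pre-production amounts) is applied
#' simultaneously: cell `i` exchanges `D * (d_j - d_i)` with each neighbour
#' `j`, and a terminal cell additionally loses `D * d_i` across its free end
#' into a zero-concentration environment. This is explicit Euler on a 1-D
#' chain with unit cell spacing and absorbing boundaries; it is stable and
#' sign-preserving for `D <= 0.5`.
#'
#' Per step the total compound changes by exactly
#' `N * production - D * (d_first + d_last)`.
#'
#' @param filament A [filament()].
#' @param D Dimensionless per-step exchange fraction, >= 0.
#' @param production Amount produced per cell per step.
#' @return The updated filament.
#' @examples
#' f <- filament(1, compound = 5)
#' diffuse_step(f)$compound # 5 + 1 - 2 * 0.01 * 5 = 5.9
#' @export
diffuse_step <- function(filament, D = 0.01, production = 1) {
  stopifnot(D >= 0, n_cells(filament) >= 1)
  d <- filament$compound
  n <- length(d)
  left <- c(0, d[-n])   # virtual zero-concentration environment at each end
  right <- c(d[-1], 0)
  f <- filament
  f$compound <- pmax((d + production) + D * ((left + right) - 2 * d), 0)
  f
}

#' Mechanical stress along a filament
#'
#' The stress proxy for cell `i` is `min(n_left, n_right)`, the smaller of
#' the cell counts on its two sides. It is 0 at the ends and maximal at (or
#' next to) the midpoint, which biases stress-triggered breaks toward the
#' middle of the filament.
#'
#' @param filament A [filament()].
#' @return Integer vector of per-cell stress values.
#' @export
stress_profile <- function(filament) {
  n <- n_cells(filament)
  pmin(seq_len(n) - 1L, n - seq_len(n))
}

#' @rdname stress_profile
#' @param index Cell position, 1-based.
#' @export
stress <- function(filament, index) {
  counts <- downstream_counts(filament, index)
  min(counts)
}
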