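#' Construct a filament
#'
#' A filament is an ordered chain of cells joined by aged connections. Each
#' cell carries the ages of its two poles (a pole is created at age 0 by the
#' division that produced it), the amount of a diffusible compound, and the
#' absolute simulation time of its next scheduled division. A filament of
#' `n` cells always has exactly `n - 1` connections.
#'
#' Internally cells and connections are stored in parallel numeric vectors;
#' positions reported by accessors and in event logs are 1-based, counted
#' from the left end.
#'
#' @param n Number of cells.
#' @param pole_left,pole_right Pole ages, recycled to length `n`. The left
#'   pole of cell `i` faces cell `i - 1`.
#' @param compound Compound amount per cell, recycled to length `n`.
#' @param next_division_at Absolute time of each cell's next division,
#'   recycled to length `n`.
#' @param connection_age Ages of the `n - 1` connections, recycled.
#'
#' @return An object of class `"filament"`.
#' @examples
#' f <- filament(3, pole_left = c(2, 0, 0), pole_right = c(0, 0, 2))
#' cell_ages(f)
#' @export
filament <- function(n = 1, pole_left = 0, pole_right = 0, compound = 0,
                     next_division_at = Inf, connection_age = 0) {
  stopifnot(n >= 1)
  f <- structure(
    list(
      pole_l = rep_len(as.double(pole_left), n),
      pole_r = rep_len(as.double(pole_right), n),
      compound = rep_len(as.double(compound), n),
      next_div = rep_len(as.double(next_division_at), n),
      conn_age = if (n > 1) rep_len(as.double(connection_age), n - 1) else double(0)
    ),
    class = "filament"
  )
  validate_filament(f)
}

validate_filament <- function(f) {
  n <- length(f$pole_l)
  stopifnot(
    length(f$pole_r) == n, length(f$compound) == n, length(f$next_div) == n,
    length(f$conn_age) == n - 1,
    all(f$pole_l >= 0), all(f$pole_r >= 0),
    all(f$compound >= 0), all(f$conn_age >= 0)
  )
  f
}

#' @export
print.filament <- function(x, ...) {
  cat("<filament> ", n_cells(x), " cells, ", length(x$conn_age),
      " connections\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Number of cells in a filament
#' @param filament A [filament()].
#' @return Integer cell count.
#' @export
n_cells <- function(filament) length(filament$pole_l)

#' Cell ages along a filament
#'
#' Cell age is defined as the mean of the two pole ages, a standard proxy
#' for the age of a cell that reproduces by binary fission (each division
#' creates two new, age-0 poles, so no single birth time exists).
#'
#' @param filament A [filament()].
#' @return Numeric vector of per-cell ages, left to right.
#' @examples
#' cell_ages(filament(1, pole_left = 4, pole_right = 2)) # 3
#' @export
cell_ages <- function(filament) (filament$pole_l + filament$pole_r) / 2

#' Cells on either side of a cell
#'
#' For the cell at `index` (1-based from the left), counts the cells
#' strictly to its left (`n_left`) and right (`n_right`). For a filament of
#' `N` cells these always sum to `N - 1`.
#'
#' @param filament A [filament()].
#' @param index Cell position, 1-based.
#' @return Named integer vector `c(n_left, n_right)`.
#' @export
downstream_counts <- function(filament, index) {
  n <- n_cells(filament)
  if (index < 1 || index > n) stop("invalid cell index: ", index)
  c(n_left = index - 1L, n_right = n - as.integer(index))
}

#' Divide one cell by binary fission
#'
#' Replaces the cell at `index` by two adjacent daughters. Each daughter
#' keeps the parent's outer pole on its outer side and gets a fresh age-0
#' pole on the side of the new age-0 connection between them. The parent's
#' compound is split equally. Both daughters are given fresh division times
#' drawn from the (truncated) normal division-time law; under the aging
#' variant a daughter's current age is added to its drawn division interval.
#'
#' Two normal draws are consumed from the R random stream, left daughter
#' first.
#'
#' @param filament A [filament()].
#' @param index Position of the dividing cell, 1-based.
#' @param now Current simulation time (absolute).
#' @param division_mean,division_sd Mean and standard deviation of the
#'   division-interval distribution.
#' @param dt Simulation step size; draws are truncated below at `dt` by
#'   resampling.
#' @param aging If `TRUE`, each daughter's current age is added to its
#'   drawn interval, so older cells divide more slowly.
#' @return The filament with `index` replaced by two daughters.
#' @examples
#' f <- filament(1, pole_left = 2, pole_right = 2, compound = 4)
#' set.seed(1)
#' divide_cell(f, 1, now = 2)
#' @export
divide_cell <- function(filament, index, now, division_mean = 1,
                        division_sd = 0.05, dt = 0.01, aging = FALSE) {
  n <- n_cells(filament)
  if (index < 1 || index > n) stop("invalid cell index: ", index)
  if (!is.finite(filament$pole_l[index])) stop("cannot divide a dead cell")
  i <- as.integer(index)
  pl <- filament$pole_l[i]; pr <- filament$pole_r[i]
  cmp <- filament$compound[i] / 2
  # left daughter inherits the left pole, right daughter the right pole;
  # the facing (new) poles start at age 0
  t_left <- now + draw_division_interval(division_mean, division_sd, dt) +
    if (aging) pl / 2 else 0
  t_right <- now + draw_division_interval(division_mean, division_sd, dt) +
    if (aging) pr / 2 else 0
  ins <- function(x, at, values) append(x[-at], values, after = at - 1L)
  f <- filament
  f$pole_l <- ins(f$pole_l, i, c(pl, 0))
  f$pole_r <- ins(f$pole_r, i, c(0, pr))
  f$compound <- ins(f$compound, i, c(cmp, cmp))
  f$next_div <- ins(f$next_div, i, c(t_left, t_right))
  f$conn_age <- append(f$conn_age, 0, after = i - 1L)
  f
}

#' @rdname divide_cell
#' @export
draw_division_interval <- function(division_mean = 1, division_sd = 0.05,
                                   dt = 0.01) {
  repeat {
    x <- stats::rnorm(1L, division_mean, division_sd)
    if (x >= dt) return(x)
  }
}

#' Mirror a filament end-for-end
#'
#' Reverses cell order and swaps the left/right pole of every cell. The
#' model is left/right symmetric, so every update and rule commutes with
#' this operation (tie-breaks use a mirrored coin).
#'
#' @param filament A [filament()].
#' @return The reversed filament.
#' @export
mirror_filament <- function(filament) {
  f <- filament
  f$pole_l <- rev(filament$pole_r)
  f$pole_r <- rev(filament$pole_l)
  f$compound <- rev(filament$compound)
  f$next_div <- rev(filament$next_div)
  f$conn_age <- rev(filament$conn_age)
  f
}

#' Tidy a filament into a one-row-per-cell tibble
#'
#' @param x A [filament()].
#' @param ... Unused.
#' @return A tibble with columns `cell`, `pole_left`, `pole_right`, `age`,
#'   `compound`, `next_division_at`, `stress`, and `connection_age_right`
#'   (age of the connection to the right neighbour, `NA` for the last cell).
#' @export
tidy.filament <- function(x, ...) {
  n <- n_cells(x)
  tibble::tibble(
    cell = seq_len(n),
    pole_left = x$pole_l,
    pole_right = x$pole_r,
    age = cell_ages(x),
    compound = x$compound,
    next_division_at = x$next_div,
    stress = stress_profile(x),
    connection_age_right = c(x$conn_age, NA_real_)
  )
}
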