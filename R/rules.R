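#' Fragmentation rules
#'
#' A fragmentation rule pairs an information cue with a threshold and a
#' severing policy. The four deterministic cues read intrinsic cell-level
#' information; the two stochastic cues are baselines with no information
#' content.
#'
#' * `cell_age` — a cell whose mean pole age exceeds `theta` breaks its
#'   older adjacent connection.
#' * `connection_age` — any connection older than `theta` breaks.
#' * `compound` — a cell whose compound amount exceeds `theta` breaks the
#'   connection toward its higher-concentration neighbour (a terminal cell
#'   breaks its only connection).
#' * `stress` — a cell whose stress `min(n_left, n_right)` exceeds `theta`
#'   breaks the connection on its more populated side.
#' * `stochastic_at_division` — each connection created by a division
#'   breaks, once, with probability `theta` at the moment it forms.
#' * `stochastic_in_time` — every connection breaks independently with
#'   probability `theta` at every time step.
#'
#' With `death = TRUE` fragmentation acts by cell death: for the cell-level
#' cues (`cell_age`, `compound`, `stress`) the triggering cell is removed
#' and both its connections severed; for the connection-level cues one of
#' the two cells flanking each broken connection is removed, chosen by a
#' fair coin.
#'
#' @param cue One of `"cell_age"`, `"connection_age"`, `"compound"`,
#'   `"stress"`, `"stochastic_at_division"`, `"stochastic_in_time"`.
#' @param theta Threshold in the cue's own units (a probability in `[0, 1]`
#'   for the stochastic cues).
#' @param death Fragment by cell death instead of clean breakage.
#' @return A `"frag_rule"` object.
#' @examples
#' frag_rule("stress", theta = 15)
#' @export
frag_rule <- function(cue = c("cell_age", "connection_age", "compound",
                              "stress", "stochastic_at_division",
                              "stochastic_in_time"),
                      theta, death = FALSE) {
  cue <- match.arg(cue)
  stopifnot(is.numeric(theta), length(theta) == 1, theta >= 0)
  if (cue %in% c("stochastic_at_division", "stochastic_in_time") && theta > 1)
    stop("stochastic cues take a probability in [0, 1], got ", theta)
  structure(list(cue = cue, theta = as.double(theta), death = isTRUE(death)),
            class = "frag_rule")
}

#' @export
print.frag_rule <- function(x, ...) {
  cat("<frag_rule> ", x$cue, ", theta = ", format(x$theta),
      if (x$death) ", death variant" else "", "\n", sep = "")
  invisible(x)
}

#' Combine two deterministic rules with Boolean logic
#'
#' Under `AND` logic a single cell must satisfy both thresholds at once to
#' trigger a break, so both cues must be cell-level (`cell_age`,
#' `compound`, or `stress`); the severed connection follows `rule1`'s
#' policy. Under `OR` logic either rule firing triggers a break; any pair
#' of deterministic cues is allowed, and when one cell satisfies both
#' cell-level cues in the same step only `rule1`'s severing policy applies.
#'
#' @param rule1,rule2 [frag_rule()] objects with distinct deterministic
#'   cues and `death = FALSE`.
#' @param logic `"AND"` or `"OR"`.
#' @return A `"combined_rule"` object.
#' @export
combined_rule <- function(rule1, rule2, logic = c("AND", "OR")) {
  logic <- match.arg(logic)
  stopifnot(inherits(rule1, "frag_rule"), inherits(rule2, "frag_rule"))
  stochastic <- c("stochastic_at_division", "stochastic_in_time")
  if (rule1$cue %in% stochastic || rule2$cue %in% stochastic)
    stop("stochastic cues cannot be combined")
  if (rule1$cue == rule2$cue)
    stop("the two combined cues must differ")
  if (rule1$death || rule2$death)
    stop("the death variant is not supported for combined rules")
  cell_level <- c("cell_age", "compound", "stress")
  if (logic == "AND" &&
      (!rule1$cue %in% cell_level || !rule2$cue %in% cell_level))
    stop("AND logic requires two cell-level cues (cell_age, compound, stress)")
  structure(list(rule1 = rule1, rule2 = rule2, logic = logic),
            class = "combined_rule")
}

#' @export
print.combined_rule <- function(x, ...) {
  cat("<combined_rule> ", x$rule1$cue, " ", x$logic, " ", x$rule2$cue,
      ", theta1 = ", format(x$rule1$theta),
      ", theta2 = ", format(x$rule2$theta), "\n", sep = "")
  invisible(x)
}

empty_decision <- function() {
  list(sever = integer(0), kill = integer(0))
}

decision_is_empty <- function(decision) {
  length(decision$sever) == 0 && length(decision$kill) == 0
}

# Per-cell cue values for the cell-level cues.
cue_values <- function(filament, cue) {
  switch(cue,
    cell_age = cell_ages(filament),
    compound = filament$compound,
    stress = as.double(stress_profile(filament)),
    stop("not a cell-level cue: ", cue)
  )
}

# Which adjacent connection a triggering cell severs, 1-based connection
# index (connection j joins cells j and j+1). Consumes one uniform draw on
# an exact tie; returns NA for a singleton filament. Iteration over
# triggering cells is always left to right so the random stream is
# well-defined.
severing_policy <- function(filament, i, cue) {
  n <- n_cells(filament)
  if (n == 1) return(NA_integer_)
  if (i == 1) return(1L)
  if (i == n) return(n - 1L)
  left <- i - 1L; right <- i
  lv <- switch(cue,
    cell_age = filament$conn_age[left],
    compound = filament$compound[i - 1L],
    stress = i - 1L  # n_left
  )
  rv <- switch(cue,
    cell_age = filament$conn_age[right],
    compound = filament$compound[i + 1L],
    stress = n - i   # n_right
  )
  if (lv > rv) left
  else if (rv > lv) right
  else if (stats::runif(1) < 0.5) left else right
}

# Evaluate a cell-level cue at threshold theta: marks one connection (or
# kills the cell) for every triggering cell, left to right. `skip` is a
# logical mask of cells that already fired a higher-precedence rule.
eval_cell_level <- function(filament, cue, theta, death = FALSE,
                            skip = NULL) {
  vals <- cue_values(filament, cue)
  hit <- vals > theta
  if (!is.null(skip)) hit <- hit & !skip
  sever <- integer(0); kill <- integer(0)
  for (i in which(hit)) {
    if (death) {
      kill <- c(kill, i)
    } else {
      j <- severing_policy(filament, i, cue)
      if (!is.na(j)) sever <- c(sever, j)
    }
  }
  list(sever = unique(sever), kill = unique(kill))
}

# Death handling for connection-level cues: one flanking cell per broken
# connection, chosen by a fair coin, increasing connection order.
kill_adjacent <- function(sever) {
  vapply(sever, function(j) {
    if (stats::runif(1) < 0.5) j else j + 1L
  }, integer(1))
}

eval_connection_age_rule <- function(filament, theta, death = FALSE) {
  sever <- which(filament$conn_age > theta)
  if (length(sever) == 0) return(empty_decision())
  kill <- if (death) unique(kill_adjacent(sever)) else integer(0)
  list(sever = as.integer(sever), kill = as.integer(kill))
}

eval_stochastic_in_time <- function(filament, theta, death = FALSE) {
  m <- length(filament$conn_age)
  if (m == 0) return(empty_decision())
  # one uniform per connection per step, left to right
  sever <- which(stats::runif(m) < theta)
  if (length(sever) == 0) return(empty_decision())
  kill <- if (death) unique(kill_adjacent(sever)) else integer(0)
  list(sever = as.integer(sever), kill = as.integer(kill))
}

eval_cell_age_rule <- function(filament, theta, death = FALSE) {
  eval_cell_level(filament, "cell_age", theta, death)
}

eval_compound_rule <- function(filament, theta, death = FALSE) {
  eval_cell_level(filament, "compound", theta, death)
}

eval_stress_rule <- function(filament, theta, death = FALSE) {
  eval_cell_level(filament, "stress", theta, death)
}

eval_combined <- function(filament, spec) {
  r1 <- spec$rule1; r2 <- spec$rule2
  if (spec$logic == "AND") {
    v1 <- cue_values(filament, r1$cue)
    v2 <- cue_values(filament, r2$cue)
    hit <- v1 > r1$theta & v2 > r2$theta
    sever <- integer(0)
    for (i in which(hit)) {
      j <- severing_policy(filament, i, r1$cue)
      if (!is.na(j)) sever <- c(sever, j)
    }
    return(list(sever = unique(sever), kill = integer(0)))
  }
  # OR: rule1 first; rule2 then fires only for cells rule1 did not claim
  conn_level <- c("connection_age", "stochastic_in_time")
  d1 <- if (r1$cue %in% conn_level) {
    eval_connection_age_rule(filament, r1$theta)
  } else {
    eval_cell_level(filament, r1$cue, r1$theta)
  }
  if (r2$cue %in% conn_level) {
    d2 <- eval_connection_age_rule(filament, r2$theta)
  } else {
    skip <- if (r1$cue %in% conn_level) NULL
            else cue_values(filament, r1$cue) > r1$theta
    d2 <- eval_cell_level(filament, r2$cue, r2$theta, skip = skip)
  }
  list(sever = unique(c(d1$sever, d2$sever)), kill = integer(0))
}

#' Evaluate a fragmentation rule on the current filament state
#'
#' Returns the set of connections to sever and cells to remove this step.
#' Every trigger that fires in the same step belongs to the same
#' fragmentation event, which is how events with more than two offspring
#' arise. Exact ties in a severing policy (equal adjacent connection ages,
#' equal neighbour concentrations, a cell exactly at the midpoint) are
#' resolved by a fair coin from the R random stream; triggering cells are
#' always scanned left to right, so the stream use is reproducible.
#'
#' `stochastic_at_division` is evaluated at the moment a connection forms
#' (inside the simulation engine), not per step, and is rejected here.
#'
#' @param filament A [filament()].
#' @param rule A [frag_rule()] or [combined_rule()].
#' @return A list with integer fields `sever` (1-based connection
#'   positions) and `kill` (1-based cell positions, empty unless the rule
#'   is a death variant).
#' @export
eval_rule <- function(filament, rule) {
  if (inherits(rule, "combined_rule")) return(eval_combined(filament, rule))
  stopifnot(inherits(rule, "frag_rule"))
  switch(rule$cue,
    cell_age = eval_cell_age_rule(filament, rule$theta, rule$death),
    connection_age = eval_connection_age_rule(filament, rule$theta, rule$death),
    compound = eval_compound_rule(filament, rule$theta, rule$death),
    stress = eval_stress_rule(filament, rule$theta, rule$death),
    stochastic_in_time = eval_stochastic_in_time(filament, rule$theta,
                                                 rule$death),
    stochastic_at_division = stop(
      "stochastic_at_division fires when a connection forms; ",
      "it has no per-step evaluation")
  )
}

#' Apply a severing decision, splitting a filament into offspring
#'
#' All marked connections are severed and all marked cells removed
#' simultaneously. Offspring are the maximal runs of surviving cells, left
#' to right; dead cells are excluded, so the offspring sizes sum to the
#' parent size minus the number of cells killed.
#'
#' @param filament A [filament()].
#' @param decision A decision from [eval_rule()].
#' @return A list with `fragments` (list of [filament()]s, left to right),
#'   `offspring_sizes` (integer vector), `parent_size`, and `n_killed`.
#' @examples
#' f <- filament(10, next_division_at = Inf)
#' apply_decision(f, list(sever = c(1L, 5L), kill = integer(0)))$offspring_sizes
#' @export
apply_decision <- function(filament, decision) {
  n <- n_cells(filament)
  if (decision_is_empty(decision)) stop("empty severing decision")
  if (length(decision$sever) && (min(decision$sever) < 1 ||
                                 max(decision$sever) > n - 1))
    stop("severing decision references invalid connections")
  if (length(decision$kill) && (min(decision$kill) < 1 ||
                                max(decision$kill) > n))
    stop("severing decision references invalid cells")
  killed <- logical(n); killed[decision$kill] <- TRUE
  cut <- logical(max(n - 1L, 0L)); cut[decision$sever] <- TRUE
  if (n > 1) {
    cut <- cut | killed[-n] | killed[-1]  # a dead cell severs both sides
  }
  fragments <- list(); sizes <- integer(0)
  start <- 1L
  close_run <- function(a, b) {
    if (b < a) return()
    idx <- a:b
    frag <- structure(list(
      pole_l = filament$pole_l[idx],
      pole_r = filament$pole_r[idx],
      compound = filament$compound[idx],
      next_div = filament$next_div[idx],
      conn_age = if (b > a) filament$conn_age[a:(b - 1L)] else double(0)
    ), class = "filament")
    fragments[[length(fragments) + 1L]] <<- frag
    sizes[length(sizes) + 1L] <<- length(idx)
  }
  for (i in seq_len(n)) {
    if (killed[i]) {
      close_run(start, i - 1L)
      start <- i + 1L
    } else if (i < n && cut[i]) {
      close_run(start, i)
      start <- i + 1L
    }
  }
  close_run(start, n)
  list(fragments = fragments, offspring_sizes = sizes,
       parent_size = n, n_killed = sum(killed))
}
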