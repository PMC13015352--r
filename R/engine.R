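cue_codes <- c(cell_age = 0L, connection_age = 1L, compound = 2L,
               stress = 3L, stochastic_at_division = 4L,
               stochastic_in_time = 5L)

rule_codes <- function(rule) {
  if (inherits(rule, "combined_rule")) {
    list(cue1 = cue_codes[[rule$rule1$cue]], theta1 = rule$rule1$theta,
         cue2 = cue_codes[[rule$rule2$cue]], theta2 = rule$rule2$theta,
         logic = if (rule$logic == "AND") 1L else 2L, death = FALSE)
  } else {
    list(cue1 = cue_codes[[rule$cue]], theta1 = rule$theta,
         cue2 = -1L, theta2 = 0, logic = 0L, death = rule$death)
  }
}

#' Label a rule for event logs
#' @param rule A [frag_rule()] or [combined_rule()].
#' @return A character scalar such as `"stress"` or `"cell_age AND compound"`.
#' @export
rule_label <- function(rule) {
  if (inherits(rule, "combined_rule"))
    paste(rule$rule1$cue, rule$logic, rule$rule2$cue)
  else paste0(rule$cue, if (rule$death) " (death)" else "")
}

#' Simulate a filament life cycle until a fixed number of fragmentations
#'
#' Runs the discrete-time simulation: a single age-0 cell grows by binary
#' fission (division intervals drawn from a normal law, truncated below at
#' `dt` by resampling), every information source is updated each step
#' (ages, then compound production and diffusion, then divisions due at the
#' step boundary), the fragmentation rule is evaluated on the fresh state,
#' and on every fragmentation the simulation follows the largest viable
#' daughter. The run stops after `n_events` logged fragmentation events.
#'
#' A fragmentation whose only viable product is the filament itself minus a
#' dead cell (possible under the death variant) is a shedding, not a
#' reproduction: by default it is counted separately and excluded from the
#' event log (`count_shedding = FALSE`).
#'
#' @param rule A [frag_rule()] or [combined_rule()].
#' @param n_events Number of fragmentation events to log.
#' @param seed Optional integer seed (`set.seed()` is called if given).
#' @param dt Time step.
#' @param division_mean,division_sd Division-interval law (defaults: mean 1,
#'   standard deviation 0.05, i.e. a 5% coefficient of variation).
#' @param D Per-step compound exchange fraction.
#' @param production Compound produced per cell per step.
#' @param aging If `TRUE`, a cell's current age is added to its drawn
#'   division interval, so older cells divide more slowly.
#' @param count_shedding Log shedding events (single viable offspring) in
#'   the event table and count them toward `n_events`.
#' @param max_cells,max_steps Guards against a threshold the rule can never
#'   reach; exceeding either is an error naming the problem.
#' @param backend `"cpp"` (compiled engine, default) or `"r"` (reference
#'   implementation composed from the exported building blocks; identical
#'   output for identical seeds, orders of magnitude slower).
#' @return A `"filament_sim"` object with fields `events` (a tibble with
#'   one row per event: `event`, `time`, `parent_size`, `n_offspring`,
#'   `offspring` list-column, `mode`, `rule`), `config`, `n_shed`,
#'   `n_extinct`, and `n_steps`.
#' @examples
#' sim <- simulate_filaments(frag_rule("stress", 15), n_events = 5, seed = 1)
#' sim$events
#' @export
simulate_filaments <- function(rule, n_events = 100, seed = NULL,
                               dt = 0.01, division_mean = 1,
                               division_sd = 0.05, D = 0.01, production = 1,
                               aging = FALSE, count_shedding = FALSE,
                               max_cells = 4096, max_steps = 1e8,
                               backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  stopifnot(n_events >= 1, dt > 0, division_mean > 0)
  if (!is.null(seed)) set.seed(seed)
  rc <- rule_codes(rule)
  raw <- if (backend == "cpp") {
    run_engine_cpp(rc$cue1, rc$theta1, rc$cue2, rc$theta2, rc$logic,
                   rc$death, aging, dt, division_mean, division_sd,
                   D, production, as.integer(n_events), count_shedding,
                   as.integer(max_cells), max_steps)
  } else {
    run_engine_r(rule, aging = aging, dt = dt,
                 division_mean = division_mean, division_sd = division_sd,
                 D = D, production = production,
                 n_events = as.integer(n_events),
                 count_shedding = count_shedding,
                 max_cells = max_cells, max_steps = max_steps)
  }
  offspring <- split_offspring(raw$offspring_concat, raw$n_offspring)
  events <- tibble::tibble(
    event = seq_along(raw$time),
    time = raw$time,
    parent_size = raw$parent_size,
    n_offspring = raw$n_offspring,
    offspring = offspring,
    mode = classify_events(raw$parent_size, offspring),
    rule = rule_label(rule)
  )
  structure(list(
    events = events,
    config = list(rule = rule, n_events = n_events, seed = seed, dt = dt,
                  division_mean = division_mean, division_sd = division_sd,
                  D = D, production = production, aging = aging,
                  count_shedding = count_shedding),
    n_shed = raw$n_shed, n_extinct = raw$n_extinct, n_steps = raw$n_steps
  ), class = "filament_sim")
}

split_offspring <- function(concat, lengths) {
  if (length(concat) == 0) return(list())
  unname(split(as.integer(concat),
               rep(seq_along(lengths), times = lengths)))
}

#' @export
print.filament_sim <- function(x, ...) {
  cat("<filament_sim> ", nrow(x$events), " fragmentation events, rule: ",
      rule_label(x$config$rule), "\n", sep = "")
  print(x$events, ...)
  invisible(x)
}

#' Run many independent simulations and pool their events
#'
#' Launches `ceiling(n_events_total / events_per_run)` independent runs
#' with distinct child seeds derived from `seed`, pools the event logs, and
#' truncates to exactly `n_events_total` events. Child streams share no
#' state, and a fixed `seed` reproduces the full pooled log.
#'
#' @inheritParams simulate_filaments
#' @param n_events_total Total fragmentation events to keep.
#' @param events_per_run Events per independent run (each run restarts from
#'   a single cell).
#' @return A tibble of events as in [simulate_filaments()], with an extra
#'   `run` column.
#' @export
simulate_batch <- function(rule, n_events_total, events_per_run = 100,
                           seed = 1, ...) {
  stopifnot(n_events_total >= 1, events_per_run >= 1)
  n_runs <- ceiling(n_events_total / events_per_run)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  events <- purrr::map2_dfr(child_seeds, seq_len(n_runs), function(s, r) {
    sim <- simulate_filaments(rule, n_events = events_per_run, seed = s, ...)
    dplyr::mutate(sim$events, run = r, .before = 1)
  })
  dplyr::slice_head(events, n = n_events_total)
}

# ---- pure-R reference engine ------------------------------------------------
#
# Composes the exported building blocks (advance_ages, diffuse_step,
# divide_cell, eval_rule, apply_decision) into the same loop as the
# compiled engine, consuming the random stream in exactly the same order.
# Used by the test suite to cross-validate the compiled path; far too slow
# for production batches.
#
# Division-driven cues (stress, stochastic_at_division) can only newly
# fire when a division changes the filament, so they are re-evaluated
# after every single division; a firing ends the step's division
# processing (remaining due cells divide next step). The time-driven cues
# are evaluated once on the end-of-step state.
run_engine_r <- function(rule, aging, dt, division_mean, division_sd,
                         D, production, n_events, count_shedding,
                         max_cells, max_steps) {
  division_driven <- inherits(rule, "frag_rule") &&
    rule$cue %in% c("stress", "stochastic_at_division")
  stoch_div <- inherits(rule, "frag_rule") &&
    rule$cue == "stochastic_at_division"
  f <- filament(1, next_division_at = draw_division_interval(
    division_mean, division_sd, dt))
  ev_time <- double(0); ev_parent <- integer(0)
  off_len <- integer(0); off_concat <- integer(0)
  n_shed <- 0L; n_extinct <- 0L
  step <- 0

  # apply a nonempty decision; returns the continuing filament (NULL on
  # extinction, which restarts from a fresh founder)
  settle <- function(decision, t) {
    res <- apply_decision(f, decision)
    n_frag <- length(res$fragments)
    if (n_frag >= 2) {
      ev_time <<- c(ev_time, t)
      ev_parent <<- c(ev_parent, res$parent_size)
      off_len <<- c(off_len, n_frag)
      off_concat <<- c(off_concat, res$offspring_sizes)
      tied <- which(res$offspring_sizes == max(res$offspring_sizes))
      keep <- if (length(tied) == 1) tied else {
        u <- stats::runif(1)
        tied[1L + min(floor(u * length(tied)), length(tied) - 1L)]
      }
      res$fragments[[keep]]
    } else if (n_frag == 1) {
      n_shed <<- n_shed + 1L
      if (count_shedding) {
        ev_time <<- c(ev_time, t)
        ev_parent <<- c(ev_parent, res$parent_size)
        off_len <<- c(off_len, 1L)
        off_concat <<- c(off_concat, res$offspring_sizes)
      }
      res$fragments[[1]]
    } else {
      n_extinct <<- n_extinct + 1L
      NULL
    }
  }

  while (length(ev_time) < n_events) {
    step <- step + 1
    if (step > max_steps)
      stop("rule never produced ", n_events,
           " fragmentation events within the step budget")
    t <- step * dt
    n <- n_cells(f)
    if (n > max_cells)
      stop("filament exceeded ", max_cells, " cells without fragmenting")

    f <- advance_ages(f, dt)
    f <- diffuse_step(f, D = D, production = production)

    due <- which(f$next_div <= t)
    fired <- FALSE
    for (k in seq_along(due)) {
      i <- due[k] + (k - 1L)
      f <- divide_cell(f, i, t, division_mean, division_sd, dt, aging)
      if (!division_driven) next
      decision <- if (stoch_div) {
        # the new connection is tested once, at creation
        if (stats::runif(1) < rule$theta) {
          list(sever = i,
               kill = if (rule$death) unique(kill_adjacent(i)) else integer(0))
        } else empty_decision()
      } else {
        eval_rule(f, rule)  # stress: profile only changes at divisions
      }
      if (!decision_is_empty(decision)) {
        f <- settle(decision, t)
        fired <- TRUE
        break
      }
    }
    if (is.null(f)) {
      f <- filament(1, next_division_at = t + draw_division_interval(
        division_mean, division_sd, dt))
      next
    }
    if (fired || division_driven) next

    decision <- eval_rule(f, rule)
    if (decision_is_empty(decision)) next
    f <- settle(decision, t)
    if (is.null(f)) {
      f <- filament(1, next_division_at = t + draw_division_interval(
        division_mean, division_sd, dt))
    }
  }
  list(time = ev_time, parent_size = ev_parent, n_offspring = off_len,
       offspring_concat = off_concat, n_shed = n_shed,
       n_extinct = n_extinct, n_steps = step)
}
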