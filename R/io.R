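#' Write and read event logs as CSV
#'
#' One row per fragmentation event; offspring sizes are serialised into a
#' single semicolon-joined column so the file stays one-row-per-event. The
#' round trip `read_events(write_events(x, path))` reproduces the event
#' tibble exactly (modes are re-derived from the sizes).
#'
#' @param events An event tibble from [simulate_filaments()] or
#'   [simulate_batch()].
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns the event tibble.
#' @export
write_events <- function(events, path) {
  flat <- dplyr::mutate(events,
    offspring = vapply(.data$offspring, paste, character(1),
                       collapse = ";"),
    mode = as.character(.data$mode))
  utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  offspring <- lapply(strsplit(flat$offspring, ";", fixed = TRUE),
                      as.integer)
  out <- tibble::as_tibble(flat)
  out$offspring <- offspring
  out$mode <- classify_events(out$parent_size, offspring)
  out
}

#' Write aggregate summaries as JSON
#'
#' Serialises [adult_size_summary()], [mode_frequencies()], and
#' [size_histogram()] of an event log into one JSON document.
#'
#' @inheritParams write_events
#' @param target_size Target adult size for the error fields.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(events, path, target_size = 32) {
  sizes <- adult_size_summary(events, target_size)
  modes <- mode_frequencies(events)
  hist <- size_histogram(events)
  payload <- list(
    target_size = target_size,
    n_events = sizes$n_events,
    mean_adult_size = sizes$mean_adult_size,
    sd_adult_size = sizes$sd_adult_size,
    mse_vs_target = sizes$mse_vs_target,
    fraction_at_target = sizes$fraction_at_target,
    mode_frequencies = stats::setNames(as.list(modes$frequency),
                                       as.character(modes$mode)),
    histogram = stats::setNames(as.list(hist$n),
                                as.character(hist$parent_size))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Default simulation configuration
#'
#' The packaged defaults: step size 0.01, division intervals normal with
#' mean 1 and standard deviation 0.05, compound production 1 per step with
#' exchange fraction 0.01, 100 fragmentation events per run, target adult
#' size 32.
#'
#' @return A named list understood by [read_config()] and the CLI.
#' @export
default_config <- function() {
  list(
    rule = "stress", theta = NULL, theta2 = NULL, rule2 = NULL,
    logic = NULL, death = FALSE, aging = FALSE,
    dt = 0.01, division_mean = 1, division_sd = 0.05,
    D = 0.01, production = 1,
    n_events = 100, events_per_run = 100, target_size = 32,
    seed = 1, count_shedding = FALSE
  )
}

#' Read a YAML configuration, filling in packaged defaults
#'
#' @param path Path to a flat YAML file whose keys are a subset of
#'   [default_config()].
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}

config_rule <- function(config) {
  if (is.null(config$theta))
    stop("missing config key: theta")
  r1 <- frag_rule(config$rule, config$theta, death = isTRUE(config$death))
  if (!is.null(config$rule2)) {
    if (is.null(config$theta2)) stop("missing config key: theta2")
    if (is.null(config$logic)) stop("missing config key: logic")
    return(combined_rule(r1, frag_rule(config$rule2, config$theta2),
                         logic = toupper(config$logic)))
  }
  r1
}
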