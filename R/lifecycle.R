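#' The five reproduction modes
#'
#' @return Character vector of mode labels in classification precedence
#'   order.
#' @export
reproduction_modes <- function() {
  c("complete_dissociation", "unicellular_propagule", "equal_binary",
    "unequal_binary", "other")
}

#' Classify one fragmentation event into a reproduction mode
#'
#' Given the parent size and the sizes of the viable offspring, assigns
#' exactly one of five modes, checked in precedence order:
#'
#' 1. `complete_dissociation` — every offspring is a single cell;
#' 2. `unicellular_propagule` — at least one single-cell offspring and at
#'    least one multicellular offspring;
#' 3. `equal_binary` — exactly two offspring, each between 40% and 60% of
#'    the parent size (bounds inclusive);
#' 4. `unequal_binary` — exactly two offspring not matching any of the
#'    above;
#' 5. `other` — everything else (three or more offspring, none unicellular).
#'
#' The precedence order resolves the overlaps: a 2-cell parent splitting
#' into (1, 1) is complete dissociation, and a (1, n-1) split is a
#' unicellular propagule even when n is small enough for the singleton to
#' fall in the 40–60% band.
#'
#' @param parent_size Cells in the parent immediately before fragmentation.
#' @param offspring_sizes Integer vector of viable offspring sizes (at
#'   least two).
#' @return One of [reproduction_modes()], as a character scalar.
#' @examples
#' classify_event(32, c(16, 16)) # equal_binary
#' classify_event(32, c(1, 31))  # unicellular_propagule
#' classify_event(10, c(2, 3, 5)) # other
#' @export
classify_event <- function(parent_size, offspring_sizes) {
  stopifnot(length(offspring_sizes) >= 2, all(offspring_sizes >= 1),
            parent_size >= sum(offspring_sizes))
  if (all(offspring_sizes == 1)) return("complete_dissociation")
  if (any(offspring_sizes == 1) && any(offspring_sizes > 1))
    return("unicellular_propagule")
  if (length(offspring_sizes) == 2) {
    frac <- offspring_sizes / parent_size
    if (all(frac >= 0.4) && all(frac <= 0.6)) return("equal_binary")
    return("unequal_binary")
  }
  "other"
}

#' Classify a list of events at once
#'
#' Vectorised companion of [classify_event()].
#'
#' @param parent_sizes Integer vector.
#' @param offspring List of integer vectors, one per event.
#' @return Factor with levels [reproduction_modes()].
#' @export
classify_events <- function(parent_sizes, offspring) {
  stopifnot(length(parent_sizes) == length(offspring))
  modes <- mapply(function(p, off) {
    if (length(off) < 2) NA_character_ else classify_event(p, off)
  }, parent_sizes, offspring)
  factor(modes, levels = reproduction_modes())
}

#' Count integer partitions with a minimum number of parts
#'
#' The number of unordered ways to partition `n` cells into offspring
#' groups with at least `min_parts` groups. `count_partitions(10, 1)` is
#' the full partition number p(10) = 42; `count_partitions(32, 2) = 8348`
#' excludes the single-group "partition" (the filament not fragmenting at
#' all), which is the relevant count of distinct reproductive allocations
#' for a 32-cell adult. The two conventions differ by exactly one, so both
#' are exposed through `min_parts`.
#'
#' Computed by dynamic programming over the largest allowed part (a
#' partition into at most k parts is, by conjugation, a partition into
#' parts of size at most k); exact in double precision far beyond the sizes
#' relevant here.
#'
#' @param n Number of cells, >= 1.
#' @param min_parts Minimum number of parts, >= 1.
#' @return A count (numeric, exact integer value).
#' @examples
#' count_partitions(10) # 42
#' count_partitions(32, min_parts = 2) # 8348
#' @export
count_partitions <- function(n, min_parts = 1) {
  stopifnot(n >= 1, min_parts >= 1, n == round(n), min_parts == round(min_parts))
  if (min_parts > n) return(0)
  partitions_at_most(n, n) - if (min_parts > 1)
    partitions_at_most(n, min_parts - 1) else 0
}

# partitions of n into at most k parts
partitions_at_most <- function(n, k) {
  ways <- c(1, rep(0, n))  # ways[j + 1] = partitions of j, parts <= current
  for (part in seq_len(min(k, n))) {
    for (j in part:n) ways[j + 1] <- ways[j + 1] + ways[j - part + 1]
  }
  ways[n + 1]
}
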