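# Brute-force oracles, written independently of the package internals:
# naive loops and explicit enumeration only.

# filament with reproducible, generic state (no exact ties anywhere)
random_filament <- function(n, seed) {
  set.seed(seed)
  filament(
    n,
    pole_left = round(runif(n, 0, 10), 3),
    pole_right = round(runif(n, 0, 10), 3),
    compound = round(runif(n, 0, 20), 3),
    next_division_at = Inf,
    connection_age = if (n > 1) round(runif(n - 1, 0, 10), 3) else 0
  )
}

# stress by explicit neighbour counting
brute_stress <- function(f, i) {
  n <- n_cells(f)
  left <- 0
  for (j in seq_len(n)) if (j < i) left <- left + 1
  right <- 0
  for (j in seq_len(n)) if (j > i) right <- right + 1
  min(left, right)
}

# all unordered partitions of n (list of sorted integer vectors)
enumerate_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in enumerate_partitions(n - p, p)) {
      out[[length(out) + 1]] <- c(p, rest)
    }
  }
  out
}

# independent per-rule severing decisions for tie-free states; each a naive
# re-reading of the rule definitions
brute_cell_age_decision <- function(f, theta) {
  sever <- integer(0)
  n <- n_cells(f)
  for (i in seq_len(n)) {
    age <- (f$pole_l[i] + f$pole_r[i]) / 2
    if (age > theta && n > 1) {
      adjacent <- c(if (i > 1) i - 1L, if (i < n) i)
      sever <- c(sever, adjacent[which.max(f$conn_age[adjacent])])
    }
  }
  sort(unique(sever))
}

brute_connection_age_decision <- function(f, theta) {
  sever <- integer(0)
  for (j in seq_along(f$conn_age)) {
    if (f$conn_age[j] > theta) sever <- c(sever, j)
  }
  sever
}

brute_compound_decision <- function(f, theta) {
  sever <- integer(0)
  n <- n_cells(f)
  for (i in seq_len(n)) {
    if (f$compound[i] > theta && n > 1) {
      if (i == 1) sever <- c(sever, 1L)
      else if (i == n) sever <- c(sever, n - 1L)
      else if (f$compound[i - 1] > f$compound[i + 1]) sever <- c(sever, i - 1L)
      else sever <- c(sever, i)
    }
  }
  sort(unique(sever))
}

brute_stress_decision <- function(f, theta) {
  sever <- integer(0)
  n <- n_cells(f)
  for (i in seq_len(n)) {
    nl <- i - 1; nr <- n - i
    if (min(nl, nr) > theta && nl != nr) {
      sever <- c(sever, if (nl > nr) i - 1L else i)
    }
  }
  sort(unique(sever))
}

# mirror a severing decision for a filament of n cells
mirror_decision <- function(decision, n) {
  list(sever = sort(n - decision$sever),
       kill = sort(n + 1L - decision$kill))
}
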