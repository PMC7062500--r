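# Independent oracles and shared fixtures for the test suite.

# ---- shared cells (built once per test run) --------------------------------

.fixtures <- new.env(parent = emptyenv())

fixture_cell <- function(seed = 1L) {
  key <- paste0("cell", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- build_cell(generate_reduced_ca1(seed = seed))
  }
  .fixtures[[key]]
}

strip_active <- function(cell) {
  for (f in c("gna", "gkdr", "gka", "gcal", "gkca", "ncx_vmax")) {
    cell$densities[[f]][] <- 0
  }
  cell
}

# ---- dense solver oracle for the Hines solve -------------------------------

dense_tree_solve <- function(parent, dg, off, rhs) {
  n <- length(dg)
  A <- matrix(0, n, n)
  diag(A) <- dg
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0) { A[i, p] <- off[i]; A[p, i] <- off[i] }
  }
  solve(A, rhs)
}

# random tree system: diagonally dominant, symmetric tree-sparse
random_tree_system <- function(n, seed) {
  set.seed(seed)
  parent <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  off <- c(0, -runif(n - 1, 0.1, 2))
  dg <- runif(n, 0.5, 2)
  for (i in 2:n) {           # make strictly diagonally dominant
    dg[i] <- dg[i] + abs(off[i])
    dg[parent[i]] <- dg[parent[i]] + abs(off[i])
  }
  list(parent = parent, dg = dg, off = off, rhs = rnorm(n))
}

# ---- naive transcription of the SPIKE-synchronization definition ----------
# Written directly from the published adaptive-coincidence rule, loop by
# loop, independently of the package implementation.

oracle_spike_sync <- function(x, y) {
  if (!length(x) || !length(y)) return(if (!length(x) && !length(y)) NA_real_ else 0)
  count_one <- function(a, b) {
    total <- 0
    for (i in seq_along(a)) {
      # nearest spike in b
      best_j <- 1
      for (j in seq_along(b)) {
        if (abs(b[j] - a[i]) < abs(b[best_j] - a[i])) best_j <- j
      }
      # neighbouring ISIs around a[i] and b[best_j]
      isis <- numeric(0)
      if (length(a) >= 2) {
        if (i > 1) isis <- c(isis, a[i] - a[i - 1])
        if (i < length(a)) isis <- c(isis, a[i + 1] - a[i])
      }
      if (length(b) >= 2) {
        if (best_j > 1) isis <- c(isis, b[best_j] - b[best_j - 1])
        if (best_j < length(b)) isis <- c(isis, b[best_j + 1] - b[best_j])
      }
      tau <- if (length(isis)) min(isis) / 2 else Inf
      if (abs(a[i] - b[best_j]) < tau) total <- total + 1
    }
    total
  }
  (count_one(x, y) + count_one(y, x)) / (length(x) + length(y))
}

oracle_sync_matrix <- function(trains) {
  n <- length(trains)
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- if (inherits(trains[[i]], "spike_train")) trains[[i]]$times else trains[[i]]
      tj <- if (inherits(trains[[j]], "spike_train")) trains[[j]]$times else trains[[j]]
      m[i, j] <- m[j, i] <- oracle_spike_sync(ti, tj)
    }
  }
  m
}

# random spike-train sets for the metric cross-check
random_train_set <- function(n_trains, seed, rate_hz = 8, duration = 1000) {
  set.seed(seed)
  lapply(seq_len(n_trains), function(i) {
    t <- cumsum(rexp(200, rate_hz / 1000))
    spike_train(t[t < duration], c(0, duration))
  })
}
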