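# Shared fixtures and independent oracles, built in code at test time.

# Compact three-level phantom used by most unit tests (full anatomy, smaller
# grid than the default five-level spec).
small_spec <- function(noise_sd = 0, ...) {
  phantom_spec(grid_shape = c(76, 80, 112), spacing = c(1.5, 1.5, 1.5),
               n_discs = 3, noise_sd = noise_sd, ...)
}

# Cached phantom for read-only tests within one test run.
.small_ph <- NULL
get_small_phantom <- function() {
  if (is.null(.small_ph))
    .small_ph <<- generate_phantom(small_spec(), intensity = TRUE)
  .small_ph
}

# Brute-force local-maximum scan: for every voxel above threshold, compare
# against all in-bounds 26-neighbours with the same plateau tie-break
# (equal-valued neighbour at a lower linear index wins).
oracle_local_maxima <- function(ch, threshold) {
  dims <- dim(ch)
  hits <- integer(0)
  for (lin in which(ch > threshold)) {
    idx <- arrayInd(lin, dims)
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- idx + c(dx, dy, dz)
      if (any(nb < 1) || any(nb > dims)) next
      nlin <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
      if (ch[nlin] > ch[lin] || (ch[nlin] == ch[lin] && nlin < lin)) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, lin)
  }
  sort(hits)
}

# Exhaustive enumeration of order-preserving injective assignments of
# template labels to Z-sorted candidates (independent of match_template's
# depth-first search). Returns the minimum matching error and the best
# candidate rows per label.
oracle_match_template <- function(pool, tmat) {
  pool <- pool[order(-pool$z), , drop = FALSE]
  d <- nrow(tmat)
  m <- nrow(pool)
  k <- min(d, m)
  dmat <- as.matrix(stats::dist(as.matrix(pool[, c("x", "y", "z")])))
  lab_sets <- utils::combn(d, k)
  cand_sets <- utils::combn(m, k)
  best_err <- Inf
  best <- NULL
  for (ls in seq_len(ncol(lab_sets))) {
    L <- lab_sets[, ls]
    err <- numeric(ncol(cand_sets))
    if (k >= 2) {
      for (a in 1:(k - 1)) for (b in (a + 1):k) {
        err <- err + abs(dmat[cbind(cand_sets[a, ], cand_sets[b, ])] -
                           tmat[L[a], L[b]])
      }
    }
    i <- which.min(err)
    if (err[i] < best_err) {
      best_err <- err[i]
      rows <- rep(NA_integer_, d)
      rows[L] <- cand_sets[, i]
      best <- rows
    }
  }
  list(err = best_err, rows = best, pool = pool)
}

random_candidate_pool <- function(d, max_per_channel = 3, spacing = 37) {
  n_per <- sample.int(max_per_channel, d, replace = TRUE)
  rows <- list()
  for (ch in seq_len(d)) {
    for (r in seq_len(n_per[ch])) {
      rows[[length(rows) + 1]] <- data.frame(
        x = stats::runif(1, -20, 20),
        y = stats::runif(1, -20, 20),
        z = (d - ch) * spacing + stats::rnorm(1, 0, 8),
        heat = stats::runif(1, 129, 256),
        channel = paste0("ch", ch), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

expect_unit <- function(v) expect_lt(abs(sqrt(sum(v^2)) - 1), 1e-9)
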