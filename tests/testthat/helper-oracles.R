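# Independent oracles used across the test files.

# Recursive (memoized) optimal-string-alignment distance, written from the
# recurrence rather than the iterative DP used by the package.
osa_ref <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- if (i == 0) j else if (j == 0) i else {
      best <- min(f(i - 1, j) + 1, f(i, j - 1) + 1,
                  f(i - 1, j - 1) + (A[i] != B[j]))
      if (i > 1 && j > 1 && A[i] == B[j - 1] && A[i - 1] == B[j])
        best <- min(best, f(i - 2, j - 2) + 1)
      best
    }
    memo[[key]] <- res
    res
  }
  f(length(A), length(B))
}

# Exhaustive one-to-one matching over a similarity matrix: maximize the
# number of pairs at/above the threshold, then total similarity.
brute_force_matching <- function(sim, threshold) {
  nt <- nrow(sim); na <- ncol(sim)
  best <- list(count = -1L, total = -Inf, pairs = NULL)
  rec <- function(ti, used_a, pairs) {
    if (ti > nt) {
      count <- nrow(pairs)
      total <- if (count) sum(sim[cbind(pairs$ti, pairs$ai)]) else 0
      if (count > best$count ||
          (count == best$count && total > best$total + 1e-12)) {
        best <<- list(count = count, total = total, pairs = pairs)
      }
      return(invisible())
    }
    rec(ti + 1L, used_a, pairs)  # leave this TRO unmatched
    for (ai in seq_len(na)) {
      if (!used_a[ai] && sim[ti, ai] >= threshold) {
        u <- used_a; u[ai] <- TRUE
        rec(ti + 1L, u, rbind(pairs, data.frame(ti = ti, ai = ai)))
      }
    }
  }
  rec(1L, logical(na), data.frame(ti = integer(), ai = integer()))
  best
}

# Textbook potential scale reduction factor, computed with explicit loops.
psrf_ref <- function(mat) {
  m <- nrow(mat)
  ch_means <- ch_vars <- numeric(ncol(mat))
  for (c in seq_len(ncol(mat))) {
    ch_means[c] <- sum(mat[, c]) / m
    ch_vars[c] <- sum((mat[, c] - ch_means[c])^2) / (m - 1)
  }
  W <- mean(ch_vars)
  B <- m * sum((ch_means - mean(ch_means))^2) / (length(ch_means) - 1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

# Minimal valid listings table builder.
make_listings <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(listing_id = r[[1]], name = r[[2]], address = r[[3]],
               latitude = as.numeric(r[[4]]), longitude = as.numeric(r[[5]]),
               outlet_class = r[[6]], block_group_id = r[[7]])))
}

# Small prepared dataset for fit tests.
small_synth_data <- function(seed = 7, rows = 10, cols = 10, ...) {
  synth <- generate_areal_dataset(
    synthetic_config(lattice_rows = rows, lattice_cols = cols,
                     seed = seed, ...))
  list(synth = synth,
       data = prepare_ndi_data(filter_units(synth$block_groups)$records,
                               synth$adjacency))
}
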