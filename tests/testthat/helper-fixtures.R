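# Shared fixtures and independent oracles for the test suite.

# small landscape used by most unit tests
tiny_cfg <- function(nrows = 20L, ncols = 20L, seed = 1L, ...) {
  landscape_config(grid_nrows = nrows, grid_ncols = ncols, seed = seed,
                   buffer_pixels = 2L, ...)
}

# Independent clustering oracle: all-pairs adjacency then breadth-first
# connected components. Quadratic and naive on purpose: no shared code with
# the union-find path.
oracle_cluster <- function(records, max_gap_days = 5L, connectivity = 8L) {
  n <- nrow(records)
  if (n == 0L) return(integer(0))
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dr <- abs(records$row[i] - records$row[j])
      dc <- abs(records$col[i] - records$col[j])
      spatial <- if (connectivity == 8L) dr <= 1L && dc <= 1L
                 else (dr + dc) <= 1L
      if (spatial &&
          abs(records$burn_date[i] - records$burn_date[j]) <= max_gap_days)
        adj[[i]] <- c(adj[[i]], j)
    }
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# do two labelings define the same partition?
same_partition <- function(a, b) {
  ta <- table(a, b)
  all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}

# random burn records on a small grid (unique pixel-date triples)
random_records <- function(n, nrows, ncols, date_range = c(0L, 40L),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- NULL
  seen <- character(0)
  while (is.null(out) || nrow(out) < n) {
    row <- sample.int(nrows, 1)
    col <- sample.int(ncols, 1)
    d <- sample(seq(date_range[1], date_range[2]), 1)
    key <- paste(row, col, d)
    if (key %in% seen) next
    seen <- c(seen, key)
    out <- rbind(out, data.frame(row = row, col = col, burn_date = d))
  }
  out
}

# uniform monthly rainfall series over given years
uniform_rain <- function(value, years, nr = 3L, nc = 3L, px = 5000) {
  time <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  time <- time[order(time$year, time$month), ]
  arr <- array(value, c(nr, nc, nrow(time)))
  fr_series(arr, time, pixel_size = px)
}
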