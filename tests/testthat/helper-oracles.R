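# Independent brute-force oracles.  These deliberately use naive scans and
# the definition of each rule, never the package's implementation path.

# First window (0-based) starting a run of >= k consecutive sleeping windows.
bf_bed <- function(states, k) {
  n <- length(states)
  for (i in seq_len(n - k + 1L))
    if (all(states[i:(i + k - 1L)] == "sleeping")) return(i - 1L)
  NA_integer_
}

# Start of the terminal awake run (>= k, extending to the night's end),
# strictly after bed.
bf_wake <- function(states, k, bed) {
  n <- length(states)
  for (i in (bed + 2L):n) {           # 1-based position after bed window
    if (n - i + 1L < k) break
    if (all(states[i:n] == "awake")) {
      if (i > 1L && states[i - 1L] == "awake") next  # not a run start
      return(i - 1L)
    }
  }
  NA_integer_
}

# Maximal awake runs strictly inside windows bed..wake-1 (0-based), and
# their total duration in windows.
bf_interruptions <- function(states, bed, wake) {
  seg <- states[(bed + 1L):wake]      # 1-based slice of windows bed..wake-1
  n_runs <- 0L; n_awake <- 0L; prev_awake <- FALSE
  for (s in seg) {
    aw <- s == "awake"
    if (aw) {
      n_awake <- n_awake + 1L
      if (!prev_awake) n_runs <- n_runs + 1L
    }
    prev_awake <- aw
  }
  list(n = n_runs, duration_windows = n_awake)
}

# Boxplot gap rule: keep events whose min-neighbour gap is within
# Q3 + 1.5 IQR of the stream's gaps; streams of < 4 events untouched.
bf_gap_keep <- function(times) {
  n <- length(times)
  if (n < 4L) return(rep(TRUE, n))
  gap <- numeric(n)
  for (i in seq_len(n)) {
    prev <- if (i > 1L) times[i] - times[i - 1L] else Inf
    nxt <- if (i < n) times[i + 1L] - times[i] else Inf
    gap[i] <- min(prev, nxt)
  }
  q1 <- quantile(gap, 0.25, names = FALSE)
  q3 <- quantile(gap, 0.75, names = FALSE)
  gap <= q3 + 1.5 * (q3 - q1)
}

# Benjamini-Hochberg by the definition: adjusted p_(i) is the minimum over
# j >= i of m * p_(j) / j, capped at 1.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Direct per-window majority-vote grid for one participant-night and a
# non-state-machine sensor: events (POSIXct, logical sleeping), night date.
bf_night_grid <- function(timestamps, sleeping, night_date) {
  start <- as.POSIXct(paste(night_date, "22:00:00"), tz = "UTC")
  states <- character(144)
  prev <- "missing"
  for (w in 0:143) {
    lo <- start + w * 300; hi <- lo + 300
    sel <- timestamps >= lo & timestamps < hi
    ns <- sum(sleeping[sel]); na_ <- sum(!sleeping[sel])
    states[w + 1L] <-
      if (ns + na_ == 0L) "missing"
      else if (ns > na_) "sleeping"
      else if (na_ > ns) "awake"
      else prev                        # tie inherits previous resolved state
    prev <- states[w + 1L]
  }
  # carry forward over missing windows after the first non-missing one
  seen <- FALSE
  for (w in seq_along(states)) {
    if (states[w] != "missing") { seen <- TRUE; last <- states[w] }
    else if (seen) states[w] <- last
  }
  states
}
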