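# Independent brute-force oracles and shared fixtures for the test suite.

# O(n^2) windowed-count burst search: the reference the fast implementation
# must reproduce. Mirrors the documented semantics literally.
oracle_find_bursts <- function(stream, window_ms = 0.5, min_counts = 35,
                               m = 10) {
  t <- stream$timestamp_ns
  n <- length(t)
  if (n == 0)
    return(data.frame(i_start = integer(), i_stop = integer()))
  w <- window_ms * 1e6
  in_burst <- vapply(seq_len(n), function(i)
    sum(t >= t[i] - w / 2 & t <= t[i] + w / 2) >= m, logical(1))
  idx <- which(in_burst)
  if (!length(idx)) return(data.frame(i_start = integer(), i_stop = integer()))
  # maximal runs, then merge across gaps <= window
  runs <- split(idx, cumsum(c(TRUE, diff(idx) > 1 | diff(t[idx]) > w)))
  starts <- vapply(runs, min, integer(1))
  ends <- vapply(runs, max, integer(1))
  o <- order(starts); starts <- starts[o]; ends <- ends[o]
  i <- 1
  while (i < length(starts)) {
    if (t[starts[i + 1]] - t[ends[i]] <= w) {
      ends[i] <- max(ends[i], ends[i + 1])
      starts <- starts[-(i + 1)]; ends <- ends[-(i + 1)]
    } else i <- i + 1
  }
  keep <- (ends - starts + 1) > min_counts
  data.frame(i_start = starts[keep], i_stop = ends[keep] + 1L)
}

# Naive per-burst channel tally.
oracle_tally <- function(stream, i0, i1) {
  s <- stream[seq.int(i0, i1 - 1L), ]
  c(F_DD = sum(s$channel == "donor_em" & s$excitation == "donor_ex"),
    F_DA = sum(s$channel == "acceptor_em" & s$excitation == "donor_ex"),
    F_AA = sum(s$channel == "acceptor_em" & s$excitation == "acceptor_ex"))
}

# Naive histogram binning with clipping.
oracle_bin <- function(e, bin_width, range) {
  edges <- seq(range[1], range[2] + bin_width / 2, by = bin_width)
  e <- pmin(pmax(e, range[1] + 1e-12), edges[length(edges)] - 1e-12)
  counts <- integer(length(edges) - 1)
  for (v in e) {
    i <- max(1, min(length(counts), ceiling((v - range[1]) / bin_width)))
    counts[i] <- counts[i] + 1L
  }
  counts
}

# Direct double-loop Debye sum over CA beads.
oracle_debye <- function(model, q, f = 1) {
  xyz <- as.matrix(model$atoms[model$atoms$name == "CA", c("x", "y", "z")])
  n <- nrow(xyz)
  vapply(q, function(qq) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      s <- s + if (r == 0 || qq == 0) f^2 else f^2 * sin(qq * r) / (qq * r)
    }
    s
  }, numeric(1))
}

# Burst-level fast path through correction + gating, with the same strict
# count threshold the burst search applies.
gated_bursts <- function(states, n, seed, corrections = correction_set(),
                         min_photons = 35) {
  cfg <- sim_config(states = states, corrections = corrections, seed = seed)
  b <- simulate_bursts(cfg, ceiling(n * 1.9), seed = seed,
                       min_photons = min_photons)
  b <- b[seq_len(min(n, nrow(b))), , drop = FALSE]
  filter_stoichiometry(compute_es(b, cfg$corrections))
}

one_state <- function(E) data.frame(fraction = 1, E = E)
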