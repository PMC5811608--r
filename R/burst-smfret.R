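#' Time-tagged PIE photon stream
#'
#' A validated container for one single-molecule measurement: photon arrival
#' times in nanoseconds (strictly increasing), the detection channel of each
#' photon, and the excitation slot it was recorded under (pulsed interleaved
#' excitation assigns each photon to the donor or acceptor laser pulse).
#'
#' @param timestamps_ns Numeric vector, strictly increasing, nanoseconds.
#' @param channel Character/factor in `c("donor_em", "acceptor_em")`.
#' @param excitation Character/factor in `c("donor_ex", "acceptor_ex")`.
#' @return An object of class `photon_stream` (a data.frame).
#' @export
photon_stream <- function(timestamps_ns, channel, excitation) {
  n <- length(timestamps_ns)
  if (length(channel) != n || length(excitation) != n)
    stop_config("timestamps, channel and excitation must have equal length")
  channel <- as.character(channel)
  excitation <- as.character(excitation)
  if (n > 0) {
    if (any(diff(timestamps_ns) <= 0))
      stop_config("timestamps must be strictly increasing")
    if (!all(channel %in% c("donor_em", "acceptor_em")))
      stop_config("unknown detection channel tag")
    if (!all(excitation %in% c("donor_ex", "acceptor_ex")))
      stop_config("unknown excitation tag")
  }
  structure(data.frame(timestamp_ns = as.numeric(timestamps_ns),
                       channel = channel, excitation = excitation,
                       stringsAsFactors = FALSE),
            class = c("photon_stream", "data.frame"))
}

#' Read / write photon streams as plain CSV
#'
#' Columns: `timestamp_ns`, `channel`, `excitation` (and any extra columns,
#' e.g. ground-truth `burst_id`, are carried along on write).
#'
#' @param path File path.
#' @return `read_photon_csv()` returns a [photon_stream()].
#' @export
read_photon_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  st <- photon_stream(d$timestamp_ns, d$channel, d$excitation)
  extra <- setdiff(names(d), names(st))
  for (k in extra) st[[k]] <- d[[k]]
  st
}

#' @rdname read_photon_csv
#' @param stream A [photon_stream()].
#' @export
write_photon_csv <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE)
  invisible(path)
}

#' Spectroscopic correction factors
#'
#' Donor leakage into the acceptor channel (`Lk`), direct excitation of the
#' acceptor by the donor laser (`DE`), and the instrumental gamma factor
#' correcting for unequal detection efficiency / quantum yield of the two
#' channels. Defaults are the values calibrated for the AF555/AF647
#' prothrombin measurements this package models: Lk = 0.08, DE = 0.15,
#' gamma = 0.85.
#'
#' @param Lk Leakage fraction, in `[0, 1)`.
#' @param DE Direct-excitation fraction, in `[0, 1)`.
#' @param gamma Gamma factor, `> 0`.
#' @return An object of class `correction_set`.
#' @export
correction_set <- function(Lk = 0.08, DE = 0.15, gamma = 0.85) {
  if (Lk < 0 || Lk >= 1 || DE < 0 || DE >= 1)
    stop_config("Lk and DE must lie in [0, 1)")
  if (gamma <= 0) stop_config("gamma must be positive")
  structure(list(Lk = Lk, DE = DE, gamma = gamma), class = "correction_set")
}

#' Neutral corrections (no leakage, no direct excitation, gamma = 1).
#' @rdname correction_set
#' @export
neutral_corrections <- function() correction_set(Lk = 0, DE = 0, gamma = 1)

#' All-photon burst search
#'
#' Sliding-window burst detection on all photons regardless of channel: a
#' photon is inside a burst region when the window of width `window_ms`
#' centred on it contains at least `m` photons; maximal runs of in-burst
#' photons closer than one window width are merged; only bursts with
#' strictly more than `min_counts` photons are kept ("more than 35 counts"
#' is read literally, i.e. >= 36).
#'
#' @param stream A [photon_stream()].
#' @param window_ms Search window width in milliseconds (default 0.5 ms).
#' @param min_counts Total-count threshold; bursts must exceed it strictly.
#' @param m Local-count threshold inside the window for region detection.
#' @return A `data.frame` of bursts: `burst_id`, `i_start`, `i_stop`
#'   (half-open photon-index range, 1-based), `t_start_ns`, `t_stop_ns`,
#'   `n_photons`; ordered by start time, non-overlapping.
#' @export
#' @examples
#' cfg <- sim_config(duration = 1, states = data.frame(fraction = 1, E = 0.5))
#' sim <- simulate_photon_stream(cfg)
#' find_bursts(sim$stream)
find_bursts <- function(stream, window_ms = 0.5, min_counts = 35, m = 10) {
  stopifnot(inherits(stream, "photon_stream"))
  if (window_ms <= 0) stop_config("`window_ms` must be positive")
  empty <- data.frame(burst_id = integer(), i_start = integer(),
                      i_stop = integer(), t_start_ns = numeric(),
                      t_stop_ns = numeric(), n_photons = integer())
  n <- nrow(stream)
  if (n == 0) return(empty)
  t <- stream$timestamp_ns
  w <- window_ms * 1e6          # ns
  # photons within [t_i - w/2, t_i + w/2]
  lo <- findInterval(t - w / 2, t, left.open = TRUE)   # photons strictly before lower edge
  hi <- findInterval(t + w / 2, t)                     # photons up to upper edge
  local_counts <- hi - lo
  in_burst <- local_counts >= m
  if (!any(in_burst)) return(empty)

  idx <- which(in_burst)
  brk <- c(TRUE, diff(idx) > 1 | diff(t[idx]) > w)     # new run if gap > window
  run_id <- cumsum(brk)
  starts <- idx[brk]
  ends <- idx[c(brk[-1], TRUE)]

  # merge runs whose inter-burst time gap is below one window width
  if (length(starts) > 1) {
    gap <- t[starts[-1]] - t[ends[-length(ends)]]
    merge_prev <- c(FALSE, gap <= w)
    grp <- factor(cumsum(!merge_prev))   # already in first-appearance order
    grp <- factor(grp, levels = unique(as.character(grp)))
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  n_ph <- ends - starts + 1L
  keep <- n_ph > min_counts
  if (!any(keep)) return(empty)
  starts <- as.integer(starts[keep]); ends <- as.integer(ends[keep])
  data.frame(burst_id = seq_along(starts),
             i_start = starts, i_stop = ends + 1L,
             t_start_ns = t[starts], t_stop_ns = t[ends],
             n_photons = as.integer(ends - starts + 1L))
}

#' Partition a burst's photons by channel and excitation slot
#'
#' Tallies the three PIE count classes inside a burst: `F_DD` donor emission
#' under donor excitation, `F_DA` acceptor emission under donor excitation,
#' `F_AA` acceptor emission under acceptor excitation. Donor emission under
#' acceptor excitation carries no FRET information and is returned as the
#' diagnostic column `F_AD`, excluded from E and S.
#'
#' @param stream A [photon_stream()].
#' @param bursts Burst table from [find_bursts()] (or a single-row subset).
#' @return `bursts` with columns `F_DD`, `F_DA`, `F_AA`, `F_AD` appended.
#' @export
integrate_bursts <- function(stream, bursts) {
  stopifnot(inherits(stream, "photon_stream"))
  n <- nrow(stream)
  if (nrow(bursts) > 0 &&
      (min(bursts$i_start) < 1 || max(bursts$i_stop) > n + 1))
    stop("burst indices out of range for this stream")
  tally <- function(i0, i1, ch, ex) {
    s <- stream[seq.int(i0, i1 - 1L), ]
    sum(s$channel == ch & s$excitation == ex)
  }
  bursts$F_DD <- mapply(tally, bursts$i_start, bursts$i_stop,
                        MoreArgs = list(ch = "donor_em", ex = "donor_ex"))
  bursts$F_DA <- mapply(tally, bursts$i_start, bursts$i_stop,
                        MoreArgs = list(ch = "acceptor_em", ex = "donor_ex"))
  bursts$F_AA <- mapply(tally, bursts$i_start, bursts$i_stop,
                        MoreArgs = list(ch = "acceptor_em", ex = "acceptor_ex"))
  bursts$F_AD <- mapply(tally, bursts$i_start, bursts$i_stop,
                        MoreArgs = list(ch = "donor_em", ex = "acceptor_ex"))
  bursts
}

#' Corrected FRET efficiency and stoichiometry
#'
#' Applies the standard PIE corrections to per-burst channel counts:
#' \deqn{F_{corr} = F_{DA} - Lk\,F_{DD} - DE\,F_{AA}}
#' \deqn{E = F_{corr} / (F_{corr} + \gamma F_{DD})}
#' \deqn{S = (F_{corr} + \gamma F_{DD}) / (F_{corr} + \gamma F_{DD} + F_{AA})}
#' Corrected E may fall slightly outside `[0, 1]`; bursts whose corrected
#' denominator is not positive are flagged invalid (`kept = FALSE`) and must
#' be excluded downstream.
#'
#' @param counts A `data.frame` with columns `F_DD`, `F_DA`, `F_AA` (one row
#'   per burst), e.g. from [integrate_bursts()] or [simulate_bursts()].
#' @param corr A [correction_set()].
#' @return `counts` with columns `E`, `S`, `kept` appended.
#' @export
#' @examples
#' compute_es(data.frame(F_DD = 100, F_DA = 100, F_AA = 100), correction_set())
compute_es <- function(counts, corr = correction_set()) {
  stopifnot(all(c("F_DD", "F_DA", "F_AA") %in% names(counts)))
  f_corr <- counts$F_DA - corr$Lk * counts$F_DD - corr$DE * counts$F_AA
  den_e <- f_corr + corr$gamma * counts$F_DD
  den_s <- den_e + counts$F_AA
  ok <- is.finite(den_e) & den_e > 0 & den_s > 0
  counts$E <- ifelse(ok, f_corr / den_e, NA_real_)
  counts$S <- ifelse(ok, den_e / den_s, NA_real_)
  counts$kept <- ok
  counts
}

#' Stoichiometry gate
#'
#' Retains bursts with `s_min <= S <= s_max` (boundaries inclusive),
#' removing donor-only (S near 1) and acceptor-only (S near 0) molecules so
#' that only dual-labelled molecules enter the population analysis. The
#' default range 0.25-0.75 is the gate used throughout this analysis.
#'
#' @param points Output of [compute_es()].
#' @param s_min,s_max Gate boundaries.
#' @return The gated subset, original order preserved.
#' @export
filter_stoichiometry <- function(points, s_min = 0.25, s_max = 0.75) {
  if (s_min > s_max) stop_config("`s_min` must not exceed `s_max`")
  keep <- !is.na(points$S) & points$kept & points$S >= s_min & points$S <= s_max
  points[keep, , drop = FALSE]
}
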