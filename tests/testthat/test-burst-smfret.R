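test_that("burst search returns nothing on an empty stream", {
  st <- photon_stream(numeric(), character(), character())
  expect_equal(nrow(find_bursts(st)), 0L)
})

test_that("a dense photon cluster flanked by silence is one burst", {
  # 50 photons uniformly covering 0.4 ms, >= 10 ms of silence either side
  t_ns <- sort(c(0, seq(10e6, 10.4e6, length.out = 50), 25e6))
  st <- photon_stream(t_ns, rep("donor_em", 52), rep("donor_ex", 52))
  b <- find_bursts(st, window_ms = 0.5, min_counts = 35)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_photons, 50L)
  expect_equal(b$i_start, 2L)
  expect_equal(b$i_stop, 52L)
})

test_that("the >35-count threshold is strict: 35 photons never qualify", {
  mk <- function(n) {
    t_ns <- seq(10e6, 10e6 + 0.3e6, length.out = n)
    photon_stream(t_ns, rep("donor_em", n), rep("donor_ex", n))
  }
  expect_equal(nrow(find_bursts(mk(35))), 0L)
  expect_equal(nrow(find_bursts(mk(36))), 1L)
})

test_that("burst search matches the brute-force windowed-count oracle on
           random streams", {
  for (s in 1:25) {
    cfg <- sim_config(duration = 0.6, burst_rate = 15,
                      burst_size_mean = 50,
                      states = one_state(0.5), seed = s)
    sim <- simulate_photon_stream(cfg)
    st <- sim$stream
    fast <- find_bursts(st)
    slow <- oracle_find_bursts(st)
    expect_equal(fast$i_start, slow$i_start, info = paste("seed", s))
    expect_equal(fast$i_stop, slow$i_stop, info = paste("seed", s))
  }
})

test_that("burst search is invariant to time translation and trailing
           silence", {
  cfg <- sim_config(duration = 1, states = one_state(0.5), seed = 8)
  st <- simulate_photon_stream(cfg)$stream
  b0 <- find_bursts(st)
  shift <- photon_stream(st$timestamp_ns + 5e9, st$channel, st$excitation)
  b1 <- find_bursts(shift)
  expect_equal(b1$i_start, b0$i_start)
  expect_equal(b1$n_photons, b0$n_photons)
  expect_equal(b1$t_start_ns - 5e9, b0$t_start_ns)
  padded <- photon_stream(c(st$timestamp_ns, max(st$timestamp_ns) + 60e9),
                          c(st$channel, "donor_em"),
                          c(st$excitation, "donor_ex"))
  b2 <- find_bursts(padded)
  expect_equal(b2$i_start, b0$i_start)
  expect_equal(b2$i_stop, b0$i_stop)
})

test_that("burst integration tallies the channel/excitation classes", {
  st <- photon_stream(c(1, 2, 3) * 1e3,
                      c("donor_em", "acceptor_em", "acceptor_em"),
                      c("donor_ex", "donor_ex", "acceptor_ex"))
  b <- data.frame(burst_id = 1L, i_start = 1L, i_stop = 4L,
                  t_start_ns = 1e3, t_stop_ns = 3e3, n_photons = 3L)
  out <- integrate_bursts(st, b)
  expect_equal(c(out$F_DD, out$F_DA, out$F_AA, out$F_AD), c(1, 1, 1, 0))

  n <- 40
  st2 <- photon_stream(seq_len(n) * 1e3, rep("donor_em", n),
                       rep("donor_ex", n))
  b2 <- data.frame(burst_id = 1L, i_start = 1L, i_stop = n + 1L,
                   t_start_ns = 1e3, t_stop_ns = n * 1e3, n_photons = n)
  out2 <- integrate_bursts(st2, b2)
  expect_equal(c(out2$F_DD, out2$F_DA, out2$F_AA), c(n, 0, 0))
})

test_that("burst integration equals an independent tally on random tags", {
  set.seed(99)
  n <- 500
  st <- photon_stream(cumsum(1 + rpois(n, 3)) * 1e3,
                      sample(c("donor_em", "acceptor_em"), n, TRUE),
                      sample(c("donor_ex", "acceptor_ex"), n, TRUE))
  b <- data.frame(burst_id = 1:2, i_start = c(10L, 300L),
                  i_stop = c(200L, 450L),
                  t_start_ns = NA, t_stop_ns = NA, n_photons = c(190L, 150L))
  out <- integrate_bursts(st, b)
  for (i in 1:2) {
    o <- oracle_tally(st, b$i_start[i], b$i_stop[i])
    expect_equal(c(out$F_DD[i], out$F_DA[i], out$F_AA[i]), unname(o))
  }
  expect_error(integrate_bursts(st, transform(b, i_stop = 600L)),
               "out of range")
})

test_that("E/S corrections reproduce hand-evaluated values", {
  # no acceptor signal under donor excitation, neutral corrections
  r0 <- compute_es(data.frame(F_DD = 100, F_DA = 0, F_AA = 50),
                   neutral_corrections())
  expect_equal(r0$E, 0)
  expect_equal(r0$S, 100 / 150)
  # hand evaluation with the calibrated corrections
  r1 <- compute_es(data.frame(F_DD = 100, F_DA = 100, F_AA = 100),
                   correction_set(0.08, 0.15, 0.85))
  expect_equal(r1$E, 77 / 162, tolerance = 1e-12)
  expect_equal(r1$S, 162 / 262, tolerance = 1e-12)
  # default correction set carries the calibrated instrument values
  co <- correction_set()
  expect_equal(c(co$Lk, co$DE, co$gamma), c(0.08, 0.15, 0.85))
})

test_that("neutral corrections reduce E to the proximity ratio", {
  set.seed(2)
  d <- data.frame(F_DD = rpois(50, 40) + 1, F_DA = rpois(50, 30),
                  F_AA = rpois(50, 35))
  r <- compute_es(d, neutral_corrections())
  expect_equal(r$E, d$F_DA / (d$F_DA + d$F_DD))
})

test_that("bursts with a non-positive corrected denominator are flagged", {
  r <- compute_es(data.frame(F_DD = 0, F_DA = 0, F_AA = 50),
                  correction_set())
  expect_false(r$kept)
  expect_true(is.na(r$E))
})

test_that("the stoichiometry gate keeps the 0.25-0.75 band inclusively", {
  pts <- data.frame(F_DD = 1, F_DA = 1, F_AA = 1,
                    E = c(0.5, 0.5, 0.5, 0.5, 0.5),
                    S = c(0.1, 0.25, 0.5, 0.75, 0.9),
                    kept = TRUE)
  out <- filter_stoichiometry(pts)
  expect_equal(out$S, c(0.25, 0.5, 0.75))
  expect_error(filter_stoichiometry(pts, s_min = 0.8, s_max = 0.2),
               "exceed")
})

test_that("the gate removes donor-only bursts at the truth-label rate", {
  cfg <- sim_config(states = one_state(0.5), donor_only_fraction = 0.3,
                    seed = 21)
  b <- simulate_bursts(cfg, 4000, min_photons = 35)
  es <- compute_es(b, cfg$corrections)
  gated <- filter_stoichiometry(es)
  expect_true(all(gated$species == "dual"))
  expect_lt(abs(nrow(gated) / sum(b$species == "dual") - 1), 0.03)
  # donor-only molecules carry no acceptor-excitation photons, so the
  # count threshold already depletes them below their 30% input share
  expect_lt(mean(b$species == "donor_only"), 0.3)
  expect_gt(sum(b$species == "donor_only"), 0)
})

test_that("corrected E round-trips the embedded corruption (median within
           3 standard errors)", {
  for (E_true in c(0.3, 0.58)) {
    g <- gated_bursts(one_state(E_true), 3000, seed = round(1000 * E_true))
    med <- stats::median(g$E)
    # per-burst shot-noise SE of the median
    n_eff <- stats::median(g$F_DD + g$F_DA)
    se_burst <- sqrt(E_true * (1 - E_true) / n_eff)
    se_med <- 1.2533 * se_burst / sqrt(nrow(g))
    expect_lt(abs(med - E_true), 3 * se_med + 0.005)
  }
})
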