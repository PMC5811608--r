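test_that("zero-duration measurement yields an empty stream and truth", {
  cfg <- sim_config(duration = 0, states = one_state(0.5))
  sim <- simulate_photon_stream(cfg)
  expect_equal(nrow(sim$stream), 0L)
  expect_equal(nrow(sim$truth$bursts), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration = -1), "non-negative")
  expect_error(sim_config(states = data.frame(fraction = c(0.5, 0.4),
                                              E = c(0.2, 0.8))), "sum to 1")
  expect_error(sim_config(states = data.frame(fraction = 1, E = 1.2)))
  expect_error(sim_config(background_rates = c(dd = -5)), "background")
})

test_that("pooled acceptor-routing fraction matches the configured E under
           neutral corrections (binomial oracle)", {
  cfg <- sim_config(states = one_state(0.5),
                    corrections = neutral_corrections(), seed = 11)
  b <- simulate_bursts(cfg, 10000)
  n_dex <- sum(b$F_DD) + sum(b$F_DA)        # all donor-slot photons
  p_hat <- sum(b$F_DA) / n_dex
  se <- sqrt(0.5 * 0.5 / n_dex)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("pooled efficiency converges to E* for other state efficiencies", {
  for (E in c(0.2, 0.8)) {
    cfg <- sim_config(states = one_state(E),
                      corrections = neutral_corrections(),
                      seed = round(100 * E))
    b <- simulate_bursts(cfg, 4000)
    n_dex <- sum(b$F_DD) + sum(b$F_DA)
    se <- sqrt(E * (1 - E) / n_dex)
    expect_lt(abs(sum(b$F_DA) / n_dex - E), 3 * se)
  }
})

test_that("photon streams are strictly ordered, correctly tagged and
           bit-reproducible under a fixed seed", {
  cfg <- sim_config(duration = 3, states = one_state(0.4), seed = 42)
  sim1 <- simulate_photon_stream(cfg)
  sim2 <- simulate_photon_stream(cfg)
  expect_identical(sim1$stream, sim2$stream)
  expect_identical(sim1$truth$bursts, sim2$truth$bursts)
  t <- sim1$stream$timestamp_ns
  expect_true(all(diff(t) > 0))
  expect_true(all(sim1$stream$channel %in% c("donor_em", "acceptor_em")))
  expect_true(all(sim1$stream$excitation %in% c("donor_ex", "acceptor_ex")))
  expect_equal(t, round(t))   # integer nanoseconds
})

test_that("ground truth labels exactly one species/state per burst", {
  cfg <- sim_config(duration = 3, states = one_state(0.5),
                    donor_only_fraction = 0.2, seed = 5)
  sim <- simulate_photon_stream(cfg)
  tb <- sim$truth$bursts
  expect_equal(nrow(tb), max(sim$stream$burst_id))
  expect_true(all(tb$species %in% c("dual", "donor_only", "acceptor_only")))
  expect_true(all(is.na(tb$true_E[tb$species != "dual"])))
})

test_that("photon CSV round-trips a stream", {
  cfg <- sim_config(duration = 1, states = one_state(0.5), seed = 3)
  sim <- simulate_photon_stream(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_photon_csv(sim$stream, path)
  back <- read_photon_csv(path)
  expect_equal(back$timestamp_ns, sim$stream$timestamp_ns)
  expect_equal(back$channel, sim$stream$channel)
  expect_equal(back$burst_id, sim$stream$burst_id)
})

test_that("toy structures honour requested site separations exactly", {
  t0 <- generate_toy_structure(n_atoms_per_domain = 5, separation = 0,
                               seed = 1)
  s0 <- attr(t0, "sites")
  expect_equal(ca_distance(t0, t0$atoms$resno[s0[1]], t0$atoms$resno[s0[2]]),
               0)
  t51 <- generate_toy_structure(n_atoms_per_domain = 1, separation = 51,
                                seed = 1)
  expect_equal(ca_distance(t51, 1, 2), 51.0)
  # a 54 A dumbbell emulating the kringle-1 to kringle-2 linker span
  t54 <- generate_toy_structure(n_atoms_per_domain = 30, separation = 54,
                                seed = 2)
  s <- attr(t54, "sites")
  expect_equal(ca_distance(t54, t54$atoms$resno[s[1]], t54$atoms$resno[s[2]]),
               54.0)
  expect_identical(generate_toy_structure(seed = 9)$atoms,
                   generate_toy_structure(seed = 9)$atoms)
  expect_error(generate_toy_structure(separation = -2), ">= 0")
})

test_that("noiseless synthetic scattering equals the forward Debye profile", {
  toy <- generate_toy_structure(n_atoms_per_domain = 15, seed = 4)
  prof0 <- simulate_saxs_curve(toy, noise_fraction = 0, n_points = 40)
  ref <- debye_profile(toy, q_grid = prof0$q)
  expect_equal(prof0$I, ref$I)
})

test_that("chi of the generating model against its own noisy curve is ~1", {
  toy <- generate_toy_structure(n_atoms_per_domain = 15, seed = 4)
  prof <- simulate_saxs_curve(toy, noise_fraction = 0.02, seed = 7)
  fit <- chi_fit(debye_profile(toy, prof$q), prof)
  expect_lt(abs(fit$chi - 1), 0.2)
})

test_that("zero activator gives a flat progress curve", {
  kp <- kinetic_params(E0 = 0)
  pc <- simulate_progress_curve(kp, times = seq(10, 600, by = 10))
  expect_equal(pc$A, rep(0, nrow(pc)))
})

test_that("noiseless progress curves rise parabolically at early times", {
  kp <- kinetic_params()
  t_early <- seq(1, 15, by = 1)   # well inside the onset regime
  pc <- progress_model(kp, t_early)
  ratio <- pc$A / t_early^2
  expect_lt(max(abs(ratio / ratio[1] - 1)), 0.01)
})
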