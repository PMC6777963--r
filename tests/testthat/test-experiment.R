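# Lifecycle, determinism and failure handling of experiment orchestration.
# Runs here use deliberately tiny networks and short phases: they exercise
# the machinery, not the science (which the acceptance suite covers).

test_that("a run is a pure function of configuration and seed", {
  net <- network_preset(0.02)
  sch <- protocol_schedule("uni", c(0.2, 0.8), c(0.5, 0), t_grow = 10,
                           t_stim = 5, t_relax = 5)
  e1 <- run_experiment(sch, network = net, seed = 42, keep_state = TRUE)
  e2 <- run_experiment(sch, network = net, seed = 42, keep_state = TRUE)
  expect_identical(e1$trace, e2$trace)
  expect_identical(e1$state$a, e2$state$a)
  expect_identical(e1$rates, e2$rates)
  e3 <- run_experiment(sch, network = net, seed = 43)
  expect_false(identical(e1$trace, e3$trace))
})

test_that("checkpoints resume exactly", {
  net <- network_preset(0.02)
  g <- grow_network(net, fractions = c(0.2, 0.8), t_grow = 10, seed = 5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(g, path)
  g2 <- load_checkpoint(path)
  sch <- protocol_schedule("uni", c(0.2, 0.8), c(0.5, 0), t_grow = 10,
                           t_stim = 5, t_relax = 5)
  e1 <- stimulate_network(g, sch, seed = 77)
  e2 <- stimulate_network(g2, sch, seed = 77)
  expect_identical(e1$trace, e2$trace)
  expect_identical(e1$final, e2$final)
  unlink(path)
})

test_that("engine window counts agree with the spike-record rates", {
  net <- network_preset(0.02)
  g <- grow_network(net, t_grow = 10, seed = 8)
  sch <- protocol_schedule("uni", 1, 0.1, t_grow = 10, t_stim = 5,
                           t_relax = 5)
  e <- stimulate_network(g, sch, seed = 9, record_spikes = TRUE,
                         window_s = 5)
  memb <- c(rep(1L, net$n_e), rep(2L, net$n_i))
  sp <- e$spikes
  sp$t_ms <- sp$t_ms - g$t_grow * 1000
  fr <- firing_rate(sp, membership = memb, window = 5, t_end = 10)
  eng <- e$rates
  for (w in 1:2) {
    expect_equal(fr$rate[fr$group == 1 & fr$window == w],
                 eng$rate[eng$group == "g1" & eng$window == w],
                 tolerance = 1e-12)
    expect_equal(fr$rate[fr$group == 2 & fr$window == w],
                 eng$rate[eng$group == "inh" & eng$window == w],
                 tolerance = 1e-12)
  }
})

test_that("zero-duration stimulation leaves the equilibrium undisturbed", {
  g <- grown_fixture(c(0.1, 0.9), seed = 22)
  sch <- protocol_schedule("uni", c(0.1, 0.9), c(0.1, 0), t_stim = 0,
                           t_relax = 50)
  e <- stimulate_network(g, sch, seed = 31)
  # total connectivity stays within a small band of its grown value
  grown_level <- tail(g$trace$conn_total, 1)
  rel <- abs(e$trace$conn_total - grown_level) / grown_level
  expect_lt(max(rel), 0.03)
})

test_that("runaway dynamics abort with a diagnostic condition", {
  g <- grown_fixture(c(0.1, 0.9), seed = 22)
  sch <- protocol_schedule("uni", c(0.1, 0.9), c(0.1, 0), t_stim = 10,
                           t_relax = 10)
  expect_error(
    stimulate_network(g, sch, seed = 1, rate_ceiling = 1,
                      ceiling_sustain = 2),
    class = "tdcsnet_runaway")
})

test_that("a single-schedule sweep reproduces stimulate_network", {
  g <- grown_fixture(c(0.1, 0.9), seed = 22)
  sch <- protocol_schedule("uni", c(0.1, 0.9), c(0.3, 0), t_stim = 20,
                           t_relax = 30)
  sw <- sweep_experiment(g, list(only = sch), seed = 55, fit = FALSE)
  e <- stimulate_network(g, sch, seed = 55)
  expect_equal(sw$final[1], e$final[1, 1])
  expect_equal(sw$baseline[1], e$baseline[1, 1])
  expect_identical(sw$name, "only")

  # failures at individual grid points are recorded, the sweep continues
  sw2 <- sweep_experiment(
    g, list(bad = sch, good = sch), seed = 55, fit = FALSE,
    rate_ceiling = c(1), ceiling_sustain = 1)
  expect_true(all(!is.na(sw2$error)))
})

test_that("mismatched group fractions are rejected", {
  g <- grown_fixture(c(0.1, 0.9), seed = 22)
  sch <- protocol_schedule("uni", c(0.2, 0.8), c(0.1, 0))
  expect_error(stimulate_network(g, sch), "fractions")
})
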