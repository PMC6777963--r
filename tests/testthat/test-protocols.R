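test_that("group sizes follow largest-remainder rounding", {
  expect_identical(assign_groups(1000, c(0.3, 0.3, 0.4), seed = 1)$sizes,
                   c(300L, 300L, 400L))
  expect_identical(assign_groups(10000, c(0.1, 0.9), seed = 1)$sizes,
                   c(1000L, 9000L))
  a <- assign_groups(50, 1, seed = 2)
  expect_true(all(a$membership == 1L))
  # disjoint cover with awkward fractions
  b <- assign_groups(101, c(1, 1, 1) / 3, seed = 3)
  expect_identical(sum(b$sizes), 101L)
  expect_identical(sort(unique(b$membership)), 1:3)
  expect_error(assign_groups(10, c(0.5, 0.4)), "sum to 1")
})

test_that("assignment is a uniform random partition, reproducible", {
  a1 <- assign_groups(200, c(0.25, 0.75), seed = 9)
  a2 <- assign_groups(200, c(0.25, 0.75), seed = 9)
  expect_identical(a1$membership, a2$membership)
  a3 <- assign_groups(200, c(0.25, 0.75), seed = 10)
  expect_false(identical(a1$membership, a3$membership))
})

test_that("delta_v_at returns the scheduled piecewise-constant bias", {
  asg <- assign_groups(20, c(0.1, 0.9), seed = 4)
  sch <- protocol_schedule("uni", c(0.1, 0.9), c(0.1, 0), t_grow = 750,
                           t_stim = 150, t_relax = 300)
  g1 <- asg$membership == 1
  # before the growth period ends: all zeros
  expect_true(all(delta_v_at(100, sch, asg) == 0))
  # first on-phase: G1 polarized, everyone else at zero
  v <- delta_v_at(800, sch, asg)
  expect_true(all(v[g1] == 0.1))
  expect_true(all(v[!g1] == 0))
  # relaxation and beyond: zeros
  expect_true(all(delta_v_at(1000, sch, asg) == 0))
  expect_true(all(delta_v_at(5000, sch, asg) == 0))

  alt <- protocol_schedule("repetitive_alternating", c(0.1, 0.9), c(0.1, 0),
                           t_stim = 150, t_relax = 150, n_cycles = 3)
  # second half of the first cycle: opposite polarity, same magnitude
  expect_true(all(delta_v_at(750 + 200, alt, asg)[g1] == -0.1))
  # second cycle on-phase
  expect_true(all(delta_v_at(750 + 350, alt, asg)[g1] == 0.1))
})

test_that("schedule |bias| integral matches the duty-cycle arithmetic", {
  asg_frac <- c(0.3, 0.7)
  for (mode in c("repetitive_on_off", "repetitive_alternating")) {
    for (n_c in c(1, 4)) {
      sch <- protocol_schedule(mode, asg_frac, c(0.2, 0), t_stim = 50,
                               t_relax = 30, n_cycles = n_c, t_post = 10)
      seg <- schedule_segments(sch)
      ends <- c(seg$t_start[-1], attr(seg, "duration"))
      integral <- sum((ends - seg$t_start) * abs(seg$g1))
      expected <- if (mode == "repetitive_on_off") {
        n_c * 50 * 0.2
      } else {
        n_c * (50 + 30) * 0.2
      }
      expect_equal(integral, expected)
    }
  }
})

test_that("catalogued presets reproduce the configured protocols", {
  p5 <- table4_preset("fig5_asymmetric")
  expect_equal(p5$schedule$t_stim, 75)
  expect_equal(p5$schedule$t_relax, 150)
  expect_equal(p5$schedule$n_cycles, 80)

  p6 <- table4_preset("fig6_on_off")
  expect_equal(p6$schedule$n_cycles, 3)
  expect_equal(p6$schedule$t_stim, 150)
  expect_equal(p6$schedule$t_relax, 150)
  expect_equal(p6$schedule$delta_v, c(0.1, 0))

  p4 <- table4_preset("fig4_intensity_grid")
  expect_setequal(p4$intensities, c(-1.2, -0.8, -0.4, 0.4, 0.8, 1.2))

  # total on-time of every duty-cycle combination is 6,000 s
  pd <- table4_preset("fig5_duty_grid")
  expect_true(all(pd$n_cycles * pd$t1_t2[, "t1"] == 6000))

  expect_equal(table4_preset("fig6_alternating2")$schedule$delta_v[1], 0.1)
  expect_equal(table4_preset("fig6_alternating1")$schedule$delta_v[1], 0.05)
  expect_error(table4_preset("fig7_nope"), "unknown preset")
  expect_gte(nrow(list_presets()), 9)
})

test_that("schedule validation rejects inconsistent requests", {
  expect_error(protocol_schedule("bi", c(0.5, 0.3, 0.2), c(0.1, -0.1, 0)),
               "expects 2 groups")
  expect_error(protocol_schedule("uni", c(0.1, 0.9), c(0.1, 0), n_cycles = 2),
               "single-cycle")
  expect_error(protocol_schedule("uni", c(0.2, 0.9), c(0.1, 0)), "sum to 1")
})

test_that("run configuration files rebuild the parameter objects", {
  cfg <- tempfile(fileext = ".json")
  writeLines('{
    "network": {"scale": 0.02, "r_ext": 25000},
    "neuron": {"tau_m": 10, "v_th": 20},
    "plasticity": {"nu": 2},
    "protocol": {"mode": "repetitive_on_off", "fractions": [0.2, 0.8],
                 "delta_v": [0.3, 0], "t_grow": 30, "t_stim": 10,
                 "t_relax": 5, "n_cycles": 2},
    "seed": 9
  }', cfg)
  rc <- read_run_config(cfg)
  expect_s3_class(rc$network, "network_config")
  expect_identical(rc$network$n_e, 200L)
  expect_equal(rc$network$r_ext, 25000)
  expect_equal(rc$plasticity$nu, 2)
  expect_equal(rc$schedule$n_cycles, 2)
  expect_identical(rc$seed, 9L)
  unlink(cfg)

  if (requireNamespace("yaml", quietly = TRUE)) {
    cfy <- tempfile(fileext = ".yaml")
    writeLines(c("network:", "  scale: 0.02", "protocol:",
                 "  mode: uni", "  fractions: [0.1, 0.9]",
                 "  delta_v: [0.1, 0.0]"), cfy)
    rcy <- read_run_config(cfy)
    expect_equal(rcy$schedule$mode, "uni")
    unlink(cfy)
  }
})

test_that("bi-group polarity swap relabels but does not change the schedule", {
  # swapping the two groups and flipping the sign of every bias gives the
  # same per-neuron bias function under the relabeled assignment
  asg <- assign_groups(50, c(0.3, 0.7), seed = 6)
  swapped <- asg
  swapped$membership <- 3L - asg$membership
  swapped$fractions <- rev(asg$fractions)
  swapped$sizes <- rev(asg$sizes)
  sch <- protocol_schedule("bi", c(0.3, 0.7), c(0.2, -0.2), t_grow = 100,
                           t_stim = 50, t_relax = 50)
  sch_swap <- protocol_schedule("bi", c(0.7, 0.3), c(-0.2, 0.2),
                                t_grow = 100, t_stim = 50, t_relax = 50)
  for (t in c(50, 120, 160, 220)) {
    expect_identical(delta_v_at(t, sch, asg),
                     delta_v_at(t, sch_swap, swapped))
  }
})
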