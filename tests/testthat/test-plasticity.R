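# The calcium trace, the linear growth rule, and the element bookkeeping.

test_that("calcium update matches the closed-form solution", {
  p <- plasticity_params()
  # pure decay over one time constant
  expect_equal(update_calcium(0.008, 0L, dt = 10, p), 0.008 * exp(-1))
  # one spike adds exactly beta_ca
  expect_equal(update_calcium(0, 1L, dt = 0.1, p),
               0 * exp(-0.01) + 1e-4)
  # iterated update against the closed form for an arbitrary spike count
  # sequence: C_n = sum_k beta * s_k * lambda^(n-k)
  set.seed(8)
  s <- rpois(200, 0.8)
  dt <- 0.1
  lam <- exp(-dt / p$tau_ca)
  c_loop <- 0
  for (k in seq_along(s)) c_loop <- update_calcium(c_loop, s[k], dt, p)
  c_closed <- sum(p$beta_ca * s * lam^(rev(seq_along(s)) - 1))
  expect_equal(c_loop, c_closed, tolerance = 1e-14)
})

test_that("a neuron firing at the target rate sits at the set point", {
  # 8 Hz steady firing: time-averaged calcium converges to
  # rate * beta_ca * tau_ca = 0.008 = eps
  p <- plasticity_params()
  dt <- 0.125 # exactly one spike per update at 8 Hz
  c_tr <- 0
  for (k in 1:4000) c_tr <- update_calcium(c_tr, 1L, dt, p)
  expect_equal(c_tr, p$eps, tolerance = 0.01) # within 1% of the set point
  expect_equal(target_rate(p), 8)
})

test_that("element growth follows nu * (1 - C / eps)", {
  p <- plasticity_params()
  pools <- element_pools(3)
  a <- matrix(0L, 3, 3)
  # C = eps: fixed point, no growth; C = 0: rate nu; C = 2 eps: rate -nu
  up <- update_elements(pools, c(p$eps, 0, 2 * p$eps), a, dt = 1, p)
  expect_equal(up$pools$z_pre, c(0, p$nu, 0)) # third clamped at 0
  expect_equal(up$pools$z_post, up$pools$z_pre)
  # unclamped decline visible from a positive starting level
  pools$z_pre <- pools$z_post <- rep(10, 3)
  up <- update_elements(pools, c(p$eps, 0, 2 * p$eps), a, dt = 1, p)
  expect_equal(up$pools$z_pre, c(10, 10 + p$nu, 10 - p$nu))
})

test_that("integer bookkeeping reports surpluses and deficits", {
  p <- plasticity_params()
  pools <- element_pools(2)
  pools$z_pre <- c(2.7, 1.2)
  pools$free_pre <- c(1L, 0L)
  a <- matrix(c(0L, 1L, 2L, 0L), 2, 2) # bound_pre = colSums = (1, 2)
  up <- update_elements(pools, c(p$eps, p$eps), a, dt = 1, p) # dz = 0
  # neuron 1: floor(2.7) = 2 = held(1 + 1), nothing to do
  # neuron 2: floor(1.2) = 1 < held(0 + 2): deficit 1
  d <- up$demand
  expect_identical(d$deficit[d$neuron == 2 & d$kind == "pre"], 1L)
  expect_false(any(d$neuron == 1 & d$kind == "pre"))
})

test_that("pairing combines free elements and never forms autapses", {
  pools <- element_pools(3)
  # no free elements: nothing happens
  a <- matrix(0L, 3, 3)
  out <- pair_free_elements(pools, a)
  expect_identical(out$a, a)
  expect_identical(nrow(out$new), 0L)

  # one bouton on neuron 1, one spine on neuron 2: forced pairing
  pools$free_pre <- c(1L, 0L, 0L)
  pools$free_post <- c(0L, 1L, 0L)
  set.seed(1)
  out <- pair_free_elements(pools, a)
  expect_identical(out$a[2, 1], 1L)
  expect_identical(sum(out$a), 1L)
  expect_identical(out$pools$free_pre, c(0L, 0L, 0L))

  # only a self-pair available: no synapse is forced into an autapse
  pools <- element_pools(2)
  pools$free_pre <- c(1L, 0L)
  pools$free_post <- c(1L, 0L)
  set.seed(2)
  out <- pair_free_elements(pools, matrix(0L, 2, 2))
  expect_identical(sum(out$a), 0L)
})

test_that("a hub bouton holder connects uniformly across spine holders", {
  # 10 boutons on neuron 1, one spine on each of neurons 2..11: every
  # pairing is forced through neuron 1 and all ten spines get used
  set.seed(33)
  pools <- element_pools(11)
  pools$free_pre[1] <- 10L
  pools$free_post[2:11] <- 1L
  out <- pair_free_elements(pools, matrix(0L, 11, 11))
  expect_equal(sum(out$a[, 1]), 10)
  expect_true(all(out$a[2:11, 1] == 1L))

  # with fewer boutons (5) than spine holders (10) the targets are drawn
  # uniformly: over repeats each holder is hit ~half the time
  hits <- numeric(11)
  for (r in 1:200) {
    pools <- element_pools(11)
    pools$free_pre[1] <- 5L
    pools$free_post[2:11] <- 1L
    out <- pair_free_elements(pools, matrix(0L, 11, 11))
    expect_equal(sum(out$a[, 1]), 5)
    hits <- hits + rowSums(out$a)
  }
  expect_equal(hits[1], 0)
  # binomial(200, 1/2) per holder: all within 5 sigma of 100
  expect_true(all(abs(hits[2:11] - 100) < 5 * sqrt(200 * 0.25)))
})

test_that("deletion consumes free elements before breaking synapses", {
  pools <- element_pools(2)
  pools$free_pre <- c(1L, 0L)
  a <- matrix(c(0L, 3L, 0L, 0L), 2, 2) # neuron 1 has 3 bound boutons
  deficits <- data.frame(neuron = 1L, kind = "pre", new_free = 0L,
                         deficit = 1L)
  out <- delete_elements(pools, a, deficits)
  expect_identical(out$a, a)                  # free element absorbed it
  expect_identical(out$pools$free_pre[1], 0L)

  # no free elements left: exactly one synapse breaks, the partner's spine
  # returns to its free pool
  out2 <- delete_elements(out$pools, a, deficits)
  expect_identical(out2$a[2, 1], 2L)
  expect_identical(out2$pools$free_post[2], 1L)
  expect_identical(out2$freed$neuron, 2L)
  expect_identical(out2$freed$kind, "post")
})

test_that("deletion picks uniformly among bound elements (multapse bias)", {
  # neuron 1's boutons: 3 synapses onto neuron 2, 1 onto neuron 3 -> the
  # multapse should lose the contact ~75% of the time
  set.seed(14)
  lost_multapse <- 0
  n_rep <- 400
  for (r in 1:n_rep) {
    pools <- element_pools(3)
    a <- matrix(0L, 3, 3)
    a[2, 1] <- 3L
    a[3, 1] <- 1L
    deficits <- data.frame(neuron = 1L, kind = "pre", new_free = 0L,
                           deficit = 1L)
    out <- delete_elements(pools, a, deficits)
    if (out$a[2, 1] == 2L) lost_multapse <- lost_multapse + 1
  }
  expect_lt(abs(lost_multapse / n_rep - 0.75), 5 * sqrt(0.75 * 0.25 / n_rep))
})

test_that("an unpayable deficit clamps the counter and warns", {
  pools <- element_pools(2)
  deficits <- data.frame(neuron = 1L, kind = "pre", new_free = 0L,
                         deficit = 2L)
  expect_warning(
    out <- delete_elements(pools, matrix(0L, 2, 2), deficits),
    "clamped")
  expect_true(out$clamped)
  expect_identical(out$pools$z_pre[1], 0)
})

test_that("create/delete cycles conserve elements (property)", {
  # random closed-loop churn on a small system; after every operation:
  # floor(z) == free + bound per neuron and kind, and the matrix column/row
  # sums equal the bound counts
  p <- plasticity_params()
  set.seed(77)
  n <- 8
  pools <- element_pools(n)
  a <- matrix(0L, n, n)
  for (iter in 1:120) {
    calcium <- runif(n, 0, 2 * p$eps)
    up <- update_elements(pools, calcium, a, dt = runif(1, 0.05, 0.5), p)
    pools <- up$pools
    del <- suppressWarnings(delete_elements(pools, a, up$demand))
    pools <- del$pools
    a <- del$a
    pr <- pair_free_elements(pools, a)
    pools <- pr$pools
    a <- pr$a
    expect_true(all(a >= 0))
    expect_true(all(diag(a) == 0))
    expect_true(all(pools$free_pre >= 0))
    expect_true(all(pools$free_post >= 0))
    # every integer element is accounted for: floor(z) = free + bound
    expect_equal(floor(pools$z_pre), pools$free_pre + colSums(a))
    expect_equal(floor(pools$z_post), pools$free_post + rowSums(a))
  }
  # bound boutons, bound spines and synapses are one and the same count
  expect_equal(sum(colSums(a)), sum(a))
  expect_equal(sum(rowSums(a)), sum(a))
})

test_that("sustained calcium above the set point prunes monotonically", {
  # closed loop at fixed C > eps: bound synapse count must fall
  # monotonically toward the level the counters allow
  p <- plasticity_params()
  set.seed(5)
  n <- 6
  pools <- element_pools(n)
  pools$z_pre <- pools$z_post <- rep(5, n)
  a <- matrix(0L, n, n)
  pr <- pair_free_elements(update_elements(pools, rep(0, n), a, 1e-9,
                                           p)$pools, a)
  # seed the system with synapses by letting floor(z)=5 elements pair
  pools <- pr$pools
  a <- pr$a
  totals <- sum(a)
  hot <- rep(2 * p$eps, n)
  for (k in 1:30) {
    up <- update_elements(pools, hot, a, dt = 0.5, p)
    del <- suppressWarnings(delete_elements(up$pools, a, up$demand))
    pools <- del$pools
    a <- del$a
    totals <- c(totals, sum(a))
  }
  expect_true(all(diff(totals) <= 0))
  expect_lt(tail(totals, 1), totals[1])
})
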