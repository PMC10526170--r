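test_that("ring front radius finds top-hat and shoulder fronts", {
  g <- small_grid(n_r = 64, n_theta = 16)
  r <- grid_radii(g)
  dr <- g$R / g$n_r
  cfg <- small_config(grid = g)

  # top-hat of radius r0: front within one grid cell
  r0 <- 0.043
  cp <- matrix(ifelse(r <= r0, 1e4, 0), g$n_r, 1)
  expect_lt(abs(ring_front_radius(cp, g, 0.05) - r0), dr)

  # alpha = 1 returns the location of the maximum
  cp2 <- matrix(exp(-(r - 0.0503)^2 / 1e-4), g$n_r, 1)
  expect_equal(ring_front_radius(cp2, g, alpha = 1),
               r[which.max(cp2)], tolerance = 1e-12)

  # randomized shoulder profiles vs the 10x-resampled brute-force scan
  set.seed(21)
  for (i in 1:100) {
    ctr <- runif(1, 0.02, 0.07)
    w <- runif(1, 0.005, 0.03)
    prof <- 1e4 / (1 + exp((r - ctr) / w)) + runif(1, 0, 50)
    cp3 <- matrix(prof, g$n_r, 1)
    expect_lt(abs(ring_front_radius(cp3, g, 0.05) -
                    oracle_front_radius(cp3, g, 0.05)), dr)
  }
})

test_that("invasion metrics cover ring, finger and degenerate cases", {
  g <- small_grid(n_r = 64, n_theta = 16)
  r <- grid_radii(g)
  cfg <- small_config(grid = g)
  r0 <- 0.04
  st <- field_state(cfg, Cp = ifelse(r <= r0, 1e4, 0))
  rf0 <- ring_front_radius(st$Cp, g)

  # no agents, static front: finger defaults to ring; labelled ring
  m <- compute_metrics(st, make_agents(), g, rf0)
  expect_equal(m$L_ring, 0, tolerance = 1e-12)
  expect_identical(m$L_finger, m$L_ring)
  expect_identical(m$pattern, "ring")
  expect_equal(m$area, 0, tolerance = 1e-10)

  # one agent d beyond the front: finger pattern with L_finger = d
  j_lead <- 55L
  d <- (j_lead + 0.5) * g$R / g$n_r - rf0
  m2 <- compute_metrics(st, make_agents(j = j_lead, k = 2L), g, rf0)
  expect_equal(m2$L_finger, d, tolerance = 1e-12)
  expect_equal(m2$L_ring, 0, tolerance = 1e-12)
  expect_identical(m2$pattern, "finger")
  expect_gt(m2$area, 0)

  # dead agents do not count toward the finger length
  dead <- make_agents(j = j_lead, k = 2L, alive = FALSE)
  m3 <- compute_metrics(st, dead, g, rf0)
  expect_identical(m3$L_finger, m3$L_ring)
})

test_that("metrics are invariant under rotation of the state", {
  g <- small_grid(n_r = 48, n_theta = 24, axisymmetric = FALSE)
  r <- grid_radii(g)
  cfg <- small_config(grid = g)
  set.seed(4)
  base <- 1e4 / (1 + exp((r - 0.05) / 0.01))
  cp <- matrix(base, g$n_r, g$n_theta) *
    (1 + 0.2 * outer(rep(1, g$n_r), sin(seq_len(g$n_theta))))
  ag <- make_agents(j = c(40L, 44L), k = c(3L, 7L))
  shift <- 5L
  cp_rot <- cp[, c((shift + 1):g$n_theta, 1:shift)]
  ag_rot <- ag
  ag_rot$k <- (ag$k + shift) %% g$n_theta
  st <- field_state(cfg, Cp = 0); st$Cp <- cp
  st_rot <- field_state(cfg, Cp = 0); st_rot$Cp <- cp_rot
  rf0 <- 0.04
  expect_equal(compute_metrics(st, ag, g, rf0)[, -7],
               compute_metrics(st_rot, ag_rot, g, rf0)[, -7],
               tolerance = 1e-12)
})

test_that("two-group comparison: permutation exactness and Welch path", {
  tbl <- data.frame(dose = rep(c(0, 1), each = 3), day = 3,
                    invasion_length = c(10, 11, 10.5, 10, 11, 10.5))
  res <- compare_conditions(tbl, 0, 1, 3, alternative = "two.sided")
  expect_identical(res$p.value, 1)  # identical groups

  # 10-sigma separation at n = 3: the single most extreme arrangement
  tbl2 <- data.frame(dose = rep(c(0, 1), each = 3), day = 3,
                     invasion_length = c(10, 10.5, 11, 110, 110.5, 111))
  res2 <- compare_conditions(tbl2, 0, 1, 3)
  expect_equal(res2$p.value, 1 / choose(6, 3))
  expect_match(res2$method, "permutation")
  # the reverse direction is maximally insignificant
  expect_equal(compare_conditions(tbl2, 1, 0, 3)$p.value, 1)

  # > 5 replicates switches to the Welch test
  set.seed(8)
  tbl3 <- data.frame(dose = rep(c(0, 1), each = 8), day = 1,
                     invasion_length = c(rnorm(8, 10), rnorm(8, 30)))
  res3 <- compare_conditions(tbl3, 0, 1, 1)
  expect_match(res3$method, "Welch")
  expect_lt(res3$p.value, 0.01)

  expect_error(compare_conditions(tbl[1:4, ], 0, 1, 3), "replicates")
})
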