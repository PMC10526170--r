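test_that("movement probabilities normalize and match the FTCS stencil", {
  p <- hdc_params()
  g <- small_grid(n_r = 64, n_theta = 32)
  dt <- 100
  r <- grid_radii(g)

  # 1e4 randomized (field, node) instances: valid distribution each time
  set.seed(11)
  for (i in 1:20) {
    prof <- 1e-9 * (1 + 0.5 * sin(runif(1, 0, 4) + runif(1, 1, 6) *
                                    r / g$R) * runif(1, -1, 1))
    f <- matrix(prof, g$n_r, 1)
    jj <- sample(1:(g$n_r - 2), 500, replace = TRUE)
    for (j in sample(jj, 25)) {
      pr <- compute_move_probabilities(f, g, p, at = c(j, 0), dt = dt)
      expect_lt(abs(sum(pr) - 1), 1e-12)
      expect_true(all(pr >= 0 & pr <= 1))
    }
    # bulk check through the low-level kernel for the rest
    res <- tumorHDC:::cpp_move_probs(f, jj, rep(0L, length(jj)),
                                     g$R / g$n_r, 2 * pi / g$n_theta,
                                     g$n_theta, p$d_i, p$chi_hap, dt)
    expect_true(all(abs(rowSums(res$prob) - 1) < 1e-12))
    expect_true(all(res$prob >= 0))
    # raw coefficients agree with the hand-derived stencil oracle
    j_chk <- jj[1:5]
    for (j in j_chk) {
      pr <- compute_move_probabilities(f, g, p, at = c(j, 0), dt = dt)
      expect_equal(unname(attr(pr, "raw")),
                   unname(oracle_raw_probs(prof, j, g, p, dt)),
                   tolerance = 1e-12)
    }
  }
})

test_that("uniform collagen gives an unbiased stencil with known P1", {
  p <- hdc_params()
  # the metric drift decays as dr/2r, so 'large r' means r >> dr: use a
  # very deep radial grid and a node near its rim
  g <- small_grid(R = 1, n_r = 2^21, n_theta = 64)
  f <- matrix(1e-9, g$n_r, 1)
  dt <- 1e-4
  pr <- compute_move_probabilities(f, g, p, at = c(g$n_r - 10, 0),
                                   dt = dt)
  raw <- attr(pr, "raw")
  expect_lt(abs(pr["P1"] - pr["P2"]), 1e-6)
  expect_equal(unname(raw["P1"]), p$d_i * dt / (g$R / g$n_r)^2,
               tolerance = 1e-6)
  # chi_hap = 0: probabilities are independent of the collagen field
  g2 <- small_grid(R = 1, n_r = 512, n_theta = 64)
  p0 <- hdc_params(chi_hap = 0)
  fa <- matrix(1e-9, g2$n_r, 1)
  fb <- matrix(1e-9 * seq(0.5, 1.5, length.out = g2$n_r), g2$n_r, 1)
  pr_a <- compute_move_probabilities(fa, g2, p0, at = c(100, 0), dt = 1000)
  pr_b <- compute_move_probabilities(fb, g2, p0, at = c(100, 0), dt = 1000)
  expect_identical(as.numeric(pr_a), as.numeric(pr_b))
})

test_that("an outward collagen gradient biases the walk outward", {
  p <- hdc_params()  # chi_hap = 2.6e3 from the parameter table
  g <- small_grid(n_r = 64, n_theta = 32)
  r <- grid_radii(g)
  f <- matrix(1e-9 * (0.5 + r / g$R), g$n_r, 1)
  pr <- compute_move_probabilities(f, g, p, at = c(32, 0), dt = 5000)
  expect_gt(pr["P1"], pr["P2"])
})

test_that("the polar stencil converges to Cartesian FTCS at large r", {
  p <- hdc_params()
  g <- small_grid(R = 1, n_r = 1024, n_theta = 64)
  f <- matrix(1e-9, g$n_r, 1)
  dt <- 1000
  cart <- p$d_i * dt / (g$R / g$n_r)^2
  dev <- vapply(c(32, 128, 1000), function(j) {
    raw <- attr(compute_move_probabilities(f, g, p, c(j, 0), dt = dt),
                "raw")
    max(abs(raw[c("P1", "P2")] - cart))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-3 * cart)
})

test_that("agent stepping is seeded, bounded and reflective", {
  p <- hdc_params()
  g <- small_grid(n_r = 32, n_theta = 16)
  f <- matrix(1e-9, g$n_r, 1)
  ag <- make_agents(j = c(5L, 10L), k = c(0L, 3L))
  a1 <- step_agents(ag, f, g, p, dt = 5000, n_steps = 200, seed = 99)
  a2 <- step_agents(ag, f, g, p, dt = 5000, n_steps = 200, seed = 99)
  expect_identical(a1, a2)  # bit-reproducible under a fixed seed
  expect_true(all(a1$j >= 0 & a1$j <= g$n_r - 1))

  # D -> 0 freezes the walk entirely (all mass on P0)
  p0 <- hdc_params(d_i = 1e-300, chi_hap = 0)
  a3 <- step_agents(ag, f, g, p0, dt = 5000, n_steps = 50, seed = 1)
  expect_identical(a3$j, ag$j)
  expect_identical(a3$k, ag$k)
  expect_equal(a3$age, rep(5000 * 50, 2))

  # agents reaching the outer node are absorbed and flagged dead
  ag_edge <- make_agents(j = rep(g$n_r - 2L, 50), k = 0:49 %% g$n_theta)
  a4 <- step_agents(ag_edge, f, g, p, dt = 5e4, n_steps = 50, seed = 7)
  expect_true(any(!a4$alive))
  expect_true(all(a4$j[!a4$alive] == g$n_r - 1))
})

test_that("the unbiased walk reproduces its diffusion limit", {
  p <- hdc_params(d_n = 1e-12, d_m = 1e-12, chi_hap = 0)
  g <- hdc_grid(R = 0.1, n_r = 128, n_theta = 64)
  f <- matrix(1e-9, g$n_r, 1)
  n_ag <- 3000
  ag <- make_agents(j = rep(63L, n_ag), k = rep(0L, n_ag))
  xy0 <- agent_xy(ag, g)[1, ]
  a <- step_agents(ag, f, g, p, dt = 13, n_steps = 250, seed = 5)
  expect_true(all(a$alive))
  xy <- agent_xy(a, g)
  msd <- mean((xy[, 1] - xy0[1])^2 + (xy[, 2] - xy0[2])^2)
  expect_gt(msd / (4 * p$d_i * 250 * 13), 0.9)
  expect_lt(msd / (4 * p$d_i * 250 * 13), 1.1)
})

test_that("haptotactic drift grows with the haptotaxis coefficient", {
  g <- small_grid(R = 0.2, n_r = 128, n_theta = 32)
  r <- grid_radii(g)
  f <- matrix(1e-9 * (0.5 + r / g$R), g$n_r, 1)  # fixed outward gradient
  drift <- vapply(c(0, 1.3e3, 2.6e3), function(chi) {
    p <- hdc_params(d_n = 1e-12, d_m = 1e-12, chi_hap = chi)
    ag <- make_agents(j = rep(40L, 2000), k = rep(0L, 2000))
    a <- step_agents(ag, f, g, p, dt = 60, n_steps = 150, seed = 31)
    mean(agent_radius(a, g)) - (40.5) * g$R / g$n_r
  }, numeric(1))
  expect_true(all(diff(drift) > 0))
})

test_that("shedding respects density, gradients and forcing", {
  p <- hdc_params()
  g <- small_grid(n_r = 32, n_theta = 16)
  cfg <- small_config(params = p, grid = g)
  hy <- hdc_hybrid(shed_rate = 1)

  # no cells anywhere: front undefined, nothing spawns
  st0 <- field_state(cfg, Cp = 0)
  expect_error(ring_front_radius(st0$Cp, g), "all-zero")
  ag <- make_agents()
  expect_identical(nrow(shed_agents(st0, ag, g, p, hy, 1e-9, seed = 1)),
                   0L)

  # forced probability on a sharp front: one agent per angular sector
  r <- grid_radii(g)
  st1 <- field_state(cfg, Cp = ifelse(r < 0.05, 1e4, 0), f = 1e-9)
  hy_force <- hdc_hybrid(shed_rate = 1e9, shed_base = 1)
  out <- shed_agents(st1, ag, g, p, hy_force, 1e-9, seed = 2)
  expect_identical(nrow(out), g$n_theta)
  expect_true(all(out$j == max(which(r < 0.05)) - 1))

  # doubling |grad f| doubles the expected spawn count (binomial means)
  grad_counts <- vapply(c(1, 2), function(s) {
    f <- 1e-9 * (1 + s * 0.05 * r / g$R)
    st <- field_state(cfg, Cp = ifelse(r < 0.05, 1e4, 0), f = f)
    st$f <- matrix(f, g$n_r, 1)
    hy2 <- hdc_hybrid(shed_rate = 2)
    set.seed(123)
    total <- 0
    for (i in 1:2500) {
      total <- total + nrow(shed_agents(st, ag, g, p, hy2, 1e-9))
    }
    total
  }, numeric(1))
  expect_gt(grad_counts[2] / grad_counts[1], 1.9)
  expect_lt(grad_counts[2] / grad_counts[1], 2.1)
})
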