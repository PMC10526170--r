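test_that("cell fluxes vanish for uniform fields and follow gradients", {
  p <- hdc_params(chi_chem = 1e-7)
  cfg <- small_config(params = p)
  st <- field_state(cfg, Cp = 5e3, n = 4.5)
  fl <- compute_cell_fluxes(st, p, cfg$grid)
  expect_true(all(fl$J_f$r == 0) && all(fl$J_d$r == 0))

  # chemotaxis off => J_d = 0 regardless of the nutrient gradient
  r <- grid_radii(cfg$grid)
  st$n[] <- 4.5 * r / max(r)
  p0 <- hdc_params(chi_chem = 0)
  expect_true(all(compute_cell_fluxes(st, p0, cfg$grid)$J_d$r == 0))

  # radially linear Cp: |J_f| = D * slope, against a one-sided oracle
  slope <- 1e4 / cfg$grid$R
  st$Cp[] <- slope * r
  jf <- compute_cell_fluxes(st, p, cfg$grid)$J_f$r
  oracle <- -p$d_i * diff(slope * r) / diff(r)[1]
  expect_equal(jf[2:(length(r) - 1)], rep(oracle[1], length(r) - 2),
               tolerance = 1e-10)
})

test_that("nutrient stays at equilibrium and floors at zero", {
  p <- inert_params()
  cfg <- small_config(params = p)
  st <- field_state(cfg, Cp = 0, n = 4.5)
  st2 <- step_nutrient(st, p, hdc_boundary(n0 = 4.5), cfg$grid,
                       n_steps = 50)
  expect_equal(st2$n, st$n, tolerance = 1e-14)

  # consumption at n = 0 must not create negative nutrient
  p2 <- hdc_params(lambda_max = 1)
  st$n[] <- 0
  st$Cp[] <- 1e4
  st3 <- step_nutrient(st, p2, hdc_boundary(n0 = 4.5), cfg$grid,
                       n_steps = 10)
  expect_true(all(st3$n >= 0))
})

test_that("axisymmetric diffusion matches the heat kernel and converges", {
  p <- inert_params(d_m = 4.2e-6)
  errs <- vapply(c(32, 64), function(nr) {
    g <- hdc_grid(R = 0.3, n_r = nr)
    cfg <- hdc_config(params = p, grid = g)
    r <- grid_radii(g)
    D <- p$d_m
    t0 <- 0.3^2 / (64 * D)
    st <- field_state(cfg, Cp = 0, M = exp(-r^2 / (4 * D * t0)))
    dt <- stability_dt(g, p)
    nst <- ceiling(0.25 * t0 / dt)
    st2 <- step_collagenase(st, p, hdc_boundary(m0 = 0), g, dt = dt,
                            n_steps = nst)
    exact <- (t0 / (t0 + nst * dt)) * exp(-r^2 / (4 * D * (t0 + nst * dt)))
    sqrt(sum((st2$M - exact)^2 * r) / sum(exact^2 * r))
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  expect_lt(errs[2], errs[1])  # refinement reduces the error
})

test_that("collagenase diffuses in from the boundary and not otherwise", {
  p <- inert_params()
  cfg <- small_config(params = p)
  # f = 0 and M at the boundary value everywhere: nothing changes
  st <- field_state(cfg, M = 2e-7, f = 0)
  st2 <- step_collagenase(st, p, hdc_boundary(m0 = 2e-7), cfg$grid,
                          n_steps = 25)
  expect_equal(st2$M, st$M, tolerance = 1e-13)
  # supplied enzyme diffuses inward monotonically when unbound
  st <- field_state(cfg, M = 0)
  prev <- st
  for (i in 1:3) {
    nxt <- step_collagenase(prev, p, hdc_boundary(m0 = 2e-7), cfg$grid,
                            n_steps = 400)
    expect_true(all(nxt$M >= prev$M - 1e-20))
    prev <- nxt
  }
  expect_gt(min(prev$M), 0)
  # no boundary supply, no initial enzyme: identically zero
  st3 <- step_collagenase(field_state(cfg, M = 0), p,
                          hdc_boundary(m0 = 0), cfg$grid, n_steps = 200)
  expect_true(all(st3$M == 0))
})

test_that("collagen follows its exact exponential solution", {
  p <- hdc_params()
  cfg <- small_config()
  st <- field_state(cfg, M = 3e-7)
  k <- 40; dt <- 25
  st2 <- step_collagen(st, p, cfg$grid, dt = dt, n_steps = k)
  expect_equal(st2$f, st$f * exp(-p$delta * 3e-7 * k * dt),
               tolerance = 1e-12)
  expect_true(all(st2$f > 0) && all(st2$f < 1e-9))
  # M = 0 leaves collagen untouched
  st3 <- step_collagen(field_state(cfg, M = 0), p, cfg$grid, n_steps = 5)
  expect_identical(st3$f, st$f)
})

test_that("zero-flux cell transport conserves mass over 1000 steps", {
  p <- inert_params()
  cfg <- small_config(params = p,
                      boundary = hdc_boundary(cell_bc = "zero_flux"))
  st <- init_state(cfg)
  m0 <- cell_mass(st, cfg$grid)
  st2 <- step_cells(st, p, cfg$boundary, cfg$grid, n_steps = 1000)
  expect_lt(abs(cell_mass(st2, cfg$grid) - m0) / m0, 1e-3)
})

test_that("proliferation follows the gated Monod rate", {
  # uniform cells below packing stress, plenty of nutrient, no gradients:
  # exponential growth at eta_max * n/(n_half + n)
  p <- hdc_params(lambda_max = 0)
  cfg <- small_config(params = p,
                      boundary = hdc_boundary(cell_bc = "zero_flux"))
  st <- field_state(cfg, Cp = 100, n = 4.5, f = 1e-9)
  dt <- stability_dt(cfg$grid, p)
  nst <- 500
  st2 <- step_cells(st, p, cfg$boundary, cfg$grid, dt = dt, n_steps = nst)
  eta <- p$eta_max * 4.5 / (p$n_half + 4.5)
  expect_equal(mean(st2$Cp) / 100, exp(eta * nst * dt), tolerance = 0.01)
  # no nutrient, no growth
  st$n[] <- 0
  st3 <- step_cells(st, p, cfg$boundary, cfg$grid, dt = dt, n_steps = 100)
  expect_equal(st3$Cp, st$Cp, tolerance = 1e-13)
  # above the critical packing stress, growth is gated off
  st$n[] <- 4.5
  st$Cp[] <- p$cp_packing * p$p_cr / p$p_max * 1.01
  st4 <- step_cells(st, p, cfg$boundary, cfg$grid, dt = dt, n_steps = 100)
  expect_equal(st4$Cp, st$Cp, tolerance = 1e-13)
})

test_that("run_continuum is inert for zero rates and tracks enzyme dose", {
  p <- inert_params(d_i = 1e-12, d_n = 1e-12, d_m = 1e-12)
  g <- small_grid(t_end = 1000)
  cfg <- small_config(params = p, grid = g)
  st <- init_state(cfg)
  snaps <- run_continuum(p, hdc_boundary(c_bc = 0, cell_bc = "zero_flux"),
                         cfg$initial, g, n_snapshots = 3)
  # diffusivities cannot be exactly zero (validated > 0), so "inert"
  # means unchanged up to the residual 1e-12 cm^2/s transport
  expect_equal(snaps[[4]]$Cp, st$Cp, tolerance = 1e-3)
  expect_equal(snaps[[4]]$f, st$f, tolerance = 1e-12)

  # higher boundary enzyme => strictly lower minimum collagen at t_end
  p2 <- hdc_params()
  g2 <- small_grid(t_end = 6 * 3600)
  fmin <- vapply(c(0, 0.001, 0.01), function(dose) {
    bc <- hdc_boundary(m0 = dose_to_molar(dose))
    out <- run_continuum(p2, bc, hdc_initial(r_tumoroid = 0.02), g2,
                         n_snapshots = 2)
    min(out[[3]]$f)
  }, numeric(1))
  expect_true(all(diff(fmin) < 0))
})

test_that("the 2-D solver reproduces axisymmetric solutions", {
  p <- hdc_params()
  dt2 <- stability_dt(small_grid(n_r = 24, n_theta = 12,
                                 axisymmetric = FALSE), p)
  g1 <- small_grid(n_r = 24, n_theta = 12, t_end = 500 * dt2, dt = dt2,
                   axisymmetric = TRUE)
  g2 <- small_grid(n_r = 24, n_theta = 12, t_end = 500 * dt2, dt = dt2,
                   axisymmetric = FALSE)
  ic <- hdc_initial(r_tumoroid = 0.02)
  bc <- hdc_boundary(m0 = 2e-7)
  s1 <- run_continuum(p, bc, ic, g1, n_snapshots = 2)
  s2 <- run_continuum(p, bc, ic, g2, n_snapshots = 2)
  expect_identical(s1[[3]]$t, s2[[3]]$t)
  for (f in c("Cp", "n", "M", "f")) {
    spread <- apply(s2[[3]][[f]], 1, function(x) diff(range(x)))
    expect_lt(max(spread), 1e-12)  # the 2-D run stays axisymmetric
    expect_lt(max(abs(rowMeans(s2[[3]][[f]]) - s1[[3]][[f]][, 1]) /
                    (abs(s1[[3]][[f]][, 1]) + 1e-30)), 1e-8)
  }
})

test_that("non-finite states are rejected with a field diagnostic", {
  cfg <- small_config()
  st <- init_state(cfg)
  st$n[3] <- NaN
  expect_error(step_nutrient(st, cfg$params, cfg$boundary, cfg$grid),
               "'n'")
})
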