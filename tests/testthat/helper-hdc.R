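# Shared fixture builders. Everything is generated in code; tests use
# small grids and short horizons unless the check itself needs scale.

# parameters with inert reactions, for transport-only checks
inert_params <- function(...) {
  hdc_params(eta_max = 0, lambda_max = 0, zeta = 0, chi_hap = 0,
             chi_chem = 0, ...)
}

small_grid <- function(R = 0.1, n_r = 32, n_theta = 16, t_end = 3600,
                       axisymmetric = TRUE, ...) {
  hdc_grid(R = R, n_r = n_r, n_theta = n_theta, t_end = t_end,
           axisymmetric = axisymmetric, ...)
}

small_config <- function(params = hdc_params(), grid = small_grid(),
                         r_tumoroid = 0.02, ...) {
  hdc_config(params = params, grid = grid,
             initial = hdc_initial(r_tumoroid = r_tumoroid), ...)
}

# a state with chosen field values on the grid of `config`
field_state <- function(config, Cp = NULL, n = NULL, M = NULL, f = NULL) {
  st <- init_state(config)
  if (!is.null(Cp)) st$Cp[] <- Cp
  if (!is.null(n)) st$n[] <- n
  if (!is.null(M)) st$M[] <- M
  if (!is.null(f)) st$f[] <- f
  st
}

# independent hand-derived FTCS stencil for the walk probabilities on an
# axisymmetric collagen profile (one-sided oracle, kept deliberately
# separate from the package implementation)
oracle_raw_probs <- function(f_prof, j, grid, params, dt) {
  dr <- grid$R / grid$n_r
  r <- (j + 0.5) * dr
  D <- params$d_i
  chi <- params$chi_hap
  jp <- min(j + 1, grid$n_r - 1) + 1L  # 1-based with clamping
  jm <- max(j - 1, 0) + 1L
  fr <- (f_prof[jp] - f_prof[jm]) / (2 * dr)
  lapf <- (f_prof[jp] - 2 * f_prof[j + 1] + f_prof[jm]) / dr^2 +
    (f_prof[jp] - f_prof[jm]) / (2 * r * dr)
  dth <- 2 * pi / grid$n_theta
  a_th <- D / (r^2 * dth^2)
  p <- c(NA,
         dt * (D / dr^2 + D / (2 * r * dr) + chi * fr / (2 * dr)),
         dt * (D / dr^2 - D / (2 * r * dr) - chi * fr / (2 * dr)),
         dt * a_th, dt * a_th)
  p[1] <- 1 - sum(pmax(p[-1], 0)) - chi * dt * lapf
  pmax(p, 0)
}

# brute-force front finder: threshold scan on a 10x linearly resampled
# angular-mean profile
oracle_front_radius <- function(Cp_field, grid, alpha) {
  prof <- rowMeans(as.matrix(Cp_field))
  r <- grid_radii(grid)
  rf <- seq(r[1], r[length(r)], length.out = 10 * length(r))
  pf <- approx(r, prof, xout = rf)$y
  thr <- alpha * max(pf)
  max(rf[pf >= thr])
}

# polar lattice positions to cartesian, for walk statistics
agent_xy <- function(agents, grid) {
  r <- agent_radius(agents, grid)
  th <- (agents$k + 0.5) * 2 * pi / grid$n_theta
  cbind(x = r * cos(th), y = r * sin(th))
}
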