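# Continuum solver surface: state construction, per-field explicit steps
# and the full reaction-diffusion march. The arithmetic lives in
# src/hdc.cpp; these wrappers validate, keep units straight and document
# the scheme.

par_vec <- function(p) {
  unlist(p[c("d_i", "d_n", "d_m", "chi_hap", "chi_chem", "zeta", "delta",
             "eta_max", "n_half", "lambda_max", "p_cr", "p_max", "c0",
             "cp_packing")])
}

#' Radial node positions of a grid
#'
#' @param grid [hdc_grid()]
#' @return cell-centre radii `(j + 1/2) * dr`, in cm
#' @export
grid_radii <- function(grid) {
  dr <- grid$R / grid$n_r
  (seq_len(grid$n_r) - 0.5) * dr
}

grid_ncol <- function(grid) if (grid$axisymmetric) 1L else grid$n_theta

grid_dtheta <- function(grid) 2 * pi / grid$n_theta

#' Initialize the four continuum fields
#'
#' Cells form a disc of radius `r_tumoroid` with a tanh edge one grid
#' cell wide; nutrient and collagen are uniform; collagenase starts at 0.
#'
#' @param config [hdc_config()] (or pass `params`/`boundary`/... parts of
#'   one)
#' @return an object of class `continuum_state`: matrices `Cp`, `n`, `M`,
#'   `f` (`n_r` rows by 1 or `n_theta` columns) and the current time `t`
#'   in seconds
#' @export
init_state <- function(config) {
  g <- config$grid
  ic <- config$initial
  r <- grid_radii(g)
  dr <- g$R / g$n_r
  nc <- grid_ncol(g)
  edge <- 0.5 * (1 - tanh((r - ic$r_tumoroid) / dr))
  mk <- function(v) matrix(v, nrow = g$n_r, ncol = nc)
  structure(list(Cp = mk(ic$c_i * edge), n = mk(ic$n_i),
                 M = mk(0), f = mk(ic$f0), t = 0),
            class = "continuum_state")
}

state_check <- function(state) {
  for (nm in c("Cp", "n", "M", "f"))
    if (!all(is.finite(state[[nm]])))
      stop("non-finite values in field '", nm, "'", call. = FALSE)
  invisible(state)
}

step_fields <- function(state, params, bc, grid, dt, n_steps,
                        which = c("Cp", "n", "M", "f")) {
  state_check(state)
  dr <- grid$R / grid$n_r
  res <- cpp_continuum_steps(
    state$Cp, state$n, state$M, state$f, par_vec(params),
    bc$c_bc, bc$n0, bc$m0, if (bc$cell_bc == "zero_flux") 1L else 0L,
    dr, grid_dtheta(grid), dt, as.integer(n_steps),
    "Cp" %in% which, "n" %in% which, "M" %in% which, "f" %in% which)
  state$Cp <- res$Cp; state$n <- res$n; state$M <- res$M; state$f <- res$f
  state$t <- state$t + n_steps * dt
  state
}

resolve_dt <- function(grid, params) {
  dt <- grid$dt
  if (is.null(dt)) dt <- stability_dt(grid, params)
  bound <- stability_dt(grid, params) / grid$safety * 0.9
  if (dt > bound * (1 + 1e-12))
    stop(sprintf("dt = %.6g violates the stability bound %.6g", dt, bound),
         call. = FALSE)
  dt
}

#' Diffusive and tactic cell fluxes of the current state
#'
#' Diagnostic central-difference evaluation of the two flux components of
#' the cell equation: the random-motility (Fickian) flux
#' `J_f = -d_i * grad(Cp)` and the chemotactic flux
#' `J_d = chi_chem * Cp * grad(n)`; both are vector fields with radial
#' and angular physical components on the grid nodes. (The stepper itself
#' uses face-centred fluxes internally; this node-centred version is the
#' one to inspect and test.)
#'
#' @param state [init_state()]
#' @param params [hdc_params()]
#' @param grid [hdc_grid()]
#' @return list with elements `J_f` and `J_d`, each `list(r = , theta = )`
#' @export
compute_cell_fluxes <- function(state, params, grid) {
  state_check(state)
  dr <- grid$R / grid$n_r
  r <- grid_radii(grid)
  grad_r <- function(u) {
    n <- nrow(u)
    g <- u
    if (n >= 3) g[2:(n - 1), ] <- (u[3:n, , drop = FALSE] -
                                     u[1:(n - 2), , drop = FALSE]) / (2 * dr)
    g[1, ] <- (u[2, ] - u[1, ]) / dr
    g[n, ] <- (u[n, ] - u[n - 1, ]) / dr
    g
  }
  grad_th <- function(u) {
    if (ncol(u) == 1) return(u * 0)
    nt <- ncol(u)
    dth <- grid_dtheta(grid)
    (u[, c(2:nt, 1), drop = FALSE] - u[, c(nt, 1:(nt - 1)), drop = FALSE]) /
      (2 * dth) / r
  }
  list(J_f = list(r = -params$d_i * grad_r(state$Cp),
                  theta = -params$d_i * grad_th(state$Cp)),
       J_d = list(r = params$chi_chem * state$Cp * grad_r(state$n),
                  theta = params$chi_chem * state$Cp * grad_th(state$n)))
}

#' Advance the nutrient field
#'
#' Explicit diffusion with Dirichlet `n0` at the outer boundary minus
#' Monod consumption `(Cp/c0) * lambda_max * n^2/(n_half + n)`, floored
#' at zero.
#'
#' @param state [init_state()]
#' @param params [hdc_params()]
#' @param bc [hdc_boundary()]
#' @param grid [hdc_grid()]
#' @param dt time step (s); `NULL` uses the stability bound
#' @param n_steps number of steps to take
#' @return the state with `n` (and `t`) updated; other fields untouched
#' @export
step_nutrient <- function(state, params, bc, grid, dt = NULL, n_steps = 1) {
  if (is.null(dt)) dt <- resolve_dt(grid, params) else
    resolve_dt(modifyList(grid, list(dt = dt)), params)
  step_fields(state, params, bc, grid, dt, n_steps, which = "n")
}

#' Advance the collagenase field
#'
#' Explicit diffusion with Dirichlet `m0` at the outer boundary (the
#' channel-supplied enzyme) minus the binding loss `zeta * M * f`,
#' floored at zero.
#'
#' @inheritParams step_nutrient
#' @return the state with `M` updated
#' @export
step_collagenase <- function(state, params, bc, grid, dt = NULL,
                             n_steps = 1) {
  if (is.null(dt)) dt <- resolve_dt(grid, params) else
    resolve_dt(modifyList(grid, list(dt = dt)), params)
  step_fields(state, params, bc, grid, dt, n_steps, which = "M")
}

#' Advance the collagen field
#'
#' The collagen equation `df/dt = -delta * M * f` has no spatial
#' operator; each node is integrated exactly as
#' `f <- f * exp(-delta * M * dt)` with the collagenase frozen over the
#' step.
#'
#' @inheritParams step_nutrient
#' @return the state with `f` updated
#' @export
step_collagen <- function(state, params, grid, dt = NULL, n_steps = 1) {
  if (is.null(dt)) dt <- resolve_dt(grid, params)
  step_fields(state, params, hdc_boundary(), grid, dt, n_steps,
              which = "f")
}

#' Advance the cell field
#'
#' Finite-volume divergence of the diffusive, haptotactic and chemotactic
#' fluxes, i.e. `dCp/dt = div(d_i grad Cp - chi_hap Cp grad f -
#' chi_chem Cp grad n) + Cp * eta`, with per-capita growth
#' `eta = eta_max * n/(n_half+n)` shut off where the packing-stress proxy
#' `p_max * Cp/cp_packing` reaches `p_cr`. The polar divergence uses the
#' conservative `(1/r) d(r J_r)/dr` form on cell faces; the inner face
#' sits exactly at r = 0 with zero area, so no special origin treatment
#' is needed and a zero-flux run conserves mass to rounding.
#'
#' @inheritParams step_nutrient
#' @param fluxes ignored (accepted for call-site symmetry with
#'   [compute_cell_fluxes()]; the stepper evaluates face fluxes
#'   internally from the same state)
#' @return the state with `Cp` updated
#' @export
step_cells <- function(state, params, bc, grid, dt = NULL, n_steps = 1,
                       fluxes = NULL) {
  if (is.null(dt)) dt <- resolve_dt(grid, params) else
    resolve_dt(modifyList(grid, list(dt = dt)), params)
  step_fields(state, params, bc, grid, dt, n_steps, which = "Cp")
}

#' Total cell mass on the grid
#'
#' @param state [init_state()]
#' @param grid [hdc_grid()]
#' @return the discrete integral of `Cp * r dr dtheta` over the domain
#' @export
cell_mass <- function(state, grid) {
  dr <- grid$R / grid$n_r
  dth <- if (grid$axisymmetric) 2 * pi else grid_dtheta(grid)
  sum(state$Cp * grid_radii(grid)) * dr * dth
}

#' Run the continuum reaction-diffusion system
#'
#' Time-marches all four fields from the initial condition to
#' `grid$t_end` with the explicit scheme, returning evenly spaced
#' snapshots. The continuum part has no randomness, so results are
#' deterministic.
#'
#' @param params [hdc_params()]
#' @param bc [hdc_boundary()]
#' @param ic [hdc_initial()]
#' @param grid [hdc_grid()]
#' @param n_snapshots number of snapshots after t = 0
#' @return list of `continuum_state` objects of length `n_snapshots + 1`
#'   (the initial state first); any non-finite node aborts with a
#'   diagnostic naming the field
#' @export
run_continuum <- function(params, bc, ic, grid, n_snapshots = 12) {
  cfg <- hdc_config(params = params, boundary = bc, initial = ic,
                    grid = grid)
  dt0 <- resolve_dt(grid, params)
  state <- init_state(cfg)
  # shrink dt (never grow it) so the march lands exactly on t_end with
  # an integer number of steps per snapshot
  per <- max(1L, ceiling(grid$t_end / dt0 / n_snapshots))
  dt <- grid$t_end / (per * n_snapshots)
  out <- vector("list", n_snapshots + 1)
  out[[1]] <- state
  for (s in seq_len(n_snapshots)) {
    state <- step_fields(state, params, bc, grid, dt, per)
    out[[s + 1]] <- state
  }
  out
}
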