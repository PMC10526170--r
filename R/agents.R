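# Discrete single-cell model: movement probabilities from the
# finite-difference stencil of the cell-flux equation, the seeded walk,
# and shedding of invading cells from the continuum ring front.

#' Create an (empty or explicit) agent table
#'
#' Agents live on the polar lattice: radial index `j` (0-based, matching
#' the continuum node radii `(j+1/2)*dr`), angular index `k` on the
#' agent lattice of `n_theta` sectors, age since shedding in seconds and
#' a viability flag (`FALSE` once absorbed at the outer boundary).
#'
#' @param j,k integer node indices (0-based)
#' @param age seconds since shedding
#' @param alive viability flags
#' @return a `data.frame` with columns `id`, `j`, `k`, `age`, `alive`
#' @export
make_agents <- function(j = integer(), k = integer(),
                        age = numeric(length(j)),
                        alive = rep(TRUE, length(j))) {
  stopifnot(length(k) == length(j))
  data.frame(id = seq_along(j), j = as.integer(j), k = as.integer(k),
             age = as.numeric(age), alive = as.logical(alive))
}

#' Movement probabilities of a cell at a lattice node
#'
#' Central-difference discretization of
#' `dC/dt = d_i lap(C) - chi_hap div(C grad f)` in polar coordinates
#' turns the update for the cell concentration at node (j, k) into a
#' five-point stencil; its coefficients, clipped at zero and normalized,
#' are the probabilities of the cell staying (`P0`), moving outward /
#' inward radially (`P1`, `P2`) or counterclockwise / clockwise
#' (`P3`, `P4`). The haptotaxis contribution is signed so the walk drifts
#' with the PDE's advection velocity `+chi_hap grad f`, i.e. up the
#' collagen gradient; the angular terms carry the local `1/r^2` metric so
#' the walk's diffusion limit is isotropic in physical space.
#'
#' @param f_field collagen matrix (`n_r` x 1 or `n_r` x `n_theta`)
#' @param grid [hdc_grid()]
#' @param params [hdc_params()] (uses `d_i`, `chi_hap`)
#' @param at integer vector `c(j, k)`, 0-based interior node
#'   (`1 <= j <= n_r - 2`)
#' @param dt walk time step (s); defaults to `agent_stride` continuum
#'   stability steps
#' @param stride continuum steps per walk step used for the default `dt`
#' @return an object of class `move_probabilities`: numeric `P0..P4`
#'   summing to exactly 1, with the un-normalized stencil coefficients in
#'   `attr(, "raw")`
#' @export
compute_move_probabilities <- function(f_field, grid, params, at,
                                       dt = NULL, stride = 100) {
  j <- as.integer(at[1]); k <- as.integer(at[2])
  if (j < 1 || j > grid$n_r - 2)
    stop("node j = ", j, " is not interior (1 <= j <= n_r - 2)",
         call. = FALSE)
  if (!all(is.finite(f_field)))
    stop("non-finite values in collagen field", call. = FALSE)
  if (is.null(dt)) dt <- stride * stability_dt(grid, params)
  dr <- grid$R / grid$n_r
  res <- cpp_move_probs(as.matrix(f_field), j, k, dr, grid_dtheta(grid),
                        grid$n_theta, params$d_i, params$chi_hap, dt)
  p <- drop(res$prob)
  p <- p / sum(p)  # exact renormalization after rounding
  names(p) <- c("P0", "P1", "P2", "P3", "P4")
  raw <- drop(res$raw)
  names(raw) <- names(p)
  structure(p, raw = raw, class = "move_probabilities")
}

#' Step the discrete cells
#'
#' Each live agent draws one move from its local five-way distribution.
#' The walk reflects at the origin and is absorbing at the outer boundary
#' (agents reaching the last radial node are marked not alive). With a
#' seeded stream the trajectory set is bit-reproducible.
#'
#' @param agents [make_agents()]
#' @param f_field collagen matrix the probabilities are read from
#' @param grid [hdc_grid()]
#' @param params [hdc_params()]
#' @param dt walk time step (s)
#' @param n_steps number of walk steps
#' @param seed optional integer; if given, `set.seed(seed)` is called
#'   first so the call is self-contained
#' @return the updated agent table
#' @export
step_agents <- function(agents, f_field, grid, params, dt, n_steps = 1,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(agents) == 0) return(agents)
  dr <- grid$R / grid$n_r
  res <- cpp_agent_walk(agents$j, agents$k, as.integer(agents$alive),
                        agents$age, as.matrix(f_field), dr,
                        grid_dtheta(grid), grid$n_theta, grid$n_r,
                        params$d_i, params$chi_hap, dt,
                        as.integer(n_steps))
  agents$j <- res$j; agents$k <- res$k
  agents$alive <- as.logical(res$alive); agents$age <- res$age
  agents
}

#' Shed invading cells from the continuum ring front
#'
#' At a coupling event, every node of the invasive front region — from
#' the ring front (outermost radius where the angular-mean cell density
#' reaches `front_alpha` of its maximum) outward through the leading
#' cell tail — spawns one agent with probability
#' `shed_rate * (Cp/c0) * (shed_base + |df/dr|/f0 * R)`, capped at 1.
#' The `Cp * |grad f|` product concentrates spawning where the leading
#' edge overlaps the enzyme's degradation zone. The spawned agents are
#' markers of invading cells; no mass is removed from the continuum. If
#' no front is found the call is a no-op.
#'
#' @param state [init_state()]
#' @param agents [make_agents()]
#' @param grid [hdc_grid()]
#' @param params [hdc_params()] (for `c0`)
#' @param hybrid [hdc_hybrid()] shedding settings
#' @param f0 collagen scale used to normalize the gradient (M)
#' @param seed optional integer seed
#' @return the agent table with any new agents appended (age 0)
#' @export
shed_agents <- function(state, agents, grid, params, hybrid, f0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dr <- grid$R / grid$n_r
  res <- cpp_shed_event(state$Cp, state$f, dr, grid$n_theta,
                        hybrid$shed_rate, hybrid$shed_base,
                        hybrid$front_alpha, params$c0, f0, grid$R,
                        nrow(agents), hybrid$max_agents)
  if (res$front_j < 0 || length(res$j) == 0) return(agents)
  add <- make_agents(res$j, res$k)
  add$id <- seq_len(nrow(add)) + if (nrow(agents)) max(agents$id) else 0L
  rbind(agents, add)
}

#' Agent radii in cm
#'
#' @param agents [make_agents()]
#' @param grid [hdc_grid()]
#' @return numeric vector of radial positions `(j + 1/2) * dr`
#' @export
agent_radius <- function(agents, grid) {
  (agents$j + 0.5) * grid$R / grid$n_r
}
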