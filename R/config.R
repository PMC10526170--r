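#' Model parameters of the hybrid discrete-continuum tumoroid model
#'
#' Constructs the full parameter set of the continuum reaction-diffusion
#' system and the discrete cell walk. Defaults are the published HDC
#' parameter table for a glioblastoma tumoroid invading fibril collagen:
#' cell diffusivity `1e-8`, nutrient diffusivity `4.2e-6` and collagenase
#' diffusivity `1e-9` cm^2/s, haptotaxis coefficient `2.6e3` cm^2/(s M),
#' collagenase binding rate `1e-6` and collagen degradation rate `1e-2`
#' 1/(s M), critical stress 1 kPa with a 5 kPa packing maximum, and an
#' initial cell concentration scale of `1e4` mg/mL.
#'
#' The proliferation and consumption rates are Monod-type closures:
#' per-capita growth `eta_max * n/(n_half + n)` gated off where the
#' packing-stress proxy `p_max * Cp/cp_packing` reaches `p_cr`, and
#' nutrient consumption `(Cp/c0) * lambda_max * n^2/(n_half + n)`.
#'
#' @param d_i cell random-motility diffusivity (cm^2/s)
#' @param d_n nutrient diffusivity (cm^2/s)
#' @param d_m collagenase diffusivity (cm^2/s)
#' @param chi_hap haptotaxis coefficient (cm^2 s^-1 M^-1)
#' @param chi_chem chemotaxis coefficient toward nutrient
#'   (cm^2 s^-1 (mg/mL)^-1); 0 disables chemotaxis
#' @param zeta collagenase binding rate (s^-1 M^-1)
#' @param delta collagen degradation rate (s^-1 M^-1)
#' @param eta_max maximal per-capita proliferation rate (s^-1)
#' @param n_half nutrient half-saturation (mg/mL)
#' @param lambda_max maximal nutrient consumption rate per unit cell
#'   fraction (s^-1)
#' @param p_cr critical mechanical stress above which proliferation stops
#'   (kPa)
#' @param p_max stress at full cell packing (kPa)
#' @param c0 reference (initial tumoroid) cell concentration (mg/mL)
#' @param cp_packing cell concentration at full packing (mg/mL)
#' @param molar_mass collagenase molar mass used by [dose_to_molar()]
#'   (g/mol; default a typical MMP1 of 55 kDa)
#' @return an object of class `hdc_params` (named list)
#' @export
hdc_params <- function(d_i = 1e-8, d_n = 4.2e-6, d_m = 1e-9,
                       chi_hap = 2.6e3, chi_chem = 0,
                       zeta = 1e-6, delta = 1e-2,
                       eta_max = 1 / 24 / 3600, n_half = 1,
                       lambda_max = 3e-6,
                       p_cr = 1, p_max = 5,
                       c0 = 1e4, cp_packing = 2e4,
                       molar_mass = 55000) {
  obj <- structure(list(
    d_i = d_i, d_n = d_n, d_m = d_m, chi_hap = chi_hap,
    chi_chem = chi_chem, zeta = zeta, delta = delta, eta_max = eta_max,
    n_half = n_half, lambda_max = lambda_max, p_cr = p_cr, p_max = p_max,
    c0 = c0, cp_packing = cp_packing, molar_mass = molar_mass
  ), class = "hdc_params")
  validate_params(obj)
  obj
}

#' Boundary conditions at the outer ring of the chamber
#'
#' Dirichlet values applied at the outer domain boundary: nutrient held at
#' the medium concentration `n0`, collagenase at the channel-supplied
#' value `m0` (in molar units; use [dose_to_molar()] to convert a dose in
#' mg/mL), and the cell value `c_bc`. By default `c_bc = 0`: cells that
#' reach the perfusion channel leave the matrix, so the boundary is
#' absorbing for the cell field; set `cell_bc = "zero_flux"` for a closed
#' (mass-conserving) domain instead.
#'
#' @param c_bc cell concentration at the outer boundary (mg/mL)
#' @param n0 nutrient supply concentration (mg/mL)
#' @param m0 collagenase boundary concentration (M)
#' @param cell_bc `"dirichlet"` or `"zero_flux"` for the cell field
#' @return an object of class `hdc_boundary`
#' @export
hdc_boundary <- function(c_bc = 0, n0 = 4.5, m0 = 0,
                         cell_bc = c("dirichlet", "zero_flux")) {
  cell_bc <- match.arg(cell_bc)
  obj <- structure(list(c_bc = c_bc, n0 = n0, m0 = m0, cell_bc = cell_bc),
                   class = "hdc_boundary")
  validate_boundary(obj)
  obj
}

#' Initial conditions of a tumoroid embedded in collagen
#'
#' The tumoroid starts as a disc of radius `r_tumoroid` at concentration
#' `c_i` (edge smoothed over roughly one grid cell), nutrient is uniform
#' at `n_i`, collagen uniform at `f0`, and collagenase is identically
#' zero at t = 0 (it only enters through the boundary).
#'
#' @param c_i initial tumoroid cell concentration (mg/mL)
#' @param n_i initial nutrient concentration (mg/mL)
#' @param f0 initial collagen fiber concentration (M)
#' @param r_tumoroid initial tumoroid radius (cm)
#' @return an object of class `hdc_initial`
#' @export
hdc_initial <- function(c_i = 1e4, n_i = 4.5, f0 = 1e-9, r_tumoroid = 0.03) {
  obj <- structure(list(c_i = c_i, n_i = n_i, f0 = f0,
                        r_tumoroid = r_tumoroid, m_init = 0),
                   class = "hdc_initial")
  validate_initial(obj)
  obj
}

#' Polar grid and time discretization
#'
#' Cell-centred radial nodes `r_j = (j + 1/2) * dr` with `dr = R/n_r`
#' avoid a node at the coordinate singularity and make the finite-volume
#' update exactly conservative. `dt = NULL` picks the largest stable
#' explicit step, `safety * h^2 / (4 * max(D))` with `h` the smallest
#' physical cell extent (`dr` when axisymmetric, else `min(dr,
#' r_min*dtheta)`).
#'
#' @param R outer domain radius (cm)
#' @param n_r radial node count (>= 16)
#' @param n_theta angular node count for the full 2-D solver and for the
#'   agent lattice
#' @param dt time step (s), or `NULL` to use the stability bound
#' @param t_end total simulated time (s)
#' @param axisymmetric collapse the continuum fields to one angular node
#' @param safety fraction of the stability bound used when `dt` is `NULL`
#' @return an object of class `hdc_grid`
#' @export
hdc_grid <- function(R = 0.32, n_r = 96, n_theta = 64, dt = NULL,
                     t_end = 3 * 86400, axisymmetric = TRUE, safety = 0.9) {
  obj <- structure(list(R = R, n_r = as.integer(n_r),
                        n_theta = as.integer(n_theta), dt = dt,
                        t_end = t_end, axisymmetric = axisymmetric,
                        safety = safety),
                   class = "hdc_grid")
  obj
}

#' Hybrid-coupling settings: shedding, stride and snapshot cadence
#'
#' Individual invading cells are shed from the invasive front region
#' (ring front outward) with per-node probability
#' `shed_rate * (Cp/c0) * (shed_base + |grad f|/f0 * R)` at every
#' coupling event (capped at 1), so the expected number of invading
#' cells scales with the local collagen gradient created by the enzyme
#' and with the leading-edge cell density. `agent_stride` continuum
#' steps are taken between successive agent updates; the walk uses the
#' accumulated time as its step.
#'
#' @param shed_rate shedding intensity (expected spawns per front node per
#'   coupling event, per unit normalized drive)
#' @param shed_base gradient-independent baseline drive (dimensionless;
#'   default 0: fingers form only where the matrix is perturbed)
#' @param max_agents cap on the total number of discrete cells
#' @param agent_stride continuum steps per coupling event
#' @param snapshots_per_day snapshot/metrics cadence
#' @param front_alpha ring-front threshold fraction (see
#'   [ring_front_radius()])
#' @param pattern_margin finger/ring labelling margin as a fraction of the
#'   initial front radius
#' @param seed root random seed for a run
#' @return an object of class `hdc_hybrid`
#' @export
hdc_hybrid <- function(shed_rate = 600, shed_base = 0, max_agents = 2000,
                       agent_stride = 100, snapshots_per_day = 4,
                       front_alpha = 0.05, pattern_margin = 0.1, seed = 1L) {
  structure(list(shed_rate = shed_rate, shed_base = shed_base,
                 max_agents = as.integer(max_agents),
                 agent_stride = as.integer(agent_stride),
                 snapshots_per_day = snapshots_per_day,
                 front_alpha = front_alpha, pattern_margin = pattern_margin,
                 seed = as.integer(seed)),
            class = "hdc_hybrid")
}

#' Assemble a full model configuration
#'
#' @param params [hdc_params()]
#' @param boundary [hdc_boundary()]
#' @param initial [hdc_initial()]
#' @param grid [hdc_grid()]
#' @param hybrid [hdc_hybrid()]
#' @param synth [synth_spec()]
#' @return an object of class `hdc_config`
#' @export
hdc_config <- function(params = hdc_params(), boundary = hdc_boundary(),
                       initial = hdc_initial(), grid = hdc_grid(),
                       hybrid = hdc_hybrid(), synth = synth_spec()) {
  cfg <- structure(list(params = params, boundary = boundary,
                        initial = initial, grid = grid, hybrid = hybrid,
                        synth = synth),
                   class = "hdc_config")
  validate_config(cfg)
  cfg
}

fail_if <- function(cond, msg, errs) if (isTRUE(cond)) c(errs, msg) else errs

validate_params <- function(p) {
  e <- character()
  for (nm in c("d_i", "d_n", "d_m"))
    e <- fail_if(!is.numeric(p[[nm]]) || p[[nm]] <= 0,
                 sprintf("%s: diffusivity must be > 0", nm), e)
  for (nm in c("chi_hap", "chi_chem", "zeta", "delta", "eta_max",
               "lambda_max"))
    e <- fail_if(!is.numeric(p[[nm]]) || p[[nm]] < 0,
                 sprintf("%s: rate must be >= 0", nm), e)
  e <- fail_if(!is.numeric(p$n_half) || p$n_half <= 0,
               "n_half: must be > 0", e)
  e <- fail_if(!(p$p_cr < p$p_max), "p_cr: must be below p_max", e)
  e <- fail_if(p$c0 <= 0, "c0: must be > 0", e)
  e <- fail_if(p$cp_packing <= 0, "cp_packing: must be > 0", e)
  e <- fail_if(p$molar_mass <= 0, "molar_mass: must be > 0", e)
  if (length(e)) stop("invalid parameters:\n  ", paste(e, collapse = "\n  "),
                      call. = FALSE)
  invisible(p)
}

validate_boundary <- function(b) {
  e <- character()
  e <- fail_if(b$n0 <= 0, "n0: must be > 0", e)
  e <- fail_if(b$m0 < 0, "m0: must be >= 0", e)
  e <- fail_if(b$c_bc < 0, "c_bc: must be >= 0", e)
  if (length(e)) stop("invalid boundary conditions:\n  ",
                      paste(e, collapse = "\n  "), call. = FALSE)
  invisible(b)
}

validate_initial <- function(ic) {
  e <- character()
  e <- fail_if(ic$f0 <= 0, "f0: must be > 0", e)
  e <- fail_if(ic$c_i < 0, "c_i: must be >= 0", e)
  e <- fail_if(ic$n_i < 0, "n_i: must be >= 0", e)
  e <- fail_if(ic$m_init != 0, "m_init: collagenase must start at 0", e)
  e <- fail_if(ic$r_tumoroid <= 0, "r_tumoroid: must be > 0", e)
  if (length(e)) stop("invalid initial conditions:\n  ",
                      paste(e, collapse = "\n  "), call. = FALSE)
  invisible(ic)
}

#' Largest stable explicit time step for a grid/parameter pair
#'
#' @param grid [hdc_grid()]
#' @param params [hdc_params()]
#' @return the bound `safety * h^2 / (4 * max(d_i, d_n, d_m))` in seconds
#' @export
stability_dt <- function(grid, params) {
  dr <- grid$R / grid$n_r
  h <- dr
  if (!grid$axisymmetric) {
    dtheta <- 2 * pi / grid$n_theta
    h <- min(dr, 0.5 * dr * dtheta)  # innermost node radius is dr/2
  }
  grid$safety * h^2 / (4 * max(params$d_i, params$d_n, params$d_m))
}

#' Validate a full configuration, collecting all violations
#'
#' @param cfg [hdc_config()]
#' @param params optional parameters to check the grid against (defaults
#'   to `cfg$params`)
#' @return `cfg`, invisibly; errors list every offending key at once
#' @export
validate_config <- function(cfg, params = cfg$params) {
  validate_params(cfg$params)
  validate_boundary(cfg$boundary)
  validate_initial(cfg$initial)
  g <- cfg$grid
  e <- character()
  e <- fail_if(g$R <= 0, "grid.R: must be > 0", e)
  e <- fail_if(g$n_r < 16, "grid.n_r: must be >= 16", e)
  e <- fail_if(g$n_theta < 1, "grid.n_theta: must be >= 1", e)
  e <- fail_if(g$t_end <= 0, "grid.t_end: must be > 0", e)
  e <- fail_if(g$safety <= 0 || g$safety > 0.9,
               "grid.safety: must lie in (0, 0.9]", e)
  e <- fail_if(cfg$initial$r_tumoroid >= g$R,
               "initial.r_tumoroid: must be below grid.R", e)
  if (!is.null(g$dt)) {
    e <- fail_if(g$dt <= 0, "grid.dt: must be > 0", e)
    bound <- stability_dt(g, params)
    e <- fail_if(is.null(g$dt) || g$dt > bound,
                 sprintf("grid.dt: %.6g exceeds the stability bound %.6g",
                         g$dt, bound), e)
  }
  if (length(e)) stop("invalid configuration:\n  ",
                      paste(e, collapse = "\n  "), call. = FALSE)
  invisible(cfg)
}

#' Convert a collagenase dose to molar concentration
#'
#' The chip experiment states doses in mg/mL while the enzyme field of
#' the PDE system is in molar units; `dose/molar_mass` maps between them
#' (1 mg/mL = 1 g/L).
#'
#' @param dose mass concentration (mg/mL)
#' @param molar_mass enzyme molar mass (g/mol)
#' @return molar concentration (mol/L)
#' @examples
#' dose_to_molar(0.01)  # 1.818e-7 M at the default 55 kDa
#' @export
dose_to_molar <- function(dose, molar_mass = 55000) {
  if (any(dose < 0)) stop("dose: must be >= 0", call. = FALSE)
  if (any(molar_mass <= 0)) stop("molar_mass: must be > 0", call. = FALSE)
  dose / molar_mass
}
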